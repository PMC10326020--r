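#' Shuffle an omics layer to break cross-analyte structure
#'
#' The default (`"within_row"`) permutes each row's values independently
#' across columns: every analyte keeps its marginal distribution (and hence
#' its variance, so a variance filter retains the same rows), but the
#' alignment between analytes — exactly the structure the lasso exploits —
#' is destroyed. `"within_column"` and `"whole_matrix"` granularities are
#' provided for sensitivity checks.
#'
#' @param m An [omics_matrix()].
#' @param seed Integer seed; shuffling is deterministic given the seed.
#' @param granularity `"within_row"`, `"within_column"`, or `"whole_matrix"`.
#' @return The shuffled `omics_matrix` (same dimnames and metadata).
#' @export
shuffle_omics <- function(m, seed,
                          granularity = c("within_row", "within_column", "whole_matrix")) {
  stopifnot(inherits(m, "omics_matrix"))
  granularity <- match.arg(granularity)
  v <- m$values
  # sample.int avoids base sample()'s scalar surprise on length-1 extents
  shuffled <- with_seed(seed, {
    out <- v
    if (granularity == "within_row") {
      for (i in seq_len(nrow(v))) out[i, ] <- v[i, sample.int(ncol(v))]
    } else if (granularity == "within_column") {
      for (j in seq_len(ncol(v))) out[, j] <- v[sample.int(nrow(v)), j]
    } else {
      out[] <- v[sample.int(length(v))]
    }
    out
  })
  omics_matrix(shuffled, m$meta, m$groups)
}

#' Read a known-interaction gene-pair list
#'
#' Tab-separated columns `gene_a`, `gene_b`, `source`. Pairs are unordered;
#' duplicates (in either orientation) are collapsed and self-pairs are
#' rejected unless `allow_self = TRUE`.
#'
#' @param path TSV path.
#' @param allow_self Keep gene-with-itself pairs?
#' @return A tibble with columns `gene_a`, `gene_b`, `source`.
#' @export
read_interaction_list <- function(path, allow_self = FALSE) {
  tbl <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  stopifnot(all(c("gene_a", "gene_b") %in% names(tbl)))
  if (!allow_self && any(tbl$gene_a == tbl$gene_b)) {
    abort("Self-pairs present; pass `allow_self = TRUE` to keep them.")
  }
  key <- pair_key(tbl$gene_a, tbl$gene_b)
  tibble::as_tibble(tbl[!duplicated(key), ])
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Count consensus associations hitting known gene pairs
#'
#' Maps each retained association's analytes to gene symbols and counts
#' how many fall on a known (literature) gene pair, order-ignored. Counting
#' is per association entry: several analyte pairs hitting the same known
#' gene pair each count; the number of distinct known gene pairs hit is
#' attached as attribute `n_unique_pairs`.
#'
#' @param rlcm An [build_rlcm()] result.
#' @param known Data frame of unordered known pairs (`gene_a`, `gene_b`).
#' @param meta Analyte metadata (`analyte_id`, `gene_symbol`, `assay`).
#' @return Integer count (with attribute `n_unique_pairs`).
#' @export
count_known_overlap <- function(rlcm, known, meta) {
  stopifnot(inherits(rlcm, "rlcm"))
  if (!nrow(rlcm) || !nrow(known)) {
    return(structure(0L, n_unique_pairs = 0L))
  }
  meta <- tibble::as_tibble(meta)
  hit <- pair_key(
    lookup_gene(rlcm$y_analyte, meta),
    lookup_gene(rlcm$x_analyte, meta)
  ) %in% pair_key(known$gene_a, known$gene_b)
  structure(
    sum(hit),
    n_unique_pairs = length(unique(pair_key(
      lookup_gene(rlcm$y_analyte, meta),
      lookup_gene(rlcm$x_analyte, meta)
    )[hit]))
  )
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Returns the sup-norm distance between the empirical CDFs of two samples,
#' \eqn{D = \sup_x |F_a(x) - F_b(x)|}, together with the classical
#' asymptotic p-value (small-sample corrected Kolmogorov series). Large D
#' on per-replicate coefficient counts is the evidence that real inputs
#' carry more linear structure than shuffled ones.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `statistic` (D in \[0, 1\]) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) abort("Both samples must be non-empty.")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  sa <- sort(a)
  sb <- sort(b)
  x <- sort(unique(c(sa, sb)))
  d <- max(abs(
    findInterval(x, sa) / length(sa) - findInterval(x, sb) / length(sb)
  ))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  lam <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d
  j <- seq_len(101)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))
  list(statistic = d, p_value = min(max(p, 0), 1))
}

#' Shuffled-input null experiment
#'
#' Runs matched lasso ensembles on the real paired input and on a shuffled
#' copy, and compares the per-replicate numbers of non-zero coefficients by
#' the two-sample KS distance. In `"post_selection"` mode the given pair is
#' taken as already variance-filtered and both arms are shuffled/used as
#' is; in `"pre_selection"` mode the pair is raw and each arm is
#' variance-filtered (with `variance_fractions`) after shuffling. Both arms
#' are then centered/normalized by [preprocess_pair()] and run with
#' identical settings and matched seeds.
#'
#' @inheritParams run_lasso_ensemble
#' @param mode `"post_selection"` or `"pre_selection"`.
#' @param variance_fractions Length-2 fractions (left, right) used in
#'   `"pre_selection"` mode.
#' @param min_frequency Consensus cutoff for the reported RLCM sizes.
#' @param granularity Passed to [shuffle_omics()].
#' @return A `null_comparison`: per-replicate non-zero counts for both
#'   arms, both RLCM sizes, and the KS statistic and p-value.
#' @export
null_experiment <- function(pair, cfg = lasso_config(), n_replicates = 50L,
                            master_seed = 1L,
                            mode = c("post_selection", "pre_selection"),
                            variance_fractions = c(1, 1),
                            min_frequency = 0.5,
                            granularity = "within_row") {
  stopifnot(inherits(pair, "paired_input"))
  mode <- match.arg(mode)
  shuffled <- paired_input(
    shuffle_omics(pair$left, derive_seed(master_seed, 10001L), granularity),
    shuffle_omics(pair$right, derive_seed(master_seed, 10002L), granularity)
  )
  prepare <- function(p) {
    if (mode == "pre_selection") {
      p <- paired_input(
        variance_filter(p$left, variance_fractions[1L]),
        variance_filter(p$right, variance_fractions[2L])
      )
    }
    preprocess_pair(p)
  }
  run <- function(p) {
    run_lasso_ensemble(prepare(p), cfg, n_replicates, master_seed)
  }
  real <- run(pair)
  null <- run(shuffled)
  ks <- ks_two_sample(real$per_replicate_nonzero, null$per_replicate_nonzero)
  structure(
    list(
      real_counts = real$per_replicate_nonzero,
      shuffled_counts = null$per_replicate_nonzero,
      rlcm_size_real = nrow(build_rlcm(real, min_frequency)),
      rlcm_size_shuffled = nrow(build_rlcm(null, min_frequency)),
      ks_statistic = ks$statistic,
      ks_p_value = ks$p_value,
      mode = mode
    ),
    class = "null_comparison"
  )
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(
    "<null_comparison> (%s)\nmean non-zero per replicate: real %.1f, shuffled %.1f\nRLCM size: real %d, shuffled %d\nKS D = %.3f (p = %.3g)\n",
    x$mode, mean(x$real_counts), mean(x$shuffled_counts),
    x$rlcm_size_real, x$rlcm_size_shuffled, x$ks_statistic, x$ks_p_value
  ))
  invisible(x)
}

#' @method glance null_comparison
#' @export
glance.null_comparison <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    mean_real = mean(x$real_counts),
    mean_shuffled = mean(x$shuffled_counts),
    rlcm_size_real = x$rlcm_size_real,
    rlcm_size_shuffled = x$rlcm_size_shuffled,
    ks_statistic = x$ks_statistic,
    ks_p_value = x$ks_p_value
  )
}

#' @method autoplot null_comparison
#' @export
autoplot.null_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(arm = "real", count = object$real_counts),
    tibble::tibble(arm = "shuffled", count = object$shuffled_counts)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, colour = .data$arm)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(
      x = "non-zero coefficients per replicate", y = "ECDF",
      title = sprintf(
        "Real vs shuffled inputs (KS D = %.3f)", object$ks_statistic
      )
    )
}
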