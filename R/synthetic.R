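#' Specify a synthetic paired-omics dataset
#'
#' The generator emulates the statistical structure the integration
#' pipeline assumes: a predictor layer `X` of independent standard-normal
#' analyte profiles, and a response layer `Y = B X + noise` whose sparse
#' coefficient matrix `B` plants a known set of cross-layer linear
#' associations. Optional group blocks plant extra entries whose effect is
#' active only on one condition group's columns — the ground truth for
#' leave-one-group-out recovery. Analytes carry synthetic gene symbols,
#' with response analytes mapped onto the predictor layer's gene universe
#' so several analytes can share a gene (exercising node coalescing and
#' self-edges downstream).
#'
#' Defaults describe the standard desk-scale benchmark: 20 response
#' analytes, 50 predictors, 24 conditions in 6 groups of 4 (ligand-by-time
#' style), 30 planted associations with magnitudes in 0.8–1.2 and noise
#' standard deviation 0.1.
#'
#' @param n_y,n_x Response / predictor layer sizes.
#' @param n_conditions Number of condition columns.
#' @param n_groups Number of equal contiguous condition groups
#'   (`G1`, `G2`, ...).
#' @param sparsity Number of globally active entries of `B`.
#' @param effect_range Magnitude range of non-zero entries (signs random).
#' @param noise_sd Gaussian noise standard deviation on `Y`.
#' @param group_blocks List of `list(group =, n_entries =)` planting
#'   group-restricted entries (disjoint from the global support).
#' @param block_activity Scale factor applied to each block predictor's
#'   values on its active group's columns, making it group-responsive
#'   (see Details).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `synthetic_spec` list.
#'
#' @details Group blocks model context-specific regulation the way it
#' arises in ligand-response data: the predictor analyte itself responds in
#' the active conditions (its values there are scaled by `block_activity`),
#' and a dedicated response analyte — one without global associations — is
#' coupled to it on those columns only. Without the activity scaling, a
#' group-restricted effect's visibility in the all-conditions run would be
#' governed by how much of the predictor's energy happens to fall in the
#' few active columns, i.e. by chance.
#' @export
synthetic_spec <- function(n_y = 20L, n_x = 50L, n_conditions = 24L,
                           n_groups = 6L, sparsity = 30L,
                           effect_range = c(0.8, 1.2), noise_sd = 0.1,
                           group_blocks = list(), block_activity = 3,
                           seed = 1L) {
  stopifnot(
    n_y >= 1L, n_x >= 1L, n_conditions >= 2L,
    n_groups >= 1L, n_groups <= n_conditions,
    sparsity >= 0L, sparsity <= n_y * n_x,
    length(effect_range) == 2L, all(effect_range > 0),
    diff(effect_range) >= 0, noise_sd >= 0, block_activity > 0
  )
  structure(
    list(
      n_y = as.integer(n_y), n_x = as.integer(n_x),
      n_conditions = as.integer(n_conditions), n_groups = as.integer(n_groups),
      sparsity = as.integer(sparsity), effect_range = effect_range,
      noise_sd = noise_sd, group_blocks = group_blocks,
      block_activity = block_activity, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic paired input with known truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `pair` (a raw [paired_input()], response layer tagged
#'   rppa, predictor layer rnaseq), `true_b` (tibble of globally active
#'   entries: `y_analyte`, `x_analyte`, `value`), `true_blocks` (tibble of
#'   group-restricted entries with their active `group`), and `meta` (the
#'   combined analyte metadata of both layers).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    y_ids <- sprintf("P_%03d", seq_len(spec$n_y))
    x_ids <- sprintf("T_%04d", seq_len(spec$n_x))
    cond_ids <- sprintf("c%02d", seq_len(spec$n_conditions))
    group_of <- sort(rep_len(seq_len(spec$n_groups), spec$n_conditions))
    groups <- tibble::tibble(
      condition_id = cond_ids,
      group = sprintf("G%d", group_of)
    )
    genes <- sprintf("GENE%04d", seq_len(spec$n_x))
    x_meta <- tibble::tibble(
      analyte_id = x_ids, gene_symbol = genes, assay = "rnaseq"
    )
    y_meta <- tibble::tibble(
      analyte_id = y_ids,
      gene_symbol = sample(genes, spec$n_y, replace = TRUE),
      assay = "rppa"
    )

    X <- matrix(rnorm(spec$n_x * spec$n_conditions), spec$n_x,
      dimnames = list(x_ids, cond_ids)
    )
    cells <- sample.int(spec$n_y * spec$n_x, spec$sparsity)
    B <- matrix(0, spec$n_y, spec$n_x, dimnames = list(y_ids, x_ids))
    B[cells] <- sample(c(-1, 1), spec$sparsity, replace = TRUE) *
      runif(spec$sparsity, spec$effect_range[1L], spec$effect_range[2L])

    # block entries: dedicated response rows (no global associations) and
    # distinct group-responsive predictors, disjoint from the global support
    idx0 <- arrayInd(cells, c(spec$n_y, spec$n_x))
    free_rows <- setdiff(y_ids, y_ids[idx0[, 1L]])
    free_x <- x_ids
    blocks <- purrr::map_dfr(spec$group_blocks, function(blk) {
      stopifnot(blk$group %in% groups$group, blk$n_entries >= 1L)
      if (length(free_rows) < blk$n_entries) {
        abort("Not enough response rows without global associations for the group blocks.")
      }
      rows <- sample(free_rows, blk$n_entries)
      free_rows <<- setdiff(free_rows, rows)
      xs <- sample(free_x, blk$n_entries)
      free_x <<- setdiff(free_x, xs)
      tibble::tibble(
        y_analyte = rows,
        x_analyte = xs,
        value = sample(c(-1, 1), blk$n_entries, replace = TRUE) *
          runif(blk$n_entries, spec$effect_range[1L], spec$effect_range[2L]),
        group = blk$group
      )
    })
    if (nrow(blocks)) {
      for (i in seq_len(nrow(blocks))) {
        cols <- groups$group == blocks$group[i]
        X[blocks$x_analyte[i], cols] <- spec$block_activity *
          X[blocks$x_analyte[i], cols]
      }
    }

    Y <- B %*% X
    if (nrow(blocks)) {
      for (i in seq_len(nrow(blocks))) {
        cols <- groups$group == blocks$group[i]
        Y[blocks$y_analyte[i], cols] <- Y[blocks$y_analyte[i], cols] +
          blocks$value[i] * X[blocks$x_analyte[i], cols]
      }
    }
    Y <- Y + spec$noise_sd * matrix(rnorm(length(Y)), nrow(Y))

    idx <- arrayInd(cells, c(spec$n_y, spec$n_x))
    true_b <- dplyr::arrange(
      tibble::tibble(
        y_analyte = y_ids[idx[, 1L]],
        x_analyte = x_ids[idx[, 2L]],
        value = B[cells]
      ),
      .data$y_analyte, .data$x_analyte
    )
    list(
      pair = paired_input(
        omics_matrix(Y, y_meta, groups),
        omics_matrix(X, x_meta, groups)
      ),
      true_b = true_b,
      true_blocks = blocks,
      meta = dplyr::bind_rows(y_meta, x_meta)
    )
  })
}

#' Support-recovery score of a consensus matrix against planted truth
#'
#' Compares the set of retained (y, x) association entries with the planted
#' support. Precision is 0 (by convention) when nothing was inferred; F1 is
#' the harmonic mean, 0 when precision and recall are both 0.
#'
#' @param rlcm An [build_rlcm()] result.
#' @param truth Data frame of true entries (`y_analyte`, `x_analyte`).
#' @param coef_threshold Score only retained entries with
#'   `abs(coefficient) > coef_threshold`; 0 scores the raw consensus
#'   support, [ian_threshold()]`("comparison")` scores the association set
#'   used for quantitative network comparisons.
#' @return A `recovery_score` tibble: precision, recall, f1, n_inferred,
#'   n_true.
#' @export
score_recovery <- function(rlcm, truth, coef_threshold = 0) {
  stopifnot(inherits(rlcm, "rlcm"), is.data.frame(truth))
  rlcm <- rlcm[abs(rlcm$coefficient) > coef_threshold, ]
  inferred <- paste(rlcm$y_analyte, rlcm$x_analyte, sep = "\r")
  true_keys <- unique(paste(truth$y_analyte, truth$x_analyte, sep = "\r"))
  tp <- sum(inferred %in% true_keys)
  precision <- if (length(inferred)) tp / length(inferred) else 0
  recall <- if (length(true_keys)) tp / length(true_keys) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  structure(
    tibble::tibble(
      precision = precision, recall = recall, f1 = f1,
      n_inferred = length(inferred), n_true = length(true_keys)
    ),
    class = c("recovery_score", class(tibble::tibble()))
  )
}
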