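#' Keep the most variant analytes of a layer
#'
#' Retains the `ceiling(fraction * R)` rows with the largest raw sample
#' variance across conditions, a standard pre-filter that focuses the
#' association inference on analytes that actually respond to the
#' experimental conditions. Typical fractions are 0.10 for transcriptomic
#' and chromatin-accessibility layers and 0.20 for the (smaller) targeted
#' proteomic layer. Ties are broken by input order, and the surviving rows
#' keep their original relative order.
#'
#' @param m An [omics_matrix()].
#' @param fraction Fraction of rows to retain, in (0, 1].
#' @return The filtered `omics_matrix`, with a `filter_report` attribute
#'   (tibble: n_input_rows, n_retained_rows, variance_fraction).
#' @export
variance_filter <- function(m, fraction) {
  stopifnot(inherits(m, "omics_matrix"))
  assert_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1].")
  }
  r <- nrow(m$values)
  keep_n <- as.integer(ceiling(fraction * r))
  v <- apply(m$values, 1L, var)
  # stable: order() breaks variance ties by row position
  keep <- sort(order(-v)[seq_len(keep_n)])
  out <- omics_matrix(
    m$values[keep, , drop = FALSE],
    m$meta[m$meta$analyte_id %in% rownames(m$values)[keep], ],
    m$groups
  )
  attr(out, "filter_report") <- tibble::tibble(
    n_input_rows = r,
    n_retained_rows = keep_n,
    variance_fraction = fraction
  )
  out
}

center_normalize <- function(values, tol = 1e-10) {
  stopifnot(ncol(values) >= 2L)
  v <- sweep(values, 2L, colMeans(values))
  v <- sweep(v, 1L, rowMeans(v))
  norms <- sqrt(rowSums(v^2))
  dropped <- rownames(v)[norms < tol]
  keep <- norms >= tol
  list(values = v[keep, , drop = FALSE] / norms[keep], dropped = dropped)
}

#' Column-center, row-center and row-normalize a pair of layers
#'
#' Each matrix is, in this order: column-centered, row-centered, and scaled
#' so every row has unit Euclidean norm. This removes per-condition and
#' per-analyte offsets and magnitude differences so the lasso compares the
#' *shape* of each analyte's response across conditions rather than its
#' scale, and drives the per-row regression offsets toward zero. Rows whose
#' norm collapses below `tol` after the two centering steps (e.g. rows that
#' are constant offsets of the column means) would normalize to NaN; they
#' are removed and reported instead.
#'
#' @param pair A [paired_input()]. Matrices must have at least 2 columns.
#' @param tol Row norms below this value (after centering) mark degenerate
#'   rows to drop.
#' @return A preprocessed `paired_input`; attribute `dropped_rows` lists the
#'   analyte ids removed from each side.
#' @export
preprocess_pair <- function(pair, tol = 1e-10) {
  stopifnot(inherits(pair, "paired_input"))
  if (ncol(pair$left$values) < 2L) {
    abort("Preprocessing needs at least 2 condition columns.")
  }
  one <- function(m) {
    res <- center_normalize(m$values, tol)
    keep <- rownames(res$values)
    list(
      m = omics_matrix(res$values, m$meta[m$meta$analyte_id %in% keep, ], m$groups),
      dropped = res$dropped
    )
  }
  l <- one(pair$left)
  r <- one(pair$right)
  out <- paired_input(l$m, r$m)
  attr(out, "dropped_rows") <- list(left = l$dropped, right = r$dropped)
  out
}

#' Remove one condition group from a paired input
#'
#' Drops every condition column carrying the given group label from both
#' layers, keeping the remaining columns aligned. This is the column
#' exclusion behind each leave-one-group-out (LOGO) run.
#'
#' @param pair A [paired_input()] whose layers carry condition group labels.
#' @param group Group label to remove.
#' @return A `paired_input` without that group's columns.
#' @export
drop_condition_group <- function(pair, group) {
  stopifnot(inherits(pair, "paired_input"))
  groups <- pair$left$groups
  if (is.null(groups)) {
    abort("Paired input has no condition group labels.")
  }
  if (!group %in% groups$group) {
    abort(sprintf("Unknown condition group '%s'.", group))
  }
  keep <- groups$condition_id[groups$group != group]
  if (length(keep) < 2L) {
    abort("Removing this group leaves fewer than 2 condition columns.")
  }
  slice_cols <- function(m) {
    omics_matrix(
      m$values[, keep, drop = FALSE],
      m$meta,
      m$groups[m$groups$condition_id %in% keep, ]
    )
  }
  paired_input(slice_cols(pair$left), slice_cols(pair$right))
}

#' Marker-threshold rules for sample stratification
#'
#' A stratification rule compares one marker analyte's (optionally
#' transformed) value against a threshold, e.g. classifying breast-cancer
#' samples as HER2-amplified when `log2(HER2 + 1) > 7`. Rules are combined
#' conjunctively by [stratify_samples()].
#'
#' @param marker Analyte id of the marker row.
#' @param op Comparison, `"<"` or `">"`.
#' @param threshold Finite numeric threshold.
#' @param transform `"identity"` or `"log2p1"` (log2(x + 1)).
#' @return A `stratification_rule` object.
#' @export
stratification_rule <- function(marker, op, threshold, transform = "identity") {
  op <- match.arg(op, c("<", ">"))
  transform <- match.arg(transform, c("identity", "log2p1"))
  assert_scalar_number(threshold, "threshold")
  structure(
    list(marker = marker, op = op, threshold = threshold, transform = transform),
    class = "stratification_rule"
  )
}

#' Select condition columns satisfying all marker rules
#'
#' @param m An [omics_matrix()] whose columns are samples.
#' @param rules List of [stratification_rule()]s; an empty list selects all
#'   samples (vacuous conjunction).
#' @return Character vector of condition (sample) ids passing every rule.
#' @export
stratify_samples <- function(m, rules) {
  stopifnot(inherits(m, "omics_matrix"))
  keep <- rep(TRUE, ncol(m$values))
  for (rule in rules) {
    stopifnot(inherits(rule, "stratification_rule"))
    if (!rule$marker %in% rownames(m$values)) {
      abort(sprintf("Marker '%s' is not a row of the matrix.", rule$marker))
    }
    x <- m$values[rule$marker, ]
    if (rule$transform == "log2p1") x <- log2(x + 1)
    keep <- keep & if (rule$op == ">") x > rule$threshold else x < rule$threshold
  }
  colnames(m$values)[keep]
}
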