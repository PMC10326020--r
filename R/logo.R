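#' Leave-one-group-out (LOGO) ensemble run
#'
#' Re-runs the full lasso ensemble after removing one condition group's
#' columns from both layers. Comparing the resulting consensus matrix with
#' the all-conditions ("FULL") one isolates the associations whose
#' inference depends on that group's data — e.g. the associations specific
#' to one ligand treatment or one patient subtype.
#'
#' Centering and row normalization are part of every module run, so they
#' are applied *after* the exclusion: `pair` is the raw-scale (typically
#' variance-filtered) pair, and each run — FULL or LOGO — preprocesses the
#' columns it actually uses. This keeps the fitted offsets negligible in
#' the reduced runs too. `run_logo(pair, group = NULL)` performs the FULL
#' run under the identical code path and seed stream.
#'
#' @inheritParams run_lasso_ensemble
#' @param pair A raw-scale [paired_input()]; the run applies
#'   [preprocess_pair()] itself after dropping the held-out columns.
#' @param group Condition group label to hold out (`NULL`: hold out
#'   nothing, i.e. the FULL run).
#' @param min_frequency Consensus cutoff passed to [build_rlcm()].
#' @return An [build_rlcm()] result whose `held_out` attribute records the
#'   excluded group.
#' @export
run_logo <- function(pair, group, cfg = lasso_config(), n_replicates = 100L,
                     master_seed = 1L, provenance = "generic",
                     min_frequency = 0.5) {
  reduced <- if (is.null(group)) pair else drop_condition_group(pair, group)
  ens <- run_lasso_ensemble(
    preprocess_pair(reduced), cfg, n_replicates, master_seed, provenance
  )
  rlcm <- build_rlcm(ens, min_frequency)
  attr(rlcm, "held_out") <- if (is.null(group)) NA_character_ else group
  rlcm
}

#' Group-specific associations from a FULL vs LOGO comparison
#'
#' The associations that depend on a condition group are the symmetric
#' difference of the FULL-data and LOGO supports: entries present only in
#' the FULL consensus (they vanish when the group is removed) and entries
#' present only in the LOGO consensus (they appear only without the group).
#' Entries present in both — even with different coefficients — are not
#' group-dependent and are excluded.
#'
#' @param full RLCM from the all-conditions run.
#' @param logo RLCM from the [run_logo()] run on the same paired input.
#' @return An `association_list` tibble: `y_analyte`, `x_analyte`, `weight`
#'   (the coefficient from whichever run contains the entry), `origin`
#'   (`"full_only"` / `"logo_only"`), `layer_pair`, `group`.
#' @export
logo_associations <- function(full, logo) {
  stopifnot(inherits(full, "rlcm"), inherits(logo, "rlcm"))
  if (!setequal(attr(full, "y_ids"), attr(logo, "y_ids")) ||
    !setequal(attr(full, "x_ids"), attr(logo, "x_ids"))) {
    abort("FULL and LOGO runs come from different analyte universes.")
  }
  key <- function(r) paste(r$y_analyte, r$x_analyte, sep = "\r")
  fk <- key(full)
  lk <- key(logo)
  keep_cols <- c("y_analyte", "x_analyte", "coefficient")
  out <- dplyr::bind_rows(
    dplyr::mutate(
      tibble::as_tibble(full)[!fk %in% lk, keep_cols],
      origin = "full_only"
    ),
    dplyr::mutate(
      tibble::as_tibble(logo)[!lk %in% fk, keep_cols],
      origin = "logo_only"
    )
  )
  out <- dplyr::arrange(
    dplyr::mutate(
      dplyr::rename(out, weight = "coefficient"),
      layer_pair = attr(full, "provenance"),
      group = attr(logo, "held_out")
    ),
    .data$y_analyte, .data$x_analyte
  )
  structure(out, class = c("association_list", class(tibble::tibble())))
}

#' Write a group-specific association list as TSV
#'
#' @param assoc An [logo_associations()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_associations <- function(assoc, path) {
  stopifnot(inherits(assoc, "association_list"))
  lines <- c(
    "y_analyte\tx_analyte\tweight\torigin\tlayer_pair\tgroup",
    sprintf(
      "%s\t%s\t%s\t%s\t%s\t%s", assoc$y_analyte, assoc$x_analyte,
      fmt_num(assoc$weight), assoc$origin, assoc$layer_pair, assoc$group
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}
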