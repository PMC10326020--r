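#' Construct a single omics layer
#'
#' An `omics_matrix` holds one omics assay as a numeric matrix of analytes
#' (rows) by conditions (columns), together with per-analyte metadata (gene
#' symbol and assay type) and optional condition-group labels (e.g. the
#' ligand treatment or patient subtype each sample column belongs to).
#'
#' The integration pipeline works on complete continuous matrices: missing
#' or non-finite values are rejected at construction.
#'
#' @param values Numeric matrix with unique rownames (analyte ids) and unique
#'   colnames (condition ids). All entries must be finite.
#' @param meta Data frame with columns `analyte_id`, `gene_symbol`, `assay`
#'   covering every row of `values`. `assay` must be one of `"rppa"`,
#'   `"rnaseq"`, `"atacseq"`, `"other"`.
#' @param groups Optional data frame with columns `condition_id`, `group`
#'   assigning each condition column to a group label.
#' @return An object of class `omics_matrix`.
#' @examples
#' vals <- matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("a", "b", "c"), c("t24", "t48"))
#' )
#' meta <- tibble::tibble(
#'   analyte_id = c("a", "b", "c"),
#'   gene_symbol = c("G1", "G2", "G1"),
#'   assay = "rnaseq"
#' )
#' omics_matrix(vals, meta)
#' @export
omics_matrix <- function(values, meta, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  ids <- rownames(values)
  conds <- colnames(values)
  if (is.null(ids) && nrow(values) == 0L) {
    ids <- character(0)
    rownames(values) <- ids
  }
  if (is.null(ids) || is.null(conds)) {
    abort("`values` must carry rownames (analyte ids) and colnames (condition ids).")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("Duplicate analyte id(s): %s", toString(dup)))
  }
  dup <- unique(conds[duplicated(conds)])
  if (length(dup)) {
    abort(sprintf("Duplicate condition id(s): %s", toString(dup)))
  }
  if (anyNA(values) || !all(is.finite(values))) {
    abort("`values` must be complete: missing or non-finite entries are not allowed.")
  }
  meta <- validate_meta(meta, ids)
  groups <- validate_groups(groups, conds)
  structure(
    list(values = values, meta = meta, groups = groups),
    class = "omics_matrix"
  )
}

validate_meta <- function(meta, ids) {
  if (!is.data.frame(meta) ||
    !all(c("analyte_id", "gene_symbol", "assay") %in% names(meta))) {
    abort("`meta` must have columns analyte_id, gene_symbol, assay.")
  }
  meta <- tibble::as_tibble(meta)[, c("analyte_id", "gene_symbol", "assay")]
  missing <- setdiff(ids, meta$analyte_id)
  if (length(missing)) {
    abort(sprintf(
      "Analyte(s) missing from metadata: %s",
      toString(head(missing, 5L))
    ))
  }
  bad <- setdiff(unique(meta$assay), c("rppa", "rnaseq", "atacseq", "other"))
  if (length(bad)) {
    abort(sprintf("Unknown assay label(s): %s", toString(bad)))
  }
  if (anyDuplicated(meta$analyte_id)) {
    abort("`meta` has duplicated analyte_id rows.")
  }
  # keep metadata in matrix row order, dropping unreferenced analytes
  meta[match(ids, meta$analyte_id), ]
}

validate_groups <- function(groups, conds) {
  if (is.null(groups)) {
    return(NULL)
  }
  if (!is.data.frame(groups) ||
    !all(c("condition_id", "group") %in% names(groups))) {
    abort("`groups` must have columns condition_id, group.")
  }
  groups <- tibble::as_tibble(groups)[, c("condition_id", "group")]
  missing <- setdiff(conds, groups$condition_id)
  if (length(missing)) {
    abort(sprintf(
      "Condition(s) missing a group label: %s",
      toString(head(missing, 5L))
    ))
  }
  groups[match(conds, groups$condition_id), ]
}

#' @export
print.omics_matrix <- function(x, ...) {
  assays <- toString(unique(x$meta$assay))
  cat(sprintf(
    "<omics_matrix> %d analytes x %d conditions [%s]\n",
    nrow(x$values), ncol(x$values), assays
  ))
  if (!is.null(x$groups)) {
    cat("groups:", toString(unique(x$groups$group)), "\n")
  }
  invisible(x)
}

#' @rdname omics_matrix
#' @param x An `omics_matrix`.
#' @export
analyte_ids <- function(x) rownames(x$values)

#' @rdname omics_matrix
#' @export
condition_ids <- function(x) colnames(x$values)

#' Pair two omics layers for integration
#'
#' The left layer is the response (`Y`) and the right layer the predictor
#' (`X`) of the linear association model `Y = B X + delta`. Both layers must
#' share the same conditions, in the same column order.
#'
#' @param left,right `omics_matrix` objects with identical `condition_ids`.
#' @return An object of class `paired_input`.
#' @export
paired_input <- function(left, right) {
  stopifnot(inherits(left, "omics_matrix"), inherits(right, "omics_matrix"))
  if (!identical(condition_ids(left), condition_ids(right))) {
    abort("`left` and `right` must have identical condition ids, in the same order.")
  }
  structure(list(left = left, right = right), class = "paired_input")
}

#' @export
print.paired_input <- function(x, ...) {
  cat(sprintf(
    "<paired_input> Y: %d analytes, X: %d analytes, %d shared conditions\n",
    nrow(x$left$values), nrow(x$right$values), ncol(x$left$values)
  ))
  invisible(x)
}

#' Read and write omics matrices as TSV
#'
#' The matrix file is tab-delimited with a header row of condition ids and
#' the first column holding analyte ids. The metadata file maps every
#' analyte id to a gene symbol and assay; the optional group file maps every
#' condition id to a group label. Values are written at full precision so a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param path Matrix TSV path.
#' @param meta_path Metadata TSV path (columns analyte_id, gene_symbol, assay).
#' @param groups_path Optional condition-group TSV (columns condition_id, group).
#' @return `read_omics_matrix()` returns an [omics_matrix()];
#'   `write_omics_matrix()` invisibly returns `path`.
#' @export
read_omics_matrix <- function(path, meta_path, groups_path = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(tab) < 2L) {
    abort("Matrix file must have an analyte id column plus at least one condition.")
  }
  ids <- tab[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("Duplicate analyte id(s) in %s: %s", path, toString(dup)))
  }
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (length(bad)) {
    abort(sprintf(
      "Non-numeric value at row '%s', column '%s'.",
      ids[bad[1L, 1L]], colnames(tab)[-1L][bad[1L, 2L]]
    ))
  }
  if (anyNA(num)) {
    abort("Matrix contains missing values; complete matrices are required.")
  }
  dimnames(num) <- list(ids, colnames(tab)[-1L])
  meta <- readr::read_tsv(meta_path, col_types = "ccc", progress = FALSE)
  groups <- if (!is.null(groups_path)) {
    readr::read_tsv(groups_path, col_types = "cc", progress = FALSE)
  }
  omics_matrix(num, meta, groups)
}

#' @rdname read_omics_matrix
#' @param m An `omics_matrix` to write.
#' @export
write_omics_matrix <- function(m, path, meta_path = NULL, groups_path = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  body <- apply(m$values, 2L, fmt_num)
  if (!is.matrix(body)) body <- matrix(body, nrow = 1L)
  lines <- c(
    paste(c("analyte_id", colnames(m$values)), collapse = "\t"),
    apply(cbind(rownames(m$values), body), 1L, paste, collapse = "\t")
  )
  readr::write_lines(lines, path)
  if (!is.null(meta_path)) {
    readr::write_tsv(m$meta, meta_path, progress = FALSE)
  }
  if (!is.null(groups_path) && !is.null(m$groups)) {
    readr::write_tsv(m$groups, groups_path, progress = FALSE)
  }
  invisible(path)
}
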