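#' Read and validate a pipeline run configuration
#'
#' A single YAML file drives the command-line pipeline: input/output paths,
#' per-layer variance fractions (defaults 0.10 for transcriptomic and
#' chromatin layers, 0.20 for proteomic), the lasso settings, the ensemble
#' size, the consensus frequency cutoff (0.5), the network edge thresholds
#' (display 0.01, comparison 0.1), the hold-out groups and one master seed
#' from which every random draw derives.
#'
#' @param path YAML file path; `NULL` gives the defaults.
#' @param overrides Named list merged over the file values.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    paths = list(),
    variance_fractions = list(rppa = 0.20, rnaseq = 0.10, atacseq = 0.10),
    lasso = list(n_folds = 4L, n_lambda = 100L),
    n_replicates = 10000L,
    min_frequency = 0.5,
    thresholds = list(display = 0.01, comparison = 0.1),
    holdout_groups = character(),
    master_seed = 1L
  )
  if (!is.null(path)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, overrides)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  fr <- unlist(cfg$variance_fractions)
  if (any(fr <= 0 | fr > 1)) {
    abort("Variance fractions must lie in (0, 1].")
  }
  if (cfg$min_frequency <= 0 || cfg$min_frequency > 1) {
    abort("`min_frequency` must lie in (0, 1].")
  }
  if (cfg$n_replicates < 1L) abort("`n_replicates` must be >= 1.")
  paths <- unlist(cfg$paths)
  if (anyDuplicated(paths)) {
    abort("All configured paths must be distinct.")
  }
  assert_scalar_number(cfg$master_seed, "master_seed")
  structure(cfg, class = "run_config")
}

#' Write a run manifest for exact reproduction
#'
#' Records the configuration, the derived replicate seeds, package version
#' and MD5 digests of the input files; together with the package this is
#' sufficient to regenerate any artifact byte-identically.
#'
#' @param cfg A [read_run_config()] result.
#' @param path Output JSON path.
#' @param input_paths Character vector of input files to digest.
#' @param seeds Optional seed vector to record.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(cfg, path, input_paths = character(), seeds = NULL) {
  input_paths <- as.character(input_paths)
  existing <- input_paths[file.exists(input_paths)]
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("ianet")),
      config = unclass(cfg),
      seeds = seeds,
      input_digests = as.list(tools::md5sum(existing))
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}
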