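#' Configuration of the per-row cross-validated lasso
#'
#' The association model is fitted one response row at a time by lasso
#' regression, minimizing
#' \deqn{\sum_{i=1}^{C} (Y_{ki} - \sum_j \beta_{kj} X_{ji} - \delta_k)^2 +
#'   \lambda \sum_j |\beta_{kj}|}
#' over the conditions i = 1..C. The penalty weight is chosen per fit as the
#' grid point with minimum k-fold cross-validated mean squared prediction
#' error. Note this objective carries no 1/(2C) factor; the glmnet backend
#' uses that scaling internally, so its penalty is `lambda / (2C)` and all
#' lambdas reported by this package are on the unscaled objective above.
#'
#' @param n_folds Cross-validation folds (default 4).
#' @param n_lambda Length of the automatic geometric lambda path.
#' @param lambda_grid Optional explicit lambda grid (unscaled objective
#'   units); overrides the automatic path.
#' @param thresh,max_iter Coordinate-descent convergence controls passed to
#'   glmnet.
#' @param zero_tol Coefficients with absolute value below this are set to
#'   exactly zero.
#' @return A `lasso_config` list.
#' @export
lasso_config <- function(n_folds = 4L, n_lambda = 100L, lambda_grid = NULL,
                         thresh = 1e-8, max_iter = 1e6, zero_tol = 1e-9) {
  stopifnot(n_folds >= 2L, n_lambda >= 2L, thresh > 0, zero_tol >= 0)
  if (!is.null(lambda_grid) && any(lambda_grid < 0)) {
    abort("`lambda_grid` values must be >= 0.")
  }
  structure(
    list(
      n_folds = as.integer(n_folds), n_lambda = as.integer(n_lambda),
      lambda_grid = lambda_grid, thresh = thresh, max_iter = max_iter,
      zero_tol = zero_tol
    ),
    class = "lasso_config"
  )
}

#' Lasso fit for one response row
#'
#' Fits the penalized regression of one response analyte's profile `y`
#' (length C, conditions as observations) on all predictor analytes (rows
#' of `X`). With `lambda = NULL` the penalty is selected by `n_folds`-fold
#' cross-validation at minimum mean squared prediction error, with the fold
#' assignment drawn from `seed`; with a fixed `lambda` (unscaled objective
#' units, see [lasso_config()]) the solution at that penalty is returned.
#'
#' @param y Numeric response vector, length C.
#' @param X Numeric predictor matrix, analytes (rows) by conditions
#'   (columns); `ncol(X) == length(y)`.
#' @param cfg A [lasso_config()].
#' @param seed Integer seed for the cross-validation fold assignment.
#' @param lambda Optional fixed penalty (skips cross-validation).
#' @return List with `beta` (named, exactly sparse), `delta` (offset) and
#'   `lambda` (the selected penalty, unscaled objective units).
#' @export
fit_lasso_row <- function(y, X, cfg = lasso_config(), seed = 1L, lambda = NULL) {
  if (!all(is.finite(y)) || !all(is.finite(X))) {
    abort("`y` and `X` must be finite.")
  }
  C <- length(y)
  stopifnot(is.matrix(X), ncol(X) == C)
  if (cfg$n_folds > C && is.null(lambda)) {
    abort("`n_folds` cannot exceed the number of conditions.")
  }
  design <- t(X)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(nrow(X)))
  }

  if (!is.null(lambda)) {
    assert_scalar_number(lambda, "lambda")
    if (lambda < 0) abort("`lambda` must be >= 0.")
    fit <- glmnet_fixed(design, y, lambda / (2 * C), cfg)
    beta <- fit$beta
    delta <- fit$delta
    lambda_sel <- lambda
  } else {
    foldid <- with_seed(seed, sample(rep_len(seq_len(cfg$n_folds), C)))
    args <- list(
      x = design, y = y, foldid = foldid, standardize = FALSE,
      grouped = FALSE, thresh = cfg$thresh, maxit = cfg$max_iter
    )
    if (!is.null(cfg$lambda_grid)) {
      args$lambda <- sort(cfg$lambda_grid, decreasing = TRUE) / (2 * C)
    } else {
      args$nlambda <- cfg$n_lambda
    }
    cv <- do.call(glmnet::cv.glmnet, args)
    co <- as.numeric(coef(cv, s = "lambda.min"))
    beta <- co[-1L]
    delta <- co[1L]
    lambda_sel <- cv$lambda.min * 2 * C
  }
  beta[abs(beta) < cfg$zero_tol] <- 0
  names(beta) <- colnames(design)
  list(beta = beta, delta = delta, lambda = lambda_sel)
}

# Solve at one fixed glmnet-scale lambda by warm-starting down a short
# geometric path; glmnet is unreliable when handed a single lambda.
glmnet_fixed <- function(design, y, lam, cfg) {
  C <- nrow(design)
  lmax <- max(abs(crossprod(design, y - mean(y)))) / C
  top <- max(lmax, lam, .Machine$double.eps) * 1.1
  lo <- max(lam, top * 1e-7)
  path <- exp(seq(log(top), log(lo), length.out = 25L))
  path[length(path)] <- lam # exact endpoint (0 allowed)
  path <- sort(unique(path), decreasing = TRUE)
  fit <- glmnet::glmnet(design, y,
    lambda = path, standardize = FALSE,
    thresh = 1e-12, maxit = 1e7
  )
  j <- which.min(abs(fit$lambda - lam)) # exact endpoint of the path
  list(beta = as.numeric(fit$beta[, j]), delta = fit$a0[[j]])
}

#' Replicated lasso ensemble over a paired input
#'
#' Runs the per-row cross-validated lasso for every response analyte and
#' repeats the whole sweep `n_replicates` times, each replicate with a
#' different fold-assignment seed derived deterministically from
#' `master_seed`. Because CV fold assignment is the only stochastic element
#' of the fit, replicate-to-replicate variation in the selected penalty
#' perturbs each solution's support; entries that persist across most
#' replicates are the robust associations extracted by [build_rlcm()].
#'
#' Replicate seeds are counter-derived, so the result is independent of the
#' order in which replicates are evaluated.
#'
#' @param pair A preprocessed [paired_input()] (see [preprocess_pair()]).
#' @param cfg A [lasso_config()].
#' @param n_replicates Number of ensemble replicates (the original analyses
#'   use 10,000; tens to hundreds suffice at desk scale).
#' @param master_seed Integer master seed for the whole ensemble.
#' @param provenance Layer-pair tag, e.g. `"rppa_rnaseq"`.
#' @return A `lasso_ensemble` object: occurrence counts, non-zero sums and
#'   sign counts per matrix cell, per-replicate non-zero totals, seeds.
#' @export
run_lasso_ensemble <- function(pair, cfg = lasso_config(), n_replicates = 100L,
                               master_seed = 1L, provenance = "generic") {
  stopifnot(inherits(pair, "paired_input"))
  if (n_replicates < 1L) abort("`n_replicates` must be >= 1.")
  Y <- pair$left$values
  X <- pair$right$values
  n_y <- nrow(Y)
  n_x <- nrow(X)
  if (n_y < 1L || n_x < 1L) {
    abort("Both layers need at least one analyte row (did preprocessing drop everything?).")
  }
  occurrence <- matrix(0L, n_y, n_x, dimnames = list(rownames(Y), rownames(X)))
  nz_sum <- matrix(0, n_y, n_x, dimnames = dimnames(occurrence))
  n_pos <- matrix(0L, n_y, n_x, dimnames = dimnames(occurrence))
  per_rep_nonzero <- integer(n_replicates)
  seeds <- vapply(seq_len(n_replicates), function(r) {
    derive_seed(master_seed, r)
  }, integer(1))
  max_delta <- 0
  for (r in seq_len(n_replicates)) {
    for (k in seq_len(n_y)) {
      fit <- fit_lasso_row(Y[k, ], X, cfg, seed = derive_seed(seeds[r], k))
      nz <- fit$beta != 0
      occurrence[k, nz] <- occurrence[k, nz] + 1L
      nz_sum[k, nz] <- nz_sum[k, nz] + fit$beta[nz]
      n_pos[k, nz & fit$beta > 0] <- n_pos[k, nz & fit$beta > 0] + 1L
      per_rep_nonzero[r] <- per_rep_nonzero[r] + sum(nz)
      max_delta <- max(max_delta, abs(fit$delta))
    }
  }
  if (max_delta > 1e-6) {
    warn(sprintf(
      "Largest fitted offset is %.3g; offsets should be negligible after preprocessing.",
      max_delta
    ))
  }
  structure(
    list(
      occurrence = occurrence, nonzero_sum = nz_sum, n_positive = n_pos,
      n_replicates = as.integer(n_replicates), seeds = seeds,
      per_replicate_nonzero = per_rep_nonzero, max_abs_delta = max_delta,
      cfg = cfg, provenance = provenance,
      y_ids = rownames(Y), x_ids = rownames(X)
    ),
    class = "lasso_ensemble"
  )
}

#' @export
print.lasso_ensemble <- function(x, ...) {
  cat(sprintf(
    "<lasso_ensemble> %d x %d cells, %d replicates [%s]\n",
    length(x$y_ids), length(x$x_ids), x$n_replicates, x$provenance
  ))
  cat(sprintf(
    "mean non-zero coefficients per replicate: %.1f\n",
    mean(x$per_replicate_nonzero)
  ))
  invisible(x)
}

#' @method tidy lasso_ensemble
#' @export
tidy.lasso_ensemble <- function(x, ...) {
  idx <- which(x$occurrence > 0L, arr.ind = TRUE)
  out <- tibble::tibble(
    y_analyte = x$y_ids[idx[, 1L]],
    x_analyte = x$x_ids[idx[, 2L]],
    occurrence = x$occurrence[idx],
    frequency = x$occurrence[idx] / x$n_replicates,
    nonzero_mean = x$nonzero_sum[idx] / x$occurrence[idx],
    sign_consistency = pmax(x$n_positive[idx], x$occurrence[idx] - x$n_positive[idx]) /
      x$occurrence[idx]
  )
  dplyr::arrange(out, .data$y_analyte, .data$x_analyte)
}

#' @method glance lasso_ensemble
#' @export
glance.lasso_ensemble <- function(x, ...) {
  tibble::tibble(
    n_y = length(x$y_ids), n_x = length(x$x_ids),
    n_replicates = x$n_replicates,
    mean_nonzero_per_replicate = mean(x$per_replicate_nonzero),
    n_cells_ever_selected = sum(x$occurrence > 0L),
    max_abs_delta = x$max_abs_delta,
    provenance = x$provenance
  )
}

#' Consensus of the lasso ensemble: the Robust Lasso Coefficient Matrix
#'
#' A matrix cell is retained when it was inferred non-zero in at least
#' `ceiling(min_frequency * n_replicates)` replicates (default: at least
#' half of them). Its consensus coefficient is the mean over only the
#' replicates in which it was non-zero. The retained entries are the
#' "associations" used by every downstream stage.
#'
#' @param ens A [run_lasso_ensemble()] result.
#' @param min_frequency Minimum selection frequency, in (0, 1].
#' @return An `rlcm`: a tibble with columns `y_analyte`, `x_analyte`,
#'   `coefficient`, `frequency`, `sign_consistency`, carrying the analyte
#'   universes and run provenance as attributes.
#' @export
build_rlcm <- function(ens, min_frequency = 0.5) {
  stopifnot(inherits(ens, "lasso_ensemble"))
  if (min_frequency <= 0 || min_frequency > 1) {
    abort("`min_frequency` must be in (0, 1].")
  }
  need <- as.integer(ceiling(min_frequency * ens$n_replicates))
  idx <- which(ens$occurrence >= need, arr.ind = TRUE)
  occ <- as.numeric(ens$occurrence[idx])
  out <- tibble::tibble(
    y_analyte = as.character(ens$y_ids[idx[, 1L]]),
    x_analyte = as.character(ens$x_ids[idx[, 2L]]),
    coefficient = as.numeric(ens$nonzero_sum[idx]) / pmax(occ, 1),
    frequency = occ / ens$n_replicates,
    sign_consistency = pmax(
      as.numeric(ens$n_positive[idx]), occ - as.numeric(ens$n_positive[idx])
    ) / pmax(occ, 1)
  )
  out <- dplyr::arrange(out, .data$y_analyte, .data$x_analyte)
  new_rlcm(out,
    n_replicates = ens$n_replicates, min_frequency = min_frequency,
    provenance = ens$provenance, held_out = NA_character_,
    y_ids = ens$y_ids, x_ids = ens$x_ids
  )
}

new_rlcm <- function(tbl, n_replicates, min_frequency, provenance, held_out,
                     y_ids, x_ids) {
  structure(
    tbl,
    class = c("rlcm", class(tibble::tibble())),
    n_replicates = n_replicates, min_frequency = min_frequency,
    provenance = provenance, held_out = held_out,
    y_ids = y_ids, x_ids = x_ids
  )
}

#' @export
print.rlcm <- function(x, ...) {
  cat(sprintf(
    "<rlcm> %d robust associations [%s]%s (min frequency %.2f of %d replicates)\n",
    nrow(x), attr(x, "provenance"),
    if (!is.na(attr(x, "held_out"))) {
      sprintf(", held-out group '%s'", attr(x, "held_out"))
    } else {
      ""
    },
    attr(x, "min_frequency"), attr(x, "n_replicates")
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Write / read an RLCM as TSV triplets
#'
#' The TSV holds one retained association per line
#' (`y_analyte, x_analyte, coefficient, frequency`); run provenance
#' (replicates, frequency cutoff, analyte universes, held-out group) goes
#' to a JSON sidecar so a read round trip restores the full object.
#'
#' @param rlcm An [build_rlcm()] result.
#' @param path Output TSV path.
#' @param sidecar_path JSON sidecar path (default: `path` + `.json`).
#' @return `write_rlcm()` invisibly returns `path`; `read_rlcm()` returns
#'   the `rlcm`.
#' @export
write_rlcm <- function(rlcm, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(rlcm, "rlcm"))
  lines <- c(
    "y_analyte\tx_analyte\tcoefficient\tfrequency",
    sprintf(
      "%s\t%s\t%s\t%s", rlcm$y_analyte, rlcm$x_analyte,
      fmt_num(rlcm$coefficient), fmt_num(rlcm$frequency)
    )
  )
  readr::write_lines(lines, path)
  if (!is.null(sidecar_path)) {
    jsonlite::write_json(
      list(
        n_replicates = attr(rlcm, "n_replicates"),
        min_frequency = attr(rlcm, "min_frequency"),
        provenance = attr(rlcm, "provenance"),
        held_out = attr(rlcm, "held_out"),
        y_ids = attr(rlcm, "y_ids"),
        x_ids = attr(rlcm, "x_ids")
      ),
      sidecar_path,
      auto_unbox = TRUE, digits = NA, null = "null", na = "null"
    )
  }
  invisible(path)
}

#' @rdname write_rlcm
#' @export
read_rlcm <- function(path, sidecar_path = paste0(path, ".json")) {
  tbl <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  tbl$coefficient <- as.numeric(tbl$coefficient)
  tbl$frequency <- as.numeric(tbl$frequency)
  tbl$sign_consistency <- NA_real_
  meta <- if (!is.null(sidecar_path) && file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    list()
  }
  new_rlcm(
    tibble::as_tibble(tbl),
    n_replicates = meta$n_replicates %||% NA_integer_,
    min_frequency = meta$min_frequency %||% NA_real_,
    provenance = meta$provenance %||% "generic",
    held_out = meta$held_out %||% NA_character_,
    y_ids = meta$y_ids %||% unique(tbl$y_analyte),
    x_ids = meta$x_ids %||% unique(tbl$x_analyte)
  )
}

#' @method glance rlcm
#' @export
glance.rlcm <- function(x, ...) {
  tibble::tibble(
    n_associations = nrow(x),
    n_replicates = attr(x, "n_replicates"),
    min_frequency = attr(x, "min_frequency"),
    provenance = attr(x, "provenance"),
    held_out = attr(x, "held_out"),
    mean_abs_coefficient = if (nrow(x)) mean(abs(x$coefficient)) else NA_real_
  )
}

#' @method autoplot rlcm
#' @export
autoplot.rlcm <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$frequency, y = .data$coefficient)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "selection frequency across replicates",
      y = "consensus coefficient",
      title = sprintf("Robust associations [%s]", attr(object, "provenance"))
    )
}

#' @method autoplot lasso_ensemble
#' @export
autoplot.lasso_ensemble <- function(object, ...) {
  freq <- object$occurrence[object$occurrence > 0L] / object$n_replicates
  ggplot2::ggplot(
    tibble::tibble(frequency = freq),
    ggplot2::aes(x = .data$frequency)
  ) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "red") +
    ggplot2::labs(
      x = "selection frequency",
      y = "matrix cells",
      title = "Ensemble selection frequencies (cells ever selected)"
    )
}
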