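# Shared fixtures and independent oracles, built in code at test time.

make_meta <- function(ids, genes = NULL, assay = "rnaseq") {
  tibble::tibble(
    analyte_id = ids,
    gene_symbol = genes %||% toupper(ids),
    assay = assay
  )
}

make_omics <- function(values, genes = NULL, assay = "rnaseq", groups = NULL) {
  omics_matrix(values, make_meta(rownames(values), genes, assay), groups)
}

random_omics <- function(n_r, n_c, seed = 1, assay = "rnaseq", groups = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n_r * n_c), n_r, n_c,
    dimnames = list(sprintf("%s_%02d", substr(assay, 1, 1), seq_len(n_r)),
      sprintf("c%02d", seq_len(n_c))
    )
  )
  make_omics(v, assay = assay, groups = groups)
}

# C x p design with orthonormal, mean-zero columns (so the lasso problem
# separates coordinate-wise and the soft-threshold closed form is exact).
orthonormal_centered_design <- function(C, p, seed = 1) {
  set.seed(seed)
  qr.Q(qr(cbind(1, matrix(rnorm(C * p), C))))[, -1, drop = FALSE]
}

# Independent proximal-gradient (ISTA) solver for
#   min_{b, d}  ||y - design b - d||^2 + lambda ||b||_1
# Deliberately shares nothing with the glmnet path.
lasso_ista <- function(y, design, lambda, iters = 60000L) {
  A <- cbind(1, design)
  L <- 2 * max(eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values)
  b <- rep(0, ncol(design))
  d <- 0
  for (i in seq_len(iters)) {
    r <- as.numeric(y - design %*% b - d)
    b <- b + 2 * as.numeric(crossprod(design, r)) / L
    b <- sign(b) * pmax(abs(b) - lambda / L, 0)
    d <- d + 2 * sum(r) / L
  }
  list(beta = b, delta = d)
}

# KKT residual of the same objective at (beta, delta); near-zero iff optimal.
lasso_kkt_violation <- function(y, design, beta, delta, lambda) {
  r <- as.numeric(y - design %*% beta - delta)
  g <- 2 * as.numeric(crossprod(design, r))
  active <- beta != 0
  max(c(
    abs(g[active] - lambda * sign(beta[active])),
    pmax(abs(g[!active]) - lambda, 0),
    abs(sum(r))
  ))
}

# Fabricate a lasso_ensemble with prescribed per-cell occurrence counts and
# non-zero sums, for testing the consensus rule in isolation.
fake_ensemble <- function(occurrence, nonzero_sum, n_replicates,
                          n_positive = NULL) {
  structure(
    list(
      occurrence = occurrence,
      nonzero_sum = nonzero_sum,
      n_positive = n_positive %||% occurrence,
      n_replicates = as.integer(n_replicates),
      seeds = integer(),
      per_replicate_nonzero = integer(n_replicates),
      max_abs_delta = 0,
      cfg = lasso_config(),
      provenance = "generic",
      y_ids = rownames(occurrence),
      x_ids = colnames(occurrence)
    ),
    class = "lasso_ensemble"
  )
}

fake_rlcm <- function(y, x, coefficient, provenance = "generic",
                      held_out = NA_character_,
                      y_ids = unique(y), x_ids = unique(x)) {
  ianet:::new_rlcm(
    tibble::tibble(
      y_analyte = y, x_analyte = x, coefficient = coefficient,
      frequency = 1, sign_consistency = 1
    ),
    n_replicates = 10L, min_frequency = 0.5, provenance = provenance,
    held_out = held_out, y_ids = y_ids, x_ids = x_ids
  )
}

random_ian <- function(seed, n_genes = 6L, n_edges = 10L) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  x_ids <- sprintf("T_%02d", seq_len(n_genes))
  y_ids <- sprintf("P_%02d", seq_len(n_genes))
  meta <- dplyr::bind_rows(
    make_meta(x_ids, genes, "rnaseq"),
    make_meta(y_ids, genes[sample.int(n_genes, n_genes, replace = TRUE)], "rppa")
  )
  rl <- fake_rlcm(
    y = sample(y_ids, n_edges, replace = TRUE),
    x = sample(x_ids, n_edges, replace = TRUE),
    coefficient = runif(n_edges, -1, 1),
    y_ids = y_ids, x_ids = x_ids
  )
  # drop duplicate (y, x) pairs to respect the consensus-matrix invariant
  rl <- rl[!duplicated(paste(rl$y_analyte, rl$x_analyte)), ]
  list(ian = build_ian(rl, meta = meta, threshold = 0.01), meta = meta)
}

# Brute-force per-gene edge summation (the ranking oracle).
rank_oracle <- function(ian, denom) {
  alpha <- stats::setNames(rep(0, nrow(ian$nodes)), ian$nodes$gene)
  for (i in seq_len(nrow(ian$edges))) {
    e <- ian$edges[i, ]
    alpha[[e$gene_a]] <- alpha[[e$gene_a]] + e$weight
    if (e$gene_b != e$gene_a) alpha[[e$gene_b]] <- alpha[[e$gene_b]] + e$weight
  }
  alpha <- alpha / denom
  alpha[order(-alpha, names(alpha))]
}

# Brute-force two-sample ECDF sup-distance.
ks_oracle <- function(a, b) {
  xs <- c(a, b)
  max(vapply(xs, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}
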