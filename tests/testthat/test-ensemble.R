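small_pair <- function(seed = 1) {
  sim <- generate_synthetic(synthetic_spec(
    n_y = 5, n_x = 10, n_conditions = 12, n_groups = 3, sparsity = 6,
    seed = seed
  ))
  list(pp = preprocess_pair(sim$pair), sim = sim)
}

test_that("the ensemble is deterministic given the master seed", {
  pp <- small_pair()$pp
  a <- run_lasso_ensemble(pp, n_replicates = 5, master_seed = 42)
  b <- run_lasso_ensemble(pp, n_replicates = 5, master_seed = 42)
  expect_identical(a, b)
  c <- run_lasso_ensemble(pp, n_replicates = 5, master_seed = 43)
  expect_false(identical(a$occurrence, c$occurrence))
})

test_that("a single-replicate ensemble reproduces one fit exactly", {
  pp <- small_pair()$pp
  ens <- run_lasso_ensemble(pp, n_replicates = 1, master_seed = 7)
  expect_true(all(ens$occurrence %in% c(0L, 1L)))
  k <- 2L
  fit <- fit_lasso_row(
    pp$left$values[k, ], pp$right$values,
    seed = ianet:::derive_seed(ianet:::derive_seed(7, 1), k)
  )
  nz <- fit$beta != 0
  expect_identical(unname(ens$occurrence[k, ]), as.integer(nz))
  expect_equal(unname(ens$nonzero_sum[k, nz]), unname(fit$beta[nz]))
})

test_that("planted associations are selected more often than background cells", {
  sp <- small_pair(seed = 5)
  ens <- run_lasso_ensemble(sp$pp, n_replicates = 20, master_seed = 11)
  truth <- sp$sim$true_b
  planted <- cbind(
    match(truth$y_analyte, ens$y_ids),
    match(truth$x_analyte, ens$x_ids)
  )
  occ_planted <- mean(ens$occurrence[planted])
  mask <- matrix(TRUE, length(ens$y_ids), length(ens$x_ids))
  mask[planted] <- FALSE
  expect_gt(occ_planted, mean(ens$occurrence[mask]))
})

test_that("offsets are negligible on preprocessed inputs", {
  pp <- small_pair(seed = 3)$pp
  ens <- run_lasso_ensemble(pp, n_replicates = 5, master_seed = 2)
  expect_lt(ens$max_abs_delta, 1e-6)
})

test_that("the consensus rule retains cells at the half-of-replicates boundary", {
  for (N in c(3L, 10L, 10000L)) {
    need <- as.integer(ceiling(0.5 * N))
    occ <- matrix(c(need, need - 1L, 0L, N), 2, 2,
      dimnames = list(c("y1", "y2"), c("x1", "x2"))
    )
    sums <- occ * 0.2
    rl <- build_rlcm(fake_ensemble(occ, sums, N), min_frequency = 0.5)
    keys <- paste(rl$y_analyte, rl$x_analyte)
    expect_true("y1 x1" %in% keys) # exactly at the boundary: kept
    expect_false("y2 x1" %in% keys) # one below: dropped
    expect_true("y2 x2" %in% keys)
    expect_equal(rl$coefficient, rep(0.2, nrow(rl)))
  }
})

test_that("consensus coefficients average only the non-zero occurrences", {
  # cell seen in 2 of 3 replicates with values 0.5 and 0.3 -> mean 0.4
  occ <- matrix(2L, 1, 1, dimnames = list("y1", "x1"))
  sums <- matrix(0.8, 1, 1, dimnames = list("y1", "x1"))
  rl <- build_rlcm(fake_ensemble(occ, sums, 3L), min_frequency = 0.5)
  expect_equal(nrow(rl), 1L)
  expect_equal(rl$coefficient, 0.4)
  expect_equal(rl$frequency, 2 / 3)
})

test_that("lowering the frequency cutoff never shrinks the consensus support", {
  ens <- run_lasso_ensemble(small_pair(seed = 9)$pp,
    n_replicates = 10, master_seed = 5
  )
  union_support <- sum(ens$occurrence > 0L)
  sizes <- vapply(
    c(1, 0.8, 0.5, 0.3, 0.1),
    function(f) nrow(build_rlcm(ens, f)),
    integer(1)
  )
  expect_true(all(diff(sizes) >= 0L))
  expect_lte(max(sizes), union_support)
})

test_that("consensus matrices survive a TSV round trip", {
  ens <- run_lasso_ensemble(small_pair(seed = 2)$pp,
    n_replicates = 5, master_seed = 3
  )
  rl <- build_rlcm(ens)
  td <- withr::local_tempdir()
  path <- file.path(td, "rlcm.tsv")
  write_rlcm(rl, path)
  rl2 <- read_rlcm(path)
  expect_identical(rl2$y_analyte, rl$y_analyte)
  expect_identical(rl2$x_analyte, rl$x_analyte)
  expect_identical(rl2$coefficient, rl$coefficient)
  expect_identical(rl2$frequency, rl$frequency)
  expect_identical(attr(rl2, "y_ids"), attr(rl, "y_ids"))
  expect_identical(attr(rl2, "n_replicates"), attr(rl, "n_replicates"))
})
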