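test_that("variance_filter keeps the most variant rows, stably", {
  set.seed(42)
  v <- matrix(rnorm(10 * 5, sd = rep(1:10, 5)), 10, 5,
    dimnames = list(sprintf("r%02d", 1:10), sprintf("c%d", 1:5))
  )
  m <- make_omics(v)
  out <- variance_filter(m, 0.2)
  expect_equal(nrow(out$values), 2L)
  vars <- apply(v, 1, var)
  expect_setequal(analyte_ids(out), names(sort(vars, decreasing = TRUE))[1:2])
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_input_rows, 10L)
  expect_equal(rep$n_retained_rows, 2L)

  expect_identical(variance_filter(m, 1)$values, m$values)

  # equal variances: stable tie-break keeps the first ceiling(R/2) rows
  tie <- make_omics(matrix(rep(c(1, -1, 0.5), each = 4), 4, 3, byrow = FALSE,
    dimnames = list(paste0("t", 1:4), paste0("c", 1:3))
  ))
  expect_identical(analyte_ids(variance_filter(tie, 0.5)), c("t1", "t2"))

  expect_error(variance_filter(m, 0), "0, 1")
  expect_error(variance_filter(m, 1.2), "0, 1")
})

test_that("two-stage variance filtering composes when no ties cross the cut", {
  m <- random_omics(20, 6, seed = 7)
  m$values <- m$values * rexp(20)
  one <- variance_filter(variance_filter(m, 0.5), 0.5)
  two <- variance_filter(m, 0.25)
  expect_identical(one$values, two$values)
})

test_that("preprocessing centers columns then rows then normalizes rows", {
  v <- matrix(c(1, 5, 2, 3), 2, 2, dimnames = list(c("a", "b"), c("c1", "c2")))
  pair <- paired_input(make_omics(v), make_omics(v, assay = "rppa"))
  out <- preprocess_pair(pair)
  s <- 1 / sqrt(2)
  expect_equal(out$left$values,
    matrix(c(-s, s, s, -s), 2, 2, dimnames = dimnames(v)),
    tolerance = 1e-12
  )

  # rows that are constant offsets of each other collapse and are dropped
  deg <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("c1", "c2")))
  degm <- make_omics(deg)
  out2 <- preprocess_pair(paired_input(degm, degm))
  expect_equal(nrow(out2$left$values), 0L)
  expect_setequal(attr(out2, "dropped_rows")$left, c("a", "b"))
})

test_that("preprocessed rows have zero mean and unit norm", {
  set.seed(3)
  for (dims in list(c(5, 4), c(12, 24), c(3, 3))) {
    m <- random_omics(dims[1], dims[2], seed = dims[1])
    out <- preprocess_pair(paired_input(m, m))
    v <- out$left$values
    expect_lt(max(abs(rowMeans(v))), 1e-12)
    expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-12)
  }
  one_col <- make_omics(matrix(1:3, 3, 1,
    dimnames = list(letters[1:3], "c1")
  ))
  expect_error(preprocess_pair(paired_input(one_col, one_col)), "2 condition")
})

test_that("dropping a condition group removes its columns from both layers", {
  groups <- tibble::tibble(
    condition_id = sprintf("c%02d", 1:8),
    group = rep(c("PBS", "EGF", "TGFB1", "OSM"), each = 2)
  )
  pair <- paired_input(
    random_omics(4, 8, seed = 1, groups = groups),
    random_omics(6, 8, seed = 2, groups = groups)
  )
  out <- drop_condition_group(pair, "TGFB1")
  expect_equal(ncol(out$left$values), 6L)
  expect_identical(condition_ids(out$left), condition_ids(out$right))
  expect_false(any(out$left$groups$group == "TGFB1"))
  expect_error(drop_condition_group(pair, "BMP2"), "Unknown")

  small_groups <- tibble::tibble(
    condition_id = sprintf("c%02d", 1:8),
    group = c(rep("big", 7), "tiny")
  )
  pair2 <- paired_input(
    random_omics(4, 8, seed = 1, groups = small_groups),
    random_omics(6, 8, seed = 2, groups = small_groups)
  )
  expect_error(drop_condition_group(pair2, "big"), "fewer than 2")
})

test_that("stratification rules select samples conjunctively", {
  v <- matrix(
    c(
      2^7.5 - 1, 0, 2^8 - 1, # HER2
      0, 0, 2^4 - 1, # ER
      0.5, 0, 2^5 - 1 # PR
    ),
    3, 3,
    byrow = TRUE,
    dimnames = list(c("HER2", "ER", "PR"), c("s1", "s2", "s3"))
  )
  m <- make_omics(v)
  her2_amp <- stratify_samples(m, list(
    stratification_rule("HER2", ">", 7, "log2p1")
  ))
  expect_setequal(her2_amp, c("s1", "s3"))

  # s2 has all three markers at zero: the triple-negative conjunction
  tnbc <- stratify_samples(m, list(
    stratification_rule("HER2", "<", 7, "log2p1"),
    stratification_rule("ER", "<", 1, "log2p1"),
    stratification_rule("PR", "<", 1, "log2p1")
  ))
  expect_identical(tnbc, "s2")

  expect_setequal(stratify_samples(m, list()), c("s1", "s2", "s3"))
  expect_error(
    stratify_samples(m, list(stratification_rule("EGFR", ">", 1))),
    "EGFR"
  )
})
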