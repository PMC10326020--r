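test_that("gene-level networks coalesce analytes and keep parallel edges", {
  meta <- dplyr::bind_rows(
    make_meta(c("p1", "p2"), c("G1", "G2"), "rppa"),
    make_meta(c("t1", "t2"), c("G1", "G2"), "rnaseq"),
    make_meta("peakA", "G2", "atacseq")
  )
  rl1 <- fake_rlcm(
    c("p1", "p1"), c("t1", "t2"), c(0.5, -0.2),
    provenance = "rppa_rnaseq",
    y_ids = c("p1", "p2"), x_ids = c("t1", "t2")
  )
  rl2 <- fake_rlcm("t1", "peakA", -0.3,
    provenance = "rnaseq_atacseq",
    y_ids = c("t1", "t2"), x_ids = "peakA"
  )
  net <- build_ian(rl1, rl2, meta, threshold = 0.01)
  expect_equal(nrow(net$nodes), 2L)
  g1 <- net$nodes$assays[net$nodes$gene == "G1"][[1]]
  expect_setequal(g1, c("rppa", "rnaseq"))
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight > 0))
  # p1 and t1 share gene G1: their association is a self-edge at gene level
  self <- net$edges[net$edges$y_analyte == "p1" & net$edges$x_analyte == "t1", ]
  expect_identical(self$gene_a, self$gene_b)

  # a threshold above every magnitude empties the network
  empty <- build_ian(rl1, rl2, meta, threshold = 0.9)
  expect_equal(nrow(empty$edges), 0L)

  bad_meta <- meta[meta$analyte_id != "peakA", ]
  expect_error(build_ian(rl1, rl2, bad_meta, 0.01), "peakA")
})

test_that("edge counts equal the number of retained entries above threshold", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12L
    meta <- make_meta(sprintf("t%02d", 1:8), paste0("G", 1:8))
    rl <- fake_rlcm(
      sample(sprintf("t%02d", 1:8), n, replace = TRUE),
      sample(sprintf("t%02d", 1:8), n, replace = TRUE),
      runif(n, -0.5, 0.5),
      y_ids = sprintf("t%02d", 1:8), x_ids = sprintf("t%02d", 1:8)
    )
    rl <- rl[!duplicated(paste(rl$y_analyte, rl$x_analyte)), ]
    thr <- 0.1
    net <- build_ian(rl, meta = meta, threshold = thr)
    expect_equal(nrow(net$edges), sum(abs(rl$coefficient) > thr))
  }
})

test_that("subnetwork filtering follows breadth-first distances", {
  meta <- make_meta(letters[1:4], toupper(letters[1:4]))
  chain <- fake_rlcm(
    c("a", "b", "c"), c("b", "c", "d"), c(0.5, 0.5, 0.5),
    y_ids = letters[1:4], x_ids = letters[1:4]
  )
  net <- build_ian(chain, meta = meta, threshold = 0.01)
  sub <- filter_subnetwork(net, "A", hops = 2)
  expect_setequal(sub$nodes$gene, c("A", "B", "C"))
  expect_equal(nrow(sub$edges), 2L)

  star <- fake_rlcm(
    rep("a", 3), c("b", "c", "d"), rep(0.4, 3),
    y_ids = letters[1:4], x_ids = letters[1:4]
  )
  starnet <- build_ian(star, meta = meta, threshold = 0.01)
  expect_setequal(
    filter_subnetwork(starnet, "A", hops = 1)$nodes$gene,
    c("A", "B", "C", "D")
  )
  expect_setequal(
    filter_subnetwork(starnet, "B", hops = 1)$nodes$gene,
    c("A", "B")
  )
  expect_warning(out <- filter_subnetwork(starnet, "ZZZ"), "seed genes")
  expect_equal(nrow(out$edges), 0L)
})

test_that("gene scores match hand summation and brute-force enumeration", {
  meta <- make_meta(c("t1", "t2", "t3"), c("GA", "GB", "GC"))
  rl <- fake_rlcm(c("t1", "t1"), c("t2", "t3"), c(0.3, -0.2),
    y_ids = c("t1", "t2", "t3"), x_ids = c("t1", "t2", "t3")
  )
  net <- build_ian(rl, meta = meta, threshold = 0.01)
  r <- rank_genes(net, layer_sizes = c(2, 3, 4))
  expect_equal(r$alpha[r$gene == "GA"], 0.5 / 24)
  expect_equal(attr(r, "normalization"), 24)

  for (seed in 1:50) {
    ri <- random_ian(seed)
    denom <- 60
    got <- rank_genes(ri$ian, layer_sizes = c(3, 4, 5))
    want <- rank_oracle(ri$ian, denom)
    expect_identical(got$gene, names(want))
    expect_equal(got$alpha, unname(want))
  }

  # the normalization constant never changes the order
  ri <- random_ian(99)
  a <- rank_genes(ri$ian, layer_sizes = c(3, 4, 5))
  b <- rank_genes(ri$ian, layer_sizes = c(10, 10, 10))
  expect_identical(a$gene, b$gene)
  expect_equal(a$alpha * 60, b$alpha * 1000)
})

test_that("preranked exports follow the GSEA .rnk dialect", {
  r <- structure(
    tibble::tibble(
      gene = c("B", "A", "C"),
      alpha = c(0.123456789012345, 0.5, 0)
    ),
    class = c("gene_ranking", class(tibble::tibble()))
  )
  td <- withr::local_tempdir()
  path <- file.path(td, "out.rnk")
  export_rnk(r, path)
  lines <- readr::read_lines(path)
  expect_length(lines, 3L)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  expect_true(all(lengths(parts) == 2L)) # two headerless columns
  scores <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  expect_identical(scores, sort(scores, decreasing = TRUE))
  expect_equal(scores[2], 0.123456789012345) # full precision survives

  dup <- r
  dup$gene <- c("A", "A", "C")
  expect_error(export_rnk(dup, path), "unique")
})

test_that("network exports round-trip or parse in their target tools", {
  ri <- random_ian(7)
  td <- withr::local_tempdir()

  edge_path <- file.path(td, "edges.tsv")
  export_network(ri$ian, edge_path, "edge_tsv")
  back <- read_ian_edges(edge_path, ri$meta, threshold = ri$ian$threshold)
  expect_equal(back$edges, ri$ian$edges)
  expect_equal(back$nodes, ri$ian$nodes)

  sif_path <- file.path(td, "net.sif")
  export_network(ri$ian, sif_path, "sif")
  sif <- readr::read_lines(sif_path)
  expect_length(sif, nrow(ri$ian$edges))
  expect_true(all(grepl("\tassoc\t", sif, fixed = TRUE)))

  gml_path <- file.path(td, "net.graphml")
  export_network(ri$ian, gml_path, "graphml")
  g <- igraph::read_graph(gml_path, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(ri$ian$nodes))
  expect_equal(igraph::gsize(g), nrow(ri$ian$edges))

  expect_error(export_network(ri$ian, file.path(td, "x"), "dot"))
})
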