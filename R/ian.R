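#' Named display/comparison thresholds for IAN edges
#'
#' Two conventional cutoffs on consensus coefficient magnitudes: `display`
#' (0.01) keeps the network readable for visualization; `comparison` (0.1)
#' is the stricter cutoff used when networks are compared or exported for
#' enrichment analysis.
#'
#' @param preset `"display"` or `"comparison"`.
#' @return The numeric threshold.
#' @export
ian_threshold <- function(preset = c("display", "comparison")) {
  c(display = 0.01, comparison = 0.1)[[match.arg(preset)]]
}

#' Assemble a gene-level Integrated Association Network
#'
#' Merges one or two layer-pair consensus matrices (e.g. proteomic ~
#' transcriptomic and transcriptomic ~ chromatin accessibility) into a
#' single gene-level graph. Each retained association whose coefficient
#' magnitude exceeds `threshold` becomes an edge between the gene symbols
#' of its two analytes; nodes are coalesced by gene symbol across assays,
#' so a gene measured in several assays is one node and an association
#' between two analytes of the same gene becomes a self-edge. Parallel
#' edges (distinct analyte pairs mapping to the same gene pair) are kept.
#'
#' @param rlcm_1 An [build_rlcm()] result.
#' @param rlcm_2 Optional second RLCM from the other layer pair.
#' @param meta Data frame mapping `analyte_id` to `gene_symbol` and `assay`
#'   for every analyte appearing in the RLCMs.
#' @param threshold Keep edges with `abs(coefficient) > threshold`; see
#'   [ian_threshold()].
#' @return An `ian` object: `nodes` (gene, assays), `edges` (gene_a, gene_b,
#'   weight = |coefficient|, coefficient, layer_pair, y_analyte, x_analyte),
#'   and the threshold used.
#' @export
build_ian <- function(rlcm_1, rlcm_2 = NULL, meta, threshold = ian_threshold("display")) {
  rlcms <- list(rlcm_1)
  if (!is.null(rlcm_2)) rlcms <- c(rlcms, list(rlcm_2))
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("analyte_id", "gene_symbol", "assay") %in% names(meta)))
  edges <- purrr::map_dfr(rlcms, function(r) {
    stopifnot(inherits(r, "rlcm"))
    tbl <- tibble::as_tibble(r)[abs(r$coefficient) > threshold, ]
    tibble::tibble(
      gene_a = lookup_gene(tbl$y_analyte, meta),
      gene_b = lookup_gene(tbl$x_analyte, meta),
      weight = abs(tbl$coefficient),
      coefficient = tbl$coefficient,
      layer_pair = attr(r, "provenance"),
      y_analyte = tbl$y_analyte,
      x_analyte = tbl$x_analyte
    )
  })
  edges <- dplyr::arrange(
    edges, .data$layer_pair, .data$gene_a, .data$gene_b,
    .data$y_analyte, .data$x_analyte
  )
  analytes <- unique(c(edges$y_analyte, edges$x_analyte))
  nodes <- meta |>
    dplyr::filter(.data$analyte_id %in% analytes) |>
    dplyr::distinct(.data$gene_symbol, .data$assay) |>
    dplyr::group_by(gene = .data$gene_symbol) |>
    dplyr::summarise(assays = list(sort(unique(.data$assay))), .groups = "drop") |>
    dplyr::arrange(.data$gene)
  new_ian(nodes, edges, threshold)
}

lookup_gene <- function(ids, meta) {
  pos <- match(ids, meta$analyte_id)
  if (anyNA(pos)) {
    abort(sprintf(
      "Analyte(s) without a gene symbol in `meta`: %s",
      toString(head(ids[is.na(pos)], 5L))
    ))
  }
  gene <- meta$gene_symbol[pos]
  if (any(!nzchar(gene) | is.na(gene))) {
    abort(sprintf(
      "Analyte(s) without a gene symbol in `meta`: %s",
      toString(head(ids[!nzchar(gene) | is.na(gene)], 5L))
    ))
  }
  gene
}

new_ian <- function(nodes, edges, threshold) {
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold),
    class = "ian"
  )
}

#' @export
print.ian <- function(x, ...) {
  cat(sprintf(
    "<ian> %d gene nodes, %d edges (|coefficient| > %g)\n",
    nrow(x$nodes), nrow(x$edges), x$threshold
  ))
  invisible(x)
}

#' @method tidy ian
#' @export
tidy.ian <- function(x, ...) x$edges

#' @method glance ian
#' @export
glance.ian <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_self_edges = sum(x$edges$gene_a == x$edges$gene_b),
    threshold = x$threshold,
    layer_pairs = toString(unique(x$edges$layer_pair))
  )
}

ian_graph <- function(ian) {
  igraph::graph_from_data_frame(
    ian$edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = ian$nodes$gene
  )
}

#' Neighborhood subnetwork around seed genes
#'
#' Keeps every gene within `hops` edges (breadth-first, edges undirected)
#' of any seed gene, plus all edges among the kept genes — the standard way
#' to zoom an association network onto a pathway of interest.
#'
#' @param ian An [build_ian()] result.
#' @param seed_genes Character vector of gene symbols.
#' @param hops Maximum graph distance from a seed gene (>= 1).
#' @return The induced `ian` subnetwork.
#' @export
filter_subnetwork <- function(ian, seed_genes, hops = 1L) {
  stopifnot(inherits(ian, "ian"), hops >= 1L)
  present <- intersect(seed_genes, ian$nodes$gene)
  if (!length(present)) {
    warn("None of the seed genes are present in the network; returning an empty IAN.")
    return(new_ian(ian$nodes[0L, ], ian$edges[0L, ], ian$threshold))
  }
  g <- ian_graph(ian)
  d <- igraph::distances(g, v = present)
  keep <- colnames(d)[apply(d, 2L, min) <= hops]
  edges <- ian$edges[ian$edges$gene_a %in% keep & ian$edges$gene_b %in% keep, ]
  new_ian(ian$nodes[ian$nodes$gene %in% keep, ], edges, ian$threshold)
}

#' Gene ranking by summed incident edge weight
#'
#' Scores each gene as the sum of the weights (coefficient magnitudes) of
#' its incident edges across both layer pairs, normalized by the product of
#' the layer sizes (the number of possible associations). The constant
#' denominator keeps scores comparable across networks from the same input
#' but never changes the order. `mode = "abs_of_sum"` instead takes the
#' absolute value of the signed coefficient sum per gene.
#'
#' @param ian An [build_ian()] result.
#' @param layer_sizes Numeric vector of the analyte counts of the (up to
#'   three) layers; their product is the normalization constant.
#' @param mode `"sum_abs"` (default) or `"abs_of_sum"`.
#' @return A `gene_ranking` tibble (`gene`, `alpha`), sorted by descending
#'   score with alphabetical tie-break.
#' @export
rank_genes <- function(ian, layer_sizes, mode = c("sum_abs", "abs_of_sum")) {
  stopifnot(inherits(ian, "ian"), all(layer_sizes >= 1))
  mode <- match.arg(mode)
  denom <- prod(layer_sizes)
  long <- dplyr::bind_rows(
    dplyr::transmute(ian$edges,
      gene = .data$gene_a, w = .data$weight, b = .data$coefficient
    ),
    # self-edges are incident once, not twice
    dplyr::transmute(
      ian$edges[ian$edges$gene_a != ian$edges$gene_b, ],
      gene = .data$gene_b, w = .data$weight, b = .data$coefficient
    )
  )
  scores <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      alpha = if (mode == "sum_abs") sum(.data$w) else abs(sum(.data$b)),
      .groups = "drop"
    )
  out <- tibble::tibble(gene = ian$nodes$gene) |>
    dplyr::left_join(scores, by = "gene") |>
    dplyr::mutate(alpha = dplyr::coalesce(.data$alpha, 0) / denom) |>
    dplyr::arrange(dplyr::desc(.data$alpha), .data$gene)
  structure(out,
    class = c("gene_ranking", class(tibble::tibble())),
    normalization = denom, mode = mode
  )
}

#' Export a gene ranking in GSEA preranked (.rnk) format
#'
#' Writes the headerless two-column tab-separated file consumed by
#' GSEAPreranked: gene symbol, then score, in descending score order.
#' Scores are written at full precision. Gene symbols must be unique.
#'
#' @param ranking A [rank_genes()] result.
#' @param path Output `.rnk` path.
#' @return Invisibly, `path`.
#' @export
export_rnk <- function(ranking, path) {
  stopifnot(is.data.frame(ranking), all(c("gene", "alpha") %in% names(ranking)))
  if (any(!nzchar(ranking$gene))) abort("Empty gene symbol in ranking.")
  dup <- unique(ranking$gene[duplicated(ranking$gene)])
  if (length(dup)) {
    abort(sprintf(".rnk requires unique gene symbols; duplicated: %s", toString(dup)))
  }
  ord <- order(-ranking$alpha, ranking$gene)
  readr::write_lines(
    sprintf("%s\t%s", ranking$gene[ord], fmt_num(ranking$alpha[ord])),
    path
  )
  invisible(path)
}

#' Export an IAN for graph tools
#'
#' `"sif"` writes the minimal Cytoscape SIF (`geneA assoc geneB`);
#' `"edge_tsv"` writes the full edge table (weights, layer pair, analyte
#' ids — enough to reconstruct the network with [read_ian_edges()]);
#' `"graphml"` writes GraphML with node assay annotations.
#'
#' @param ian An [build_ian()] result.
#' @param path Output path.
#' @param format One of `"sif"`, `"edge_tsv"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(ian, path, format = c("edge_tsv", "sif", "graphml")) {
  stopifnot(inherits(ian, "ian"))
  format <- match.arg(format)
  e <- ian$edges
  if (format == "sif") {
    readr::write_lines(sprintf("%s\tassoc\t%s", e$gene_a, e$gene_b), path)
  } else if (format == "edge_tsv") {
    lines <- c(
      "gene_a\tgene_b\tweight\tcoefficient\tlayer_pair\ty_analyte\tx_analyte",
      sprintf(
        "%s\t%s\t%s\t%s\t%s\t%s\t%s", e$gene_a, e$gene_b,
        fmt_num(e$weight), fmt_num(e$coefficient), e$layer_pair,
        e$y_analyte, e$x_analyte
      )
    )
    readr::write_lines(lines, path)
  } else {
    g <- ian_graph(ian)
    igraph::V(g)$assays <- vapply(
      ian$nodes$assays, paste, character(1), collapse = ","
    )
    igraph::E(g)$weight <- e$weight
    igraph::E(g)$layer_pair <- e$layer_pair
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Rebuild an IAN from an exported edge table
#'
#' @param path Path written by `export_network(..., format = "edge_tsv")`.
#' @param meta Analyte metadata (`analyte_id`, `gene_symbol`, `assay`) used
#'   to restore node assay sets.
#' @param threshold Threshold to record on the rebuilt object.
#' @return An `ian`.
#' @export
read_ian_edges <- function(path, meta, threshold = 0) {
  edges <- readr::read_tsv(path, col_types = "ccccccc", progress = FALSE)
  edges$weight <- as.numeric(edges$weight)
  edges$coefficient <- as.numeric(edges$coefficient)
  meta <- tibble::as_tibble(meta)
  analytes <- unique(c(edges$y_analyte, edges$x_analyte))
  nodes <- meta |>
    dplyr::filter(.data$analyte_id %in% analytes) |>
    dplyr::distinct(.data$gene_symbol, .data$assay) |>
    dplyr::group_by(gene = .data$gene_symbol) |>
    dplyr::summarise(assays = list(sort(unique(.data$assay))), .groups = "drop") |>
    dplyr::arrange(.data$gene)
  new_ian(nodes, tibble::as_tibble(edges), threshold)
}

#' @method autoplot ian
#' @export
autoplot.ian <- function(object, ...) {
  g <- ian_graph(object)
  set.seed(1L) # layout only; analysis results never depend on this
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    gene = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L]
  )
  edges <- object$edges |>
    dplyr::left_join(nodes, by = c(gene_a = "gene")) |>
    dplyr::left_join(nodes, by = c(gene_b = "gene"), suffix = c("", "_end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$x_end, yend = .data$y_end,
        linewidth = .data$weight, colour = .data$layer_pair
      ),
      alpha = 0.5
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -0.8, size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Integrated Association Network")
}

#' @method autoplot gene_ranking
#' @export
autoplot.gene_ranking <- function(object, top_n = 20L, ...) {
  top <- head(object, top_n)
  ggplot2::ggplot(
    top,
    ggplot2::aes(
      x = .data$alpha,
      y = stats::reorder(.data$gene, .data$alpha)
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "gene weight (normalized summed |coefficient|)", y = NULL,
      title = sprintf("Top %d ranked genes", nrow(top))
    )
}
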