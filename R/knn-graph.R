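#' Build an exact k-nearest-neighbor graph in standardized feature space
#'
#' Connects each variant to its `k` nearest neighbors by Euclidean
#' distance (the default `k = 6` mirrors the network display convention of
#' connecting every variant to its 6 nearest neighbors). Neighbor search
#' is exact, computed blockwise so large variant sets never materialize a
#' full distance matrix. Distance ties are broken deterministically toward
#' the lexicographically smaller variant key; `k >= N` is clamped to
#' `N - 1` with a warning.
#'
#' @param x A standardized [feature_matrix][assemble_features()] (z-scored)
#'   or a numeric matrix with variant-key rownames.
#' @param k Number of neighbors per node (default 6).
#' @param block Rows per block in the blockwise distance computation.
#' @return A directed [igraph][igraph::make_graph] graph; nodes are
#'   variant keys, each with out-degree `min(k, N - 1)`, edge attribute
#'   `weight` holding the Euclidean distance, graph attribute `k`.
#' @export
build_knn_graph <- function(x, k = 6, block = 1024L) {
  z <- as_z_matrix(x)
  n <- nrow(z)
  if (n < 2L) abort("Need at least 2 variants to build a kNN graph.")
  if (k <= 0) abort("`k` must be positive.")
  if (k >= n) {
    warn(sprintf("k = %d >= N = %d; clamped to %d.", k, n, n - 1L))
    k <- n - 1L
  }
  keys <- rownames(z)
  # sort order of keys used for tie-breaking: smaller key rank wins
  key_rank <- rank(keys, ties.method = "first")

  nbr <- matrix(0L, n, k)
  wts <- matrix(0, n, k)
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    d2 <- cross_dist2(z[s:e, , drop = FALSE], z)
    for (i in seq_len(e - s + 1L)) {
      row <- d2[i, ]
      row[s + i - 1L] <- Inf          # no self-edges
      ord <- order(row, key_rank)     # ties toward smaller key
      nbr[s + i - 1L, ] <- ord[seq_len(k)]
      wts[s + i - 1L, ] <- sqrt(row[ord[seq_len(k)]])
    }
  }
  edges <- rbind(rep(seq_len(n), each = k), as.vector(t(nbr)))
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  g <- igraph::add_edges(g, as.vector(edges))
  igraph::V(g)$name <- keys
  igraph::E(g)$weight <- as.vector(t(wts))
  g <- igraph::set_graph_attr(g, "k", k)
  g
}

as_z_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) {
    if (!x$standardized) {
      inform("Feature matrix is not standardized; applying zscore_features().")
      x <- zscore_features(x)
    }
    x$values
  } else if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x))) rownames(x) <- sprintf("v%06d", seq_len(nrow(x)))
    x
  } else {
    abort("`x` must be a feature_matrix or a numeric matrix.")
  }
}

#' Export a labelled variant network
#'
#' Writes a kNN graph with node attributes `cluster`, `label` (benign-like
#' / pathogenic-like) and `origin` (catalog / anchor / query / other) to
#' GraphML (or an edge-list CSV). For display, the node set can be
#' subsampled to `n` nodes with a fixed seed before the neighbor graph is
#' taken, reproducing the convention of displaying a random subset of
#' variants.
#'
#' @param graph A [build_knn_graph()] graph.
#' @param result A labelled [cluster_variants()] result.
#' @param path Output file; `.graphml` or `.csv` decides the format.
#' @param n Optional number of nodes to keep (seeded subsample).
#' @param seed Seed for the subsample.
#' @param origin Optional tibble (`variant`, `origin`).
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, result, path, n = NULL, seed = 1,
                           origin = NULL) {
  stopifnot(inherits(result, "variant_clustering"))
  keys <- igraph::V(graph)$name
  assign <- result$assignment
  if (!all(keys %in% assign$variant)) {
    abort("Graph nodes and clustering assignment do not share the same variants.")
  }
  if (!is.null(n) && n < length(keys)) {
    set.seed(seed)
    keep <- sort(sample(seq_along(keys), n))
    graph <- igraph::induced_subgraph(graph, keep)
    keys <- igraph::V(graph)$name
  }
  idx <- match(keys, assign$variant)
  igraph::V(graph)$cluster <- assign$cluster[idx]
  labels <- cluster_labels(result)
  igraph::V(graph)$label <- if (is.null(labels)) NA_character_ else
    unname(labels[as.character(assign$cluster[idx])])
  org <- rep("other", length(keys))
  if (!is.null(origin)) {
    m <- match(keys, origin$variant)
    org[!is.na(m)] <- origin$origin[m[!is.na(m)]]
  }
  igraph::V(graph)$origin <- org
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    readr::write_csv(as_tibble(el), path, progress = FALSE)
  } else {
    igraph::write_graph(graph, path, format = "graphml")
  }
  invisible(path)
}
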