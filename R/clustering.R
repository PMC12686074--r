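#' Two-way unsupervised clustering of the variant feature space
#'
#' Partitions variants into two clusters in standardized feature space.
#' Two documented methods are provided:
#'
#' * `"kmeans2"` (default) — centroid-based k-means with `nstart` seeded
#'   restarts;
#' * `"knn_community"` — Louvain community detection on the k-nearest-
#'   neighbor graph (edge affinities `1 / (1 + distance)`), with the
#'   resulting communities merged down to two by hierarchical
#'   centroid-linkage on the community centroids.
#'
#' Both are deterministic given `(method, seed)`. Cluster ids are
#' renumbered so that cluster 1 contains the lexicographically smallest
#' variant key, making the numbering itself reproducible; the
#' benign-like / pathogenic-like orientation is decided later by
#' [label_clusters()].
#'
#' @param x A standardized [feature_matrix][assemble_features()] or
#'   numeric matrix with variant rownames.
#' @param method `"kmeans2"` or `"knn_community"`.
#' @param k Neighbors for the kNN graph (only for `"knn_community"`).
#' @param seed Random seed (mandatory for reproducibility; recorded in
#'   the result).
#' @param nstart Seeded restarts for k-means.
#' @return A `variant_clustering` object: list with `assignment` (tibble
#'   `variant`, `cluster`), `centroids` (2 x p matrix in z-space),
#'   `sizes`, `method`, `k`, `seed`, `stats` (the standardization
#'   statistics if `x` was a feature matrix), `labels` (`NULL` until
#'   labelled) and convergence metadata.
#' @export
cluster_variants <- function(x, method = c("kmeans2", "knn_community"),
                             k = 6, seed = 1, nstart = 25) {
  method <- match.arg(method)
  stats <- if (inherits(x, "feature_matrix")) {
    if (!x$standardized) x <- zscore_features(x)
    x$stats
  } else NULL
  z <- as_z_matrix(x)
  n <- nrow(z)
  if (n < 2L) abort("Need at least 2 variants to cluster.")
  if (all(apply(z, 2, function(col) length(unique(col)) == 1L))) {
    abort("Degenerate matrix: all rows identical.")
  }
  meta <- list()
  if (method == "kmeans2") {
    set.seed(seed)
    km <- kmeans(z, centers = 2L, nstart = nstart, iter.max = 100L)
    cl <- km$cluster
    meta <- list(tot_withinss = km$tot.withinss, iterations = km$iter,
                 converged = !km$ifault)
  } else {
    set.seed(seed)
    g <- build_knn_graph(z, k = k)
    und <- igraph::as_undirected(g, mode = "collapse",
                                 edge.attr.comb = list(weight = "min"))
    aff <- 1 / (1 + igraph::E(und)$weight)
    comm <- igraph::cluster_louvain(und, weights = aff)
    mem <- igraph::membership(comm)
    cents <- rowsum(z, mem) / as.vector(table(mem))
    if (nrow(cents) > 2L) {
      hc <- hclust(dist(cents)^2, method = "centroid")
      merged <- cutree(hc, k = 2L)
      cl <- merged[as.character(mem)]
    } else if (nrow(cents) == 2L) {
      cl <- as.integer(mem)
    } else {
      abort("Community detection found a single community; cannot split in two.")
    }
    meta <- list(n_communities = length(unique(mem)),
                 modularity = igraph::modularity(comm))
  }
  # deterministic renumbering: cluster 1 holds the smallest variant key
  keys <- rownames(z)
  first_key <- order(keys)[1]
  if (cl[first_key] != 1L) cl <- 3L - cl
  centroids <- rowsum(z, cl) / as.vector(table(cl))
  sizes <- as.integer(table(factor(cl, levels = 1:2)))
  if (any(sizes == 0L)) abort("Clustering produced an empty cluster.")
  structure(
    list(
      assignment = tibble(variant = keys, cluster = as.integer(cl)),
      centroids = centroids, sizes = sizes,
      method = method, k = if (method == "knn_community") k else NA_integer_,
      seed = seed, stats = stats, labels = NULL,
      anchor_conflicts = character(), meta = meta
    ),
    class = "variant_clustering"
  )
}

cluster_labels <- function(result) result$labels

#' @export
print.variant_clustering <- function(x, ...) {
  cat(sprintf("<variant_clustering> method=%s seed=%d\n", x$method, x$seed))
  lbl <- x$labels
  for (i in 1:2) {
    tag <- if (is.null(lbl)) "" else sprintf(" [%s]", lbl[[as.character(i)]])
    cat(sprintf("  cluster %d: %d variants%s\n", i, x$sizes[i], tag))
  }
  if (length(x$anchor_conflicts) > 0L) {
    cat("  anchor conflicts:", paste(x$anchor_conflicts, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Label clusters as benign-like / pathogenic-like
#'
#' The cluster with the higher fraction of catalog-flagged variants
#' (population-catalog membership, e.g. variants frequently reported in
#' gnomAD) is labelled `benign_like`, the other `pathogenic_like`.
#' Anchor variants — known gain-of-function variants expected in the
#' pathogenic-like cluster — are used as a consistency check: anchors
#' found in the benign-like cluster are reported in `anchor_conflicts`
#' with a warning, never silently reassigned. An exact 50/50 split of the
#' flags is resolved by the anchors (the cluster holding the anchor
#' majority becomes pathogenic-like) and is an error when no anchors are
#' given.
#'
#' @param result A [cluster_variants()] result.
#' @param flags Character vector of catalog-flagged variant keys, or a
#'   tibble with columns `variant` and logical `flagged`.
#' @param anchors Optional character vector of anchor variant keys.
#' @return The result with `labels` set (named character,
#'   `"1"`/`"2"` -> label) and `anchor_conflicts` populated.
#' @export
label_clusters <- function(result, flags, anchors = NULL) {
  stopifnot(inherits(result, "variant_clustering"))
  flagged <- normalize_flags(flags, result$assignment$variant)
  if (sum(flagged) == 0L && length(anchors) == 0L) {
    abort("Need at least one catalog flag or one anchor to label clusters.")
  }
  cl <- result$assignment$cluster
  frac <- vapply(1:2, function(i) {
    idx <- cl == i
    if (!any(idx)) 0 else mean(flagged[idx])
  }, numeric(1))
  if (sum(flagged) > 0L && frac[1] != frac[2]) {
    benign <- which.max(frac)
  } else {
    if (length(anchors) == 0L) {
      abort("Catalog flags split evenly between clusters; anchors required to label.")
    }
    anchor_cl <- cl[match(anchors, result$assignment$variant)]
    anchor_cl <- anchor_cl[!is.na(anchor_cl)]
    if (length(anchor_cl) == 0L) abort("No anchor variant found in the clustering.")
    patho <- as.integer(names(which.max(table(anchor_cl))))
    benign <- 3L - patho
  }
  labels <- setNames(c("benign_like", "pathogenic_like"),
                     as.character(c(benign, 3L - benign)))
  labels <- labels[order(names(labels))]
  result$labels <- labels
  if (length(anchors) > 0L) {
    anchor_idx <- match(anchors, result$assignment$variant)
    present <- !is.na(anchor_idx)
    in_benign <- anchors[present][cl[anchor_idx[present]] == benign]
    if (length(in_benign) > 0L) {
      warn(sprintf("Anchor(s) in the benign-like cluster: %s",
                   paste(in_benign, collapse = ", ")))
    }
    result$anchor_conflicts <- in_benign
  }
  result
}

normalize_flags <- function(flags, variants) {
  if (is.data.frame(flags)) {
    stopifnot(all(c("variant", "flagged") %in% names(flags)))
    out <- rep(FALSE, length(variants))
    m <- match(flags$variant, variants)
    out[m[!is.na(m)]] <- flags$flagged[!is.na(m)]
    out
  } else {
    variants %in% flags
  }
}

benign_cluster_id <- function(result) {
  if (is.null(result$labels)) abort("Clustering is not labelled; call label_clusters().")
  as.integer(names(result$labels)[result$labels == "benign_like"])
}

#' Summarize clusters on the original feature scale
#'
#' Per-cluster, per-feature means and standard deviations computed on the
#' *original* (pre-standardization) feature matrix, plus per-cluster
#' anchor counts. Weighted cluster means recombine exactly to the global
#' feature means.
#'
#' @param result A [cluster_variants()] result.
#' @param fm The original-scale [feature_matrix][assemble_features()].
#' @param anchors Optional anchor variant keys to count per cluster.
#' @return Tibble: `cluster`, `label`, `feature`, `mean`, `sd`, `n`,
#'   `n_anchors`.
#' @export
summarize_clusters <- function(result, fm, anchors = NULL) {
  stopifnot(inherits(result, "variant_clustering"),
            inherits(fm, "feature_matrix"))
  assign <- result$assignment
  idx <- match(assign$variant, rownames(fm$values))
  if (anyNA(idx)) abort("Feature matrix does not cover all clustered variants.")
  vals <- fm$values[idx, , drop = FALSE]
  labels <- result$labels
  purrr::map_dfr(1:2, function(i) {
    rows <- assign$cluster == i
    sub <- vals[rows, , drop = FALSE]
    tibble(
      cluster = i,
      label = if (is.null(labels)) NA_character_ else
        unname(labels[as.character(i)]),
      feature = colnames(sub),
      mean = unname(colMeans(sub)),
      sd = unname(apply(sub, 2, sd)),
      n = sum(rows),
      n_anchors = if (is.null(anchors)) 0L else
        sum(anchors %in% assign$variant[rows])
    )
  })
}

#' Catalog enrichment of a cluster (exact test)
#'
#' Builds the 2x2 table of catalog-reported status against cluster
#' membership and tests association with the exact (hypergeometric,
#' two-sided) test. The odds ratio is the direct cross-product ratio
#' `(a*d)/(b*c)` with the Haldane–Anscombe +0.5 correction applied to all
#' cells only when some cell is zero.
#'
#' @param result A [cluster_variants()] result (labelled or not; when
#'   labelled, the table rows are oriented benign-like first).
#' @param flags As in [label_clusters()].
#' @return An `enrichment_result`: list with `table` (2x2 matrix),
#'   `odds_ratio`, `p_value`, `enriched_cluster`, `haldane` flag.
#' @export
enrichment_test <- function(result, flags) {
  stopifnot(inherits(result, "variant_clustering"))
  flagged <- normalize_flags(flags, result$assignment$variant)
  if (sum(flagged) == 0L || all(flagged)) {
    abort("Need both flagged and unflagged variants for an enrichment test.")
  }
  first <- if (is.null(result$labels)) 1L else benign_cluster_id(result)
  ord <- c(first, 3L - first)
  cl <- result$assignment$cluster
  tab <- vapply(ord, function(i) {
    c(sum(flagged & cl == i), sum(!flagged & cl == i))
  }, numeric(2))
  # rows: flagged / not flagged; columns: cluster (benign-like first)
  tab <- t(tab)
  dimnames(tab) <- list(paste0("cluster_", ord), c("flagged", "unflagged"))
  a <- tab[1, 1]; b <- tab[2, 1]; c_ <- tab[1, 2]; d <- tab[2, 2]
  haldane <- any(tab == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  p <- fisher.test(tab)$p.value
  frac <- tab[, 1] / rowSums(tab)
  enriched <- ord[which.max(frac)]
  structure(
    list(table = tab, odds_ratio = or, p_value = p,
         enriched_cluster = enriched, haldane = haldane),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  print(x$table)
  cat(sprintf("  OR = %.4g%s, exact two-sided p = %.3g, enriched: cluster %d\n",
              x$odds_ratio, if (x$haldane) " (Haldane corrected)" else "",
              x$p_value, x$enriched_cluster))
  invisible(x)
}

#' Assign new variants to the labelled clusters
#'
#' Projects query variants into the training standardized space (using the
#' stored standardization statistics) and assigns each to the nearest
#' cluster centroid. Both centroid distances are reported; an exact tie is
#' reported as `"unclassified"`.
#'
#' @param newdata A `feature_matrix` (original scale, same features) or a
#'   tibble with a `variant` column and one column per feature.
#' @param result A labelled [cluster_variants()] result.
#' @param stats Standardization statistics; defaults to those stored in
#'   `result`.
#' @return Tibble: `variant`, `label`, `dist_benign_like`,
#'   `dist_pathogenic_like`.
#' @export
assign_variants <- function(newdata, result, stats = result$stats) {
  stopifnot(inherits(result, "variant_clustering"))
  if (is.null(result$labels)) abort("Clustering must be labelled before assignment.")
  if (is.null(stats)) abort("No standardization statistics available.")
  feats <- colnames(result$centroids)
  if (inherits(newdata, "feature_matrix")) {
    vals <- newdata$values
  } else if (is.data.frame(newdata)) {
    stopifnot("variant" %in% names(newdata))
    missing_feats <- setdiff(feats, names(newdata))
    if (length(missing_feats) > 0L) {
      abort(sprintf("Missing feature column(s): %s",
                    paste(missing_feats, collapse = ", ")))
    }
    vals <- as.matrix(newdata[, feats, drop = FALSE])
    rownames(vals) <- newdata$variant
  } else {
    abort("`newdata` must be a feature_matrix or a data frame.")
  }
  if (!all(feats %in% colnames(vals))) abort("Feature dimension mismatch.")
  vals <- vals[, feats, drop = FALSE]
  st <- stats[match(feats, stats$feature), ]
  z <- sweep(sweep(vals, 2, st$mean, "-"), 2, st$sd, "/")
  benign <- benign_cluster_id(result)
  d_b <- sqrt(rowSums(sweep(z, 2, result$centroids[benign, ], "-")^2))
  d_p <- sqrt(rowSums(sweep(z, 2, result$centroids[3L - benign, ], "-")^2))
  label <- ifelse(d_b < d_p, "benign_like",
                  ifelse(d_p < d_b, "pathogenic_like", "unclassified"))
  tibble(variant = rownames(z), label = unname(label),
         dist_benign_like = unname(d_b), dist_pathogenic_like = unname(d_p))
}
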