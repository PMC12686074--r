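test_that("kNN graph matches the brute-force neighbor oracle", {
  set.seed(5)
  for (n in c(30, 120)) {
    x <- matrix(rnorm(n * 4), n, dimnames = list(sprintf("p.A%dC", 1:n), NULL))
    k <- 6
    g <- build_knn_graph(x, k = k)
    # O(N^2) oracle
    d <- as.matrix(dist(x))
    for (i in seq_len(n)) {
      di <- d[i, ]; di[i] <- Inf
      want <- rownames(x)[order(di)[1:k]]
      got <- igraph::V(g)$name[igraph::neighbors(g, i, mode = "out")]
      expect_setequal(got, want)
    }
    expect_true(all(igraph::degree(g, mode = "out") == k))
  }
})

test_that("kNN graph clamps k, forbids self-edges and breaks ties by key", {
  x <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE,
              dimnames = list(c("p.A1C", "p.A2C", "p.A3C"), NULL))
  expect_warning(g <- build_knn_graph(x, k = 6), "clamped")
  expect_true(all(igraph::degree(g, mode = "out") == 2))
  expect_false(any(igraph::which_loop(g)))

  # duplicated points: tie broken toward the lexicographically smaller key
  y <- matrix(c(0, 0, 0, 0, 0, 0), ncol = 2, byrow = TRUE,
              dimnames = list(c("p.C9A", "p.A1C", "p.B5D"), NULL))
  g1 <- build_knn_graph(y, k = 1)
  nb <- vapply(1:3, function(i)
    igraph::V(g1)$name[igraph::neighbors(g1, i, mode = "out")], character(1))
  expect_equal(nb, c("p.A1C", "p.B5D", "p.A1C"))
})

test_that("collinear-point neighbors follow exact distances", {
  x <- matrix(c(0, 0, 3, 0, 10, 0), ncol = 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  g <- build_knn_graph(x, k = 1)
  expect_equal(igraph::V(g)$name[igraph::neighbors(g, 2, mode = "out")], "a")
})

test_that("both clustering methods split well-separated groups and are
           deterministic under a fixed seed", {
  set.seed(9)
  n1 <- 60; n2 <- 80
  x <- rbind(matrix(rnorm(n1 * 3, 0), n1),
             matrix(rnorm(n2 * 3, 6), n2))
  rownames(x) <- sprintf("p.A%dC", seq_len(n1 + n2))
  truth <- rep(1:2, c(n1, n2))
  for (m in c("kmeans2", "knn_community")) {
    r1 <- cluster_variants(x, method = m, seed = 4)
    r2 <- cluster_variants(x, method = m, seed = 4)
    expect_identical(r1$assignment, r2$assignment)
    expect_equal(sum(r1$sizes), n1 + n2)
    expect_gte(ari(r1$assignment$cluster, truth), 0.99)
  }
})

test_that("a duplicated block of points splits perfectly", {
  block <- matrix(rnorm(20, sd = 0.01), 10, 2)
  x <- rbind(block, block + 10)
  rownames(x) <- sprintf("p.A%dC", 1:20)
  r <- cluster_variants(x, seed = 1)
  expect_equal(sort(r$sizes), c(10L, 10L))
  expect_error(cluster_variants(rbind(block, block)[rep(1, 20), ], seed = 1),
               "identical")
})

test_that("labelling follows catalog-flag concentration and checks anchors", {
  cl <- fake_clustering(rep(c(1, 2), each = 10), labelled = FALSE)
  flags <- cl$assignment$variant[c(1:9, 11)]     # 90% of flags in cluster 1
  r <- label_clusters(cl, flags)
  expect_equal(unname(r$labels["1"]), "benign_like")
  expect_equal(unname(r$labels["2"]), "pathogenic_like")

  anchors <- cl$assignment$variant[15:18]        # cluster 2: no conflict
  r2 <- label_clusters(cl, flags, anchors)
  expect_length(r2$anchor_conflicts, 0)

  bad_anchor <- cl$assignment$variant[2]         # cluster 1: conflict reported
  expect_warning(r3 <- label_clusters(cl, flags, bad_anchor), "conflict|benign")
  expect_equal(r3$anchor_conflicts, bad_anchor)

  # even split cannot be labelled without anchors
  even <- cl$assignment$variant[c(1, 11)]
  expect_error(label_clusters(cl, even), "anchors")
  r4 <- label_clusters(cl, even, anchors = cl$assignment$variant[15])
  expect_equal(unname(r4$labels["2"]), "pathogenic_like")
})

test_that("cluster summaries recombine to the global mean", {
  set.seed(21)
  v <- parse_variants(sprintf("p.A%dC", 1:50))
  fm <- assemble_features(v, list(
    score_table_mem(v$variant, rnorm(50, 20, 5), "CADD"),
    score_table_mem(v$variant, rnorm(50, -5, 2), "ESM1b")))
  r <- cluster_variants(zscore_features(fm), seed = 2)
  s <- summarize_clusters(r, fm)
  for (f in fm$features) {
    sf <- s[s$feature == f, ]
    recombined <- sum(sf$mean * sf$n) / sum(sf$n)
    expect_equal(recombined, mean(fm$values[, f]), tolerance = 1e-9)
  }
  # simple two-value oracle
  keys <- c("p.A1C", "p.A2C", "p.A3C")
  cl2 <- fake_clustering(c(1, 1, 2), variants = keys)
  fm2 <- assemble_features(tibble::tibble(variant = keys),
                           list(score_table_mem(keys, c(2, 4, 9), "CADD")))
  s2 <- summarize_clusters(cl2, fm2)
  expect_equal(s2$mean[s2$cluster == 1], 3)
})

test_that("enrichment odds ratio and exact p match direct oracles", {
  # balanced table: no association
  cl <- fake_clustering(rep(c(1, 2), each = 10))
  flags <- cl$assignment$variant[c(1:5, 11:15)]
  e <- enrichment_test(cl, flags)
  expect_equal(e$odds_ratio, 1)
  expect_equal(e$p_value, 1)

  # zero cells take the Haldane correction and match enumeration
  cl2 <- fake_clustering(rep(c(1, 2), each = 5))
  e2 <- enrichment_test(cl2, cl2$assignment$variant[1:5])
  expect_true(e2$haldane)
  expect_true(is.finite(e2$odds_ratio))
  expect_equal(e2$p_value, hyper_p_enum(5, 0, 0, 5), tolerance = 1e-12)

  # random small tables: exact p equals exhaustive hypergeometric enumeration
  set.seed(33)
  for (i in 1:15) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(1:12, 1); d <- sample(1:12, 1)
    if ((a + b) == 0) a <- 1
    cl3 <- fake_clustering(rep(c(1, 2), c(a + c_, b + d)))
    flags3 <- c(cl3$assignment$variant[seq_len(a)],
                cl3$assignment$variant[a + c_ + seq_len(b)])
    e3 <- enrichment_test(cl3, flags3)
    expect_equal(e3$p_value, hyper_p_enum(a, b, c_, d), tolerance = 1e-10)
    if (all(c(a, b, c_, d) > 0)) {
      expect_equal(e3$odds_ratio, (a * d) / (b * c_), tolerance = 1e-12)
    }
  }
})

test_that("new variants go to the nearest centroid with tie -> unclassified", {
  set.seed(2)
  v <- parse_variants(sprintf("p.A%dC", 1:40))
  vals <- c(rnorm(20, 0, 0.4), rnorm(20, 8, 0.4))
  fm <- assemble_features(v, list(
    score_table_mem(v$variant, vals, "CADD"),
    score_table_mem(v$variant, vals + rnorm(40, 0, 0.2), "ESM1b")))
  zfm <- zscore_features(fm)
  r <- cluster_variants(zfm, seed = 6)
  r <- label_clusters(r, flags = v$variant[1:10])   # low-value group = benign
  # a point equal to the pathogenic centroid on the original scale
  st <- r$stats
  benign <- as.integer(names(r$labels)[r$labels == "benign_like"])
  patho_centroid_orig <- r$centroids[3 - benign, ] * st$sd + st$mean
  nd <- tibble::tibble(variant = "p.Q1W",
                       CADD = patho_centroid_orig["CADD"],
                       ESM1b = patho_centroid_orig["ESM1b"])
  a <- assign_variants(nd, r)
  expect_equal(a$label, "pathogenic_like")
  expect_equal(a$dist_pathogenic_like, 0, tolerance = 1e-9)

  # exact midpoint is unclassified
  mid_z <- colMeans(r$centroids)
  mid_orig <- mid_z * st$sd + st$mean
  a2 <- assign_variants(tibble::tibble(variant = "p.Q2W",
                                       CADD = mid_orig["CADD"],
                                       ESM1b = mid_orig["ESM1b"]), r)
  expect_equal(a2$label, "unclassified")
  expect_error(assign_variants(tibble::tibble(variant = "x", CADD = 1), r),
               "Missing feature")
})

test_that("network export writes attributes and subsamples reproducibly", {
  set.seed(8)
  n <- 40
  x <- matrix(rnorm(n * 3), n, dimnames = list(sprintf("p.A%dC", 1:n), NULL))
  g <- build_knn_graph(x, k = 3)
  r <- cluster_variants(x, seed = 1)
  r <- label_clusters(r, flags = rownames(x)[r$assignment$cluster == 1])

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(g, r, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), n)
  expect_true(all(c("cluster", "label", "origin") %in%
                    igraph::vertex_attr_names(back)))

  sub1 <- withr::local_tempfile(fileext = ".graphml")
  sub2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(g, r, sub1, n = 15, seed = 7)
  export_network(g, r, sub2, n = 15, seed = 7)
  b1 <- igraph::read_graph(sub1, format = "graphml")
  expect_equal(igraph::vcount(b1), 15)
  expect_identical(readLines(sub1), readLines(sub2))

  # edge-list round trip preserves adjacency
  csv <- withr::local_tempfile(fileext = ".csv")
  export_network(g, r, csv)
  el <- readr::read_csv(csv, show_col_types = FALSE)
  got <- sort(paste(el$from, el$to))
  want <- igraph::as_data_frame(g, what = "edges")
  expect_equal(got, sort(paste(want$from, want$to)))
})
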