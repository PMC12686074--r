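# Shared fixtures, all generated in code.

random_protein <- function(L, seed = 1) {
  set.seed(seed)
  protein_seq(paste(sample(amino_acids(), L, replace = TRUE), collapse = ""))
}

write_tsv_fixture <- function(df, name = "tab.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# score_table built in memory (same constructor the readers use)
score_table_mem <- function(variants, values, feature = "CADD",
                            orientation = "higher_is_damaging") {
  parsed <- parse_variants(variants)
  structure(
    tibble::tibble(variant = parsed$variant, position = parsed$position,
                   ref_aa = parsed$ref_aa, alt_aa = parsed$alt_aa,
                   value = values),
    feature = feature, orientation = orientation,
    class = c("score_table", class(tibble::tibble()))
  )
}

# a hand-assembled clustering object, for table-driven enrichment oracles
fake_clustering <- function(cluster, variants = sprintf("p.A%dC", seq_along(cluster)),
                            labelled = TRUE) {
  cluster <- as.integer(cluster)
  res <- structure(
    list(
      assignment = tibble::tibble(variant = variants, cluster = cluster),
      centroids = matrix(0, 2, 2, dimnames = list(c("1", "2"), c("f1", "f2"))),
      sizes = as.integer(table(factor(cluster, levels = 1:2))),
      method = "kmeans2", k = NA_integer_, seed = 1L, stats = NULL,
      labels = NULL, anchor_conflicts = character(), meta = list()
    ),
    class = "variant_clustering"
  )
  if (labelled) {
    res$labels <- c(`1` = "benign_like", `2` = "pathogenic_like")
  }
  res
}

# Exhaustive two-sided hypergeometric p for a 2x2 table (enumeration oracle).
# Arguments follow the enrichment layout: a/b = flagged in cluster 1/2,
# c/d = unflagged in cluster 1/2.
hyper_p_enum <- function(a, b, c, d) {
  kf <- a + b          # flagged total
  k1 <- a + c          # cluster-1 size
  n <- a + b + c + d
  support <- max(0, k1 + kf - n):min(k1, kf)
  probs <- stats::dhyper(support, kf, n - kf, k1)
  p_obs <- stats::dhyper(a, kf, n - kf, k1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# minimal hand-written PDB text (fixed-width records)
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     record = "ATOM", element = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, "", resn, chain, resno, x, y, z, 1, 0, element)
}

# random proper rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# adjusted Rand index between two labelings (independent of the package)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
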