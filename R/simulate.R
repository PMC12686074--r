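#' Default per-feature simulation parameters
#'
#' Two-population (benign-like / pathogenic-like) Gaussian parameters for
#' the nine default features. The CADD, ESM1b and closed-state ddG means
#' are the reported per-cluster means of the full JAK1 variant clustering
#' (20.99 / 26.68, -4.47 / -10.75 and -2.05 / -6.36); the remaining means
#' and all standard deviations are this generator's choices of plausible
#' predictor scales (see the methods vignette).
#'
#' @return Tibble: `feature`, `mean_benign`, `sd_benign`,
#'   `mean_pathogenic`, `sd_pathogenic`.
#' @export
default_sim_features <- function() {
  tibble(
    feature = default_features(),
    mean_benign     = c(20.99, 0.25, -4.47, 0.35, 0.60, 0.20, 0.30, -1.20, -2.05),
    sd_benign       = c(4.50, 0.18, 3.20, 0.25, 0.25, 0.18, 0.20, 1.80, 2.20),
    mean_pathogenic = c(26.68, 0.70, -10.75, 0.75, 0.15, 0.60, 0.70, -3.50, -6.36),
    sd_pathogenic   = c(4.50, 0.18, 3.20, 0.25, 0.15, 0.22, 0.20, 1.80, 2.20)
  )
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by [simulate_feature_matrix()]:
#' population sizes (defaults 7559 benign-like + 14,367 pathogenic-like,
#' the reported cluster sizes of the 21,926-variant saturation space of a
#' 1154-residue protein), per-feature Gaussian parameters, catalog-flag
#' probabilities per population (defaults chosen so the expected flagged
#' counts are 214 and 75), gain-of-function anchor variants placed in the
#' pathogenic population, and a missingness rate.
#'
#' @param n_benign,n_pathogenic Population sizes.
#' @param protein_length Residue count of the synthetic protein; the two
#'   populations are drawn from its saturation space, so
#'   `n_benign + n_pathogenic` must not exceed `19 * protein_length`.
#' @param features Per-feature parameter tibble as in
#'   [default_sim_features()].
#' @param flag_prob Length-2 named numeric: catalog-flag probability in the
#'   benign and pathogenic populations.
#' @param anchors Anchor variant labels (known GOF variants); their
#'   reference residues are pinned into the synthetic sequence and the
#'   variants are forced into the pathogenic population. The default
#'   (`NULL`) places the four pseudokinase-domain GOF anchors
#'   `p.H596D`, `p.A634D`, `p.S703I`, `p.C787F` at their native positions
#'   for a 1154-residue protein, scaled proportionally for shorter ones.
#' @param missing_rate Fraction of feature cells blanked (then imputed and
#'   masked downstream).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_benign = 7559, n_pathogenic = 14367,
                       protein_length = 1154,
                       features = default_sim_features(),
                       flag_prob = c(benign = 214 / 7559,
                                     pathogenic = 75 / 14367),
                       anchors = NULL,
                       missing_rate = 0) {
  stopifnot(n_benign >= 1, n_pathogenic >= 1, protein_length >= 1)
  if (is.null(anchors)) anchors <- default_anchors(protein_length)
  if (n_benign + n_pathogenic > 19 * protein_length) {
    abort("Population sizes exceed the saturation space of the protein.")
  }
  stopifnot(is.data.frame(features),
            all(c("feature", "mean_benign", "sd_benign", "mean_pathogenic",
                  "sd_pathogenic") %in% names(features)))
  if (any(features$sd_benign <= 0) || any(features$sd_pathogenic <= 0)) {
    abort("Feature standard deviations must be > 0.")
  }
  if (any(flag_prob < 0) || any(flag_prob > 1)) {
    abort("`flag_prob` must lie in [0, 1].")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  structure(
    list(n_benign = as.integer(n_benign),
         n_pathogenic = as.integer(n_pathogenic),
         protein_length = as.integer(protein_length),
         features = features, flag_prob = flag_prob,
         anchors = anchors, missing_rate = missing_rate),
    class = "sim_config"
  )
}

# GOF anchor variants at their native 1154-residue positions, scaled
# proportionally onto shorter synthetic proteins (collisions bumped apart).
default_anchors <- function(protein_length) {
  ref <- c("H", "A", "S", "C"); alt <- c("D", "D", "I", "F")
  if (protein_length < 10L) abort("Protein too short to place default anchors.")
  pos <- pmax(1L, pmin(protein_length - 3L,
                       as.integer(round(protein_length * c(596, 634, 703, 787) / 1154))))
  while (anyDuplicated(pos)) {
    pos[duplicated(pos)] <- pos[duplicated(pos)] + 1L
  }
  format_variant(pos, ref, alt)
}

#' Simulate a two-population variant feature matrix
#'
#' Draws variants from the saturation space of a seeded random protein
#' (anchor reference residues pinned), assigns each to the benign-like or
#' pathogenic-like population, and samples every feature independently
#' from that population's Gaussian. Catalog flags are Bernoulli draws with
#' per-population probabilities; anchors always belong to the pathogenic
#' population. Fully reproducible: the same config and seed give identical
#' output.
#'
#' This emulates the marginal two-population structure the clustering
#' pipeline assumes — independent Gaussian features at the reported
#' per-cluster means — not the correlation structure of real predictor
#' panels (see the methods vignette for what that does and does not
#' validate).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `sim_output` list: `fm` (original-scale `feature_matrix`,
#'   with missingness imputed and masked), `truth` (tibble `variant`,
#'   `population`), `flags` (tibble `variant`, `flagged`), `anchors`,
#'   `protein`, `manifest` (config + seed).
#' @export
simulate_feature_matrix <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  L <- config$protein_length
  seq_res <- sample(AA_CODES, L, replace = TRUE)
  anchor_tab <- parse_variants(config$anchors)
  if (any(anchor_tab$position > L)) {
    abort("Anchor position outside the synthetic protein.")
  }
  seq_res[anchor_tab$position] <- anchor_tab$ref_aa
  protein <- protein_seq(paste(seq_res, collapse = ""), id = "synthetic")
  space <- enumerate_saturation(protein)

  n_b <- config$n_benign; n_p <- config$n_pathogenic
  n <- n_b + n_p
  anchor_idx <- match(anchor_tab$variant, space$variant)
  pool <- setdiff(seq_len(nrow(space)), anchor_idx)
  picked <- sample(pool, n - length(anchor_idx))
  path_idx <- c(anchor_idx, picked[seq_len(n_p - length(anchor_idx))])
  ben_idx <- picked[(n_p - length(anchor_idx) + 1):length(picked)]
  variants <- space[sort(c(path_idx, ben_idx)), ]
  population <- ifelse(seq_len(nrow(space))[sort(c(path_idx, ben_idx))] %in% path_idx,
                       "pathogenic", "benign")

  fs <- config$features
  p <- nrow(fs)
  values <- matrix(NA_real_, nrow = n, ncol = p,
                   dimnames = list(variants$variant, fs$feature))
  is_path <- population == "pathogenic"
  for (j in seq_len(p)) {
    values[is_path, j] <- rnorm(sum(is_path), fs$mean_pathogenic[j],
                                fs$sd_pathogenic[j])
    values[!is_path, j] <- rnorm(sum(!is_path), fs$mean_benign[j],
                                 fs$sd_benign[j])
  }
  mask <- matrix(FALSE, n, p, dimnames = dimnames(values))
  if (config$missing_rate > 0) {
    holes <- which(matrix(stats::runif(n * p) < config$missing_rate, n, p))
    mask[holes] <- TRUE
    vals_missing <- values
    vals_missing[holes] <- NA_real_
    for (j in seq_len(p)) {
      mj <- mask[, j]
      if (all(mj)) abort("Missingness wiped out a whole feature; lower `missing_rate`.")
      values[mj, j] <- median(vals_missing[!mj, j])
    }
  }
  flagged <- logical(n)
  flagged[!is_path] <- rbinom(sum(!is_path), 1, config$flag_prob[["benign"]]) == 1
  flagged[is_path] <- rbinom(sum(is_path), 1, config$flag_prob[["pathogenic"]]) == 1

  orientation <- setNames(rep("higher_is_damaging", p), fs$feature)
  fm <- new_feature_matrix(values, mask, orientation)
  structure(
    list(
      fm = fm,
      truth = tibble(variant = variants$variant, position = variants$position,
                     ref_aa = variants$ref_aa, alt_aa = variants$alt_aa,
                     population = population),
      flags = tibble(variant = variants$variant, flagged = flagged),
      anchors = anchor_tab$variant,
      protein = protein,
      manifest = list(seed = seed, config = unclass(config))
    ),
    class = "sim_output"
  )
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d variants (%d benign / %d pathogenic), %d features, seed %d\n",
              nrow(x$truth), sum(x$truth$population == "benign"),
              sum(x$truth$population == "pathogenic"),
              ncol(x$fm$values), x$manifest$seed))
  invisible(x)
}

#' Write simulated per-feature score tables
#'
#' Writes one dialect-correct TSV per feature (columns `variant`,
#' `value`), omitting masked cells, so that reading the tables back with
#' [read_score_table()] and [assemble_features()] reconstructs the
#' simulated matrix exactly (imputed cells included, since the imputation
#' policy is deterministic). The open/closed ddG features are written as
#' ddG tables (columns `variant`, `ddg`). A `manifest.json` records the
#' config and seed.
#'
#' @param sim A [simulate_feature_matrix()] output.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
simulate_score_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fm <- sim$fm
  if (nrow(fm$values) == 0L) abort("Empty variant set; nothing to write.")
  paths <- character(0)
  for (j in seq_len(ncol(fm$values))) {
    feat <- colnames(fm$values)[j]
    obs <- !fm$mask[, j]
    is_ddg <- feat %in% c("ddG_open", "ddG_closed")
    tab <- tibble(variant = rownames(fm$values)[obs], value = fm$values[obs, j])
    if (is_ddg) names(tab)[2] <- "ddg"
    path <- file.path(dir, paste0(feat, ".tsv"))
    readr::write_tsv(tab, path, progress = FALSE)
    paths[feat] <- path
  }
  flags_path <- file.path(dir, "catalog_flags.tsv")
  readr::write_tsv(sim$flags, flags_path, progress = FALSE)
  paths["catalog_flags"] <- flags_path
  anchors_path <- file.path(dir, "anchors.txt")
  writeLines(sim$anchors, anchors_path)
  paths["anchors"] <- anchors_path
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Simulate a toy two-domain structure
#'
#' Builds a deterministic synthetic structure with two residue groups
#' ("domains") laid out as parallel strands separated by a configurable
#' gap, plus an optional single-atom-set ligand centered at a known point.
#' Each residue carries N, CA, C, O and CB heavy atoms. Intended as a
#' fixture generator for the geometry operations (interfaces appear for
#' small gaps and vanish for large ones; the pocket centroid is exactly
#' the requested ligand center).
#'
#' @param n_res Residues per domain.
#' @param gap Distance between the two strands in Angstroms.
#' @param ligand_center Optional length-3 numeric; adds a HET residue
#'   (`"LIG"`) of four atoms whose centroid is exactly this point.
#' @param spacing CA-CA spacing along each strand.
#' @return A `structure_model` with residues `1..n_res` in chain A and
#'   `101..100+n_res` in chain B.
#' @export
simulate_structure <- function(n_res = 10, gap = 4, ligand_center = NULL,
                               spacing = 3.8) {
  res_atoms <- function(resno, chain, y, z = 0) {
    x0 <- (resno %% 100) * spacing
    tibble(
      model = 1L,
      eleno = 0L,
      elety = c("N", "CA", "C", "O", "CB"),
      resid = "ALA",
      chain = chain,
      resno = resno,
      het = FALSE,
      element = c("N", "C", "C", "O", "C"),
      x = x0 + c(-0.8, 0, 0.8, 1.2, 0),
      y = y + c(0.4, 0, -0.4, 0.6, 0),
      z = z + c(0, 0, 0, 0, 1.2)
    )
  }
  a <- purrr::map_dfr(seq_len(n_res), res_atoms, chain = "A", y = 0)
  b <- purrr::map_dfr(100 + seq_len(n_res), res_atoms, chain = "B", y = gap)
  atoms <- bind_rows(a, b)
  if (!is.null(ligand_center)) {
    stopifnot(length(ligand_center) == 3)
    off <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0), c(0, -0.5, 0))
    lig <- tibble(
      model = 1L, eleno = 0L, elety = c("C1", "C2", "O1", "N1"),
      resid = "LIG", chain = "L", resno = 999L, het = TRUE,
      element = c("C", "C", "O", "N"),
      x = ligand_center[1] + off[, 1],
      y = ligand_center[2] + off[, 2],
      z = ligand_center[3] + off[, 3]
    )
    atoms <- bind_rows(atoms, lig)
  }
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure_model(atoms, id = "synthetic")
}

#' Simulate a coordinate ensemble by Gaussian jitter
#'
#' Replicates the first model of `base` into `n_frames` frames, adding
#' iid Gaussian noise with standard deviation `jitter_sd` per axis to
#' every atom. For large ensembles the per-residue fluctuation converges
#' to `jitter_sd * sqrt(3)`.
#'
#' @param base A `structure_model`.
#' @param jitter_sd Noise standard deviation per axis (Angstroms).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A multi-model `structure_model`.
#' @export
simulate_ensemble <- function(base, jitter_sd, n_frames, seed = 1) {
  stopifnot(inherits(base, "structure_model"), n_frames >= 2)
  set.seed(seed)
  a1 <- filter(base$atoms, .data$model == 1L)
  frames <- purrr::map_dfr(seq_len(n_frames), function(m) {
    f <- a1
    f$model <- m
    f$x <- f$x + rnorm(nrow(f), 0, jitter_sd)
    f$y <- f$y + rnorm(nrow(f), 0, jitter_sd)
    f$z <- f$z + rnorm(nrow(f), 0, jitter_sd)
    f
  })
  new_structure_model(frames, id = paste0(base$id, "_ensemble"))
}
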