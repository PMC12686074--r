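#' Assemble a variant-by-feature matrix from score tables
#'
#' Joins per-predictor score tables (and optional open/closed-state
#' free-energy-change tables) onto a variant set, producing one row per
#' variant and one column per feature. Cells absent from a table are
#' imputed — by default with the per-feature median over observed values —
#' and flagged in a missingness mask so that standardization statistics
#' are computed over observed values only.
#'
#' @param variants Tibble with a `variant` column (e.g. from
#'   [enumerate_saturation()] or [parse_variants()]).
#' @param score_tables List of [read_score_table()] results. A table whose
#'   keys contain no variant of `variants` is an error.
#' @param ddg_open,ddg_closed Optional tibbles with `variant` and `ddg`
#'   columns (from [read_ddg_table()] or [dual_state_profile()]), ingested
#'   as features `ddG_open` / `ddG_closed`.
#' @param impute `"median"` (default) or `"none"` (missing cells left NA
#'   but still masked; such a matrix cannot be clustered).
#' @return A `feature_matrix` object: a list with elements
#'   `values` (numeric matrix, rownames = variant keys),
#'   `mask` (logical matrix, `TRUE` where imputed),
#'   `features`, `orientation` (named character),
#'   `stats` (standardization statistics, `NULL` until [zscore_features()]),
#'   and `standardized` flag.
#' @export
assemble_features <- function(variants, score_tables = list(),
                              ddg_open = NULL, ddg_closed = NULL,
                              impute = c("median", "none")) {
  impute <- match.arg(impute)
  stopifnot(is.data.frame(variants), "variant" %in% names(variants))
  keys <- variants$variant
  if (anyDuplicated(keys)) abort("`variants` contains duplicate variant keys.")
  if (length(keys) == 0L) abort("`variants` is empty.")

  tables <- score_tables
  ddg_as_table <- function(tab, feat) {
    stopifnot(is.data.frame(tab), all(c("variant", "ddg") %in% names(tab)))
    out <- tibble(variant = tab$variant, value = tab$ddg)
    structure(out, feature = feat, orientation = "lower_is_damaging")
  }
  if (!is.null(ddg_open)) tables <- c(tables, list(ddg_as_table(ddg_open, "ddG_open")))
  if (!is.null(ddg_closed)) tables <- c(tables, list(ddg_as_table(ddg_closed, "ddG_closed")))
  if (length(tables) == 0L) abort("No score tables supplied.")

  feats <- vapply(tables, function(t) attr(t, "feature"), character(1))
  if (anyDuplicated(feats)) {
    abort(sprintf("Duplicate feature name(s): %s",
                  paste(unique(feats[duplicated(feats)]), collapse = ", ")))
  }
  orientation <- vapply(tables, function(t) attr(t, "orientation") %||% NA_character_,
                        character(1))
  names(orientation) <- feats

  values <- matrix(NA_real_, nrow = length(keys), ncol = length(feats),
                   dimnames = list(keys, feats))
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    idx <- match(tab$variant, keys)
    hit <- !is.na(idx)
    if (!any(hit)) {
      abort(sprintf("Score table '%s' shares no variants with the variant set.",
                    feats[i]))
    }
    values[idx[hit], i] <- tab$value[hit]
  }
  mask <- is.na(values)
  if (impute == "median") {
    for (j in seq_len(ncol(values))) {
      mj <- mask[, j]
      if (all(mj)) abort(sprintf("Feature '%s' has no observed values.", feats[j]))
      if (any(mj)) values[mj, j] <- median(values[!mj, j])
    }
  }
  new_feature_matrix(values, mask, orientation)
}

new_feature_matrix <- function(values, mask, orientation, stats = NULL,
                               standardized = FALSE) {
  structure(
    list(values = values, mask = mask, features = colnames(values),
         orientation = orientation, stats = stats,
         standardized = standardized),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d variants x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (z-scored)" else ""))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  n_imp <- sum(x$mask)
  if (n_imp > 0) cat(sprintf("  imputed cells: %d (%.2f%%)\n", n_imp,
                             100 * n_imp / length(x$mask)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @rdname assemble_features
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  bind_cols(tibble(variant = rownames(x$values)),
            as_tibble(x$values, .name_repair = "minimal"))
}

#' Standardize a feature matrix (z-scores)
#'
#' Centers and scales each feature to mean 0 and standard deviation 1
#' (sample standard deviation, denominator n - 1), with the statistics
#' computed over *observed* values only; imputed cells are transformed
#' with the same statistics. Constant features cannot be scaled and are
#' dropped with a warning. Stored statistics allow new variants to be
#' projected into the same standardized space (see [assign_variants()]).
#'
#' @param fm A [assemble_features()] feature matrix.
#' @param stats Optional statistics tibble (`feature`, `mean`, `sd`) from a
#'   previous call, applied as-is instead of being re-estimated.
#' @return The standardized `feature_matrix`, with `stats` recorded.
#' @export
zscore_features <- function(fm, stats = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 2L) abort("Need at least 2 variants to standardize.")
  if (anyNA(fm$values)) abort("Feature matrix contains NA cells; impute first.")
  if (is.null(stats)) {
    mu <- numeric(ncol(fm$values)); s <- numeric(ncol(fm$values))
    for (j in seq_len(ncol(fm$values))) {
      obs <- fm$values[!fm$mask[, j], j]
      if (length(obs) == 0L) obs <- fm$values[, j]
      mu[j] <- mean(obs)
      s[j] <- sd(obs)
    }
    stats <- tibble(feature = fm$features, mean = mu, sd = s)
  } else {
    stats <- stats[match(fm$features, stats$feature), , drop = FALSE]
    if (anyNA(stats$mean)) abort("Supplied `stats` do not cover all features.")
  }
  const <- which(!is.finite(stats$sd) | stats$sd == 0)
  if (length(const) > 0L) {
    warn(sprintf("Dropping constant feature(s): %s",
                 paste(fm$features[const], collapse = ", ")))
    fm$values <- fm$values[, -const, drop = FALSE]
    fm$mask <- fm$mask[, -const, drop = FALSE]
    fm$features <- colnames(fm$values)
    fm$orientation <- fm$orientation[fm$features]
    stats <- stats[-const, , drop = FALSE]
  }
  if (ncol(fm$values) == 0L) abort("All features are constant; nothing to standardize.")
  z <- sweep(sweep(fm$values, 2, stats$mean, "-"), 2, stats$sd, "/")
  new_feature_matrix(z, fm$mask, fm$orientation, stats = stats,
                     standardized = TRUE)
}

#' Write / read a feature matrix as TSV plus a JSON sidecar
#'
#' The values go to `<path>` as TSV (first column `variant`); the mask,
#' per-feature orientation, standardization flag and statistics go to
#' `<path>.json`. `read_feature_matrix()` restores an identical object.
#'
#' @param fm A `feature_matrix`.
#' @param path Output TSV path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the restored `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  readr::write_tsv(as_tibble(fm), path, progress = FALSE)
  sidecar <- list(
    features = fm$features,
    orientation = as.list(fm$orientation),
    standardized = fm$standardized,
    stats = if (is.null(fm$stats)) NULL else as.list(fm$stats),
    imputed = {
      idx <- which(fm$mask, arr.ind = TRUE)
      list(variant = rownames(fm$values)[idx[, 1]],
           feature = colnames(fm$values)[idx[, 2]])
    }
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feats <- side$features
  values <- as.matrix(tab[, feats, drop = FALSE])
  rownames(values) <- tab$variant
  mask <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  if (length(side$imputed$variant) > 0L) {
    mask[cbind(match(side$imputed$variant, rownames(values)),
               match(side$imputed$feature, colnames(values)))] <- TRUE
  }
  stats <- if (is.null(side$stats)) NULL else as_tibble(side$stats)
  new_feature_matrix(values, mask,
                     orientation = unlist(side$orientation),
                     stats = stats,
                     standardized = isTRUE(side$standardized))
}

#' @rdname tidy-dualstab
#' @export
tidy.feature_matrix <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-"variant", names_to = "feature",
                        values_to = "value") |>
    mutate(imputed = as.vector(t(x$mask)))
}
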