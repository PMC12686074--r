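#' Default feature set for the variant feature matrix
#'
#' The nine features used by the clustering workflow: seven per-variant
#' predictor scores plus the free-energy changes of the open and closed
#' conformations.
#'
#' @return Character vector of feature names.
#' @export
default_features <- function() {
  c("CADD", "AlphaMissense", "ESM1b", "PolyPhen2", "SIFT", "MutFunc",
    "ClinPred", "ddG_open", "ddG_closed")
}

# Normalize predictor-name spelling variants used in the wild.
canonical_feature_name <- function(x) {
  alias <- c(
    "ESMB1" = "ESM1b", "ESMB-1" = "ESM1b", "ESM-1B" = "ESM1b",
    "ESM1B" = "ESM1b", "POLYPHEN2" = "PolyPhen2", "POLYPHEN-2" = "PolyPhen2",
    "ALPHAMISSENSE" = "AlphaMissense", "CADD" = "CADD", "SIFT" = "SIFT",
    "MUTFUNC" = "MutFunc", "CLINPRED" = "ClinPred",
    "DDG_OPEN" = "ddG_open", "DDG_CLOSED" = "ddG_closed"
  )
  key <- toupper(x)
  ifelse(key %in% names(alias), unname(alias[key]), x)
}

# All columns are read as character and converted explicitly, so that
# malformed numerics (e.g. comma decimals) are reported with their row
# instead of being silently reinterpreted.
read_delim_auto <- function(path) {
  ct <- readr::cols(.default = readr::col_character())
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, col_types = ct, progress = FALSE)
  } else {
    readr::read_tsv(path, col_types = ct, progress = FALSE)
  }
}

#' Read a per-variant predictor score table
#'
#' Reads a TSV/CSV table of per-variant scores in either of two dialects:
#' a single variant-label column (`p.V464M`-style) or separate
#' position / reference / alternate columns. Both dialects produce an
#' identical score table. Duplicate variant keys and non-numeric values
#' are errors; each predictor declares whether higher or lower values are
#' damaging, which is kept as metadata for reporting (clustering itself is
#' orientation-agnostic).
#'
#' @param path TSV or CSV file with a header.
#' @param feature Feature name (aliases such as "ESMb-1" are normalized to
#'   "ESM1b").
#' @param orientation `"higher_is_damaging"` or `"lower_is_damaging"`.
#' @param columns Named list mapping logical roles to column names. Either
#'   `list(variant = ..., value = ...)` or
#'   `list(position = ..., ref = ..., alt = ..., value = ...)`.
#' @return A `score_table`: a tibble with columns `variant`, `position`,
#'   `ref_aa`, `alt_aa`, `value` and attributes `feature` and
#'   `orientation`.
#' @export
read_score_table <- function(path, feature,
                             orientation = c("higher_is_damaging",
                                             "lower_is_damaging"),
                             columns = list(variant = "variant",
                                            value = "value")) {
  orientation <- match.arg(orientation)
  raw <- read_delim_auto(path)
  score_table_from_df(raw, feature, orientation, columns, source = path)
}

score_table_from_df <- function(raw, feature, orientation, columns,
                                source = "<data>") {
  feature <- canonical_feature_name(feature)
  need <- unlist(columns)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Missing column(s) in %s: %s", source,
                  paste(missing_cols, collapse = ", ")))
  }
  val <- raw[[columns$value]]
  if (!is.numeric(val)) {
    suppressWarnings(num <- as.numeric(val))
    bad <- which(is.na(num) & !is.na(val))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric value '%s' in row %d of %s.",
                    val[bad[1]], bad[1], source))
    }
    val <- num
  }
  if (!is.null(columns$variant)) {
    parsed <- parse_variants(raw[[columns$variant]])
  } else {
    parsed <- tibble(
      position = as.integer(raw[[columns$position]]),
      ref_aa = toupper(as.character(raw[[columns$ref]])),
      alt_aa = toupper(as.character(raw[[columns$alt]]))
    )
    parsed$variant <- format_variant(parsed$position, parsed$ref_aa,
                                     parsed$alt_aa)
  }
  tab <- tibble(
    variant = parsed$variant, position = parsed$position,
    ref_aa = parsed$ref_aa, alt_aa = parsed$alt_aa, value = val
  )
  dup <- tab$variant[duplicated(tab$variant)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate variant key(s) in %s: %s", source,
                  paste(unique(dup), collapse = ", ")))
  }
  structure(tab, feature = feature, orientation = orientation,
            class = c("score_table", class(tab)))
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %s (%s), %d variants\n",
              attr(x, "feature"), attr(x, "orientation"), nrow(x)))
  NextMethod()
}
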