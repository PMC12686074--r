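#' Run the full variant-prioritization pipeline
#'
#' Orchestrates enumerate/parse -> score ingestion -> dual-state stability
#' -> standardization -> two-way clustering -> labelling -> enrichment ->
#' query assignment -> ranked report, as one seeded, reproducible run.
#' Each stage failure is reported with its stage name.
#'
#' The configuration is a named list (or a YAML file parsed into one) with
#' elements:
#' \describe{
#'   \item{fasta / protein}{Path to a FASTA file, or a [protein_seq()].}
#'   \item{variants}{Optional path to a one-label-per-line file or a tibble
#'     of variants to score; defaults to the full saturation space.}
#'   \item{score_tables}{List of `score_table`s, or of specs
#'     `list(path=, feature=, orientation=, columns=)` for
#'     [read_score_table()].}
#'   \item{ddg_open, ddg_closed}{Optional ddG tibbles (from
#'     [read_ddg_table()]) or path specs.}
#'   \item{flags}{Catalog-flagged variant keys (vector, tibble, or path to
#'     a TSV with `variant`/`flagged` columns).}
#'   \item{anchors}{Known-GOF anchor labels (vector or path to a text file).}
#'   \item{query}{Optional query variant labels to assign (vector or path).}
#'   \item{domains}{Optional [domain_map()].}
#'   \item{method, k, seed, tau}{Clustering method, kNN k, seed, stability
#'     threshold.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return A `prioritization_report`: list with `report` (per-variant
#'   tibble with cluster label, centroid distances, rank, flags),
#'   `clustering`, `enrichment`, `summary`, `query` (assignment of query
#'   variants, if any) and `manifest`.
#' @export
run_prioritization <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- config
  seed <- cfg$seed %||% 1L
  method <- cfg$method %||% "kmeans2"
  k <- cfg$k %||% 6L
  tau <- cfg$tau %||% 1

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }

  protein <- stage("variant_space", {
    if (!is.null(cfg$protein)) cfg$protein
    else if (!is.null(cfg$fasta)) read_protein_fasta(cfg$fasta)
    else abort("Config needs `fasta` or `protein`.")
  })
  variants <- stage("variant_space", {
    if (is.null(cfg$variants)) enumerate_saturation(protein)
    else if (is.data.frame(cfg$variants)) cfg$variants
    else parse_variants(readLines(cfg$variants), protein)
  })
  if (!is.null(cfg$domains)) {
    variants <- stage("variant_space", annotate_domains(variants, cfg$domains))
  }

  tables <- stage("score_ingest", {
    purrr::map(cfg$score_tables, function(t) {
      if (inherits(t, "score_table")) t
      else rlang::exec(read_score_table, !!!t)
    })
  })
  load_ddg <- function(x) {
    if (is.null(x) || is.data.frame(x)) x else rlang::exec(read_ddg_table, !!!x)
  }
  ddg_open <- stage("stability", load_ddg(cfg$ddg_open))
  ddg_closed <- stage("stability", load_ddg(cfg$ddg_closed))
  consensus <- NULL
  if (!is.null(ddg_open) && !is.null(ddg_closed) &&
      all(c("predictor", "state") %in% names(ddg_open))) {
    consensus <- stage("stability",
      dual_state_profile(bind_rows(ddg_open, ddg_closed), tau = tau)$consensus)
  }

  fm <- stage("score_ingest", assemble_features(
    variants, tables, ddg_open = ddg_open, ddg_closed = ddg_closed
  ))
  zfm <- stage("score_ingest", zscore_features(fm))

  flags <- stage("cluster_engine", {
    f <- cfg$flags
    if (is.null(f)) character(0)
    else if (is.character(f) && length(f) == 1L && file.exists(f)) {
      readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
    } else f
  })
  anchors <- stage("cluster_engine", {
    a <- cfg$anchors
    if (is.null(a)) NULL
    else if (is.character(a) && length(a) == 1L && file.exists(a)) readLines(a)
    else a
  })

  clustering <- stage("cluster_engine",
    cluster_variants(zfm, method = method, k = k, seed = seed))
  clustering <- stage("cluster_engine",
    label_clusters(clustering, flags, anchors))
  enrichment <- stage("cluster_engine", {
    flagged <- normalize_flags(flags, clustering$assignment$variant)
    if (sum(flagged) > 0L && !all(flagged)) enrichment_test(clustering, flags)
    else NULL
  })
  summary_tbl <- stage("cluster_engine",
    summarize_clusters(clustering, fm, anchors = anchors))

  assignment <- stage("cluster_engine",
    assign_variants(fm, clustering))

  report <- stage("report", {
    labels <- clustering$labels
    out <- variants |>
      left_join(clustering$assignment, by = "variant") |>
      mutate(label = unname(labels[as.character(.data$cluster)])) |>
      left_join(select(assignment, "variant", "dist_benign_like",
                       "dist_pathogenic_like"), by = "variant") |>
      mutate(flagged = normalize_flags(flags, .data$variant),
             anchor = .data$variant %in% (anchors %||% character(0)))
    if (!is.null(consensus)) {
      out <- left_join(out, consensus, by = "variant")
    }
    # pathogenic-like first, then decreasing distance to the benign centroid
    ord <- order(out$label != "pathogenic_like", -out$dist_benign_like,
                 out$variant)
    out$rank <- NA_integer_
    out$rank[ord] <- seq_len(nrow(out))
    arrange(out, .data$rank)
  })

  query <- NULL
  if (!is.null(cfg$query)) {
    query <- stage("assign", {
      q <- cfg$query
      if (is.character(q) && length(q) == 1L && file.exists(q)) q <- readLines(q)
      q_tab <- if (is.data.frame(q)) q else parse_variants(q, protein)
      idx <- match(q_tab$variant, report$variant)
      if (anyNA(idx)) abort(sprintf("Query variant(s) not in the scored set: %s",
                                    paste(q_tab$variant[is.na(idx)], collapse = ", ")))
      report[idx, ]
    })
  }

  manifest <- list(
    seed = seed, method = method, k = k, tau = tau,
    n_variants = nrow(report),
    cluster_sizes = as.list(setNames(clustering$sizes, c("cluster_1", "cluster_2"))),
    labels = as.list(clustering$labels),
    enrichment = if (!is.null(enrichment)) {
      list(odds_ratio = enrichment$odds_ratio, p_value = enrichment$p_value,
           enriched_cluster = enrichment$enriched_cluster)
    },
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("dualstab"))
  )
  structure(
    list(report = report, clustering = clustering, enrichment = enrichment,
         summary = summary_tbl, query = query, manifest = manifest),
    class = "prioritization_report"
  )
}

#' @export
print.prioritization_report <- function(x, ...) {
  cat(sprintf("<prioritization_report> %d variants, method=%s, seed=%d\n",
              x$manifest$n_variants, x$manifest$method, x$manifest$seed))
  print(x$clustering)
  if (!is.null(x$query)) {
    cat(sprintf("  query variants: %d (%d pathogenic-like)\n",
                nrow(x$query), sum(x$query$label == "pathogenic_like")))
  }
  invisible(x)
}

#' Write a prioritization report to disk
#'
#' Writes the per-variant table as `report.tsv`, the run manifest as
#' `manifest.json` (schema version recorded), and the query assignment (if
#' any) as `query.tsv`.
#'
#' @param x A [run_prioritization()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "prioritization_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(x$report, file.path(dir, "report.tsv"), progress = FALSE)
  if (!is.null(x$query)) {
    readr::write_tsv(x$query, file.path(dir, "query.tsv"), progress = FALSE)
  }
  manifest <- c(list(schema_version = "1.0"), x$manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
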