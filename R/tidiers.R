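#' Broom-style tidiers for dualstab result objects
#'
#' `tidy()` returns one row per atomic result (variant assignment, table
#' cell, ...); `glance()` returns a one-row summary of the fit.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-dualstab
NULL

#' @rdname tidy-dualstab
#' @export
tidy.variant_clustering <- function(x, ...) {
  out <- x$assignment
  if (!is.null(x$labels)) {
    out$label <- unname(x$labels[as.character(out$cluster)])
  }
  out
}

#' @rdname tidy-dualstab
#' @export
glance.variant_clustering <- function(x, ...) {
  tibble(
    n = sum(x$sizes), n_cluster_1 = x$sizes[1], n_cluster_2 = x$sizes[2],
    method = x$method, seed = x$seed,
    benign_like = if (is.null(x$labels)) NA_integer_ else benign_cluster_id(x),
    tot_withinss = x$meta$tot_withinss %||% NA_real_,
    n_anchor_conflicts = length(x$anchor_conflicts)
  )
}

#' @rdname tidy-dualstab
#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(as.data.frame.table(x$table, responseName = "n")) |>
    rename(cluster = "Var1", catalog = "Var2") |>
    mutate(cluster = as.character(.data$cluster),
           catalog = as.character(.data$catalog))
}

#' @rdname tidy-dualstab
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
         enriched_cluster = x$enriched_cluster, haldane = x$haldane)
}

#' @rdname tidy-dualstab
#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms_used = x$n_atoms_used,
         n_pruned = x$n_pruned, degenerate = x$degenerate)
}
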