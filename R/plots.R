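#' Plot a two-way variant clustering
#'
#' Principal-component scatter of the standardized feature space, colored
#' by cluster label, with cluster centroids marked. Catalog-flagged and
#' anchor variants can be highlighted.
#'
#' @param object A [cluster_variants()] result.
#' @param fm The standardized `feature_matrix` the clustering was fit on.
#' @param flags,anchors Optional highlighting, as in [label_clusters()].
#' @param max_points Subsample limit for display (seeded by the
#'   clustering's own seed).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variant_clustering <- function(object, fm, flags = NULL,
                                        anchors = NULL, max_points = 2000,
                                        ...) {
  z <- as_z_matrix(fm)
  idx <- match(object$assignment$variant, rownames(z))
  z <- z[idx, , drop = FALSE]
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  dat <- tibble(
    variant = object$assignment$variant,
    PC1 = pc$x[, 1], PC2 = pc$x[, 2],
    cluster = factor(object$assignment$cluster)
  )
  if (!is.null(object$labels)) {
    dat$cluster <- factor(unname(object$labels[as.character(object$assignment$cluster)]))
  }
  dat$origin <- "other"
  if (!is.null(flags)) {
    dat$origin[normalize_flags(flags, dat$variant)] <- "catalog"
  }
  if (!is.null(anchors)) dat$origin[dat$variant %in% anchors] <- "anchor"
  if (nrow(dat) > max_points) {
    set.seed(object$seed)
    keep <- dat$origin != "other"
    extra <- sample(which(!keep), max_points - sum(keep))
    dat <- dat[sort(c(which(keep), extra)), ]
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster,
                                     shape = .data$origin),
                        alpha = 0.6, size = 1.3) +
    ggplot2::labs(x = "PC1 (z-scored features)", y = "PC2",
                  colour = "cluster", shape = "origin") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue fluctuation profile
#'
#' Line plot of RMSF against residue number, one panel per chain.
#'
#' @param object An [ensemble_rmsf()] profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resno, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chain), scales = "free_x") +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster feature means
#'
#' Dot plot of per-cluster feature means (original scale) from
#' [summarize_clusters()], with +/- 1 sd ranges.
#'
#' @param summary A [summarize_clusters()] tibble.
#' @return A ggplot object.
#' @export
plot_cluster_summary <- function(summary) {
  grp <- if (all(is.na(summary$label))) factor(summary$cluster) else
    factor(summary$label)
  summary$group <- grp
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$mean, y = .data$feature,
                               colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean - .data$sd, xmax = .data$mean + .data$sd),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "mean (original scale)", y = NULL, colour = "cluster") +
    ggplot2::theme_minimal()
}
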