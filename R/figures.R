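## Figure analogues: depth-vs-richness scatters per scenario, index
## distributions across scenarios, and rarefaction-curve panels contrasting
## sample-wise with pooled processing.

#' Depth-versus-richness scatter plots per scenario
#'
#' One facet per scenario: observed richness against the original full-data
#' sequencing depth, with a least-squares line. The plotted points are
#' exactly the values the grid summary was computed from.
#'
#' @param grid a `grid_result`.
#' @return a ggplot object.
#' @export
plot_depth_richness <- function(grid) {
  stopifnot(inherits(grid, "grid_result"))
  df <- do.call(rbind, lapply(names(grid$diversity), function(lab) {
    div <- grid$diversity[[lab]]
    data.frame(scenario = lab, sample_id = div$sample_id,
               original_depth = as.numeric(
                 grid$original_depths[div$sample_id]),
               observed_richness = div$observed_richness,
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$original_depth,
                                   .data$observed_richness)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::facet_wrap(~scenario, scales = "free_y") +
    ggplot2::labs(x = "original sequencing depth",
                  y = "observed richness") +
    ggplot2::theme_bw(base_size = 9)
}

#' Distribution of an alpha-diversity index across scenarios
#'
#' @param grid a `grid_result`.
#' @param index column name of [diversity_profile()] output
#'   (e.g. `"chao1"`, `"goods_coverage"`).
#' @return a ggplot object.
#' @export
plot_index_distributions <- function(grid, index = "observed_richness") {
  stopifnot(inherits(grid, "grid_result"))
  abort_if(!index %in% names(grid$diversity[[1]]),
           "unknown index: ", index)
  df <- do.call(rbind, lapply(seq_len(nrow(grid$scenarios)), function(i) {
    lab <- grid$scenarios$label[i]
    data.frame(scenario = lab,
               subsampling = grid$scenarios$subsampling[i],
               pooling = grid$scenarios$pooling[i],
               prior = grid$scenarios$prior[i],
               value = as.numeric(grid$diversity[[lab]][[index]]),
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$subsampling, .data$value,
                                   fill = .data$prior)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::facet_wrap(~pooling) +
    ggplot2::labs(x = "sub-sampling stage", y = index) +
    ggplot2::theme_bw(base_size = 9)
}

#' Rarefaction-curve panels
#'
#' @param curves a `rarefaction_curves` data frame (or an rbind of several
#'   with an extra grouping column named in `facet`).
#' @param facet optional column to facet by (e.g. `"scenario"`).
#' @return a ggplot object.
#' @export
plot_rarefaction <- function(curves, facet = NULL) {
  df <- as.data.frame(curves)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$depth,
                                        .data$expected_richness,
                                        group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = "sub-sample depth", y = "expected richness") +
    ggplot2::theme_bw(base_size = 9)
  if (!is.null(facet)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", facet)),
                                 scales = "free")
  }
  p
}

#' Write the standard figure set for a grid run
#'
#' Depth-richness scatters, observed-richness / Chao1 / coverage
#' distributions, and rarefaction panels for the no-sub-sampling
#' sample-wise vs pooled scenarios.
#'
#' @param grid a `grid_result`.
#' @param dir output directory (created if missing).
#' @param grid_points depths per rarefaction curve.
#' @return named character vector of written files, invisibly.
#' @export
make_figures <- function(grid, dir, grid_points = 20L) {
  stopifnot(inherits(grid, "grid_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    depth_richness = file.path(dir, "depth_vs_richness.png"),
    richness_dist = file.path(dir, "observed_richness_distribution.png"),
    chao1_dist = file.path(dir, "chao1_distribution.png"),
    coverage_dist = file.path(dir, "goods_coverage_distribution.png"),
    rarefaction = file.path(dir, "rarefaction_curves.png")
  )
  ggplot2::ggsave(files[["depth_richness"]], plot_depth_richness(grid),
                  width = 9, height = 7, dpi = 150)
  ggplot2::ggsave(files[["richness_dist"]],
                  plot_index_distributions(grid, "observed_richness"),
                  width = 7, height = 4, dpi = 150)
  ggplot2::ggsave(files[["chao1_dist"]],
                  plot_index_distributions(grid, "chao1"),
                  width = 7, height = 4, dpi = 150)
  ggplot2::ggsave(files[["coverage_dist"]],
                  plot_index_distributions(grid, "goods_coverage"),
                  width = 7, height = 4, dpi = 150)
  baseline <- c("none.samplewise.none", "none.pooled.none")
  curves <- do.call(rbind, lapply(baseline, function(lab) {
    cbind(scenario = lab,
          as.data.frame(rarefaction_curve(grid$tables[[lab]], grid_points)))
  }))
  ggplot2::ggsave(files[["rarefaction"]],
                  plot_rarefaction(curves, facet = "scenario"),
                  width = 8, height = 4, dpi = 150)
  invisible(files)
}
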