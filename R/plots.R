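# ggplot2 visualisations for the main result types.

#' Plot normalized window depth along the genome
#'
#' The classic coverage plot: capped normalized depth per sliding window,
#' with a reference line at 1 and optional shading of called regions.
#'
#' @param object A `window_track`.
#' @param regions Optional `region_calls` to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_track <- function(object, regions = NULL, ...) {
  df <- as_tibble(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = .data$capped_norm_depth
  ))
  if (!is.null(regions) && nrow(regions) > 0L) {
    gg <- gg + ggplot2::geom_rect(
      data = as_tibble(regions),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf,
                   fill = dplyr::coalesce(.data$label, .data$direction)),
      inherit.aes = FALSE, alpha = 0.25
    ) +
      ggplot2::labs(fill = "region")
  }
  gg +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "position (bp)", y = "normalized depth (capped)") +
    ggplot2::theme_minimal()
}

#' Plot per-site group minor allele frequencies along contigs
#'
#' Allele-frequency scatter per contig, faceted by phenotype group — the
#' visual used to spot swept (uniformly low-MAF) regions.
#'
#' @param gm A [genotype_matrix()].
#' @param group_col Sample-metadata column defining groups.
#' @param sweep Optional sweep-interval tibble to shade.
#' @return A ggplot.
#' @export
plot_group_maf <- function(gm, group_col = "phenotype", sweep = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  groups <- unique(gm$samples[[group_col]])
  df <- bind_rows(purrr::map(groups, function(g) {
    rows <- which(gm$samples[[group_col]] == g)
    st <- site_allele_stats(gm$geno[rows, , drop = FALSE])
    tibble(group = g, contig = gm$sites$contig, pos = gm$sites$pos,
           maf = st$maf)
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$maf))
  if (!is.null(sweep) && nrow(sweep) > 0L) {
    gg <- gg + ggplot2::geom_rect(
      data = as_tibble(sweep),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.2
    )
  }
  gg +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$group),
      cols = ggplot2::vars(.data$contig),
      scales = "free_x"
    ) +
    ggplot2::labs(x = "position (bp)", y = "minor allele frequency") +
    ggplot2::theme_minimal()
}

#' Plot vial sex-ratio trajectories
#'
#' One line per replicate vial: percent female among emerging adults per
#' generation, with the 50% expectation marked.
#'
#' @param object A `vial_trajectories` tibble from
#'   [simulate_mixed_population()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vial_trajectories <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$generation, y = .data$percent_female,
    group = .data$replicate
  )) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "generation", y = "% female among adults") +
    ggplot2::theme_minimal()
}
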