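#' Plot elution profiles for selected proteins
#'
#' Fraction-wise SILAC ratios per channel and replicate, the standard
#' visual check of co-elution: members of one complex display overlapping
#' profiles.
#'
#' @param chromatograms Long chromatogram tibble.
#' @param proteins Accessions to display.
#' @return A ggplot object.
#' @export
plot_profiles <- function(chromatograms, proteins) {
  df <- filter(chromatograms, .data$protein %in% proteins)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$ratio,
                                   colour = .data$protein)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(replicate ~ channel) +
    ggplot2::labs(x = "fraction", y = "SILAC ratio") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_ratio_mixture Histogram of the ratios with the fitted
#'   mixture density overlaid.
#' @param object A `cofrac_mixture`.
#' @param ... Unused.
#' @method autoplot cofrac_mixture
#' @export
autoplot.cofrac_mixture <- function(object, ...) {
  df <- tibble(x = object$data)
  grid <- tibble(x = seq(min(df$x), max(df$x), length.out = 400))
  for (j in seq_len(object$k)) {
    grid[[paste0("c", j)]] <- object$weights[j] *
      dnorm(grid$x, object$means[j], object$sds[j])
  }
  dens <- grid |>
    pivot_longer(-"x", names_to = "component", values_to = "density")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "log2 ratio", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a network's degree distribution on log-log axes
#'
#' @param edges Unique-pair edge tibble.
#' @return A ggplot object with the power-law fit overlaid when defined.
#' @export
plot_degree_distribution <- function(edges) {
  deg <- table(c(edges$protein_a, edges$protein_b))
  hist <- as.data.frame(table(as.integer(deg)), stringsAsFactors = FALSE)
  names(hist) <- c("degree", "count")
  hist$degree <- as.numeric(hist$degree)
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "vertex degree", y = "count") +
    ggplot2::theme_minimal()
  fit <- suppressWarnings(degree_powerlaw(edges))
  if (!is.na(fit$slope)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept,
                                  linetype = "dashed")
  }
  p
}

#' Map complex clusters along the separation gradient
#'
#' Cluster size against elution centre, the overview of where complexes
#' of each size elute.
#'
#' @param clusters Cluster tibble with `center` and `n_members`.
#' @return A ggplot object.
#' @export
plot_cluster_map <- function(clusters) {
  ggplot2::ggplot(clusters, ggplot2::aes(x = .data$center,
                                         y = .data$n_members)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "cluster centre (fraction)", y = "members") +
    ggplot2::theme_minimal()
}
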