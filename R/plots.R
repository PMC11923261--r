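#' Plot a free-end point cloud
#'
#' In-plane (x-y) projection of the sampled free-end positions, the view
#' used to judge ring-like confinement.
#'
#' @param object A `point_cloud`.
#' @param projection `"xy"` (default), `"xz"` or `"yz"`.
#' @param alpha Point transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.point_cloud <- function(object, projection = c("xy", "xz", "yz"),
                                 alpha = 0.2, ...) {
  projection <- match.arg(projection)
  ax <- strsplit(projection, "")[[1]]
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]])) +
    ggplot2::geom_point(alpha = alpha, size = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(ax[1], " (nm)"), y = paste0(ax[2], " (nm)"),
                  title = attr(object, "scenario") %||% NULL) +
    ggplot2::theme_minimal()
}

#' Plot an effective radial potential
#'
#' The radial density \eqn{\rho^2 P_{eq}(\rho)} and the effective
#' potential \eqn{\beta U(\rho)} side by side.
#'
#' @param object A `radial_potential`.
#' @param ... Unused.
#' @return A ggplot object (faceted).
#' @exportS3Method ggplot2::autoplot
autoplot.radial_potential <- function(object, ...) {
  df <- tibble(rho = object$rho,
               `rho^2 P_eq` = object$rho^2 * object$p_eq,
               `beta U` = object$beta_u)
  long <- tidyr::pivot_longer(df, -"rho", names_to = "panel")
  ggplot2::ggplot(long, ggplot2::aes(.data$rho, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "rho (nm)", y = NULL,
                  title = attr(object, "scenario")) +
    ggplot2::theme_minimal()
}

#' Plot normalized stepping rates over target distance
#'
#' Normalized stepping rate (scenario over baseline) as a function of the
#' tether-target distance, one line per scenario, faceted by contact
#' distance when several are present.
#'
#' @param object A `rate_table` from [sweep_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rate_table <- function(object, ...) {
  df <- as_tibble(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$normalized_rate,
                                         colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "a (nm)", y = "normalized stepping rate") +
    ggplot2::theme_minimal()
  if (length(unique(df$epsilon)) > 1)
    gg <- gg + ggplot2::facet_wrap(~epsilon,
                                   labeller = ggplot2::label_both)
  gg
}

#' Overlay a cloud marginal histogram with its model curve
#'
#' @param cloud A `point_cloud`.
#' @param scenario,params Model to overlay (defaults taken from the cloud).
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_marginal_fit <- function(cloud, scenario = attr(cloud, "scenario"),
                              params = attr(cloud, "params"),
                              axis = "x", bins = 60) {
  pts <- as_xyz(cloud)
  rng <- range(pts[[axis]])
  pad <- 0.05 * diff(rng)
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = 301)
  box <- bounding_box(params, scenario)
  lims <- list(x = box$xlim, y = box$ylim, z = box$zlim)[[axis]]
  grid <- pmin(pmax(grid, lims[1]), lims[2])
  grid <- sort(unique(grid))
  m <- marginal_density(scenario, axis, params, grid)
  ggplot2::ggplot(pts, ggplot2::aes(.data[[axis]])) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = m, ggplot2::aes(.data$value, .data$density),
                       colour = "red", linetype = 2, inherit.aes = FALSE) +
    ggplot2::labs(x = paste0(axis, " (nm)"), y = "density") +
    ggplot2::theme_minimal()
}
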