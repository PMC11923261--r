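#' Sample a synthetic free-end point cloud
#'
#' Draws i.i.d. positions from the normalized scenario density by rejection
#' sampling from a uniform envelope over the scenario bounding box. The
#' envelope constant is 1.2 times the maximum density found on a coarse
#' grid. Sampling is bitwise-reproducible: the same
#' `(scenario, params, n, seed)` always yields the same cloud
#' (Mersenne-Twister, seeded locally without touching the session RNG).
#'
#' These clouds emulate the distributional structure of coarse-grained
#' trajectory point clouds of the free end; they carry no temporal
#' correlation.
#'
#' @inheritParams free_end_density
#' @param n Number of points to draw.
#' @param seed Integer seed.
#' @return A `point_cloud`: a tibble with columns `x`, `y`, `z` (nm) and
#'   attributes `scenario`, `params`, `seed`, `source = "synthetic"` and
#'   `acceptance_rate`.
#' @examples
#' p <- confinement_params(beta_k = 5, L = 11.5)
#' cloud <- sample_free_end("baseline", p, n = 1000, seed = 1)
#' @export
sample_free_end <- function(scenario, params, n, seed) {
  validate_scenario(scenario, params)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    abort("`n` must be a positive count")
  n <- as.integer(n)
  box <- bounding_box(params, scenario)
  envelope <- 1.2 * coarse_density_max(scenario, params, box)
  if (envelope <= 0) abort("density is zero over the whole bounding box")
  vol_draw <- function(lim, m) runif(m, lim[1], lim[2])
  acc <- matrix(numeric(0), 0, 3)
  proposed <- 0
  accepted <- 0
  withr::with_seed(seed, {
    while (nrow(acc) < n) {
      rate_est <- if (proposed > 0) max(accepted / proposed, 1e-4) else 0.05
      m <- min(max(50000, ceiling(1.3 * (n - nrow(acc)) / rate_est)), 5e6)
      x <- vol_draw(box$xlim, m); y <- vol_draw(box$ylim, m)
      z <- vol_draw(box$zlim, m); u <- runif(m)
      f <- density_eval(scenario, x, y, z, params)
      keep <- u * envelope < f
      proposed <- proposed + m
      accepted <- accepted + sum(keep)
      acc <- rbind(acc, cbind(x[keep], y[keep], z[keep]))
      if (proposed >= 1e6 && accepted / proposed < 1e-4)
        abort("rejection-sampling envelope failure (acceptance < 1e-4)")
    }
  })
  rate <- accepted / proposed
  acc <- acc[seq_len(n), , drop = FALSE]
  structure(
    tibble(x = acc[, 1], y = acc[, 2], z = acc[, 3]),
    class = c("point_cloud", class(tibble())),
    scenario = scenario, params = params, seed = seed,
    source = "synthetic", acceptance_rate = rate)
}

coarse_density_max <- function(scenario, params, box, n_grid = 41) {
  gx <- seq(box$xlim[1], box$xlim[2], length.out = n_grid)
  gy <- seq(box$ylim[1], box$ylim[2], length.out = n_grid)
  gz <- seq(box$zlim[1], box$zlim[2], length.out = n_grid)
  mx <- 0
  for (z in gz) {
    f <- density_eval(scenario, rep(gx, times = n_grid),
                      rep(gy, each = n_grid), rep(z, n_grid^2), params)
    mx <- max(mx, max(f))
  }
  mx
}

#' Kolmogorov-Smirnov check of cloud marginals against a model
#'
#' One-sample KS distance per Cartesian axis between the empirical marginal
#' of a point cloud and the model's marginal CDF (obtained by quadrature).
#' For a cloud truly drawn from the model, each distance falls below
#' \eqn{1.63/\sqrt{n}} with asymptotic probability ~0.99.
#'
#' @param cloud A `point_cloud` (or any data frame with `x`, `y`, `z`).
#' @inheritParams free_end_density
#' @param n_cdf Grid size for the model marginal CDF.
#' @return A tibble with columns `axis`, `statistic`, `n`, `band`
#'   (`1.63/sqrt(n)`).
#' @export
ks_marginal_check <- function(cloud, scenario = attr(cloud, "scenario"),
                              params = attr(cloud, "params"), n_cdf = 1001) {
  pts <- as_xyz(cloud)
  n <- nrow(pts)
  if (n < 1000) abort("`cloud` must contain at least 1000 points")
  validate_scenario(scenario, params)
  box <- bounding_box(params, scenario)
  lims <- list(x = box$xlim, y = box$ylim, z = box$zlim)
  purrr::map_dfr(c("x", "y", "z"), function(ax) {
    grid <- seq(lims[[ax]][1], lims[[ax]][2], length.out = n_cdf)
    m <- marginal_density(scenario, ax, params, grid)
    cdf_vals <- pracma::cumtrapz(m$value, m$density)[, 1]
    cdf <- approxfun(m$value, pmin(cdf_vals / max(cdf_vals), 1),
                     yleft = 0, yright = 1)
    s <- sort(pts[[ax]])
    Fm <- cdf(s)
    d <- max(abs(Fm - seq_len(n) / n), abs(Fm - (seq_len(n) - 1) / n))
    tibble(axis = ax, statistic = d, n = n, band = 1.63 / sqrt(n))
  })
}
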