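#' One-dimensional marginal of a confined free-end density
#'
#' Integrates the scenario density over the two remaining Cartesian axes by
#' Gauss-Legendre quadrature and returns the marginal normalized on the
#' supplied grid. The grid must cover the support: if the mass it captures
#' falls short of the full 3-D normalization constant by more than 1%, an
#' error is raised.
#'
#' @inheritParams free_end_density
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param grid Strictly increasing numeric vector (nm) on which to evaluate
#'   the marginal.
#' @param n_quad Quadrature nodes per integrated axis.
#' @return A tibble with columns `value` (the grid) and `density`,
#'   integrating to 1 on the grid (trapezoid rule).
#' @examples
#' p <- confinement_params(beta_k = 5, L = 11.5)
#' m <- marginal_density("baseline", "x", p, seq(-15, 15, length.out = 101))
#' sum(diff(m$value) * (head(m$density, -1) + tail(m$density, -1)) / 2)
#' @export
marginal_density <- function(scenario, axis = c("x", "y", "z"), params, grid,
                             n_quad = 48) {
  axis <- match.arg(axis)
  validate_scenario(scenario, params)
  if (length(grid) < 5 || is.unsorted(grid, strictly = TRUE))
    abort("`grid` must be a strictly increasing vector of length >= 5")
  vals <- marginal_values(scenario, axis, params, grid, n_quad)
  mass_on_grid <- pracma::trapz(grid, vals)
  total <- normalization_constant(scenario, params)
  if (mass_on_grid < (1 - 0.01) * total)
    abort(sprintf(
      "grid does not cover the support of the %s-marginal (mass deficit %.2f%%)",
      axis, 100 * (1 - mass_on_grid / total)))
  tibble(value = grid, density = vals / mass_on_grid)
}

## unnormalized marginal values at `grid` along `axis`
marginal_values <- function(scenario, axis, params, grid, n_quad = 48) {
  box <- bounding_box(params, scenario)
  other <- setdiff(c("x", "y", "z"), axis)
  lims <- list(x = box$xlim, y = box$ylim, z = box$zlim)
  g1 <- gl_rule(n_quad, lims[[other[1]]][1], lims[[other[1]]][2])
  g2 <- gl_rule(n_quad, lims[[other[2]]][1], lims[[other[2]]][2])
  ng <- length(grid)
  ## full tensor grid: grid x g1 x g2
  A <- rep(grid, times = n_quad * n_quad)
  B <- rep(rep(g1$x, each = ng), times = n_quad)
  C <- rep(g2$x, each = ng * n_quad)
  W <- rep(rep(g1$w, each = ng), times = n_quad) * rep(g2$w, each = ng * n_quad)
  coords <- setNames(list(A, B, C), c(axis, other))
  f <- density_eval(scenario, coords$x, coords$y, coords$z, params)
  rowSums(matrix(W * f, nrow = ng))
}
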