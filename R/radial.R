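## Mean-field radial reduction about the binding target.
##
## The 3-D density is re-expressed in spherical polars centered on the
## target at (a, 0, 0): x = a + rho sin(theta) cos(phi),
## y = rho sin(theta) sin(phi), z = rho cos(theta), and integrated over the
## angles theta in [0, pi/2], phi in [0, pi] (the phi half-range exploits
## the y-mirror symmetry of every scenario). The steric constraints
## 0 <= z <= z_max and |y| <= h_max/2 are imposed as exact limits of the
## angular domain, so the Gauss-Legendre quadrature only ever sees smooth
## integrands:
##   theta in [acos(min(1, z_max/rho)), pi/2]
##   phi   in [0, phi1] U [pi - phi1, pi], phi1 = asin(min(1, h_max/(2 rho sin theta)))
## (when the trench constraint is inactive the two phi intervals tile
## [0, pi] exactly).

#' Radial equilibrium density of the free end about the target
#'
#' Builds the mean-field radial density \eqn{P_{eq}(\rho)} of the
#' target-to-free-end distance by angular integration of the scenario
#' density, normalized so that \eqn{\int_\epsilon^{\rho_{max}} \rho^2
#' P_{eq}\, d\rho = 1}. The outer cutoff is
#' \eqn{\rho_{max} = a + L + 6/\sqrt{\beta k}}, beyond which the shell mass
#' is negligible (< 1e-9).
#'
#' @inheritParams free_end_density
#' @param geom A [target_geometry()] object (target distance `a` and
#'   contact distance `epsilon`).
#' @param rho_grid Optional strictly increasing radial grid starting at
#'   `epsilon`; by default `n_rho` log-spaced points on
#'   `[epsilon, rho_max]`.
#' @param n_rho Number of default radial grid points.
#' @param n_theta,n_phi Gauss-Legendre nodes for the polar and azimuthal
#'   integrals.
#' @return A `radial_potential` tibble with columns `rho`, `p_eq`,
#'   `beta_u` (`NA` until [effective_potential()] is applied) and
#'   `reachable`; scenario, parameters and geometry are carried as
#'   attributes.
#' @examples
#' p <- confinement_params(beta_k = 5, L = 11.5)
#' rp <- radial_equilibrium_density("baseline", p, target_geometry(11.5, 2))
#' rp$rho[which.max(rp$rho^2 * rp$p_eq)]
#' @export
radial_equilibrium_density <- function(scenario, params, geom,
                                       rho_grid = NULL, n_rho = 400,
                                       n_theta = 48, n_phi = 48) {
  validate_scenario(scenario, params)
  stopifnot(inherits(geom, "target_geometry"))
  rho_max <- geom$a + params$L + 6 / sqrt(params$beta_k)
  if (geom$epsilon >= rho_max)
    abort("`epsilon` lies outside the radial domain (epsilon >= rho_max)")
  if (is.null(rho_grid)) {
    rho_grid <- exp(seq(log(geom$epsilon), log(rho_max), length.out = n_rho))
    rho_grid[1] <- geom$epsilon
    rho_grid[length(rho_grid)] <- rho_max
  } else {
    if (is.unsorted(rho_grid, strictly = TRUE))
      abort("`rho_grid` must be strictly increasing")
    if (abs(rho_grid[1] - geom$epsilon) > 1e-9)
      abort("`rho_grid` must start at `epsilon`")
    rho_max <- rho_grid[length(rho_grid)]
  }
  p_ang <- angular_integral(scenario, params, geom$a, rho_grid,
                            n_theta, n_phi)
  w <- rho_grid^2 * p_ang
  Z <- pracma::trapz(rho_grid, w)
  if (!is.finite(Z) || Z <= 0)
    abort("empty radial support: the density vanishes on the whole grid")
  new_radial_potential(
    tibble(rho = rho_grid, p_eq = p_ang / Z, beta_u = NA_real_,
           reachable = NA),
    scenario = scenario, params = params, geom = geom, rho_max = rho_max)
}

new_radial_potential <- function(df, scenario, params, geom, rho_max) {
  structure(df,
            class = c("radial_potential", class(tibble())),
            scenario = scenario, params = params, geom = geom,
            rho_max = rho_max)
}

## P_eq(rho) = int density(r(rho,theta,phi)) sin(theta) dtheta dphi,
## vectorized over the whole rho grid at once.
angular_integral <- function(scenario, params, a, rho, n_theta, n_phi) {
  nr <- length(rho)
  xi_t <- gl_rule(n_theta, 0, 1)
  xi_p <- gl_rule(n_phi, 0, 1)
  th0 <- if (has_tail_confinement(scenario)) {
    acos(pmin(1, params$z_max / rho))
  } else rep(0, nr)
  jac_t <- pi / 2 - th0                               # length nr
  ## theta array: nr x n_theta
  TH <- th0 + outer(jac_t, xi_t$x)
  ST <- sin(TH); CT <- cos(TH)
  ## phi half-width per (rho, theta): nr x n_theta
  PHI1 <- if (has_trench_confinement(scenario)) {
    asin(pmin(1, params$h_max / (2 * (rho * ST))))
  } else matrix(pi / 2, nr, n_theta)
  acc <- matrix(0, nr, n_theta)                       # phi-integrated density
  for (side in 1:2) {
    for (j in seq_len(n_phi)) {
      PH <- if (side == 1) PHI1 * xi_p$x[j] else pi - PHI1 * xi_p$x[j]
      X <- a + (rho * ST) * cos(PH)
      Y <- (rho * ST) * sin(PH)
      Z <- rho * CT
      f <- density_eval(scenario, as.vector(X), as.vector(Y), as.vector(Z),
                        params)
      acc <- acc + xi_p$w[j] * PHI1 * matrix(f, nr, n_theta)
    }
  }
  ## theta quadrature with sin(theta) measure and interval jacobian
  as.vector(((acc * ST) %*% xi_t$w) * jac_t)
}

#' Effective radial potential from a radial equilibrium density
#'
#' Fills `beta_u = -log(rho^2 p_eq)` (energy in units of \eqn{k_BT}).
#' Grid points where \eqn{\rho^2 P_{eq}} falls below `floor_frac` times its
#' maximum are marked unreachable (`reachable = FALSE`, `beta_u = NA`):
#' the walker effectively never visits them and downstream integrals treat
#' them as reflecting walls.
#'
#' @param rp A `radial_potential` from [radial_equilibrium_density()].
#' @param floor_frac Relative floor under which \eqn{\rho^2 P_{eq}} is
#'   treated as zero.
#' @return `rp` with `beta_u` and `reachable` filled.
#' @export
effective_potential <- function(rp, floor_frac = 1e-300) {
  stopifnot(inherits(rp, "radial_potential"))
  w <- rp$rho^2 * rp$p_eq
  floor_val <- floor_frac * max(w)
  reach <- w > floor_val & is.finite(w)
  if (!any(reach)) abort("all grid points are unreachable (p_eq ~ 0 everywhere)")
  rp$beta_u <- ifelse(reach, -log(w), NA_real_)
  rp$reachable <- reach
  rp
}

#' Radial potential about a target (density + effective potential)
#'
#' Convenience wrapper:
#' [radial_equilibrium_density()] followed by [effective_potential()].
#'
#' @inheritParams radial_equilibrium_density
#' @inheritParams effective_potential
#' @return A `radial_potential` tibble with `p_eq`, `beta_u`, `reachable`
#'   filled.
#' @export
radial_potential <- function(scenario, params, geom, rho_grid = NULL,
                             n_rho = 400, n_theta = 48, n_phi = 48,
                             floor_frac = 1e-300) {
  effective_potential(
    radial_equilibrium_density(scenario, params, geom, rho_grid, n_rho,
                               n_theta, n_phi),
    floor_frac = floor_frac)
}

#' Construct a radial potential from explicit density values
#'
#' Builds a `radial_potential` directly from a radial grid and (possibly
#' unnormalized) radial density values, normalizing so that
#' \eqn{\int \rho^2 P_{eq} d\rho = 1} and filling the effective
#' potential. Useful for analytically known landscapes (e.g. the flat
#' potential whose Szabo time has a closed form).
#'
#' @param rho Strictly increasing radial grid (nm); `rho[1]` is the
#'   contact distance.
#' @param p_eq Non-negative radial density values on `rho`.
#' @return A `radial_potential` with scenario tag `"manual"`.
#' @examples
#' rho <- seq(2, 12, length.out = 201)
#' rp <- manual_radial_potential(rho, 1 / rho^2)  # flat beta*U
#' @export
manual_radial_potential <- function(rho, p_eq) {
  if (is.unsorted(rho, strictly = TRUE)) abort("`rho` must be strictly increasing")
  if (length(rho) != length(p_eq) || any(p_eq < 0))
    abort("`p_eq` must be non-negative and match `rho` in length")
  Z <- pracma::trapz(rho, rho^2 * p_eq)
  if (!is.finite(Z) || Z <= 0) abort("`p_eq` carries no mass")
  effective_potential(new_radial_potential(
    tibble(rho = rho, p_eq = p_eq / Z, beta_u = NA_real_, reachable = NA),
    scenario = "manual", params = NULL,
    geom = structure(list(a = 0, epsilon = rho[1]), class = "target_geometry"),
    rho_max = max(rho)))
}

#' Write or read a radial potential as CSV
#'
#' Three columns (`rho`, `p_eq`, `beta_u`) with a commented header
#' recording scenario, parameters and target geometry, so the file
#' round-trips.
#'
#' @param rp A `radial_potential`.
#' @param path File path.
#' @return `read_radial_potential()` returns a `radial_potential`;
#'   `write_radial_potential()` returns `path` invisibly.
#' @export
write_radial_potential <- function(rp, path) {
  stopifnot(inherits(rp, "radial_potential"))
  params <- attr(rp, "params"); geom <- attr(rp, "geom")
  hdr <- c(
    paste0("# scenario: ", attr(rp, "scenario")),
    paste0("# a: ", format(geom$a, digits = 15)),
    paste0("# epsilon: ", format(geom$epsilon, digits = 15)),
    vapply(names(params)[!vapply(params, is.null, logical(1))],
           function(nm) paste0("# ", nm, ": ", format(params[[nm]], digits = 15)),
           character(1)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(rp[c("rho", "p_eq", "beta_u")]), con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_radial_potential
#' @export
read_radial_potential <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- parse_kv_header(hdr)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  par_keys <- intersect(names(meta), c("beta_k", "L", "beta_k_prime", "z_max",
                                       "beta_k_dprime", "h_max", "n_terms"))
  params <- do.call(confinement_params, lapply(meta[par_keys], as.numeric))
  geom <- target_geometry(as.numeric(meta$a), as.numeric(meta$epsilon))
  rp <- new_radial_potential(
    tibble(rho = df$rho, p_eq = df$p_eq, beta_u = df$beta_u,
           reachable = is.finite(df$beta_u)),
    scenario = meta$scenario, params = params, geom = geom,
    rho_max = max(df$rho))
  rp
}

parse_kv_header <- function(hdr) {
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  setNames(as.list(vals), trimws(keys))
}
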