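#' Mean stepping time from the Szabo relation
#'
#' Evaluates the mean first-reaction time of a 1-D diffuser in the
#' effective radial potential \eqn{U(\rho)} with a partially reactive
#' boundary at the contact distance \eqn{\epsilon}:
#' \deqn{\tau = \frac{1}{D}\int_\epsilon^{\rho_{max}} e^{\beta U(\rho)}
#'   \Big[\int_\rho^{\rho_{max}} e^{-\beta U(\rho')} d\rho'\Big]^2 d\rho
#'   + \frac{e^{\beta U(\epsilon)}}{\kappa},}
#' with the outer boundary reflecting at \eqn{\rho_{max}} and the initial
#' position Boltzmann-distributed in \eqn{U(\rho)}. The first term is the
#' mean time to the first encounter; the second collects the rebounds
#' before a successful reaction. Since \eqn{\rho^2 P_{eq}} is normalized,
#' \eqn{e^{-\beta U(\rho)} = \rho^2 P_{eq}(\rho)} and the nested integrals
#' are evaluated by a single cumulative trapezoid pass over the grid;
#' unreachable grid regions are excluded from the outer integral.
#'
#' @param rp A `radial_potential` (with `beta_u` filled, normalized per
#'   [radial_equilibrium_density()]).
#' @param kin A [kinetic_params()] object.
#' @return A one-row tibble with columns `tau`, `tau_diffusion`,
#'   `tau_reaction` (seconds); `tau = tau_diffusion + tau_reaction`.
#' @examples
#' p <- confinement_params(beta_k = 5, L = 11.5)
#' rp <- radial_potential("baseline", p, target_geometry(11.5, 2))
#' szabo_mfpt(rp, kinetic_params(D = 5e7, kappa = 1))
#' @export
szabo_mfpt <- function(rp, kin) {
  stopifnot(inherits(rp, "radial_potential"), inherits(kin, "kinetic_params"))
  if (all(is.na(rp$beta_u)))
    abort("`rp` has no effective potential; run effective_potential() first")
  if (!isTRUE(rp$reachable[1]))
    abort("the contact distance epsilon is unreachable (p_eq ~ 0 at the grid start)")
  rho <- rp$rho
  w <- rp$rho^2 * rp$p_eq                      # e^{-beta U}
  w[!rp$reachable] <- 0
  cum <- pracma::cumtrapz(rho, w)[, 1]
  inner <- cum[length(cum)] - cum              # int_rho^rhomax e^{-bU}
  integrand <- ifelse(rp$reachable, inner^2 / w, 0)
  tau_diff <- pracma::trapz(rho, integrand) / kin$D
  tau_react <- 1 / (kin$kappa * w[1])
  if (!is.finite(tau_diff) || !is.finite(tau_react))
    abort("non-finite Szabo integral (potential too extreme for the grid)")
  tibble(tau = tau_diff + tau_react, tau_diffusion = tau_diff,
         tau_reaction = tau_react)
}

#' Diffusion-to-reaction regime ratio
#'
#' Returns \eqn{D\sqrt{\beta k}/\kappa}, the dimensionless ratio comparing
#' diffusive relaxation across the shell width to the intrinsic
#' reactivity. Values much larger than 1 place the kinetics in the
#' reaction-limited regime, where the stepping time is dominated by the
#' rebound term \eqn{e^{\beta U(\epsilon)}/\kappa}.
#'
#' @inheritParams free_end_density
#' @param kin A [kinetic_params()] object.
#' @return A dimensionless scalar.
#' @examples
#' regime_ratio(confinement_params(beta_k = 5, L = 11.5), kinetic_params())
#' @export
regime_ratio <- function(params, kin) {
  stopifnot(inherits(params, "confinement_params"),
            inherits(kin, "kinetic_params"))
  kin$D * sqrt(params$beta_k) / kin$kappa
}

#' Stepping rate of a confined scenario normalized by the baseline
#'
#' Computes \eqn{\tau_{baseline}/\tau_{scenario}} at a common target
#' geometry and kinetic parameters (both stepping times via
#' [szabo_mfpt()]). With `method = "contact"` the reaction-limited
#' approximation is used instead: the ratio of the normalized contact
#' densities \eqn{[\rho^2 P_{eq}(\epsilon)]_{scenario} /
#' [\rho^2 P_{eq}(\epsilon)]_{baseline}}, which agrees with the full ratio
#' to well under 1% whenever [regime_ratio()] exceeds about 1e4.
#'
#' @inheritParams radial_equilibrium_density
#' @param kin A [kinetic_params()] object.
#' @param method `"szabo"` (full relation) or `"contact"`
#'   (reaction-limited contact-density ratio).
#' @return A dimensionless scalar (> 1 means faster stepping than baseline).
#' @export
normalized_rate <- function(scenario, params, kin, geom,
                            method = c("szabo", "contact"),
                            n_rho = 400, n_theta = 48, n_phi = 48) {
  method <- match.arg(method)
  rp_s <- radial_potential(scenario, params, geom, n_rho = n_rho,
                           n_theta = n_theta, n_phi = n_phi)
  if (scenario == "baseline" && method == "szabo") return(1)
  rp_b <- radial_potential("baseline", params, geom, n_rho = n_rho,
                           n_theta = n_theta, n_phi = n_phi)
  if (method == "contact") {
    w_s <- rp_s$rho[1]^2 * rp_s$p_eq[1]
    w_b <- rp_b$rho[1]^2 * rp_b$p_eq[1]
    return(w_s / w_b)
  }
  szabo_mfpt(rp_b, kin)$tau / szabo_mfpt(rp_s, kin)$tau
}

#' Sweep stepping times and normalized rates over target distances
#'
#' Evaluates [szabo_mfpt()] for each requested scenario on a grid of
#' tether-target distances `a` and contact distances `epsilon`, and
#' normalizes every stepping rate by the baseline at the matching
#' `(a, epsilon)` (the baseline is always computed, and included in the
#' output when listed in `scenarios`). Rows where the evaluation fails are
#' flagged (`ok = FALSE`) rather than dropped.
#'
#' @param scenarios Character vector of scenario tags.
#' @inheritParams free_end_density
#' @param kin A [kinetic_params()] object.
#' @param a_grid Numeric vector of tether-target distances (nm).
#' @param epsilon Numeric vector of contact distances (nm).
#' @param n_rho,n_theta,n_phi Quadrature resolution passed through to
#'   [radial_potential()].
#' @return A `rate_table` tibble with columns `scenario`, `a`, `epsilon`,
#'   `tau`, `tau_diffusion`, `tau_reaction`, `normalized_rate`, `ok`.
#' @examples
#' p <- confinement_params(beta_k = 5, L = 11.5)
#' sweep_rates("baseline", p, kinetic_params(), a_grid = 11.5, epsilon = 2)
#' @export
sweep_rates <- function(scenarios, params, kin, a_grid, epsilon,
                        n_rho = 400, n_theta = 48, n_phi = 48) {
  if (!length(a_grid)) abort("`a_grid` must be non-empty")
  purrr::walk(scenarios, validate_scenario, params = params)
  grid <- tidyr::expand_grid(a = a_grid, epsilon = epsilon)
  rows <- purrr::pmap(grid, function(a, epsilon) {
    geom <- target_geometry(a, epsilon)
    tau_of <- function(scn) {
      tryCatch({
        rp <- radial_potential(scn, params, geom, n_rho = n_rho,
                               n_theta = n_theta, n_phi = n_phi)
        szabo_mfpt(rp, kin)
      }, error = function(e) {
        tibble(tau = NA_real_, tau_diffusion = NA_real_,
               tau_reaction = NA_real_)
      })
    }
    base <- tau_of("baseline")
    out <- lapply(union("baseline", scenarios), function(scn) {
      res <- if (scn == "baseline") base else tau_of(scn)
      dplyr::mutate(res,
        scenario = scn, a = a, epsilon = epsilon,
        normalized_rate = base$tau / .data$tau,
        ok = is.finite(.data$tau), .before = 1)
    })
    dplyr::bind_rows(out)
  })
  tab <- dplyr::bind_rows(rows)
  tab <- tab[tab$scenario %in% scenarios, , drop = FALSE]
  tab <- dplyr::arrange(tab, factor(.data$scenario, levels = scenario_tags),
                        .data$epsilon, .data$a)
  tab <- tab[, c("scenario", "a", "epsilon", "tau", "tau_diffusion",
                 "tau_reaction", "normalized_rate", "ok")]
  structure(tab, class = c("rate_table", class(tibble())))
}

#' Write a rate table to CSV
#'
#' Plain CSV with the exact column names of the rate-table schema.
#'
#' @param tab A `rate_table` from [sweep_rates()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(tab, path) {
  readr::write_csv(as_tibble(tab), path)
  invisible(path)
}
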