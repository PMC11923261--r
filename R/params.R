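#' Geometry and stiffness parameters of the confined walker-foothold complex
#'
#' Bundles the parameters of the confined free-end probability densities:
#' the harmonic shell stiffness and mean complex length of the baseline
#' model, the slit (tail) confinement, and the trench confinement. All
#' energies are expressed in units of \eqn{k_BT}, so only the products
#' \eqn{\beta k}, \eqn{\beta k'}, \eqn{\beta k''} appear.
#'
#' @param beta_k Shell stiffness \eqn{\beta k} (nm^-2). The free end is
#'   harmonically biased towards the hemispherical shell of radius `L`.
#' @param L Mean length of the walker-foothold complex (nm); the radius of
#'   the preferred shell.
#' @param beta_k_prime Tail-confinement stiffness \eqn{\beta k'} (nm^-2),
#'   damping the higher modes of the slit sine series. Required for the
#'   `"tail"` and `"combined"` scenarios.
#' @param z_max Vertical confinement height (nm): the free end is restricted
#'   to \eqn{0 \le z \le z_{max}} when a tail is present.
#' @param beta_k_dprime Trench-series stiffness \eqn{\beta k''} (nm^-2),
#'   only used by the `"trench_series"` scenario (the full cosine series).
#'   No canonical value exists; it must be supplied explicitly.
#' @param h_max Trench width (nm): lateral restriction
#'   \eqn{|y| \le h_{max}/2}. Required for trench and combined scenarios.
#' @param n_terms Truncation order of the confinement series (default 20).
#'
#' @return An object of class `confinement_params` (a named list).
#' @seealso [target_geometry()], [kinetic_params()], [free_end_density()]
#' @examples
#' confinement_params(beta_k = 5, L = 11.5)
#' confinement_params(beta_k = 5, L = 11.5, beta_k_prime = 0.75, z_max = 12.5)
#' @export
confinement_params <- function(beta_k = 5, L = 11.5,
                               beta_k_prime = NULL, z_max = NULL,
                               beta_k_dprime = NULL, h_max = NULL,
                               n_terms = 20L) {
  chk_pos <- function(x, nm, allow_null = TRUE) {
    if (is.null(x)) {
      if (allow_null) return(invisible(NULL))
      abort(paste0("`", nm, "` must be supplied"))
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      abort(paste0("`", nm, "` must be a single positive finite number"))
  }
  chk_pos(beta_k, "beta_k", allow_null = FALSE)
  chk_pos(L, "L", allow_null = FALSE)
  chk_pos(beta_k_prime, "beta_k_prime")
  chk_pos(z_max, "z_max")
  chk_pos(beta_k_dprime, "beta_k_dprime")
  chk_pos(h_max, "h_max")
  if (!is.numeric(n_terms) || length(n_terms) != 1L || n_terms < 1)
    abort("`n_terms` must be an integer >= 1")
  structure(
    list(beta_k = beta_k, L = L, beta_k_prime = beta_k_prime, z_max = z_max,
         beta_k_dprime = beta_k_dprime, h_max = h_max,
         n_terms = as.integer(n_terms)),
    class = "confinement_params")
}

#' @export
print.confinement_params <- function(x, ...) {
  cat("<confinement_params>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Transport and reaction parameters of the stepping kinetics
#'
#' @param D Diffusion coefficient of the free end of the complex (nm^2/s).
#'   The default corresponds to 50 um^2/s.
#' @param kappa Intrinsic (sequence-dependent) reactivity of the contact
#'   boundary (nm/s).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params()          # D = 5e7 nm^2/s, kappa = 1 nm/s
#' @export
kinetic_params <- function(D = 5e7, kappa = 1) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    abort("`D` must be a single positive finite number (nm^2/s)")
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    abort("`kappa` must be a single positive finite number (nm/s)")
  structure(list(D = D, kappa = kappa), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> D = %g nm^2/s, kappa = %g nm/s\n", x$D, x$kappa))
  invisible(x)
}

#' Position of the binding target relative to the tether
#'
#' The target (the base of the next foothold) sits on the substrate plane at
#' `(a, 0, 0)`; binding can occur once the free end comes within the contact
#' distance `epsilon` of it, which lumps the toehold reach.
#'
#' @param a Tether-to-target distance along x (nm), `a >= 0`.
#' @param epsilon Contact (binding) distance (nm), `> 0`.
#' @return An object of class `target_geometry`.
#' @examples
#' target_geometry(a = 11.5, epsilon = 2)
#' @export
target_geometry <- function(a, epsilon) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0)
    abort("`a` must be a single finite number >= 0")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0)
    abort("`epsilon` must be a single positive finite number")
  structure(list(a = a, epsilon = epsilon), class = "target_geometry")
}

#' @export
print.target_geometry <- function(x, ...) {
  cat(sprintf("<target_geometry> a = %g nm, epsilon = %g nm\n", x$a, x$epsilon))
  invisible(x)
}

## Scenario tags ------------------------------------------------------------

scenario_tags <- c("baseline", "tail", "trench", "trench_series", "combined")

has_tail_confinement <- function(scenario) scenario %in% c("tail", "combined")
has_trench_confinement <- function(scenario)
  scenario %in% c("trench", "trench_series", "combined")

#' Validate a scenario tag against a parameter set
#'
#' Checks that `scenario` is one of `"baseline"`, `"tail"`, `"trench"`,
#' `"trench_series"`, `"combined"` and that `params` carries the fields the
#' scenario needs (`beta_k_prime`/`z_max` for tail-like scenarios, `h_max`
#' for trench-like ones, `beta_k_dprime` for the full trench series).
#'
#' @param scenario Scenario tag (character scalar).
#' @param params A [confinement_params()] object.
#' @return `scenario`, invisibly, after validation.
#' @export
validate_scenario <- function(scenario, params) {
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% scenario_tags)
    abort(paste0("`scenario` must be one of: ",
                 paste(scenario_tags, collapse = ", ")))
  if (!inherits(params, "confinement_params"))
    abort("`params` must be a confinement_params object")
  need <- function(field) {
    if (is.null(params[[field]]))
      abort(sprintf("scenario \"%s\" requires `%s` in `params`", scenario, field))
  }
  if (has_tail_confinement(scenario)) { need("beta_k_prime"); need("z_max") }
  if (has_trench_confinement(scenario)) need("h_max")
  if (scenario == "trench_series") need("beta_k_dprime")
  invisible(scenario)
}

## Config round-trip --------------------------------------------------------

#' Read or write a confinement parameter set as a flat config file
#'
#' Parameter sets serialize to a flat key-value file in YAML or JSON
#' (chosen by the file extension), with keys named exactly
#' `beta_k`, `L`, `beta_k_prime`, `z_max`, `beta_k_dprime`, `h_max`,
#' `n_terms`.
#'
#' @param params A [confinement_params()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_params_config()` returns a `confinement_params` object;
#'   `write_params_config()` returns `path` invisibly.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "confinement_params"))
  x <- params[!vapply(params, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("beta_k", "L", "beta_k_prime", "z_max", "beta_k_dprime",
             "h_max", "n_terms")
  extra <- setdiff(names(x), known)
  if (length(extra))
    abort(paste0("unknown config keys: ", paste(extra, collapse = ", ")))
  do.call(confinement_params, x)
}
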