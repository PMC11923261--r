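#' Minimal annulus enclosing a fraction of an in-plane point cloud
#'
#' Exhaustive (brute-force) search over concentric radius pairs on a
#' regular grid centered at the tether-projected origin: among all pairs
#' `(R_min, R_max)` whose annulus encloses at least `coverage` of the
#' points, the one of minimal area `pi (R_max^2 - R_min^2)` is returned,
#' ties broken by smaller `R_max`, then larger `R_min`.
#'
#' @param points A data frame with at least columns `x` and `y` (nm);
#'   further columns are ignored.
#' @param coverage Required enclosed fraction, strictly between 0 and 1
#'   (default 0.9).
#' @param grid_step Radius grid step (nm, default 0.05).
#' @return An `annulus_fit` object (fields `R_min`, `R_max`, `coverage`,
#'   `coverage_target`, `n`, `grid_step`) with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 100)
#' fit_annulus(data.frame(x = 5 * cos(th), y = 5 * sin(th)))
#' @export
fit_annulus <- function(points, coverage = 0.9, grid_step = 0.05) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points)))
    abort("`points` must be a data frame with columns x and y")
  if (nrow(points) < 10) abort("need at least 10 points")
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1)
    abort("`coverage` must be strictly between 0 and 1")
  r <- sqrt(points$x^2 + points$y^2)
  if (diff(range(points$x)) == 0 && diff(range(points$y)) == 0)
    abort("degenerate input: all points are identical")
  n <- length(r)
  grid <- seq(0, ceiling(max(r) / grid_step) * grid_step, by = grid_step)
  G <- length(grid)
  r_sorted <- sort(r)
  ## counts of points with r <= g and r < g per grid radius
  n_le <- findInterval(grid, r_sorted)
  n_lt <- findInterval(grid, r_sorted, left.open = TRUE)
  need <- ceiling(coverage * n)
  ## enclosed(i, j) = #(grid[i] <= r <= grid[j]) = n_le[j] - n_lt[i]
  ENC <- outer(-n_lt, n_le, `+`)               # G x G; row i = R_min index
  AREA <- outer(-grid^2, grid^2, `+`)
  feas <- ENC >= need & AREA >= 0
  if (!any(feas)) abort("no feasible annulus on the radius grid")
  AREA[!feas] <- Inf
  best_area <- min(AREA)
  cand <- which(AREA == best_area, arr.ind = TRUE)
  j <- min(cand[, 2])                          # smaller R_max
  i <- max(cand[cand[, 2] == j, 1])            # then larger R_min
  structure(list(R_min = grid[i], R_max = grid[j],
                 coverage = (n_le[j] - n_lt[i]) / n,
                 coverage_target = coverage, n = n, grid_step = grid_step),
            class = "annulus_fit")
}

#' @export
print.annulus_fit <- function(x, ...) {
  cat(sprintf("<annulus_fit> R_min = %.3f nm, R_max = %.3f nm (%.1f%% of %d points)\n",
              x$R_min, x$R_max, 100 * x$coverage, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.annulus_fit <- function(x, ...) {
  tibble(term = c("R_min", "R_max"), estimate = c(x$R_min, x$R_max))
}

#' @exportS3Method generics::glance
glance.annulus_fit <- function(x, ...) {
  tibble(R_min = x$R_min, R_max = x$R_max,
         area = pi * (x$R_max^2 - x$R_min^2),
         coverage = x$coverage, coverage_target = x$coverage_target,
         n = x$n, grid_step = x$grid_step)
}

## ---------------------------------------------------------------------------

#' Fit confinement parameters to a free-end point cloud
#'
#' Least-squares fit of the model's three 1-D marginal densities to the
#' per-axis histograms of the cloud. Bins follow the Freedman-Diaconis
#' rule computed on the cloud and are shared between data and model; the
#' model marginal is averaged over each bin by Simpson's rule (normalized
#' by the 3-D normalization constant), so the comparison with
#' bin-averaged counts carries no binning bias.
#' Optimization is bounded (`L-BFGS-B`) over the
#' requested free parameters with deterministic restarts; a fit whose
#' parameters end pinned at the box bounds is reported with a warning.
#'
#' @param cloud A `point_cloud` (or data frame with `x`, `y`, `z`).
#' @param scenario Scenario tag the model density should use.
#' @param free Character vector of parameter names to optimize, a subset
#'   of `c("beta_k", "L", "beta_k_prime", "z_max", "h_max")`. Empty means
#'   "evaluate the objective at `init` without optimizing".
#' @param init A [confinement_params()] object supplying starting values
#'   and the values of all fixed parameters.
#' @param n_quad Quadrature nodes per marginalized axis.
#' @param max_restarts Deterministic restarts attempted on non-convergence.
#' @return A `confinement_fit` object: fitted [confinement_params()],
#'   objective value, per-axis residual summaries, sample size and (if
#'   synthetic) the cloud's seed. Has `tidy()` and `glance()` methods.
#' @export
fit_parameters <- function(cloud, scenario, free = c("beta_k", "L"),
                           init, n_quad = 32, max_restarts = 3) {
  pts <- as_xyz(cloud)
  if (!nrow(pts)) abort("`cloud` is empty")
  allowed <- c("beta_k", "L", "beta_k_prime", "z_max", "h_max")
  if (length(free) && !all(free %in% allowed))
    abort(paste0("`free` must be a subset of: ", paste(allowed, collapse = ", ")))
  validate_scenario(scenario, init)

  ## shared binning rule (Freedman-Diaconis on the cloud, per axis)
  hist_axes <- lapply(c(x = "x", y = "y", z = "z"), function(ax) {
    v <- pts[[ax]]
    bw <- 2 * IQR(v) / length(v)^(1 / 3)
    if (bw <= 0) bw <- diff(range(v)) / 30
    breaks <- seq(min(v), max(v) + bw, by = bw)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    ## interleaved edges/centers grid for Simpson bin averages of the model
    grid <- sort(c(breaks, h$mids))
    list(breaks = breaks, centers = h$mids, density = h$density, grid = grid)
  })

  ## model marginal averaged over each histogram bin (Simpson), so that the
  ## comparison with bin-averaged data carries no binning bias
  model_binned <- function(ax, p, Z) {
    hx <- hist_axes[[ax]]
    m <- marginal_values(scenario, ax, p, hx$grid, n_quad) / Z
    k <- seq_along(hx$centers)
    (m[2 * k - 1] + 4 * m[2 * k] + m[2 * k + 1]) / 6
  }

  lower <- c(beta_k = 0.01, L = 0.1, beta_k_prime = 0.01, z_max = 0.5,
             h_max = 0.5)
  upper <- c(beta_k = 100, L = 100, beta_k_prime = 100, z_max = 100,
             h_max = 100)

  params_from <- function(theta) {
    p <- unclass(init)
    p[free] <- as.list(theta)
    do.call(confinement_params, p)
  }
  objective <- function(theta) {
    p <- tryCatch(params_from(theta), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    Z <- tryCatch(normalization_constant(scenario, p, n_nodes = n_quad,
                                         rel_tol = 1e-2),
                  error = function(e) NA_real_)
    if (!is.finite(Z) || Z <= 0) return(1e10)
    sum(vapply(c("x", "y", "z"), function(ax) {
      sum((hist_axes[[ax]]$density - model_binned(ax, p, Z))^2)
    }, numeric(1)))
  }

  if (!length(free)) {
    obj <- objective(numeric(0))
    fitted <- init
    conv <- 0L
  } else {
    theta0 <- unlist(unclass(init)[free])
    if (any(vapply(unclass(init)[free], is.null, logical(1))))
      abort("`init` must provide a value for every free parameter")
    fit <- NULL
    for (k in 0:max_restarts) {
      start <- theta0 * 1.15^k                  # deterministic restart ladder
      fit <- optim(start, objective, method = "L-BFGS-B",
                   lower = lower[free], upper = upper[free],
                   control = list(maxit = 500, factr = 1e9))
      if (fit$convergence == 0) break
    }
    if (fit$convergence != 0)
      abort(sprintf("optimizer failed to converge after %d restarts (code %d)",
                    max_restarts, fit$convergence))
    at_bound <- fit$par <= lower[free] * (1 + 1e-8) |
      fit$par >= upper[free] * (1 - 1e-8)
    if (any(at_bound))
      warn(paste0("fitted parameter(s) pinned at bounds: ",
                  paste(free[at_bound], collapse = ", ")))
    fitted <- params_from(fit$par)
    obj <- fit$value
    conv <- fit$convergence
  }

  Zf <- normalization_constant(scenario, fitted, n_nodes = n_quad,
                               rel_tol = 1e-2)
  residuals <- purrr::map_dfr(c("x", "y", "z"), function(ax) {
    m <- model_binned(ax, fitted, Zf)
    tibble(axis = ax, rss = sum((hist_axes[[ax]]$density - m)^2),
           n_bins = length(m))
  })
  structure(list(params = fitted, scenario = scenario, free = free,
                 objective = obj, residuals = residuals, n = nrow(pts),
                 seed = attr(cloud, "seed"), convergence = conv),
            class = "confinement_fit")
}

#' @export
print.confinement_fit <- function(x, ...) {
  cat(sprintf("<confinement_fit> scenario %s, n = %d, objective = %.4g\n",
              x$scenario, x$n, x$objective))
  if (length(x$free))
    cat("  fitted:", paste(sprintf("%s = %.4g", x$free,
                                   unlist(unclass(x$params)[x$free])),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.confinement_fit <- function(x, ...) {
  nm <- if (length(x$free)) x$free else
    names(x$params)[!vapply(x$params, is.null, logical(1))]
  nm <- setdiff(nm, "n_terms")
  tibble(term = nm, estimate = unname(unlist(unclass(x$params)[nm])),
         fitted = nm %in% x$free)
}

#' @exportS3Method generics::glance
glance.confinement_fit <- function(x, ...) {
  tibble(objective = x$objective, n = x$n, n_free = length(x$free),
         convergence = x$convergence, scenario = x$scenario)
}

#' Serialize a confinement fit to a flat config file
#'
#' Writes the fitted parameters in the same key-value dialect as
#' [write_params_config()], plus an `objective`/diagnostics block.
#'
#' @param fit A `confinement_fit`.
#' @param path Output path (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "confinement_fit"))
  p <- unclass(fit$params)
  x <- c(p[!vapply(p, is.null, logical(1))],
         list(diagnostics = list(scenario = fit$scenario,
                                 free = as.list(fit$free),
                                 objective = fit$objective,
                                 n = fit$n,
                                 convergence = fit$convergence)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------

#' Detect modes of a 1-D marginal density
#'
#' Local maxima of the (boxcar-smoothed) density, filtered by topographic
#' prominence relative to the global maximum. The defaults (5-point
#' window, 2% prominence) suppress truncation-series ripple while
#' preserving genuinely separated states, e.g. the two stable
#' conformations of the combined tail-trench confinement.
#'
#' @param marginal A data frame with columns `value` and `density` (as
#'   returned by [marginal_density()]).
#' @param smooth_window Boxcar window in grid points (odd; 1 disables).
#' @param prominence_frac Minimal prominence as a fraction of the maximum
#'   smoothed density.
#' @return A tibble with columns `location`, `density`, `prominence`,
#'   sorted by location. Empty when the density is flat.
#' @export
detect_modes <- function(marginal, smooth_window = 5, prominence_frac = 0.02) {
  if (!is.data.frame(marginal) ||
      !all(c("value", "density") %in% names(marginal)))
    abort("`marginal` must have columns value and density")
  v <- marginal$value
  d <- marginal$density
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    pad <- (smooth_window - 1) %/% 2
    dpad <- c(rep(d[1], pad), d, rep(d[length(d)], smooth_window - 1 - pad))
    d <- as.numeric(stats::filter(dpad, k, sides = 1))[
      (smooth_window):(length(dpad))]
  }
  n <- length(d)
  if (diff(range(d)) < .Machine$double.eps * max(abs(d), 1))
    return(tibble(location = numeric(), density = numeric(),
                  prominence = numeric()))
  ## local maxima with plateau handling (first index of each plateau top)
  peaks <- integer()
  i <- 2L
  while (i < n) {
    if (d[i] > d[i - 1]) {
      j <- i
      while (j < n && d[j + 1] == d[j]) j <- j + 1L
      if (j < n && d[j + 1] < d[j]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(peaks))
    return(tibble(location = numeric(), density = numeric(),
                  prominence = numeric()))
  prom <- vapply(peaks, function(p) {
    side_min <- function(idx_range) {
      if (!length(idx_range)) return(min(d))
      path <- d[idx_range]
      higher <- which(path > d[p])
      if (length(higher)) min(path[seq_len(min(higher))]) else min(path)
    }
    left <- side_min(rev(seq_len(p - 1)))
    right <- side_min(seq(p + 1, n))
    d[p] - max(left, right)
  }, numeric(1))
  keep <- prom >= prominence_frac * max(d)
  out <- tibble(location = v[peaks[keep]], density = d[peaks[keep]],
                prominence = prom[keep])
  dplyr::arrange(out, .data$location)
}
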