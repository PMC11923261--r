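#' Run the end-to-end stepping-kinetics pipeline
#'
#' Drives the full analysis from one structured config: synthetic
#' point-cloud sampling (optional), parameter fitting against the clouds
#' (optional), radial reduction and stepping-rate sweeps, and a
#' Brownian-dynamics oracle cross-check (optional). Outputs (rate-table
#' CSV, point-cloud CSVs, fit configs, radial-potential CSVs) and a
#' run manifest are written under `out_dir`.
#'
#' Config keys (YAML or JSON file, or an equivalent named list):
#' \describe{
#'   \item{scenarios}{character vector of scenario tags}
#'   \item{params}{confinement parameters (keys as in
#'     [confinement_params()])}
#'   \item{kinetics}{list with `D` (nm^2/s) and `kappa` (nm/s)}
#'   \item{epsilon}{numeric vector of contact distances (nm)}
#'   \item{a_grid}{either a numeric vector or a list with `min`, `max`,
#'     `step` (nm)}
#'   \item{sample}{optional: list with `n`, `seed` -- sample a cloud per
#'     scenario}
#'   \item{fit}{optional (needs `sample`): list with `free` (parameter
#'     names to refit from the sampled clouds)}
#'   \item{oracle}{optional: list with `n`, `seed`, and optionally
#'     `method`, `a`, `epsilon` -- BD cross-check of the Szabo time}
#'   \item{write_potentials}{logical: also write one radial-potential CSV
#'     per scenario at the median `a` (default `FALSE`)}
#'   \item{out_dir}{output directory (created if missing)}
#' }
#'
#' @param config Path to a YAML/JSON config file, or a named list.
#' @param out_dir Optional override of the config's `out_dir`.
#' @return The run manifest (named list, also written as
#'   `manifest.yaml`), invisibly. Contains the config snapshot, package
#'   version, seeds, output paths and per-stage status; any failed stage
#'   raises an error after the manifest is written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  params <- do.call(confinement_params, cfg$params)
  kin <- do.call(kinetic_params, cfg$kinetics)
  manifest <- list(
    package_version = as.character(utils::packageVersion("walkerkinetics")),
    config = config, seeds = list(), outputs = character(), stages = list(),
    diagnostics = list())
  ## the two silent-failure risks are surfaced here: series-truncation
  ## clipping and rejection-sampling acceptance
  for (scn in cfg$scenarios) {
    clip <- series_clip_diagnostic(scn, params)
    if (nrow(clip))
      manifest$diagnostics[[paste0("clipped_mass_", scn)]] <-
        max(clip$clipped_fraction)
  }
  record <- function(stage, status, secs) {
    manifest$stages[[stage]] <<- list(status = status,
                                      seconds = round(secs, 2))
  }
  add_output <- function(f) manifest$outputs <<- c(manifest$outputs, f)
  add_seed <- function(nm, s) manifest$seeds[[nm]] <<- s
  run_stage <- function(stage, expr) {
    t0 <- proc.time()["elapsed"]
    res <- tryCatch(expr, error = function(e) e)
    secs <- proc.time()["elapsed"] - t0
    if (inherits(res, "error")) {
      record(stage, paste0("failed: ", conditionMessage(res)), secs)
      NULL
    } else {
      record(stage, "ok", secs)
      res
    }
  }
  out_path <- function(...) file.path(cfg$out_dir, paste0(...))

  clouds <- NULL
  if (!is.null(cfg$sample)) {
    clouds <- run_stage("sample", {
      purrr::map(setNames(cfg$scenarios, cfg$scenarios), function(scn) {
        cl <- sample_free_end(scn, params, cfg$sample$n, cfg$sample$seed)
        manifest$diagnostics[[paste0("acceptance_rate_", scn)]] <<-
          attr(cl, "acceptance_rate")
        f <- out_path("cloud_", scn, ".csv")
        write_point_cloud(cl, f)
        add_output(f)
        cl
      })
    })
    add_seed("sample", cfg$sample$seed)
  }

  if (!is.null(cfg$fit) && !is.null(clouds)) {
    run_stage("fit", {
      for (scn in cfg$scenarios) {
        free <- intersect(cfg$fit$free, c("beta_k", "L", "beta_k_prime",
                                          "z_max", "h_max"))
        if (scn == "baseline")
          free <- intersect(free, c("beta_k", "L"))
        if (!length(free)) next
        fit <- fit_parameters(clouds[[scn]], scn, free = free, init = params)
        f <- out_path("fit_", scn, ".yaml")
        write_fit_result(fit, f)
        add_output(f)
      }
      TRUE
    })
  }

  rates <- run_stage("rates", {
    tab <- sweep_rates(cfg$scenarios, params, kin, cfg$a_grid, cfg$epsilon)
    f <- out_path("rate_table.csv")
    write_rate_table(tab, f)
    add_output(f)
    tab
  })

  if (isTRUE(cfg$write_potentials)) {
    run_stage("potentials", {
      a_mid <- cfg$a_grid[ceiling(length(cfg$a_grid) / 2)]
      for (scn in cfg$scenarios) {
        rp <- radial_potential(scn, params,
                               target_geometry(a_mid, cfg$epsilon[1]))
        f <- out_path("potential_", scn, ".csv")
        write_radial_potential(rp, f)
        add_output(f)
      }
      TRUE
    })
  }

  if (!is.null(cfg$oracle)) {
    run_stage("oracle", {
      a_o <- cfg$oracle$a %||% cfg$a_grid[ceiling(length(cfg$a_grid) / 2)]
      eps_o <- cfg$oracle$epsilon %||% cfg$epsilon[1]
      method <- cfg$oracle$method %||% "renewal"
      geom <- target_geometry(a_o, eps_o)
      res <- purrr::map_dfr(cfg$scenarios, function(scn) {
        rp <- radial_potential(scn, params, geom)
        s <- summarize_fpt(simulate_fpt(rp, kin, n = cfg$oracle$n,
                                        seed = cfg$oracle$seed,
                                        method = method))
        dplyr::mutate(s, scenario = scn, a = a_o, epsilon = eps_o,
                      tau_szabo = szabo_mfpt(rp, kin)$tau, .before = 1)
      })
      f <- out_path("oracle.csv")
      readr::write_csv(res, f)
      add_output(f)
      res
    })
    add_seed("oracle", cfg$oracle$seed)
  }

  manifest_file <- out_path("manifest.yaml")
  yaml::write_yaml(manifest, manifest_file)
  failed <- purrr::keep(manifest$stages,
                        ~ !identical(.x$status, "ok"))
  if (length(failed))
    abort(paste0("pipeline stage(s) failed: ",
                 paste(names(failed), collapse = ", "), " (see ",
                 manifest_file, ")"))
  invisible(manifest)
}

## schema validation with key-path error messages
validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) abort("config must be a named list or a config file path")
  known <- c("scenarios", "params", "kinetics", "epsilon", "a_grid",
             "sample", "fit", "oracle", "write_potentials", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  for (key in c("scenarios", "params", "epsilon", "a_grid"))
    if (is.null(cfg[[key]]))
      abort(paste0("config key `", key, "` is required"))
  bad <- which(!cfg$scenarios %in% scenario_tags)
  if (length(bad))
    abort(sprintf("scenarios[%d]: unknown scenario tag \"%s\"",
                  bad[1], cfg$scenarios[bad[1]]))
  if (is.list(cfg$a_grid)) {
    for (k in c("min", "max", "step"))
      if (is.null(cfg$a_grid[[k]]))
        abort(paste0("a_grid: `", k, "` is required when a_grid is a list"))
    cfg$a_grid <- seq(cfg$a_grid$min, cfg$a_grid$max, by = cfg$a_grid$step)
  }
  cfg$kinetics <- cfg$kinetics %||% list()
  cfg$out_dir <- cfg$out_dir %||% "walker-run"
  if (!is.null(cfg$sample)) {
    if (is.null(cfg$sample$n) || is.null(cfg$sample$seed))
      abort("sample: both `n` and `seed` are required")
  }
  if (!is.null(cfg$oracle)) {
    if (is.null(cfg$oracle$n) || is.null(cfg$oracle$seed))
      abort("oracle: both `n` and `seed` are required")
  }
  cfg
}
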