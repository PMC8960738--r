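.config_protocols <- c("clamp", "restitution", "erp", "cable", "s1s2",
                       "analyze", "fixtures")
.config_keys <- c("protocol", "parameters", "options", "output_dir")

#' Read / write an experiment configuration
#'
#' One experiment = one YAML config = one output directory. A config has a
#' `protocol` (one of `clamp`, `restitution`, `erp`, `cable`, `s1s2`,
#' `analyze`, `fixtures`), an optional `parameters` block of [pig_params()]
#' overrides (any Table-of-conductances name, kinetic constant or grid
#' setting), an `options` block of protocol arguments and an `output_dir`.
#' Unknown top-level keys or unknown parameter names are rejected.
#'
#' @param path YAML file path.
#' @return `read_experiment_config()`: a validated `experiment_config` list.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_experiment_config(cfg)
}

#' @rdname read_experiment_config
#' @param config an `experiment_config` (or plain list with the same keys).
#' @export
write_experiment_config <- function(config, path) {
  config <- validate_experiment_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_experiment_config
#' @export
validate_experiment_config <- function(config) {
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown) > 0)
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  if (is.null(config$protocol) || !config$protocol %in% .config_protocols)
    abort(paste0("config 'protocol' must be one of: ",
                 paste(.config_protocols, collapse = ", ")))
  if (!is.null(config$parameters)) {
    bad <- setdiff(names(config$parameters), names(pig_params()))
    if (length(bad) > 0)
      abort(paste0("unknown model parameter(s) in config: ",
                   paste(bad, collapse = ", ")))
  }
  if (is.null(config$output_dir)) config$output_dir <- "."
  if (is.null(config$options)) config$options <- list()
  structure(config, class = "experiment_config")
}

#' Run a configured experiment end to end
#'
#' Executes the protocol named by the config with the configured parameter
#' overrides, writes columnar-text results (and an RDS bundle for field
#' histories) into `output_dir` together with a log recording the package
#' version, the config and timing. The model is deterministic: identical
#' configs produce identical outputs.
#'
#' @param config an `experiment_config`, or the path of a YAML config.
#' @return A list with `result` (protocol output) and `files` written.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  config <- validate_experiment_config(config)
  params <- do.call(pig_params, config$parameters %||% list())
  opts <- config$options
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  files <- character(0)
  out_csv <- function(df, name) {
    f <- file.path(config$output_dir, name)
    write.csv(as.data.frame(df), f, row.names = FALSE)
    files <<- c(files, f)
    f
  }
  result <- switch(config$protocol,
    clamp = {
      pr <- clamp_protocol(
        measured_current = opts$current %||% "i_cal",
        holding_potential = opts$holding_potential %||% -80,
        test_potentials = opts$test_potentials %||% seq(-40, 60, 5),
        step_duration = opts$step_duration %||% 300,
        measurement_rule = opts$measurement_rule %||% "peak",
        cai_clamp = opts$cai_clamp %||% NA_real_)
      iv <- run_voltage_clamp(pr, params)
      out_csv(iv, "iv.csv")
      iv
    },
    restitution = {
      rest <- run_restitution(params,
        frequencies = opts$frequencies %||% c(0.25, 0.5, 1, 2, 3, 4),
        n_beats = opts$n_beats %||% 20, last = opts$last %||% 10)
      out_csv(rest, "restitution.csv")
      rest
    },
    erp = {
      erp <- measure_erp(params, s1_count = opts$s1_count %||% 8,
                         s1_cl = opts$s1_cl %||% 1000,
                         mode = opts$mode %||% "cell")
      out_csv(tibble(erp_ms = erp), "erp.csv")
      erp
    },
    cable = {
      sim <- simulate_cable(opts$length_cm %||% 10, params,
        stim_times = opts$stim_times %||% 0,
        probe_pos_cm = opts$probe_pos_cm %||% c(3, 6),
        duration = opts$duration %||% 800)
      cv <- measure_cv(sim)
      wl <- measure_wavelength(sim, cv)
      out_csv(tibble(time = sim$probe_times,
                     as.data.frame(sim$probe_v)), "cable_probes.csv")
      out_csv(tibble(cv_cm_s = cv, wl_cm = wl), "cable_metrics.csv")
      list(sim = sim, cv = cv, wl = wl)
    },
    s1s2 = {
      sim <- s1s2_crossfield(params, nx = opts$nx %||% 512,
        duration_after_s2 = opts$duration_after_s2 %||% 1000,
        snapshot_every = opts$snapshot_every %||% 10)
      f <- file.path(config$output_dir, "run.rds")
      saveRDS(sim, f); files <- c(files, f)
      sim
    },
    analyze = {
      sim <- readRDS(opts$run %||%
                       file.path(config$output_dir, "run.rds"))
      traj <- tip_trajectory(sim)
      spec <- trajectory_spectrum(traj)
      ps <- count_phase_singularities(sim)
      out_csv(traj, "tip_trajectory.csv")
      out_csv(spec, "spectrum.csv")
      out_csv(ps, "phase_singularities.csv")
      list(trajectory = traj, spectrum = spec, ps = ps)
    },
    fixtures = {
      generate_fixtures(opts$kind %||% "resting_state",
                        dir = config$output_dir, params = params)
    })
  log_file <- file.path(config$output_dir, "experiment_log.yaml")
  yaml::write_yaml(list(
    package_version = as.character(utils::packageVersion("pigatria")),
    r_version = R.version.string,
    protocol = config$protocol,
    parameters = config$parameters,
    options = config$options,
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    log_file)
  files <- c(files, log_file)
  list(result = result, files = files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
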