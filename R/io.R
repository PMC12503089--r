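#' Read and validate a study configuration
#'
#' A study configuration is a single YAML or JSON file (chosen by extension)
#' with an `info` block holding the five initial-information values, and
#' optional `error` (`sigma`, `rho`), `windows` (`lower`, `upper` per-time
#' vectors), `optimizer` and `calibration` blocks overriding defaults. Omitted
#' error values default to the scenario-analysis setup `sigma = 0.25`,
#' `rho = 0.73`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `study_config`: list with `info` ([initial_information()]),
#'   `error` ([error_model()]), `windows` (or `NULL`), `settings`
#'   ([optimizer_settings()]), `control` ([calibration_control()]).
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::yaml.load_file(path)
  as_study_config(raw)
}

#' Build a study configuration from a list
#'
#' @param x a list as produced by parsing a config file; see
#'   [read_study_config()].
#' @return A `study_config` object.
#' @export
as_study_config <- function(x) {
  if (is.null(x$info)) stop("config must contain an 'info' block")
  for (f in c("tmax", "Amax", "tplat", "Aplat")) {
    if (is.null(x$info[[f]]))
      stop("config field 'info.", f, "' is missing")
  }
  info <- initial_information(
    A0 = if (is.null(x$info$A0)) 0 else x$info$A0,
    tmax = x$info$tmax, Amax = x$info$Amax,
    tplat = x$info$tplat, Aplat = x$info$Aplat)
  err <- error_model(
    sigma = if (is.null(x$error$sigma)) 0.25 else x$error$sigma,
    rho = if (is.null(x$error$rho)) 0.73 else x$error$rho)
  windows <- x$windows
  if (!is.null(windows) && (is.null(windows$lower) || is.null(windows$upper)))
    stop("'windows' must supply 'lower' and 'upper' vectors")
  settings <- do.call(optimizer_settings,
                      x$optimizer %||% list())
  control <- do.call(calibration_control,
                     x$calibration %||% list())
  structure(list(info = info, error = err, windows = windows,
                 settings = settings, control = control),
            class = "study_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## fully-resolved config as a plain list, for echoing next to results
resolved_config <- function(config) {
  list(schema = "immunodesign/1",
       info = unclass(config$info),
       error = unclass(config$error),
       windows = config$windows,
       optimizer = unclass(config$settings),
       calibration = unclass(config$control))
}

#' Calibrate from a config and write results
#'
#' Writes `calibration.json` (parameters to full precision, residuals,
#' convergence diagnostics), `curve.csv` (dense mean curve) and
#' `config_resolved.json` (the config with defaults filled) to `out_dir`.
#'
#' @param config a `study_config` (or path to one).
#' @param out_dir output directory, created if needed.
#' @return The `calibration_result`, invisibly.
#' @export
run_calibrate <- function(config, out_dir = ".") {
  config <- ensure_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cal <- calibrate(config$info, config$control)
  out <- list(converged = cal$converged,
              params = if (cal$converged) unclass(cal$params) else NULL,
              residuals = if (cal$converged)
                as.list(system_residual(cal$params, config$info)) else NULL,
              residual_norm = cal$residual_norm,
              method_used = cal$method_used,
              n_attempts = cal$n_attempts,
              reason = cal$reason)
  jsonlite::write_json(out, file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(resolved_config(config),
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (cal$converged)
    export_curve_csv(cal$params, config$info, file.path(out_dir, "curve.csv"))
  if (!cal$converged)
    warning("calibration did not converge: ", cal$reason)
  invisible(cal)
}

#' Compute a D-optimal schedule from a config and write results
#'
#' Calibrates, optimizes the sampling times, and writes `schedule.csv`
#' (index, time, lower, upper; full precision), `design.json` (diagnostics:
#' objective value, det FIM, evaluation count) and the resolved config.
#'
#' @inheritParams run_calibrate
#' @return The [sampling_design()], invisibly.
#' @export
run_design <- function(config, out_dir = ".") {
  config <- ensure_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cal <- calibrate(config$info, config$control)
  if (!cal$converged) stop("calibration did not converge: ", cal$reason)
  des <- optimal_design(cal$params, config$info, config$error,
                        windows = config$windows, settings = config$settings)
  sched <- data.frame(index = seq_along(des$times), time = des$times,
                      lower = des$lower, upper = des$upper)
  utils::write.csv(sched, file.path(out_dir, "schedule.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(params = unclass(cal$params),
         times = des$times,
         objective = attr(des, "objective"),
         det_fim = attr(des, "det_fim"),
         n_evals = attr(des, "n_evals")),
    file.path(out_dir, "design.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(resolved_config(config),
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(des)
}

#' Run misspecification sweeps and write results
#'
#' For the requested scenarios and parameters, runs [sweep_single()] (and
#' [sweep_double()] when `double = TRUE`) and writes a long-format CSV
#' (`robustness_long.csv`: scenario, parameter, grid value(s), converged,
#' efficiency, per-time deviations) plus a pooled summary CSV
#' (`robustness_summary.csv`: quartiles and non-convergence per parameter).
#' Individual non-converged grid points are reported, not fatal.
#'
#' @param scenario_ids subset of 1..12.
#' @param params parameters to sweep; `A0` is skipped automatically for
#'   scenarios with `A0 = 0`.
#' @param n_grid grid size per sweep.
#' @param double also run the tmax x Aplat double sweep (grid
#'   `n_grid x n_grid`).
#' @param error an [error_model()].
#' @param settings optimizer settings.
#' @param out_dir output directory.
#' @return List with `results` (the `robustness_result` objects), `long` and
#'   `summary` data frames, invisibly.
#' @export
run_robustness <- function(scenario_ids = 1:12,
                           params = c("A0", "Amax", "Aplat", "tmax", "tplat"),
                           n_grid = 21, double = FALSE,
                           error = error_model(),
                           settings = optimizer_settings(),
                           out_dir = ".") {
  if (length(scenario_ids) == 0) stop("no scenarios requested")
  if (!all(scenario_ids %in% 1:12)) stop("scenario ids must be in 1..12")
  params <- match.arg(params, c("A0", "Amax", "Aplat", "tmax", "tplat"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  long <- list()
  for (sid in scenario_ids) {
    sc <- scenario(sid)
    for (pp in params) {
      if (pp == "A0" && sc$info$A0 == 0) next
      res <- sweep_single(sc, pp, n_grid, error, settings)
      results[[paste0("s", sid, "_", pp)]] <- res
      devs <- matrix(NA_real_, length(res$grid), 4)  # pad 3-time scenarios
      devs[, seq_len(ncol(res$deviations))] <- res$deviations
      colnames(devs) <- paste0("dev", 1:4)
      long[[paste0("s", sid, "_", pp)]] <-
        data.frame(scenario = sid, parameter = pp, value = res$grid,
                   converged = res$converged, efficiency = res$efficiencies,
                   devs)
    }
    if (double) {
      res <- sweep_double(sc, n_grid, error, settings)
      results[[paste0("s", sid, "_double")]] <- res
    }
  }
  long_df <- do.call(rbind, c(long, make.row.names = FALSE))
  utils::write.csv(long_df, file.path(out_dir, "robustness_long.csv"),
                   row.names = FALSE)

  summ <- list()
  for (pp in unique(vapply(results, function(r) paste(r$varied, collapse = ","),
                           character(1)))) {
    pool <- Filter(function(r) paste(r$varied, collapse = ",") == pp, results)
    s <- summarize_pooled(pool)
    summ[[pp]] <- data.frame(parameter = pp, min = s$summary["min"],
                             q1 = s$summary["q1"], median = s$summary["median"],
                             q3 = s$summary["q3"], max = s$summary["max"],
                             n_runs = s$n_runs,
                             n_nonconverged = s$n_nonconverged)
  }
  summary_df <- do.call(rbind, c(summ, make.row.names = FALSE))
  utils::write.csv(summary_df, file.path(out_dir, "robustness_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(schema = "immunodesign/1", scenario_ids = scenario_ids,
         params = params, n_grid = n_grid, double = double,
         error = unclass(error), optimizer = unclass(settings)),
    file.path(out_dir, "config_resolved.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = results, long = long_df, summary = summary_df))
}

ensure_config <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  if (!inherits(config, "study_config")) stop("not a study_config")
  config
}
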