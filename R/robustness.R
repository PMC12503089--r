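#' The 12 scenario presets of the robustness analysis
#'
#' Scenarios span no / low / high pre-existing antibodies (`A0` 0, 1, 5), a
#' faster or slower rise (`tmax` 30 or 70 days), and a lower or higher plateau
#' (`Aplat` 1 or 2.5), with the peak height fixed at `Amax = 10` (a reference
#' level: other concentrations read as fractions of the peak) and
#' `tplat = 365` days.
#'
#' @return A data frame with columns `id`, `description`, `A0`, `tmax`,
#'   `Amax`, `tplat`, `Aplat`.
#' @export
scenario_table <- function() {
  data.frame(
    id = 1:12,
    description = paste0("Start at ",
                         rep(c("zero", "lower level", "higher level"), each = 4),
                         ", ", rep(c("faster", "slower"), 6), " increase, ",
                         rep(rep(c("lower", "higher"), each = 2), 3), " plateau"),
    A0 = rep(c(0, 1, 5), each = 4),
    tmax = rep(c(30, 70), 6),
    Amax = 10,
    tplat = 365,
    Aplat = rep(rep(c(1, 2.5), each = 2), 3)
  )
}

#' A single scenario preset
#'
#' @param id scenario number, 1 to 12.
#' @return An object of class `scenario`: list with `id`, `description`, and
#'   `info` (an [initial_information()]).
#' @export
scenario <- function(id) {
  tab <- scenario_table()
  if (!id %in% tab$id) stop("scenario id must be in 1..12")
  row <- tab[tab$id == id, ]
  structure(list(id = row$id, description = row$description,
                 info = initial_information(row$A0, row$tmax, row$Amax,
                                            row$tplat, row$Aplat)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario %d: %s\n", x$id, x$description))
  print(x$info)
  invisible(x)
}

#' Misspecification range of one initial-information parameter
#'
#' The plausible ranges a planner might misstate each input by: +-2
#' concentration units for `A0`, `Amax` and `Aplat` (floored at 0 where
#' applicable), +-14 days for `tmax`, +-50 days for `tplat`. `A0` is not
#' varied when the true `A0` is 0 (whether a population has pre-existing
#' antibodies is assumed known at the planning stage).
#'
#' @param scen a [scenario()] or [initial_information()] object.
#' @param param one of `"A0"`, `"Amax"`, `"Aplat"`, `"tmax"`, `"tplat"`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
misspecification_range <- function(scen, param) {
  info <- if (inherits(scen, "scenario")) scen$info else scen
  param <- match.arg(param, c("A0", "Amax", "Aplat", "tmax", "tplat"))
  if (param == "A0" && info$A0 == 0)
    stop("A0 is not varied for scenarios starting at zero")
  true <- info[[param]]
  switch(param,
         A0 = c(max(0, true - 2), true + 2),
         Amax = c(true - 2, true + 2),
         Aplat = c(max(0, true - 2), true + 2),
         tmax = c(true - 14, true + 14),
         tplat = c(true - 50, true + 50))
}

## One grid point of a sweep: calibrate the misspecified information, find its
## optimal design, and score that design under the TRUE parameters against the
## TRUE optimal design. Returns efficiency, deviations, and a failure reason.
sweep_point <- function(mis_values, info, p_true, np, ld_ref, ref_times,
                        error, settings, control) {
  mis <- tryCatch(
    initial_information(mis_values$A0, mis_values$tmax, mis_values$Amax,
                        mis_values$tplat, mis_values$Aplat),
    error = function(e) NULL)
  if (is.null(mis))
    return(list(eff = NA_real_, dev = rep(NA_real_, np), reason = "calibration"))
  ## misspecifying A0 to 0 under a 4-parameter truth drops a parameter: the
  ## 3-point candidate cannot identify the true model (singular FIM)
  if (mis$A0 == 0 && info$A0 > 0)
    return(list(eff = NA_real_, dev = rep(NA_real_, np), reason = "calibration"))
  cal <- calibrate(mis, control)
  if (!cal$converged)
    return(list(eff = NA_real_, dev = rep(NA_real_, np), reason = "calibration"))
  des <- tryCatch(optimal_design(cal$params, mis, error, settings = settings),
                  error = function(e) NULL)
  if (is.null(des) || length(des$times) != np)
    return(list(eff = NA_real_, dev = rep(NA_real_, np), reason = "optimization"))
  ld_cand <- logdet_fim(des$times, p_true, error)
  eff <- if (ld_cand == -Inf) 0 else min(max(exp((ld_cand - ld_ref) / np), 0), 1)
  list(eff = eff, dev = des$times - ref_times, reason = NA_character_)
}

sweep_result <- function(scenario_id, varied, grid, effs, devs, reasons) {
  conv <- !is.na(effs)
  structure(list(
    scenario_id = scenario_id,
    varied = varied,
    grid = grid,
    efficiencies = effs,
    deviations = devs,
    converged = conv,
    n_nonconverged = sum(!conv),
    failure_reasons = table(reasons[!conv]),
    summary = if (any(conv))
      stats::quantile(effs[conv], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      else rep(NA_real_, 5)
  ), class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("Robustness sweep: scenario %d, varied %s, %d grid points\n",
              x$scenario_id, paste(x$varied, collapse = " x "),
              if (is.data.frame(x$grid)) nrow(x$grid) else length(x$grid)))
  s <- x$summary
  cat(sprintf("  D-efficiency min %.3f, Q1 %.3f, median %.3f, Q3 %.3f, max %.3f\n",
              s[1], s[2], s[3], s[4], s[5]))
  cat(sprintf("  not converging: %d (%.1f%%)\n", x$n_nonconverged,
              100 * x$n_nonconverged /
                (if (is.data.frame(x$grid)) nrow(x$grid) else length(x$grid))))
  invisible(x)
}

#' Single-parameter misspecification sweep
#'
#' Varies one initial-information parameter over its
#' [misspecification_range()] on an equidistant grid (endpoints included),
#' keeping the others at their true values. For each grid value the
#' misspecified information is calibrated and its optimal design computed;
#' that design is then scored by its D-efficiency under the *true* curve
#' parameters against the true optimal design, and per-measurement time
#' deviations (misspecified minus true optimal times, both sorted) are
#' recorded. Failures at individual grid points (calibration or design
#' optimization) are recorded as non-converged, never aborting the sweep.
#'
#' @param scen a [scenario()] object (or an [initial_information()] treated as
#'   the truth).
#' @param param the parameter to vary (see [misspecification_range()]).
#' @param n_grid grid size; the production analysis uses 1001.
#' @param error an [error_model()].
#' @param settings optimizer settings.
#' @param control calibration settings.
#' @return A `robustness_result` with the grid, per-point efficiencies,
#'   per-point deviation matrix, convergence flags and a five-number summary
#'   over converged points.
#' @export
sweep_single <- function(scen, param, n_grid = 1001, error = error_model(),
                         settings = optimizer_settings(),
                         control = calibration_control()) {
  stopifnot(n_grid >= 2)
  info <- if (inherits(scen, "scenario")) scen$info else scen
  scenario_id <- if (inherits(scen, "scenario")) scen$id else NA_integer_
  rng <- misspecification_range(info, param)
  grid <- seq(rng[1], rng[2], length.out = n_grid)

  cal <- calibrate(info, control)
  if (!cal$converged) stop("true scenario failed to calibrate")
  p_true <- cal$params
  np <- n_parameters(p_true)
  ref <- optimal_design(p_true, info, error, settings = settings)
  ld_ref <- logdet_fim(ref$times, p_true, error)

  effs <- rep(NA_real_, n_grid)
  devs <- matrix(NA_real_, n_grid, np)
  reasons <- rep(NA_character_, n_grid)
  for (k in seq_len(n_grid)) {
    mv <- info
    mv[[param]] <- grid[k]
    pt <- sweep_point(mv, info, p_true, np, ld_ref, ref$times,
                      error, settings, control)
    effs[k] <- pt$eff; devs[k, ] <- pt$dev; reasons[k] <- pt$reason
  }
  sweep_result(scenario_id, param, grid, effs, devs, reasons)
}

#' Double misspecification sweep over tmax and Aplat
#'
#' Varies the time of the peak and the height of the plateau simultaneously on
#' a full Cartesian grid over their misspecification ranges (the two inputs
#' the single-parameter analysis identifies as most sensitive). Bookkeeping is
#' as in [sweep_single()]. The production analysis uses 101 points per axis
#' (10 201 combinations per scenario).
#'
#' @inheritParams sweep_single
#' @param n_grid_per_axis grid size per axis.
#' @return A `robustness_result`; `grid` is a data frame with columns `tmax`
#'   and `Aplat`.
#' @export
sweep_double <- function(scen, n_grid_per_axis = 101, error = error_model(),
                         settings = optimizer_settings(),
                         control = calibration_control()) {
  stopifnot(n_grid_per_axis >= 2)
  info <- if (inherits(scen, "scenario")) scen$info else scen
  scenario_id <- if (inherits(scen, "scenario")) scen$id else NA_integer_
  r1 <- misspecification_range(info, "tmax")
  r2 <- misspecification_range(info, "Aplat")
  grid <- expand.grid(tmax = seq(r1[1], r1[2], length.out = n_grid_per_axis),
                      Aplat = seq(r2[1], r2[2], length.out = n_grid_per_axis))

  cal <- calibrate(info, control)
  if (!cal$converged) stop("true scenario failed to calibrate")
  p_true <- cal$params
  np <- n_parameters(p_true)
  ref <- optimal_design(p_true, info, error, settings = settings)
  ld_ref <- logdet_fim(ref$times, p_true, error)

  n <- nrow(grid)
  effs <- rep(NA_real_, n)
  devs <- matrix(NA_real_, n, np)
  reasons <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    mv <- info
    mv$tmax <- grid$tmax[k]; mv$Aplat <- grid$Aplat[k]
    pt <- sweep_point(mv, info, p_true, np, ld_ref, ref$times,
                      error, settings, control)
    effs[k] <- pt$eff; devs[k, ] <- pt$dev; reasons[k] <- pt$reason
  }
  sweep_result(scenario_id, c("tmax", "Aplat"), grid, effs, devs, reasons)
}

#' Pool misspecification sweeps across scenarios
#'
#' Pools the converged D-efficiencies of several sweeps of the same varied
#' parameter(s) and summarizes them as minimum, quartiles and maximum
#' (quartiles by linear interpolation of order statistics, R's default type
#' 7), plus non-convergence counts relative to attempted runs.
#'
#' @param results list of `robustness_result` objects varying the same
#'   parameter(s).
#' @param by optional parameter name to check the results against.
#' @return A list: `varied`, `n_runs`, `n_converged`, `n_nonconverged`,
#'   `fraction_nonconverged`, and `summary` (`min`, `q1`, `median`, `q3`,
#'   `max`).
#' @export
summarize_pooled <- function(results, by = NULL) {
  if (length(results) == 0) stop("empty pool")
  varied <- results[[1]]$varied
  for (r in results) {
    if (!identical(r$varied, varied)) stop("results vary different parameters")
  }
  if (!is.null(by) && !identical(paste(varied, collapse = ","),
                                 paste(by, collapse = ",")))
    stop("results do not vary '", paste(by, collapse = ","), "'")
  effs <- unlist(lapply(results, function(r) r$efficiencies[r$converged]))
  if (length(effs) == 0) stop("no converged runs to pool")
  n_runs <- sum(vapply(results, function(r)
    if (is.data.frame(r$grid)) nrow(r$grid) else length(r$grid), numeric(1)))
  n_nc <- sum(vapply(results, function(r) r$n_nonconverged, numeric(1)))
  q <- stats::quantile(effs, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(varied = varied, n_runs = n_runs, n_converged = length(effs),
       n_nonconverged = n_nc, fraction_nonconverged = n_nc / n_runs,
       summary = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5]))
}
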