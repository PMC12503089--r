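#' Residuals of the calibration system
#'
#' Evaluates the nonlinear system that ties the curve parameters to the
#' initial information. Without pre-existing antibodies (`A0 = 0`, `c = 0`)
#' the system has three equations in `(alpha, beta, t_scale)`:
#' the peak-location (mode) equation
#' `(alpha-1)/(alpha+beta-2) - tmax/t_scale = 0`, and the two height equations
#' `f(tmax/t_scale) = Amax` and `f(tplat/t_scale) = Aplat`. With `A0 > 0` a
#' shift `c` is added, all time arguments become `(t + c)/t_scale`, and a
#' fourth equation `f(c/t_scale) = A0` pins the starting level.
#'
#' @param params a [curve_parameters()] object.
#' @param info an [initial_information()] object.
#' @return Residual vector, length 3 (`A0 = 0`) or 4, ordered as
#'   (mode equation, `A0` equation if present, `Amax` equation, `Aplat`
#'   equation). An exact zero vector characterizes a solution.
#' @export
system_residual <- function(params, info) {
  a <- params$alpha; b <- params$beta; ts <- params$t_scale; cc <- params$c
  xmax <- (info$tmax + cc) / ts
  xplat <- (info$tplat + cc) / ts
  if (xmax <= 0 || xmax >= 1 || xplat <= 0 || xplat > 1)
    stop("scaled time argument outside the unit interval")
  r <- c(mode = (a - 1) / (a + b - 2) - xmax,
         Amax = stats::dbeta(xmax, a, b) - info$Amax,
         Aplat = stats::dbeta(xplat, a, b) - info$Aplat)
  if (info$A0 > 0) {
    xc <- cc / ts
    if (xc <= 0 || xc >= 1) stop("scaled shift c/t_scale outside the unit interval")
    r <- c(r["mode"], A0 = stats::dbeta(xc, a, b) - info$A0, r["Amax"], r["Aplat"])
  }
  r
}

#' Solver settings for [calibrate()]
#'
#' @param tol convergence tolerance on the residual infinity norm.
#' @param max_iter iteration cap per solver attempt.
#' @param t_scale_factors multi-start grid for `t_scale` as multiples of
#'   `tplat`.
#' @param alpha_starts multi-start grid for `alpha`.
#' @param c_min smallest admissible shift when `A0 > 0`; roots with smaller `c`
#'   are numerically degenerate (the shifted and unshifted systems become
#'   indistinguishable) and are rejected as non-converged.
#' @return A list of settings, class `calibration_control`.
#' @export
calibration_control <- function(tol = 1e-8, max_iter = 1000,
                                t_scale_factors = c(1.05, 1.5, 2, 3, 5, 10),
                                alpha_starts = c(1.1, 1.5, 2, 3),
                                c_min = 1e-8) {
  stopifnot(tol > 0, max_iter >= 1, all(t_scale_factors > 1), all(alpha_starts > 1))
  structure(list(tol = tol, max_iter = max_iter, t_scale_factors = t_scale_factors,
                 alpha_starts = alpha_starts, c_min = c_min),
            class = "calibration_control")
}

## Transformed coordinates keep every iterate feasible:
##   u1 = log(alpha - 1), u2 = log(beta - 1),
##   u3 = log(t_scale - tplat - c)   (ensures (tplat + c)/t_scale < 1),
##   u4 = log(c)                     (4-parameter system only).
params_from_u <- function(u, tplat) {
  if (length(u) == 3L)
    list(alpha = 1 + exp(u[1]), beta = 1 + exp(u[2]),
         t_scale = tplat + exp(u[3]), c = 0)
  else {
    cc <- exp(u[4])
    list(alpha = 1 + exp(u[1]), beta = 1 + exp(u[2]),
         t_scale = tplat + cc + exp(u[3]), c = cc)
  }
}

resid_u <- function(u, info) {
  p <- params_from_u(u, info$tplat)
  a <- p$alpha; b <- p$beta; ts <- p$t_scale; cc <- p$c
  xmax <- (info$tmax + cc) / ts
  r <- c((a - 1) / (a + b - 2) - xmax,
         stats::dbeta(xmax, a, b) - info$Amax,
         stats::dbeta((info$tplat + cc) / ts, a, b) - info$Aplat)
  if (length(u) == 4L)
    r <- c(r[1], stats::dbeta(cc / ts, a, b) - info$A0, r[2], r[3])
  r
}

nonconverged <- function(reason, n_attempts = 0L) {
  structure(list(params = NULL, converged = FALSE, residual_norm = NA_real_,
                 method_used = NA_character_, n_iterations = NA_integer_,
                 n_attempts = n_attempts, reason = reason),
            class = "calibration_result")
}

#' Calibrate curve parameters from initial information
#'
#' Solves the three-equation system (no pre-existing antibodies, `c = 0`) or
#' the four-equation shifted system (`A0 > 0`) for the beta-curve parameters.
#' A multi-start strategy is used: for each start, the mode equation fixes the
#' starting `beta` given starting `alpha` and `t_scale`, and the system is
#' solved in log-transformed coordinates (which keep `alpha, beta > 1`,
#' `t_scale > tplat + c` and `c > 0` throughout the iteration) by a Broyden
#' quasi-Newton method and, if that fails, a full Newton method. The first
#' feasible converged root is returned.
#'
#' `calibrate()` never throws on solver failure: a non-converged result is
#' returned instead, so misspecification sweeps can count failures. `Aplat = 0`
#' (or `A0 = 0` in a context requiring the shifted system) is rejected without
#' solving: the beta density is strictly positive on (0, 1), so the height
#' equations have no root, and letting the solver run produces spurious
#' underflow "roots".
#'
#' @param info an [initial_information()] object.
#' @param control a [calibration_control()] object.
#' @return A `calibration_result`: list with `params` ([curve_parameters()] or
#'   `NULL`), `converged`, `residual_norm`, `method_used`, `n_iterations`,
#'   `n_attempts`, `reason`.
#' @examples
#' cal <- calibrate(initial_information(0, 30, 10, 365, 1))
#' cal$params
#' @export
calibrate <- function(info, control = calibration_control()) {
  stopifnot(inherits(info, "initial_information"))
  if (info$Aplat <= 0)
    return(nonconverged("Aplat must be positive: the beta-density plateau height has no root at 0"))
  four <- info$A0 > 0
  n_attempts <- 0L
  for (tsf in control$t_scale_factors) {
    for (a0 in control$alpha_starts) {
      ts0 <- tsf * info$tplat
      c0 <- if (four) 0.05 * info$tmax else 0
      x0 <- (info$tmax + c0) / ts0
      b0 <- (a0 - 1) / x0 - a0 + 2  # mode equation holds exactly at the start
      if (b0 <= 1) next
      u0 <- c(log(a0 - 1), log(b0 - 1), log(ts0 - info$tplat - c0))
      if (four) u0 <- c(u0, log(c0))
      for (method in c("broyden", "newton")) {
        n_attempts <- n_attempts + 1L
        sol <- tryCatch(suppressWarnings({
          if (method == "broyden")
            pracma::broyden(resid_u, u0, info = info,
                            maxiter = control$max_iter, tol = control$tol / 10)
          else
            pracma::newtonsys(resid_u, u0, info = info,
                              maxiter = control$max_iter, tol = control$tol / 10)
        }), error = function(e) NULL)
        if (is.null(sol)) next
        u <- if (!is.null(sol$zero)) sol$zero else sol$x
        if (any(!is.finite(u))) next
        r <- resid_u(u, info)
        if (max(abs(r)) >= control$tol) next
        p <- params_from_u(u, info$tplat)
        if (four && p$c < control$c_min) next  # degenerate shift
        params <- curve_parameters(p$alpha, p$beta, p$t_scale, p$c)
        return(structure(list(params = params, converged = TRUE,
                              residual_norm = max(abs(r)),
                              method_used = method,
                              n_iterations = if (!is.null(sol$niter)) sol$niter else NA_integer_,
                              n_attempts = n_attempts, reason = NULL),
                         class = "calibration_result"))
      }
    }
  }
  nonconverged("no solver attempt converged to a feasible root", n_attempts)
}

#' @export
print.calibration_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Calibration converged (%s, attempt %d, residual %.2e)\n",
                x$method_used, x$n_attempts, x$residual_norm))
    print(x$params)
  } else {
    cat("Calibration did not converge:", x$reason, "\n")
  }
  invisible(x)
}

#' @export
as.list.calibration_result <- function(x, ...) unclass(x)
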