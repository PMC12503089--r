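#' Initial information describing an antibody-kinetics curve
#'
#' Bundles the five quantities a clinician can state at the planning stage of
#' an immunization study: the antibody concentration at the immunization event
#' (`A0`), the time and height of the expected peak (`tmax`, `Amax`), and the
#' time and height of the expected plateau (`tplat`, `Aplat`). Together they
#' uniquely determine a mean antibody-kinetics curve (see
#' [mean_concentration()]); concentrations are in arbitrary units, times in
#' days since immunization.
#'
#' @param A0 starting concentration at time 0 (>= 0). Zero means no
#'   pre-existing antibodies; positive values arise e.g. from prior exposure or
#'   maternally transferred antibodies.
#' @param tmax time of the peak, days (0 < tmax < tplat).
#' @param Amax expected peak concentration (> A0 and > Aplat).
#' @param tplat time at which the plateau is reached, days.
#' @param Aplat expected plateau concentration (>= 0).
#' @return An object of class `initial_information` (a named list).
#' @examples
#' initial_information(A0 = 0, tmax = 30, Amax = 10, tplat = 365, Aplat = 1)
#' @export
initial_information <- function(A0 = 0, tmax, Amax, tplat, Aplat) {
  vals <- c(A0 = A0, tmax = tmax, Amax = Amax, tplat = tplat, Aplat = Aplat)
  if (!all(is.finite(vals))) stop("all initial information values must be finite numbers")
  if (A0 < 0) stop("A0 must be >= 0")
  if (Aplat < 0) stop("Aplat must be >= 0")
  if (!(tmax > 0 && tplat > tmax)) stop("times must satisfy 0 < tmax < tplat")
  if (!(Amax > A0)) stop("Amax must exceed A0 (initial increase)")
  if (!(Amax > Aplat)) stop("Amax must exceed Aplat (decrease to plateau)")
  structure(list(A0 = A0, tmax = tmax, Amax = Amax, tplat = tplat, Aplat = Aplat),
            class = "initial_information")
}

#' @export
print.initial_information <- function(x, ...) {
  cat("Initial information (times in days, concentrations in arbitrary units)\n")
  cat(sprintf("  A0 = %g, tmax = %g, Amax = %g, tplat = %g, Aplat = %g\n",
              x$A0, x$tmax, x$Amax, x$tplat, x$Aplat))
  invisible(x)
}

#' Calibrated parameters of the beta-density mean curve
#'
#' The mean curve is the beta density evaluated at scaled, shifted time
#' `x = (t + c) / t_scale`. `alpha` and `beta` are the beta shape parameters
#' (both > 1 so the curve rises to a single interior peak and then falls),
#' `t_scale` maps study time onto the unit interval, and `c` shifts the curve
#' so it can start above zero at `t = 0`; `c = 0` corresponds to `A0 = 0`.
#'
#' @param alpha,beta shape parameters, both > 1.
#' @param t_scale time scaling, days (> 0).
#' @param c time shift, days (>= 0).
#' @return An object of class `curve_parameters`.
#' @seealso [calibrate()], which produces these from [initial_information()].
#' @export
curve_parameters <- function(alpha, beta, t_scale, c = 0) {
  if (!all(is.finite(c(alpha, beta, t_scale, c)))) stop("parameters must be finite")
  if (alpha <= 1 || beta <= 1) stop("alpha and beta must both exceed 1")
  if (t_scale <= 0) stop("t_scale must be positive")
  if (c < 0) stop("c must be >= 0")
  structure(list(alpha = alpha, beta = beta, t_scale = t_scale, c = c),
            class = "curve_parameters")
}

#' @export
print.curve_parameters <- function(x, ...) {
  cat(sprintf("Beta-curve parameters: alpha = %.4f, beta = %.4f, t_scale = %.2f, c = %.4f\n",
              x$alpha, x$beta, x$t_scale, x$c))
  invisible(x)
}

#' Number of curve parameters (3 without shift, 4 with shift)
#' @param params a [curve_parameters()] object.
#' @return 3 if `c = 0`, else 4.
#' @export
n_parameters <- function(params) if (params$c > 0) 4L else 3L

#' Beta probability density with shape restrictions
#'
#' The density `x^(alpha-1) (1-x)^(beta-1) / B(alpha, beta)` on the unit
#' interval, used here purely as the functional form of the mean antibody
#' curve, not as a probability model. Both shapes must exceed 1, which
#' guarantees a zero value at the endpoints and a single interior mode.
#'
#' @param x evaluation points in `[0, 1]` (vectorized).
#' @param alpha,beta shape parameters, both > 1.
#' @return Density values; 0 at `x = 0` and `x = 1`.
#' @examples
#' beta_density(0.5, 2, 2) # 1.5
#' @export
beta_density <- function(x, alpha, beta) {
  if (alpha <= 1 || beta <= 1) stop("alpha and beta must both exceed 1")
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  stats::dbeta(x, alpha, beta)
}

#' Mode of the beta density
#'
#' For shapes `alpha, beta > 1` the density peaks at
#' `(alpha - 1) / (alpha + beta - 2)`, strictly inside (0, 1). On the study
#' time scale the peak sits at `mode_location(alpha, beta) * t_scale - c`.
#'
#' @inheritParams beta_density
#' @return The mode, a value in (0, 1).
#' @examples
#' mode_location(2, 2) # 0.5
#' @export
mode_location <- function(alpha, beta) {
  if (any(alpha <= 1) || any(beta <= 1)) stop("alpha and beta must both exceed 1")
  (alpha - 1) / (alpha + beta - 2)
}

#' Mean antibody concentration over time
#'
#' The piecewise mean curve: the (rescaled, shifted) beta density before the
#' plateau time, and the constant plateau height from `tplat` onwards,
#'
#' `E[A(t)] = f((t + c)/t_scale, alpha, beta)` for `0 <= t < tplat`, and
#' `E[A(t)] = Aplat` for `t >= tplat`.
#'
#' The density branch is used on the half-open interval `[0, tplat)`; at
#' `t = tplat` exactly the plateau applies. No `1/t_scale` Jacobian factor is
#' applied: the curve's amplitude is controlled implicitly through
#' `(alpha, beta, t_scale)` by the calibration.
#'
#' @param t times in days (vectorized, >= 0).
#' @param params a [curve_parameters()] object.
#' @param info the [initial_information()] the parameters were calibrated from
#'   (supplies `tplat` and `Aplat`).
#' @return Mean concentrations at `t`.
#' @export
mean_concentration <- function(t, params, info) {
  if (any(t < 0)) stop("t must be >= 0")
  x <- (t + params$c) / params$t_scale
  if (any(x < 0 | x > 1)) stop("scaled time (t + c)/t_scale outside [0, 1]")
  out <- stats::dbeta(x, params$alpha, params$beta)
  out[t >= info$tplat] <- info$Aplat
  out
}

#' Export the mean curve as a two-column CSV
#'
#' Writes `time, mean` pairs on a regular grid over `[0, t_end]`, for external
#' plotting or reporting.
#'
#' @inheritParams mean_concentration
#' @param file output path.
#' @param t_end last time on the grid (defaults to `info$tplat`).
#' @param n number of grid points.
#' @return The data frame that was written, invisibly.
#' @export
export_curve_csv <- function(params, info, file, t_end = info$tplat, n = 501) {
  tt <- seq(0, t_end, length.out = n)
  df <- data.frame(time = tt, mean = mean_concentration(tt, params, info))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
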