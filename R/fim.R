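#' Measurement error model
#'
#' Measurements on one subject are multivariate normal around the mean curve
#' with a common known standard deviation `sigma` and AR(1) correlation `rho`
#' between successive measurements (in measurement order). The defaults are the
#' values used throughout the scenario analysis (`sigma = 0.25`,
#' `rho = 0.73`); note that the optimal sampling times themselves do not depend
#' on either value.
#'
#' @param sigma measurement standard deviation (> 0), concentration units.
#' @param rho AR(1) correlation between consecutive measurements, |rho| < 1.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sigma = 0.25, rho = 0.73) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(rho) || abs(rho) >= 1) stop("rho must satisfy |rho| < 1")
  structure(list(sigma = sigma, rho = rho), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("Error model: sigma = %g, AR(1) rho = %g\n", x$sigma, x$rho))
  invisible(x)
}

#' A sampling schedule with optional per-time windows
#'
#' An ordered vector of sampling times (days) and optional elementwise bounds
#' (time windows within which each sample must be drawn, e.g. a fixed visit
#' two weeks after immunization).
#'
#' @param times sampling times in days, nondecreasing.
#' @param lower,upper optional per-time bounds, same length as `times`,
#'   `lower <= times <= upper`.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(times, lower = NULL, upper = NULL) {
  if (is.unsorted(times)) stop("times must be nondecreasing")
  if (any(times < 0)) stop("times must be >= 0")
  n <- length(times)
  if (is.null(lower)) lower <- rep(0, n)
  if (is.null(upper)) upper <- rep(Inf, n)
  if (length(lower) != n || length(upper) != n)
    stop("lower and upper must match the length of times")
  if (any(lower > times) || any(times > upper))
    stop("bounds must satisfy lower <= times <= upper elementwise")
  structure(list(times = times, lower = lower, upper = upper),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("Sampling design (days):", paste(sprintf("%.2f", x$times), collapse = ", "), "\n")
  if (any(is.finite(x$upper)) &&
      !(all(x$lower == 0) && all(!is.finite(x$upper)))) {
    cat("  windows:", paste(sprintf("[%g, %g]", x$lower, x$upper), collapse = " "), "\n")
  }
  for (a in c("objective", "det_fim", "n_evals")) {
    if (!is.null(attr(x, a))) cat(sprintf("  %s: %g\n", a, attr(x, a)))
  }
  invisible(x)
}

#' AR(1) covariance matrix of n measurements
#'
#' `Sigma[i, j] = sigma^2 * rho^|i - j|` with indices in measurement order.
#' The covariance is index-based, not time-based, so it does not depend on the
#' sampling times; this is what makes the optimal times invariant to the
#' choice of `sigma` and `rho`.
#'
#' @param n number of measurements (>= 1).
#' @param error an [error_model()].
#' @return An `n x n` symmetric positive-definite matrix.
#' @export
ar1_covariance <- function(n, error) {
  stopifnot(n >= 1)
  idx <- seq_len(n)
  error$sigma^2 * error$rho^abs(outer(idx, idx, "-"))
}

#' Gradient of the mean curve in the curve parameters
#'
#' Closed-form partial derivatives of the beta-density mean with respect to
#' `(alpha, beta, t_scale, c)`, evaluated at times `t`. With
#' `x = (t + c)/t_scale`, `f = beta_density(x)`, digamma `psi`:
#'
#' * `dmu/dalpha   = f * (log(x) - psi(alpha) + psi(alpha + beta))`
#' * `dmu/dbeta    = f * (log(1 - x) - psi(beta) + psi(alpha + beta))`
#' * `dmu/dt_scale = ((beta-1)(t+c) x^(a-1)(1-x)^(b-2)`
#'                  `- (alpha-1)(t+c) x^(a-2)(1-x)^(b-1)) / (B t_scale^2)`
#' * `dmu/dc       = ((alpha-1) x^(a-2)(1-x)^(b-1)`
#'                  `- (beta-1) x^(a-1)(1-x)^(b-2)) / (B t_scale)`
#'
#' All kernels are evaluated in the log domain and exponentiated, so large
#' shape parameters do not overflow.
#'
#' @param t times in days (vectorized); each `(t + c)/t_scale` must lie
#'   strictly inside (0, 1).
#' @param params a [curve_parameters()] object.
#' @param include_c if `TRUE` return all four components; if `FALSE` drop the
#'   `c` component and evaluate at `c = 0` (the simplified three-parameter
#'   model used when `A0 = 0`). Defaults to the model implied by `params`.
#' @return A `length(t) x p` matrix (p = 3 or 4) of partial derivatives, one
#'   row per time.
#' @export
mean_gradient <- function(t, params, include_c = params$c > 0) {
  a <- params$alpha; b <- params$beta; ts <- params$t_scale
  cc <- if (include_c) params$c else 0
  x <- (t + cc) / ts
  if (any(x <= 0) || any(x >= 1))
    stop("(t + c)/t_scale must lie strictly inside (0, 1)")
  lB <- lbeta(a, b)
  lx <- log(x); l1x <- log1p(-x)
  f <- exp((a - 1) * lx + (b - 1) * l1x - lB)
  k_am2 <- exp((a - 2) * lx + (b - 1) * l1x - lB)  # x^(a-2)(1-x)^(b-1)/B
  k_bm2 <- exp((a - 1) * lx + (b - 2) * l1x - lB)  # x^(a-1)(1-x)^(b-2)/B
  J <- cbind(alpha = f * (lx - digamma(a) + digamma(a + b)),
             beta = f * (l1x - digamma(b) + digamma(a + b)),
             t_scale = ((b - 1) * (t + cc) * k_bm2 - (a - 1) * (t + cc) * k_am2) / ts^2)
  if (include_c) J <- cbind(J, c = ((a - 1) * k_am2 - (b - 1) * k_bm2) / ts)
  J
}

design_times <- function(design) {
  if (inherits(design, "sampling_design")) design$times else as.numeric(design)
}

## Times at 0 with an unshifted curve sit on the log singularity of the
## gradient; they are nudged to a fixed small positive value.
prep_times <- function(t, params) {
  if (params$c == 0) pmax(t, 1e-6) else t
}

#' Fisher information matrix of a sampling design
#'
#' For multivariate-normal measurements with constant covariance `Sigma`, the
#' information about the curve parameters contributed by sampling at the
#' design times is `FIM = J' Sigma^-1 J`, where row i of `J` is
#' [mean_gradient()] at time i. With `p` parameters, a D-optimal design uses
#' exactly `p` samples (more would replicate existing times).
#'
#' @param design a [sampling_design()] or a numeric vector of times.
#' @param params a [curve_parameters()] object.
#' @param error an [error_model()].
#' @param include_c see [mean_gradient()].
#' @return A `p x p` symmetric positive-semidefinite matrix.
#' @export
fisher_information <- function(design, params, error, include_c = params$c > 0) {
  t <- prep_times(design_times(design), params)
  J <- mean_gradient(t, params, include_c)
  Sigma <- ar1_covariance(length(t), error)
  crossprod(J, solve(Sigma, J))
}

## log-determinant of the FIM; -Inf when singular or numerically negative
logdet_fim <- function(design, params, error, include_c = params$c > 0) {
  FIM <- fisher_information(design, params, error, include_c)
  ld <- determinant(FIM, logarithm = TRUE)
  if (ld$sign <= 0) -Inf else as.numeric(ld$modulus)
}

#' D-optimality objective: -ln(det(FIM) + 1)
#'
#' The quantity minimized when searching for optimal sampling times. The
#' constant 1 maps degenerate designs (`det(FIM) = 0`, e.g. any design with a
#' duplicated time) to an objective of exactly 0 and keeps the transform
#' numerically stable for very small determinants; the objective is strictly
#' decreasing in `det(FIM)`.
#'
#' @inheritParams fisher_information
#' @return A scalar, 0 for degenerate designs and negative otherwise.
#' @export
d_objective <- function(design, params, error, include_c = params$c > 0) {
  ld <- logdet_fim(design, params, error, include_c)
  if (ld == -Inf) return(0)
  -log1p(exp(ld))
}

#' D-efficiency of a candidate design relative to an optimal design
#'
#' `(det FIM(candidate) / det FIM(reference))^(1/p)`, clipped to `[0, 1]`.
#' Both designs are evaluated under the same (true) curve parameters and error
#' model. The `1/p` exponent gives the sample-size interpretation: a design
#' with D-efficiency 0.5 extracts as much information as the optimal design
#' would with half the resources. The value is free of `sigma` (it cancels in
#' the ratio).
#'
#' @param candidate,reference designs ([sampling_design()] or numeric times);
#'   `reference` is typically the optimal design under `params`.
#' @inheritParams fisher_information
#' @return A value in `[0, 1]`; 1 when the candidate matches the reference,
#'   0 when the candidate design is singular.
#' @export
d_efficiency <- function(candidate, reference, params, error,
                         include_c = params$c > 0) {
  p <- if (include_c) 4 else 3
  ld_ref <- logdet_fim(reference, params, error, include_c)
  if (ld_ref == -Inf) stop("reference design has a singular information matrix")
  ld_cand <- logdet_fim(candidate, params, error, include_c)
  if (ld_cand == -Inf) return(0)
  min(max(exp((ld_cand - ld_ref) / p), 0), 1)
}
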