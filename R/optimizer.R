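#' Settings for the Hooke-Jeeves pattern search
#'
#' @param max_evals cap on objective evaluations.
#' @param initial_step starting step size per coordinate, days. `NULL` (the
#'   default) uses `0.1 * (upper - lower) * step_expansion`, i.e. a scale-aware
#'   step enlarged by `step_expansion`.
#' @param step_expansion factor applied to the default initial step (>= 1).
#' @param shrink_factor step-size reduction applied when no exploratory move
#'   improves (0 < shrink < 1).
#' @param tol_step search stops once all step sizes fall below this (days).
#' @return An `optimizer_settings` object.
#' @export
optimizer_settings <- function(max_evals = 1e5, initial_step = NULL,
                               step_expansion = 1.5, shrink_factor = 0.5,
                               tol_step = 1e-4) {
  stopifnot(max_evals >= 1, step_expansion >= 1,
            shrink_factor > 0, shrink_factor < 1, tol_step > 0)
  if (!is.null(initial_step) && any(initial_step <= 0))
    stop("initial_step must be positive")
  structure(list(max_evals = max_evals, initial_step = initial_step,
                 step_expansion = step_expansion, shrink_factor = shrink_factor,
                 tol_step = tol_step),
            class = "optimizer_settings")
}

#' Bound-constrained Hooke-Jeeves pattern search
#'
#' Minimizes a scalar function without derivatives by alternating exploratory
#' coordinate moves (each coordinate tried at +/- the current step, greedy
#' acceptance) with pattern moves that extrapolate along the improving
#' direction. Trial points are projected onto the box `[lower, upper]`. When a
#' full exploration fails to improve, all steps shrink by `shrink_factor`;
#' the search stops when steps fall below `tol_step` or `max_evals` is
#' exhausted.
#'
#' @param objective scalar function of a numeric p-vector.
#' @param start starting point, within bounds.
#' @param lower,upper box constraints (scalars are recycled).
#' @param settings an [optimizer_settings()] object.
#' @return List with `par` (the best point found), `value`, `n_evals`, and
#'   `converged` (`TRUE` when the step-size tolerance was reached).
#' @examples
#' hooke_jeeves(function(x) sum((x - c(3, 4))^2), c(0, 0), -10, 10)$par
#' @export
hooke_jeeves <- function(objective, start, lower, upper,
                         settings = optimizer_settings()) {
  p <- length(start)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  if (any(lower > upper)) stop("invalid bounds: lower > upper")
  if (any(start < lower) || any(start > upper)) stop("start must lie within bounds")
  step <- settings$initial_step
  if (is.null(step)) step <- 0.1 * (upper - lower) * settings$step_expansion
  step <- rep_len(step, p)
  if (any(!is.finite(step))) stop("initial_step must be finite (supply it when bounds are infinite)")
  clip <- function(x) pmin(pmax(x, lower), upper)

  n_evals <- 0L
  fcall <- function(x) { n_evals <<- n_evals + 1L; objective(x) }

  explore <- function(x, f) {
    for (i in seq_len(p)) {
      for (s in c(1, -1)) {
        xt <- x; xt[i] <- xt[i] + s * step[i]
        xt <- clip(xt)
        if (xt[i] == x[i]) next
        if (n_evals >= settings$max_evals) return(list(x = x, f = f))
        ft <- fcall(xt)
        if (ft < f) { x <- xt; f <- ft; break }
      }
    }
    list(x = x, f = f)
  }

  xb <- clip(start)
  fb <- fcall(xb)
  converged <- FALSE
  while (n_evals < settings$max_evals) {
    if (max(step) <= settings$tol_step) { converged <- TRUE; break }
    ex <- explore(xb, fb)
    if (ex$f < fb) {
      ## pattern moves: extrapolate from the old base through the new point
      repeat {
        xp <- clip(ex$x + (ex$x - xb))
        xb <- ex$x; fb <- ex$f
        if (n_evals >= settings$max_evals) break
        fp <- fcall(xp)
        ex2 <- explore(xp, fp)
        if (ex2$f < fb) ex <- ex2 else break
      }
    } else {
      step <- step * settings$shrink_factor
    }
  }
  list(par = xb, value = fb, n_evals = n_evals, converged = converged)
}

## Fast closure for the D-objective used inside optimal_design and the sweeps:
## precomputes everything that does not depend on the candidate times.
## Returns -ln(det(FIM)+1); 0 for degenerate / out-of-domain designs.
make_design_objective <- function(params, error, np) {
  a <- params$alpha; b <- params$beta; ts <- params$t_scale; cc <- params$c
  include_c <- np == 4L
  if (!include_c) cc <- 0
  idx <- seq_len(np)
  Sig_inv <- solve(error$sigma^2 * error$rho^abs(outer(idx, idx, "-")))
  lB <- lbeta(a, b)
  dga <- digamma(a) - digamma(a + b)
  dgb <- digamma(b) - digamma(a + b)
  function(t) {
    if (cc == 0) t <- pmax(t, 1e-6)
    x <- (t + cc) / ts
    if (any(x <= 0) || any(x >= 1)) return(0)
    lx <- log(x); l1x <- log1p(-x)
    f <- exp((a - 1) * lx + (b - 1) * l1x - lB)
    k_am2 <- exp((a - 2) * lx + (b - 1) * l1x - lB)
    k_bm2 <- exp((a - 1) * lx + (b - 2) * l1x - lB)
    J <- cbind(f * (lx - dga), f * (l1x - dgb),
               ((b - 1) * (t + cc) * k_bm2 - (a - 1) * (t + cc) * k_am2) / ts^2)
    if (include_c) J <- cbind(J, ((a - 1) * k_am2 - (b - 1) * k_bm2) / ts)
    d <- det(crossprod(J, Sig_inv %*% J))
    if (!is.finite(d) || d <= 0) return(0)
    -log1p(d)
  }
}

#' D-optimal sampling schedule
#'
#' Finds the sampling times minimizing the D-objective [d_objective()] for a
#' calibrated curve, using the bound-constrained Hooke-Jeeves search. The
#' number of times equals the number of curve parameters: 3 without
#' pre-existing antibodies, 4 with. Start values are day 1, `tmax`, `tplat`,
#' and (4-parameter case) the midpoint of `tmax` and `tplat`; default bounds
#' are `[0, tplat]` for every time. Per-time windows may be supplied to force
#' samples into clinically fixed visits.
#'
#' The search itself treats the times as unordered (the objective is
#' permutation-symmetric); the returned design is sorted. The result does not
#' depend on `sigma` or `rho`: with as many samples as parameters,
#' `det(FIM) = det(J)^2 det(Sigma^-1)` and the covariance factor is constant
#' in the times.
#'
#' @param params calibrated [curve_parameters()].
#' @param info the [initial_information()] used for calibration.
#' @param error an [error_model()].
#' @param windows optional list with `lower` and `upper` vectors of per-time
#'   bounds (each of length p, within `[0, tplat]`).
#' @param settings an [optimizer_settings()] object.
#' @return A [sampling_design()] of the optimized, sorted times, with
#'   attributes `objective`, `det_fim`, `n_evals`, and `converged`.
#' @examples
#' info <- initial_information(0, 30, 10, 365, 1)
#' cal <- calibrate(info)
#' optimal_design(cal$params, info)
#' @export
optimal_design <- function(params, info, error = error_model(), windows = NULL,
                           settings = optimizer_settings()) {
  np <- n_parameters(params)
  start <- if (np == 3L) c(1, info$tmax, info$tplat)
           else c(1, info$tmax, info$tmax + (info$tplat - info$tmax) / 2, info$tplat)
  lower <- rep(0, np); upper <- rep(info$tplat, np)
  if (!is.null(windows)) {
    if (length(windows$lower) != np || length(windows$upper) != np)
      stop("windows must supply lower and upper of length ", np)
    lower <- pmax(lower, windows$lower); upper <- pmin(upper, windows$upper)
    if (any(lower > upper)) stop("empty time window")
    start <- pmin(pmax(start, lower), upper)
  }
  objective <- make_design_objective(params, error, np)
  fit <- hooke_jeeves(objective, start, lower, upper, settings)
  if (!is.finite(fit$value)) stop("optimizer failed: non-finite objective")
  ord <- order(fit$par)
  des <- sampling_design(fit$par[ord], lower[ord], upper[ord])
  attr(des, "objective") <- fit$value
  attr(des, "det_fim") <- expm1(-fit$value)
  attr(des, "n_evals") <- fit$n_evals
  attr(des, "converged") <- fit$converged
  des
}
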