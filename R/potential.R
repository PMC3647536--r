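#' Parameters of the asymmetric double-well potential
#'
#' Bundles the two dimensionless shape parameters of the quartic potential
#' \eqn{V(x) = -x^2/2 + \alpha x^4/4 + \beta x}. `alpha` controls the height
#' of the barrier between the two wells (smaller `alpha`, deeper wells);
#' `beta` tilts the potential so that the remission (left, negative-x) well
#' is deeper than the relapse well, which is how the model encodes that
#' remissions last much longer than relapses.
#'
#' The potential is bistable — three distinct real stationary points — if
#' and only if \eqn{27 \alpha \beta^2 < 4}. On that boundary the relapse
#' well merges with the saddle (a saddle-node bifurcation) and the two-state
#' description breaks down.
#'
#' @param alpha positive control parameter of the well height.
#' @param beta non-negative asymmetry parameter.
#' @return An object of class `"dw_params"`: a list with elements `alpha`
#'   and `beta`.
#' @examples
#' p <- dw_params(alpha = 1, beta = 0.19)
#' is_bistable(p)
#' @seealso [steady_states()], [dw_potential()]
#' @export
dw_params <- function(alpha = 1, beta = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive finite number")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("`beta` must be a single non-negative finite number")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "dw_params")
}

as_dw_params <- function(x) {
  if (inherits(x, "dw_params")) return(x)
  if (is.list(x) && all(c("alpha", "beta") %in% names(x)))
    return(dw_params(x$alpha, x$beta))
  stop("expected a `dw_params` object (see `dw_params()`)")
}

#' @rdname dw_params
#' @param params a `"dw_params"` object.
#' @export
is_bistable <- function(params) {
  params <- as_dw_params(params)
  27 * params$alpha * params$beta^2 < 4
}

# largest beta (exclusive) that keeps the well bistable for a given alpha
beta_bifurcation <- function(alpha) sqrt(4 / (27 * alpha))

#' Evaluate the double-well potential and its drift
#'
#' `dw_potential()` returns \eqn{V(x) = -x^2/2 + \alpha x^4/4 + \beta x};
#' `dw_drift()` returns the deterministic force \eqn{-V'(x) =
#' x(1 - \alpha x^2) - \beta} that appears in the state equation
#' \eqn{dx = [x(1-\alpha x^2) - \beta]\,dt + \sqrt{\epsilon}\,dW}.
#' Both are vectorised over `x`.
#'
#' @param x numeric vector of health-state values.
#' @param params a [dw_params()] object.
#' @return Numeric vector, same length as `x`.
#' @examples
#' p <- dw_params(1, 0.08)
#' dw_potential(c(-1, 0, 1), p)
#' dw_drift(c(-1, 0, 1), p)
#' @export
dw_potential <- function(x, params) {
  params <- as_dw_params(params)
  -x^2 / 2 + params$alpha * x^4 / 4 + params$beta * x
}

#' @rdname dw_potential
#' @export
dw_drift <- function(x, params) {
  params <- as_dw_params(params)
  x * (1 - params$alpha * x^2) - params$beta
}

#' Stationary states and barriers of the double well
#'
#' Solves \eqn{\alpha x^3 - x + \beta = 0} for the three stationary points
#' of the deterministic dynamics and evaluates the two potential barriers.
#' Roots are found with the companion-matrix solver behind
#' [polyroot()][base::polyroot] and polished by Newton iteration, which
#' keeps residuals below 1e-10 even close to the bifurcation where naive
#' Cardano formulas lose accuracy.
#'
#' The left stable root is the health (remission) state: the clinical
#' encoding puts remission at -1, and a positive tilt `beta` lowers the
#' potential at negative `x`, so for `beta > 0` the health well is the
#' deeper one.
#'
#' @param params a [dw_params()] object in the bistable regime
#'   (`27 * alpha * beta^2 < 4`).
#' @return An object of class `"dw_geometry"`: list with `x_health`
#'   (left stable point), `x_saddle` (unstable point), `x_disease` (right
#'   stable point), `dV1 = V(x_saddle) - V(x_health)` and
#'   `dV2 = V(x_saddle) - V(x_disease)`.
#' @examples
#' steady_states(dw_params(1, 0))     # (-1, 0, +1), barriers 0.25 each
#' steady_states(dw_params(1, 0.19))  # tilted: dV1 > dV2
#' @export
steady_states <- function(params) {
  params <- as_dw_params(params)
  if (!is_bistable(params))
    stop(bifurcation_error(params))
  ## roots of alpha*x^3 - x + beta (coefficients in increasing degree)
  r <- polyroot(c(params$beta, -1, 0, params$alpha))
  x <- Re(r[abs(Im(r)) < 1e-6 * (1 + abs(Re(r)))])
  if (length(x) != 3L)  # bistability guarantees three real roots
    stop(bifurcation_error(params))
  for (i in 1:3) {  # Newton polish of each root
    f  <- params$alpha * x^3 - x + params$beta
    fp <- 3 * params$alpha * x^2 - 1
    x  <- x - f / fp
  }
  x <- sort(x)
  v <- dw_potential(x, params)
  structure(list(x_health = x[1], x_saddle = x[2], x_disease = x[3],
                 dV1 = v[2] - v[1], dV2 = v[2] - v[3]),
            class = "dw_geometry")
}

bifurcation_error <- function(params) {
  structure(class = c("dw_bifurcation_error", "error", "condition"),
            list(message = sprintf(
              paste0("monostable parameter regime: 27*alpha*beta^2 = %.6g >= 4 ",
                     "(saddle-node bifurcation); the two-state description ",
                     "requires beta < %.6g at alpha = %.6g"),
              27 * params$alpha * params$beta^2,
              beta_bifurcation(params$alpha), params$alpha),
              call = NULL))
}

#' @export
print.dw_geometry <- function(x, ...) {
  cat("Double-well geometry\n")
  cat(sprintf("  stationary points: x_health = %.6f, x_saddle = %.6f, x_disease = %.6f\n",
              x$x_health, x$x_saddle, x$x_disease))
  cat(sprintf("  barriers: dV1 (health) = %.6f, dV2 (disease) = %.6f, ratio = %.4f\n",
              x$dV1, x$dV2, x$dV1 / x$dV2))
  invisible(x)
}

#' Barrier asymmetry ratio of the double well
#'
#' The ratio \eqn{\Delta V_1 / \Delta V_2} of the health-side barrier to the
#' disease-side barrier. It equals 1 for the symmetric well (`beta = 0`) and
#' increases strictly with `beta`, diverging at the saddle-node bifurcation
#' where the disease well disappears.
#'
#' @inheritParams steady_states
#' @return A single number `>= 1` for `beta >= 0`.
#' @examples
#' barrier_ratio(dw_params(1, 0))     # 1
#' barrier_ratio(dw_params(1, 0.12))  # ~2.7
#' @export
barrier_ratio <- function(params) {
  g <- steady_states(params)
  g$dV1 / g$dV2
}

#' Solve for the asymmetry parameter matching a barrier ratio
#'
#' Inverts the strictly monotone map `beta -> barrier_ratio(alpha, beta)` by
#' bracketed root search on `[0, beta_c)`, where `beta_c = sqrt(4/(27 alpha))`
#' is the saddle-node bifurcation point. This is the per-patient model fit:
#' given a barrier ratio estimated from mean state durations, it returns the
#' tilt `beta` that reproduces that asymmetry at fixed `alpha`.
#'
#' @param target_ratio desired barrier ratio `dV1/dV2`, must be `>= 1`.
#' @param alpha positive control parameter (conventionally fixed at 1 for
#'   inference).
#' @return The asymmetry parameter `beta` such that
#'   `barrier_ratio(dw_params(alpha, beta))` matches `target_ratio` to
#'   within 1e-9.
#' @examples
#' solve_beta(1)                       # 0 (symmetric)
#' solve_beta(5.3)                     # ~0.19
#' round(solve_beta(2.7), 2)           # 0.12
#' @export
solve_beta <- function(target_ratio, alpha = 1) {
  if (!is.numeric(target_ratio) || length(target_ratio) != 1L ||
      !is.finite(target_ratio))
    stop("`target_ratio` must be a single finite number")
  if (target_ratio < 1)
    stop("`target_ratio` must be >= 1: the health well is by convention ",
         "at least as deep as the disease well")
  if (target_ratio == 1) return(0)
  upper <- (1 - 1e-9) * beta_bifurcation(alpha)
  f <- function(b) barrier_ratio(dw_params(alpha, b)) - target_ratio
  f_up <- f(upper)
  if (f_up < 0)
    stop(sprintf(paste0("`target_ratio` = %.6g exceeds the ratio attainable ",
                        "before the saddle-node bifurcation (attainable range ",
                        "[1, %.6g] at alpha = %.6g)"),
                 target_ratio, f_up + target_ratio, alpha))
  beta <- uniroot(f, interval = c(0, upper), tol = 1e-13)$root
  ## secant polish: uniroot's x-tolerance may leave the ratio residual above
  ## the contract when the map is steep near the bifurcation
  for (i in 1:8) {
    r0 <- f(beta)
    if (abs(r0) < 1e-10) break
    h <- max(1e-9, 1e-7 * beta)
    r1 <- f(beta + h)
    beta <- max(0, min(upper, beta - r0 * h / (r1 - r0)))
  }
  beta
}

#' Barrier ratio estimated from mean state durations
#'
#' The log-ratio estimator: taking logarithms of the Kramers-type mean exit
#' times \eqn{\tau_1 \approx e^{2\Delta V_1/\epsilon}} and
#' \eqn{\tau_2 \approx e^{2\Delta V_2/\epsilon}} and dividing cancels the
#' (shared) noise variance, so
#' \deqn{\Delta V_1 / \Delta V_2 \approx \ln(\tau_1) / \ln(\tau_2).}
#' Durations must be expressed in weeks — the estimator substitutes the
#' mean durations directly, so it is not invariant to a change of time
#' units — and both must exceed 1 week for the logarithms to be positive.
#'
#' @param tau_health mean duration of the health (remission) state, weeks.
#' @param tau_disease mean duration of the disease (relapse) state, weeks.
#' @return The estimated barrier ratio `dV1/dV2`.
#' @examples
#' barrier_ratio_from_durations(100, 4.3)    # ~3.16 (cohort means)
#' barrier_ratio_from_durations(117.7, 1.5)  # ~11.8
#' @export
barrier_ratio_from_durations <- function(tau_health, tau_disease) {
  stopifnot(is.numeric(tau_health), length(tau_health) == 1L,
            is.numeric(tau_disease), length(tau_disease) == 1L)
  if (!is.finite(tau_health) || tau_health <= 1 ||
      !is.finite(tau_disease) || tau_disease <= 1)
    stop("estimator undefined: both mean durations must exceed 1 week ",
         "(log of a duration <= 1 week is non-positive)")
  log(tau_health) / log(tau_disease)
}

#' Kramers-type mean exit time and its inversion
#'
#' `kramers_mean_exit_time()` returns the small-noise approximation
#' \eqn{\tau \approx e^{2\Delta V/\epsilon}} for the mean residence time in
#' a well with barrier \eqn{\Delta V} under noise variance \eqn{\epsilon}.
#' The pre-exponential (attempt-frequency) factor is deliberately not
#' included, so absolute times are order-of-magnitude only; the exponent —
#' the slope of \eqn{\ln\tau} against \eqn{1/\epsilon} — is the quantity
#' the formula pins down (see [kramers_slope_check()]).
#'
#' `noise_from_exit_time()` inverts the same relation for the noise
#' variance: \eqn{\epsilon = 2\Delta V / \ln(\tau)}, defined for mean exit
#' times above 1 week.
#'
#' @param barrier positive barrier height (dimensionless potential units).
#' @param epsilon positive noise variance.
#' @param mean_exit_time mean residence time in weeks, must exceed 1.
#' @return A single positive number: weeks for `kramers_mean_exit_time()`,
#'   a noise variance for `noise_from_exit_time()`.
#' @examples
#' kramers_mean_exit_time(0.25, 0.13)          # ~46.9 weeks
#' noise_from_exit_time(0.25, exp(0.5 / 0.13)) # 0.13 (round trip)
#' @export
kramers_mean_exit_time <- function(barrier, epsilon) {
  stopifnot(is.numeric(barrier), length(barrier) == 1L, barrier > 0,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  exp(2 * barrier / epsilon)
}

#' @rdname kramers_mean_exit_time
#' @export
noise_from_exit_time <- function(barrier, mean_exit_time) {
  stopifnot(is.numeric(barrier), length(barrier) == 1L, barrier > 0,
            is.numeric(mean_exit_time), length(mean_exit_time) == 1L)
  if (!is.finite(mean_exit_time) || mean_exit_time <= 1)
    stop("`mean_exit_time` must exceed 1 week (log must be positive)")
  2 * barrier / log(mean_exit_time)
}
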