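#' Configuration of a stochastic double-well simulation
#'
#' Collects everything a simulation run needs: the potential parameters,
#' the noise variance `epsilon` (per unit time; one model time unit is one
#' week so that simulated residence times are directly comparable with
#' clinical durations), the Euler-Maruyama step `dt` in weeks, the number
#' of steps, the initial state and the RNG seed.
#'
#' A stability guard rejects steps too large for the local relaxation rate:
#' `dt` must satisfy `dt < 0.1 / max |drift'|` over the stationary points,
#' where `drift'(x) = 1 - 3 alpha x^2`.
#'
#' @param params a [dw_params()] object (bistable).
#' @param epsilon noise variance, `>= 0`.
#' @param dt time step in weeks (default 0.01).
#' @param n_steps number of Euler-Maruyama steps, `>= 1`.
#' @param x_init initial state; default is the health well minimum.
#' @param seed integer RNG seed.
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(dw_params(1, 0.08), epsilon = 0.13,
#'                   n_steps = 1e4, seed = 1)
#' @export
sim_config <- function(params, epsilon, dt = 0.01, n_steps,
                       x_init = NULL, seed = 1L) {
  params <- as_dw_params(params)
  geom <- steady_states(params)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(n_steps), length(n_steps) == 1L, n_steps >= 1,
            is.numeric(seed), length(seed) == 1L)
  if (is.null(x_init)) x_init <- geom$x_health
  stopifnot(is.numeric(x_init), length(x_init) == 1L, is.finite(x_init))
  ## |drift'| = |1 - 3 alpha x^2| is largest at the outer stable point
  max_relax <- max(abs(1 - 3 * params$alpha *
                         c(geom$x_health, geom$x_saddle, geom$x_disease)^2))
  if (dt >= 0.1 / max_relax)
    stop(sprintf("`dt` = %g too large for stability: need dt < %g",
                 dt, 0.1 / max_relax))
  structure(list(params = params, epsilon = epsilon, dt = dt,
                 n_steps = as.numeric(floor(n_steps)), x_init = x_init,
                 seed = as.integer(seed), geometry = geom),
            class = "sim_config")
}

#' Simulate a health-state trajectory
#'
#' Integrates the Langevin equation
#' \eqn{dx = [x(1-\alpha x^2) - \beta]\,dt + \sqrt{\epsilon}\,dW}
#' with the Euler-Maruyama recursion
#' \eqn{x_{k+1} = x_k + \mathrm{drift}(x_k)\,dt + \sqrt{\epsilon\,dt}\,z_k},
#' where the \eqn{z_k} are iid standard normal draws from the seeded
#' generator. Trajectories are reproducible bit-for-bit given an identical
#' configuration.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `"dw_trajectory"`: list with `times` (weeks,
#'   uniform spacing `dt`, length `n_steps + 1`), `states` (the simulated
#'   `x` values) and `config`.
#' @examples
#' cfg <- sim_config(dw_params(1, 0), epsilon = 0.13, n_steps = 5e3, seed = 7)
#' traj <- simulate_trajectory(cfg)
#' range(traj$states)
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$geometry
  res <- em_core(config$x_init, config$params$alpha, config$params$beta,
                 config$epsilon, config$dt, config$n_steps,
                 keep_path = TRUE, x_health = g$x_health,
                 x_disease = g$x_disease, max_exits = 0)
  if (res$diverged)
    stop(sprintf("trajectory diverged (|x| > 10) at step %d: decrease `dt`",
                 as.integer(res$steps_run)))
  structure(list(times = seq(0, by = config$dt,
                             length.out = config$n_steps + 1),
                 states = res$path, config = config),
            class = "dw_trajectory")
}

#' Label a trajectory as health / disease / transit
#'
#' Converts the continuous state into the clinical two-state description
#' with a two-threshold hysteresis rule: the label switches to `"health"`
#' only when `x` first reaches the health minimum `x_health`, and to
#' `"disease"` only when `x` first reaches `x_disease`; between commitments
#' the previous label persists. Samples before the first commitment are
#' `"transit"`. Hysteresis prevents jitter around the saddle from being
#' counted as state transitions.
#'
#' @param traj a [simulate_trajectory()] result.
#' @param geometry optionally, the `"dw_geometry"` to take thresholds from;
#'   defaults to the geometry of `traj$config$params`.
#' @return Character vector of labels, one per trajectory sample.
#' @export
label_states <- function(traj, geometry = NULL) {
  stopifnot(inherits(traj, "dw_trajectory"))
  if (is.null(geometry)) geometry <- traj$config$geometry
  x <- traj$states
  lab <- integer(length(x))
  lab[x <= geometry$x_health]  <- -1L
  lab[x >= geometry$x_disease] <- 1L
  idx <- seq_along(lab)
  last_commit <- cummax(ifelse(lab != 0L, idx, 0L))
  out <- ifelse(last_commit == 0L, 0L, lab[pmax(last_commit, 1L)])
  c("health", "transit", "disease")[out + 2L]
}

#' Residence times from a labelled state sequence
#'
#' Extracts the durations of maximal constant-label runs. A residence runs
#' from the commitment to a state until the commitment to the other state,
#' so transit time is attributed to the state being left. The leading
#' transit segment (before any commitment) is dropped and the final,
#' still-open residence is censored and excluded, so means are computed
#' over complete residences only.
#'
#' @param labels character vector from [label_states()].
#' @param dt sample spacing in weeks.
#' @return An object of class `"residence_summary"`: list with
#'   `health_durations`, `disease_durations` (weeks), `mean_health`,
#'   `mean_disease` and `n_transitions`. With no complete residence the
#'   duration lists are empty and `n_transitions` is 0.
#' @examples
#' labs <- rep(c("health", "disease", "health"), c(100, 10, 50))
#' residence_times(labs, dt = 1)   # health 100 complete; trailing run censored
#' @export
residence_times <- function(labels, dt) {
  stopifnot(is.character(labels), length(labels) > 0, dt > 0)
  r <- rle(labels)
  starts <- cumsum(c(1, head(r$lengths, -1L)))
  keep <- r$values != "transit"      # only a leading transit run can exist
  vals <- r$values[keep]
  starts <- starts[keep]
  empty <- structure(list(health_durations = numeric(0),
                          disease_durations = numeric(0),
                          mean_health = NaN, mean_disease = NaN,
                          n_transitions = 0L),
                     class = "residence_summary")
  m <- length(vals)
  if (m < 2L) return(empty)
  dur <- diff(starts) * dt           # residence i: commit i -> commit i+1
  st  <- vals[-m]                    # last run is censored
  h <- dur[st == "health"]
  d <- dur[st == "disease"]
  structure(list(health_durations = h, disease_durations = d,
                 mean_health = if (length(h)) mean(h) else NaN,
                 mean_disease = if (length(d)) mean(d) else NaN,
                 n_transitions = m - 1L),
            class = "residence_summary")
}

#' @export
print.residence_summary <- function(x, ...) {
  cat("Residence-time summary\n")
  cat(sprintf("  complete health residences:  %d (mean %.2f weeks)\n",
              length(x$health_durations), x$mean_health))
  cat(sprintf("  complete disease residences: %d (mean %.2f weeks)\n",
              length(x$disease_durations), x$mean_disease))
  cat(sprintf("  transitions: %d\n", x$n_transitions))
  invisible(x)
}

#' Collect complete residence times without storing the path
#'
#' Runs the same Euler-Maruyama integration and hysteresis bookkeeping as
#' [simulate_trajectory()] followed by [label_states()] and
#' [residence_times()], but online in compiled code, so arbitrarily long
#' runs (millions of steps per recorded exit at small noise) need no
#' trajectory storage. Used by [kramers_slope_check()] and useful for any
#' Monte-Carlo estimate of mean exit times.
#'
#' @param params a bistable [dw_params()] object.
#' @param epsilon noise variance, `> 0`.
#' @param n_exits stop after this many complete residences (health and
#'   disease pooled; they alternate, so roughly half are of each kind).
#' @param dt time step in weeks.
#' @param x_init initial state, default the health minimum.
#' @param seed integer RNG seed.
#' @param max_steps hard cap on integration steps.
#' @return A `"residence_summary"` (see [residence_times()]).
#' @export
collect_exit_times <- function(params, epsilon, n_exits, dt = 0.01,
                               x_init = NULL, seed = 1L, max_steps = 5e9) {
  params <- as_dw_params(params)
  stopifnot(epsilon > 0, n_exits >= 1, dt > 0)
  g <- steady_states(params)
  if (is.null(x_init)) x_init <- g$x_health
  set.seed(seed)
  res <- em_core(x_init, params$alpha, params$beta, epsilon, dt,
                 max_steps, keep_path = FALSE, x_health = g$x_health,
                 x_disease = g$x_disease, max_exits = n_exits)
  if (res$diverged)
    stop("trajectory diverged (|x| > 10): decrease `dt`")
  h <- res$health_durations
  d <- res$disease_durations
  structure(list(health_durations = h, disease_durations = d,
                 mean_health = if (length(h)) mean(h) else NaN,
                 mean_disease = if (length(d)) mean(d) else NaN,
                 n_transitions = res$n_transitions),
            class = "residence_summary")
}

#' Monte-Carlo check of the Kramers exponent
#'
#' The mean residence time in a well of barrier \eqn{\Delta V} under noise
#' variance \eqn{\epsilon} is approximately \eqn{\tau \propto
#' e^{2\Delta V/\epsilon}}, so \eqn{\ln \tau} is linear in
#' \eqn{1/\epsilon} with slope \eqn{2\Delta V}. This routine simulates the
#' required number of complete exits from the health well at each value of
#' `epsilon_grid`, regresses the log mean exit time on `1/epsilon` and
#' returns the fitted slope. The absolute level of the exit times reflects
#' the attempt-frequency prefactor that the closed-form
#' [kramers_mean_exit_time()] omits; the slope does not, which is why the
#' comparison is made on the exponent.
#'
#' @param alpha,beta potential parameters (bistable).
#' @param epsilon_grid at least 4 noise variances in the small-noise regime.
#' @param reps target number of complete health-well exits per grid point
#'   (at least 100 recommended).
#' @param seed master seed; each grid point uses an independent derived seed.
#' @param dt time step in weeks.
#' @return List with `slope`, `intercept`, `epsilon_grid`, `mean_exit`
#'   (weeks per grid point), `n_exits`, and `expected_slope = 2*dV1`.
#' @examples
#' \donttest{
#' chk <- kramers_slope_check(1, 0, epsilon_grid = c(0.13, 0.16, 0.2, 0.25),
#'                            reps = 50, seed = 1)
#' chk$slope  # close to 0.5 = 2 * 0.25
#' }
#' @export
kramers_slope_check <- function(alpha = 1, beta = 0, epsilon_grid,
                                reps = 100, seed = 1L, dt = 0.01) {
  stopifnot(length(epsilon_grid) >= 4, all(epsilon_grid > 0), reps >= 10)
  params <- dw_params(alpha, beta)
  g <- steady_states(params)
  seeds <- local({ set.seed(seed); sample.int(.Machine$integer.max - 1L,
                                              length(epsilon_grid)) })
  mean_exit <- n_exits <- numeric(length(epsilon_grid))
  for (i in seq_along(epsilon_grid)) {
    ## residences alternate, so ~2*reps total gives ~reps health exits
    rs <- collect_exit_times(params, epsilon_grid[i],
                             n_exits = 2 * reps + 1, dt = dt,
                             x_init = g$x_health, seed = seeds[i])
    n_exits[i] <- length(rs$health_durations)
    if (n_exits[i] < 10)
      stop(sprintf("only %d complete health exits at epsilon = %g",
                   n_exits[i], epsilon_grid[i]))
    mean_exit[i] <- rs$mean_health
  }
  fit <- lm(log(mean_exit) ~ I(1 / epsilon_grid))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       epsilon_grid = epsilon_grid, mean_exit = mean_exit,
       n_exits = n_exits, expected_slope = 2 * g$dV1)
}

#' Export a labelled trajectory as a tidy table
#'
#' @param traj a `"dw_trajectory"`.
#' @param path optional file; if given, the table is written as CSV.
#' @return (Invisibly, when writing) a data frame with columns
#'   `time_weeks`, `x`, `label`.
#' @export
trajectory_table <- function(traj, path = NULL) {
  stopifnot(inherits(traj, "dw_trajectory"))
  df <- data.frame(time_weeks = traj$times, x = traj$states,
                   label = label_states(traj))
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
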