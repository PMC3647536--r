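#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a pre-treatment-era relapsing-remitting clinical cohort:
#' 70 patients observed over spans of 40 to 1311 weeks, mean relapse
#' duration about 4.3 weeks and mean remission about 100 weeks, with both
#' episode laws exponential on a weekly grid. Patients differ: each one's
#' pair of means is scaled by a shared log-normal multiplier with median 1
#' and coefficient of variation `heterogeneity_cv` (default 0.5, wide
#' enough to span per-patient remission means from roughly 47 to 118
#' weeks). Observation spans follow a truncated exponential on
#' `[span_min_weeks, span_max_weeks]` whose rate is calibrated so that a
#' fraction `span_anchor_prob` of spans falls at or below
#' `span_anchor_weeks` (defaults 0.36 at 200 weeks).
#'
#' @param n_patients number of patients (default 70).
#' @param mean_relapse_weeks cohort mean relapse duration (default 4.3).
#' @param mean_remission_weeks cohort mean remission duration (default 100).
#' @param span_min_weeks,span_max_weeks observation span range
#'   (defaults 40, 1311).
#' @param heterogeneity_cv coefficient of variation of the per-patient
#'   log-normal multiplier on both means (default 0.5; 0 disables
#'   heterogeneity).
#' @param span_anchor_weeks,span_anchor_prob calibration anchor of the span
#'   distribution (defaults 200 weeks, 0.36).
#' @param seed integer master seed.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 70, mean_relapse_weeks = 4.3,
                          mean_remission_weeks = 100,
                          span_min_weeks = 40, span_max_weeks = 1311,
                          heterogeneity_cv = 0.5,
                          span_anchor_weeks = 200, span_anchor_prob = 0.36,
                          seed = 1L) {
  stopifnot(n_patients >= 1, mean_relapse_weeks > 0, mean_remission_weeks > 0,
            span_min_weeks >= 2, span_max_weeks >= span_min_weeks,
            heterogeneity_cv >= 0,
            span_anchor_weeks > span_min_weeks,
            span_anchor_weeks < span_max_weeks,
            span_anchor_prob > 0, span_anchor_prob < 1)
  structure(list(n_patients = as.integer(n_patients),
                 mean_relapse_weeks = mean_relapse_weeks,
                 mean_remission_weeks = mean_remission_weeks,
                 span_min_weeks = as.integer(span_min_weeks),
                 span_max_weeks = as.integer(span_max_weeks),
                 heterogeneity_cv = heterogeneity_cv,
                 span_anchor_weeks = span_anchor_weeks,
                 span_anchor_prob = span_anchor_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## Rate of the exponential law truncated to [lo, hi] such that
## P(span <= anchor) = p. Monotone in the rate, solved by bisection.
span_rate <- function(lo, hi, anchor, p) {
  f <- function(lam)
    (1 - exp(-lam * (anchor - lo))) / (1 - exp(-lam * (hi - lo))) - p
  ## uniform limit lam -> 0 gives P -> (anchor-lo)/(hi-lo); P increases with
  ## lam towards 1, so any anchor probability above the uniform limit has a
  ## unique positive rate
  if ((anchor - lo) / (hi - lo) >= p)
    stop("span anchor probability must exceed the uniform limit ",
         "(anchor - min)/(max - min)")
  uniroot(f, interval = c(1e-8, 1), tol = 1e-12)$root
}

rtrunc_exp <- function(n, lo, hi, rate) {
  u <- runif(n)
  lo - log(1 - u * (1 - exp(-rate * (hi - lo)))) / rate
}

#' Generate one synthetic patient course
#'
#' Builds a weekly course that starts with a relapse and alternates states,
#' drawing each episode duration from an exponential law with the given
#' state mean and rounding it up to a whole week (minimum one week, the
#' clinical recording convention). The sequence is truncated at
#' `span_weeks`, so the final episode is right-censored exactly as in the
#' clinical encoding. The ceiling adds a positive bias of about half a
#' week to realised mean durations (exactly, the mean of
#' `ceiling(Exp(m))` is `1 / (1 - exp(-1/m))`).
#'
#' @param mean_relapse_weeks,mean_remission_weeks positive state means.
#' @param span_weeks observation span in weeks, `>= 2`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param patient_id id for the resulting course.
#' @return A [patient_course()].
#' @examples
#' generate_patient(4.3, 100, span_weeks = 300, seed = 42)
#' @export
generate_patient <- function(mean_relapse_weeks, mean_remission_weeks,
                             span_weeks, seed = NULL,
                             patient_id = "synthetic") {
  stopifnot(mean_relapse_weeks > 0, mean_remission_weeks > 0,
            span_weeks >= 2)
  if (!is.null(seed)) set.seed(seed)
  span_weeks <- as.integer(span_weeks)
  durations <- integer(0)
  total <- 0L
  state_mean <- c(mean_relapse_weeks, mean_remission_weeks)
  i <- 0L
  while (total < span_weeks) {
    m <- state_mean[i %% 2L + 1L]
    d <- max(1L, as.integer(ceiling(rexp(1, rate = 1 / m))))
    durations <- c(durations, d)
    total <- total + d
    i <- i + 1L
  }
  vals <- rep(rep_len(c(1L, -1L), length(durations)), durations)
  patient_course(patient_id, vals[seq_len(span_weeks)])
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient log-normal multipliers (median 1, CV
#' `heterogeneity_cv`) applied to both state means, observation spans from
#' the calibrated truncated exponential, and one course per patient via
#' [generate_patient()]. Each patient uses an independent seed derived
#' from the master seed, so the cohort is reproducible and insensitive to
#' the order in which patients are generated.
#'
#' @param config a [cohort_config()].
#' @return Named list of [patient_course()] objects (`"p01"`, `"p02"`, ...)
#'   with the config attached as attribute `config` and the per-patient
#'   multipliers as attribute `multipliers`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 3))
#' sapply(coh, function(p) length(p$series))
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  set.seed(config$seed)
  sdlog <- sqrt(log(1 + config$heterogeneity_cv^2))
  mult <- if (config$heterogeneity_cv > 0) rlnorm(n, 0, sdlog) else rep(1, n)
  rate <- span_rate(config$span_min_weeks, config$span_max_weeks,
                    config$span_anchor_weeks, config$span_anchor_prob)
  spans <- pmin(config$span_max_weeks,
                pmax(config$span_min_weeks,
                     as.integer(round(rtrunc_exp(n, config$span_min_weeks,
                                                 config$span_max_weeks,
                                                 rate)))))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("p%02d", seq_len(n))
  cohort <- lapply(seq_len(n), function(i)
    generate_patient(config$mean_relapse_weeks * mult[i],
                     config$mean_remission_weeks * mult[i],
                     spans[i], seed = seeds[i], patient_id = ids[i]))
  names(cohort) <- ids
  attr(cohort, "config") <- config
  attr(cohort, "multipliers") <- mult
  cohort
}

#' Generate a patient course from the stochastic model
#'
#' Instead of drawing episode durations from exponential laws, this runs
#' the Langevin dynamics itself ([simulate_trajectory()]), labels the
#' continuous path with the hysteresis rule and downsamples to the weekly
#' clinical encoding (the label of week `w` is the committed state at the
#' end of the week). The observation convention starts the record at the
#' first relapse: the trajectory is started in the disease well by default
#' and any leading weeks before the first relapse label are trimmed. If
#' the path never visits the disease well (e.g. `epsilon = 0` starting
#' from health) the untrimmed all-remission course is returned with the
#' onset convention relaxed.
#'
#' @param params a bistable [dw_params()].
#' @param epsilon noise variance, `>= 0`.
#' @param span_weeks weeks of trajectory to simulate.
#' @param seed integer seed.
#' @param dt Euler-Maruyama step (weeks).
#' @param x_init initial state; default the disease minimum (relapse onset).
#' @param patient_id id for the course.
#' @return A [patient_course()] of at most `span_weeks` weeks.
#' @examples
#' p <- generate_from_model(dw_params(1, 0.08), epsilon = 0.13,
#'                          span_weeks = 200, seed = 5)
#' table(p$series)
#' @export
generate_from_model <- function(params, epsilon, span_weeks, seed = 1L,
                                dt = 0.01, x_init = NULL,
                                patient_id = "model") {
  params <- as_dw_params(params)
  stopifnot(span_weeks >= 2)
  g <- steady_states(params)
  if (is.null(x_init)) x_init <- g$x_disease
  cfg <- sim_config(params, epsilon = epsilon, dt = dt,
                    n_steps = ceiling(span_weeks / dt), x_init = x_init,
                    seed = seed)
  traj <- simulate_trajectory(cfg)
  labels <- label_states(traj)
  week_end_idx <- round(seq_len(span_weeks) / dt) + 1L
  wk <- labels[week_end_idx]
  series <- ifelse(wk == "disease", 1L, ifelse(wk == "health", -1L, NA))
  series <- series[!is.na(series)]      # leading uncommitted weeks
  if (length(series) == 0L)
    stop("trajectory never committed to a state within `span_weeks`")
  first_relapse <- match(1L, series)
  if (is.na(first_relapse))
    return(patient_course(patient_id, series, require_onset = FALSE))
  patient_course(patient_id, series[first_relapse:length(series)])
}
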