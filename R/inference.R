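#' Fit the double-well model to one patient's course
#'
#' The per-patient analysis chain: mean complete-episode durations
#' ([duration_summary()]) feed the log-ratio barrier estimator
#' ([barrier_ratio_from_durations()]); the asymmetry parameter is then
#' solved at fixed `alpha` ([solve_beta()]); the fitted well geometry gives
#' the barriers, and inverting the Kramers relation on the health side
#' gives the noise variance ([noise_from_exit_time()]). By construction of
#' the fit the disease-side inversion yields the same `epsilon_hat`
#' (both equalities `epsilon * ln(tau) = 2 * dV` hold simultaneously
#' because `beta` matches the log-ratio exactly); this is asserted, not
#' assumed.
#'
#' Courses whose mean durations make the estimator undefined (a mean at or
#' below 1 week, or no complete episode of a state) are not errors: the
#' inference is returned with the duration fields populated, the model
#' fields `NA`, and an explanatory flag.
#'
#' @param course a [patient_course()].
#' @param alpha control parameter fixed for inference (default 1; only
#'   `beta` is identified from the single ratio).
#' @param drop_censored exclude the final censored episode from means
#'   (default `TRUE`).
#' @return A `"patient_inference"`: list with `patient_id`,
#'   `tau_health_weeks` (mean remission), `tau_disease_weeks` (mean
#'   relapse), `n_health`, `n_disease`, `barrier_ratio`, `beta_hat`,
#'   `dV1_hat`, `dV2_hat`, `epsilon_hat`, `alpha` and `flags` (character
#'   vector, empty when the full chain succeeded).
#' @examples
#' p <- generate_patient(4.3, 100, span_weeks = 2000, seed = 11)
#' analyze_patient(p)
#' @export
analyze_patient <- function(course, alpha = 1, drop_censored = TRUE) {
  stopifnot(inherits(course, "patient_course"))
  s <- duration_summary(course, drop_censored = drop_censored)
  inf <- infer_from_means(tau_health = s$mean_remission_weeks,
                          tau_disease = s$mean_relapse_weeks,
                          alpha = alpha)
  inf$patient_id <- course$patient_id
  inf$n_health <- s$n_remissions
  inf$n_disease <- s$n_relapses
  if (s$n_remissions == 0L || s$n_relapses == 0L)
    inf$flags <- c(inf$flags,
                   "partial: no complete episode of at least one state")
  structure(inf[c("patient_id", "tau_health_weeks", "tau_disease_weeks",
                  "n_health", "n_disease", "barrier_ratio", "beta_hat",
                  "dV1_hat", "dV2_hat", "epsilon_hat", "alpha", "flags")],
            class = "patient_inference")
}

## Core of the chain, on bare means; used for per-patient and pooled fits.
infer_from_means <- function(tau_health, tau_disease, alpha = 1) {
  out <- list(tau_health_weeks = tau_health, tau_disease_weeks = tau_disease,
              barrier_ratio = NA_real_, beta_hat = NA_real_,
              dV1_hat = NA_real_, dV2_hat = NA_real_,
              epsilon_hat = NA_real_, alpha = alpha,
              flags = character(0))
  if (!is.finite(tau_health) || !is.finite(tau_disease) ||
      tau_health <= 1 || tau_disease <= 1) {
    out$flags <- "estimator undefined: a mean duration is <= 1 week or missing"
    return(out)
  }
  ratio <- barrier_ratio_from_durations(tau_health, tau_disease)
  out$barrier_ratio <- ratio
  if (ratio < 1) {
    out$flags <- paste("estimator ratio < 1 (disease residences outlast",
                       "health): asymmetry convention violated, no beta fit")
    return(out)
  }
  beta <- solve_beta(ratio, alpha = alpha)
  g <- steady_states(dw_params(alpha, beta))
  eps1 <- noise_from_exit_time(g$dV1, tau_health)
  eps2 <- noise_from_exit_time(g$dV2, tau_disease)
  stopifnot(abs(eps1 - eps2) <= 1e-6 * eps1)  # same epsilon from both wells
  out$beta_hat <- beta
  out$dV1_hat <- g$dV1
  out$dV2_hat <- g$dV2
  out$epsilon_hat <- eps1
  out
}

#' @export
print.patient_inference <- function(x, ...) {
  cat(sprintf("Inference for patient '%s'\n", x$patient_id))
  cat(sprintf("  mean remission %.2f weeks (n=%d), mean relapse %.2f weeks (n=%d)\n",
              x$tau_health_weeks, x$n_health,
              x$tau_disease_weeks, x$n_disease))
  if (length(x$flags)) {
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  } else {
    cat(sprintf("  barrier ratio %.3f -> beta = %.4f (alpha = %g)\n",
                x$barrier_ratio, x$beta_hat, x$alpha))
    cat(sprintf("  barriers dV1 = %.4f, dV2 = %.4f; epsilon = %.4f\n",
                x$dV1_hat, x$dV2_hat, x$epsilon_hat))
  }
  invisible(x)
}

#' Fit the double-well model to a whole cohort
#'
#' Runs [analyze_patient()] on every course and additionally fits the
#' pooled model: all complete episodes of the cohort are pooled into one
#' multiset, their per-state means computed, and the barrier ratio taken
#' of those pooled means (not averaged over per-patient ratios — the
#' cohort-level estimate is a ratio of pooled means).
#'
#' @param cohort non-empty list of [patient_course()] objects.
#' @param alpha control parameter for inference (default 1).
#' @param drop_censored exclude final censored episodes (default `TRUE`).
#' @param bin_width_weeks bin width of the report histograms.
#' @return A `"cohort_report"`: list with `patients` (per-patient
#'   inferences), `pooled` (a `"patient_inference"` for the pooled
#'   episodes, id `"pooled"`), `histograms` (relapse / remission / span
#'   tables from [pooled_histogram()]) and `provenance`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 10, seed = 2))
#' rep <- analyze_cohort(coh)
#' rep$pooled$barrier_ratio
#' @export
analyze_cohort <- function(cohort, alpha = 1, drop_censored = TRUE,
                           bin_width_weeks = 4) {
  if (inherits(cohort, "patient_course")) cohort <- list(cohort)
  if (length(cohort) == 0L) stop("empty cohort")
  stopifnot(all(vapply(cohort, inherits, logical(1), "patient_course")))
  patients <- lapply(cohort, analyze_patient, alpha = alpha,
                     drop_censored = drop_censored)
  names(patients) <- vapply(cohort, `[[`, character(1), "patient_id")
  summaries <- lapply(cohort, duration_summary, drop_censored = drop_censored)
  pooled_rel <- unlist(lapply(summaries, `[[`, "relapse_weeks"))
  pooled_rem <- unlist(lapply(summaries, `[[`, "remission_weeks"))
  pooled <- infer_from_means(
    tau_health = if (length(pooled_rem)) mean(pooled_rem) else NaN,
    tau_disease = if (length(pooled_rel)) mean(pooled_rel) else NaN,
    alpha = alpha)
  pooled$patient_id <- "pooled"
  pooled$n_health <- length(pooled_rem)
  pooled$n_disease <- length(pooled_rel)
  pooled <- structure(pooled[c("patient_id", "tau_health_weeks",
                               "tau_disease_weeks", "n_health", "n_disease",
                               "barrier_ratio", "beta_hat", "dV1_hat",
                               "dV2_hat", "epsilon_hat", "alpha", "flags")],
                      class = "patient_inference")
  cfg <- attr(cohort, "config")
  structure(list(
    patients = patients,
    pooled = pooled,
    histograms = list(
      relapse = pooled_histogram(cohort, "relapse", bin_width_weeks,
                                 drop_censored = drop_censored),
      remission = pooled_histogram(cohort, "remission", bin_width_weeks,
                                   drop_censored = drop_censored),
      span = pooled_histogram(cohort, "span", bin_width_weeks)),
    provenance = list(
      n_patients = length(cohort),
      alpha = alpha,
      drop_censored = drop_censored,
      generator_config = if (!is.null(cfg)) unclass(cfg) else NULL,
      package_version = as.character(utils::packageVersion("msdoublewell")))),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d patients\n", x$provenance$n_patients))
  p <- x$pooled
  cat(sprintf("  pooled mean remission %.2f weeks (n=%d), relapse %.2f weeks (n=%d)\n",
              p$tau_health_weeks, p$n_health,
              p$tau_disease_weeks, p$n_disease))
  if (!length(p$flags))
    cat(sprintf("  pooled barrier ratio %.3f -> beta = %.4f, epsilon = %.4f\n",
                p$barrier_ratio, p$beta_hat, p$epsilon_hat))
  n_flagged <- sum(vapply(x$patients, function(q) length(q$flags) > 0,
                          logical(1)))
  cat(sprintf("  patients with flags: %d\n", n_flagged))
  invisible(x)
}

#' Reconstruct a patient's potential on a grid
#'
#' Evaluates the fitted potential \eqn{V(x) = -x^2/2 + \alpha x^4/4 +
#' \beta x} on a grid, with the stationary points and barriers attached as
#' attributes — the per-patient energy-landscape picture implied by the
#' inferred asymmetry.
#'
#' @param inference a `"patient_inference"` with a defined `beta_hat`, or
#'   a bare numeric `beta`.
#' @param x_grid grid of state values (default `seq(-2, 2, by = 0.01)`).
#' @param alpha control parameter; defaults to the inference's `alpha`.
#' @return Data frame with columns `x`, `V`; attributes `geometry` (the
#'   `"dw_geometry"`) and `beta`.
#' @examples
#' pot <- reconstruct_potential(0.19)
#' attr(pot, "geometry")
#' @export
reconstruct_potential <- function(inference, x_grid = seq(-2, 2, by = 0.01),
                                  alpha = NULL) {
  if (inherits(inference, "patient_inference")) {
    if (!is.finite(inference$beta_hat))
      stop("no beta fit available for this patient (flags: ",
           paste(inference$flags, collapse = "; "), ")")
    beta <- inference$beta_hat
    if (is.null(alpha)) alpha <- inference$alpha
  } else {
    beta <- as.numeric(inference)
    if (is.null(alpha)) alpha <- 1
  }
  params <- dw_params(alpha, beta)
  g <- steady_states(params)
  out <- data.frame(x = x_grid, V = dw_potential(x_grid, params))
  attr(out, "geometry") <- g
  attr(out, "beta") <- beta
  out
}
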