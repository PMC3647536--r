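#' A patient's weekly relapse/remission course
#'
#' The clinical encoding: one value per week, `+1` during a relapse
#' ("no health") and `-1` during remission ("health"). The observation
#' window starts with the first relapse at onset, so by convention the
#' first value is `+1`; episodes shorter than a week are rounded up to one
#' week, so every episode lasts an integer number of weeks.
#'
#' @param patient_id single string identifying the patient.
#' @param series integer vector of weekly states, values in `{-1, +1}`.
#' @param require_onset if `TRUE` (default), enforce that the series starts
#'   with a relapse (`+1`). Model-generated courses that never relapse can
#'   set this to `FALSE`.
#' @return An object of class `"patient_course"`.
#' @examples
#' patient_course("p1", c(1, 1, -1, -1, -1, 1))
#' @export
patient_course <- function(patient_id, series, require_onset = TRUE) {
  if (!is.character(patient_id) || length(patient_id) != 1L ||
      is.na(patient_id) || !nzchar(patient_id))
    stop("`patient_id` must be a single non-empty string")
  if (length(series) == 0L)
    stop("`series` must be non-empty")
  series <- as.integer(series)
  if (anyNA(series) || !all(series %in% c(-1L, 1L)))
    stop("`series` values must all be +1 (relapse) or -1 (remission)")
  if (require_onset && series[1] != 1L)
    stop("`series` must start with a relapse (+1): the observation window ",
         "begins at the first relapse onset")
  structure(list(patient_id = patient_id, series = series),
            class = "patient_course")
}

#' @export
print.patient_course <- function(x, ...) {
  ep <- episodes_from_series(x)
  cat(sprintf("Patient course '%s': %d weeks, %d relapse(s), %d remission(s)\n",
              x$patient_id, length(x$series),
              sum(ep$state == "relapse"), sum(ep$state == "remission")))
  invisible(x)
}

#' Run-length encode a weekly course into episodes
#'
#' Maximal runs of equal sign become episodes: `+1` runs are relapses,
#' `-1` runs remissions. Episodes occupy the half-open week interval
#' `[start_week, start_week + duration_weeks)` with 0-based starts.
#' Exact inverse of [series_from_episodes()].
#'
#' @param course a [patient_course()].
#' @return An `"episode_list"`: data frame with columns `state`
#'   (`"relapse"`/`"remission"`), `start_week`, `duration_weeks`, carrying
#'   the patient id as attribute `patient_id`.
#' @examples
#' episodes_from_series(patient_course("p1", c(1, 1, -1, -1, -1, 1)))
#' @export
episodes_from_series <- function(course) {
  stopifnot(inherits(course, "patient_course"))
  r <- rle(course$series)
  ep <- data.frame(
    state = ifelse(r$values == 1L, "relapse", "remission"),
    start_week = cumsum(c(0L, head(r$lengths, -1L))),
    duration_weeks = r$lengths)
  attr(ep, "patient_id") <- course$patient_id
  class(ep) <- c("episode_list", "data.frame")
  ep
}

#' Rebuild a weekly course from an episode list
#'
#' @param episodes an `"episode_list"` (or data frame with columns `state`,
#'   `start_week`, `duration_weeks`), contiguous and alternating in state.
#' @param patient_id patient id; defaults to the `patient_id` attribute.
#' @param require_onset passed to [patient_course()].
#' @return A [patient_course()].
#' @export
series_from_episodes <- function(episodes, patient_id = NULL,
                                 require_onset = TRUE) {
  if (is.null(patient_id)) patient_id <- attr(episodes, "patient_id")
  if (is.null(patient_id)) stop("`patient_id` missing")
  validate_episodes(episodes)
  vals <- ifelse(episodes$state == "relapse", 1L, -1L)
  patient_course(patient_id, rep(vals, episodes$duration_weeks),
                 require_onset = require_onset)
}

validate_episodes <- function(episodes) {
  need <- c("state", "start_week", "duration_weeks")
  if (!all(need %in% names(episodes)))
    stop("episode list must have columns state, start_week, duration_weeks")
  if (nrow(episodes) == 0L) stop("episode list is empty")
  if (!all(episodes$state %in% c("relapse", "remission")))
    stop("unknown state code: states must be 'relapse' or 'remission'")
  if (any(episodes$duration_weeks < 1))
    stop("episode durations must be >= 1 week")
  expected_start <- cumsum(c(0, head(episodes$duration_weeks, -1)))
  if (!isTRUE(all.equal(as.numeric(episodes$start_week), expected_start)))
    stop("episodes must be contiguous: start_week must equal the cumulative ",
         "duration of the preceding episodes")
  if (nrow(episodes) > 1L &&
      any(episodes$state[-1] == head(episodes$state, -1)))
    stop("episodes must alternate between relapse and remission")
  invisible(episodes)
}

#' Per-state duration statistics of a course
#'
#' Splits a course into episodes and summarises durations by state. The
#' observation window truncates the last episode (it ends with the shift
#' out of the relapsing-remitting phase, not with a state change), so by
#' default that right-censored final episode is excluded from the duration
#' lists and means; set `drop_censored = FALSE` to include it.
#'
#' @param course a [patient_course()] or an `"episode_list"`.
#' @param drop_censored drop the final episode from the statistics
#'   (default `TRUE`).
#' @return A `"duration_summary"`: list with `relapse_weeks` and
#'   `remission_weeks` (duration vectors), `mean_relapse_weeks`,
#'   `mean_remission_weeks` (NaN when no complete episode of that state),
#'   `n_relapses`, `n_remissions`, `span_weeks` and `censored_state` (the
#'   state of the dropped final episode, or `NA`).
#' @examples
#' duration_summary(patient_course("p1", c(1, 1, -1, -1, -1, 1)))
#' @export
duration_summary <- function(course, drop_censored = TRUE) {
  ep <- if (inherits(course, "episode_list")) course
        else episodes_from_series(course)
  span <- sum(ep$duration_weeks)
  censored_state <- NA_character_
  if (drop_censored) {
    censored_state <- ep$state[nrow(ep)]
    ep <- ep[-nrow(ep), , drop = FALSE]
  }
  rel <- ep$duration_weeks[ep$state == "relapse"]
  rem <- ep$duration_weeks[ep$state == "remission"]
  structure(list(
    relapse_weeks = rel, remission_weeks = rem,
    mean_relapse_weeks = if (length(rel)) mean(rel) else NaN,
    mean_remission_weeks = if (length(rem)) mean(rem) else NaN,
    n_relapses = length(rel), n_remissions = length(rem),
    span_weeks = span, censored_state = censored_state),
    class = "duration_summary")
}

#' @export
print.duration_summary <- function(x, ...) {
  cat(sprintf("Duration summary over %d weeks\n", x$span_weeks))
  cat(sprintf("  relapses:   n = %d, mean = %.2f weeks\n",
              x$n_relapses, x$mean_relapse_weeks))
  cat(sprintf("  remissions: n = %d, mean = %.2f weeks\n",
              x$n_remissions, x$mean_remission_weeks))
  if (!is.na(x$censored_state))
    cat(sprintf("  (final %s episode censored and excluded)\n",
                x$censored_state))
  invisible(x)
}

#' Fit an exponential law to episode durations
#'
#' Maximum-likelihood exponential fit (the MLE of the mean is the sample
#' mean) plus a one-sample Kolmogorov-Smirnov test against the fitted
#' exponential as a quantitative stand-in for the visual "exponential
#' decay" of duration histograms. Durations are recorded as whole weeks,
#' and the KS statistic is computed on these discretised values against a
#' continuous law, which inflates the statistic (ties, and the fitted
#' parameter re-used in the test); treat `gof_pvalue` as a diagnostic, not
#' an exact test level.
#'
#' @param durations numeric vector of at least 5 positive durations (weeks).
#' @return An `"exp_fit"`: list with `mean`, `n`, `ks_stat`, `gof_pvalue`.
#' @examples
#' set.seed(1)
#' fit_exponential(rexp(200, 1 / 4.3))
#' @export
fit_exponential <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) < 5L)
    stop("need at least 5 durations to fit an exponential")
  if (anyNA(durations) || any(durations <= 0))
    stop("durations must be positive and non-missing")
  m <- mean(durations)
  ks <- suppressWarnings(ks.test(durations, "pexp", rate = 1 / m))
  structure(list(mean = m, n = length(durations),
                 ks_stat = unname(ks$statistic),
                 gof_pvalue = unname(ks$p.value)),
            class = "exp_fit")
}

#' Pooled duration histogram over a cohort
#'
#' Pools episode durations of one state over all patients and bins them in
#' half-open intervals `[b, b + bin_width)` starting at the smallest
#' observed duration. With `state = "span"` it instead bins the per-patient
#' observation spans.
#'
#' @param cohort list of [patient_course()] objects (or a single course).
#' @param state `"relapse"`, `"remission"` or `"span"`.
#' @param bin_width_weeks bin width, `>= 1` week.
#' @param drop_censored exclude each patient's final censored episode
#'   (ignored for `state = "span"`).
#' @return Data frame with columns `bin_start`, `bin_end`, `count`
#'   (zero rows for an empty cohort).
#' @examples
#' coh <- list(patient_course("a", c(1, -1, -1, 1, 1, -1)))
#' pooled_histogram(coh, "relapse", 1)
#' @export
pooled_histogram <- function(cohort, state = c("relapse", "remission", "span"),
                             bin_width_weeks = 1, drop_censored = TRUE) {
  state <- match.arg(state)
  stopifnot(bin_width_weeks >= 1)
  if (inherits(cohort, "patient_course")) cohort <- list(cohort)
  vals <- if (state == "span") {
    vapply(cohort, function(p) length(p$series), numeric(1))
  } else {
    unlist(lapply(cohort, function(p) {
      s <- duration_summary(p, drop_censored = drop_censored)
      if (state == "relapse") s$relapse_weeks else s$remission_weeks
    }))
  }
  if (length(vals) == 0L)
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0)))
  lo <- min(vals)
  breaks <- seq(lo, max(vals) + bin_width_weeks, by = bin_width_weeks)
  idx <- findInterval(vals, breaks)      # [b, b + w) half-open bins
  data.frame(bin_start = head(breaks, -1L),
             bin_end = breaks[-1L],
             count = tabulate(idx, nbins = length(breaks) - 1L))
}
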