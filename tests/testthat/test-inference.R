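test_that("the inference chain reproduces the worked per-patient estimates", {
  # patient with mean remission 117.7 and mean relapse 1.5 weeks
  inf23 <- msdoublewell:::infer_from_means(117.7, 1.5)
  expect_equal(inf23$barrier_ratio, 11.75968, tolerance = 1e-6)
  expect_equal(inf23$beta_hat, 0.2562605, tolerance = 1e-5)
  # patient with means (54.0, 2.1)
  inf32 <- msdoublewell:::infer_from_means(54.0, 2.1)
  expect_equal(inf32$barrier_ratio, 5.376443, tolerance = 1e-6)
  expect_equal(round(inf32$beta_hat, 2), 0.19)
  # patient with means (47.0, 4.3)
  inf53 <- msdoublewell:::infer_from_means(47.0, 4.3)
  expect_equal(inf53$barrier_ratio, 2.639591, tolerance = 1e-6)
  expect_equal(round(inf53$beta_hat, 2), 0.12)
})

test_that("inference invariants hold on fitted patients", {
  p <- generate_patient(4.3, 100, span_weeks = 5000, seed = 13)
  inf <- analyze_patient(p)
  expect_length(inf$flags, 0)
  expect_equal(inf$barrier_ratio,
               log(inf$tau_health_weeks) / log(inf$tau_disease_weeks))
  expect_lt(abs(barrier_ratio(dw_params(inf$alpha, inf$beta_hat)) -
                  inf$barrier_ratio), 1e-6)
  expect_lt(abs(inf$epsilon_hat * log(inf$tau_health_weeks) - 2 * inf$dV1_hat),
            1e-9)
  expect_lt(abs(inf$epsilon_hat * log(inf$tau_disease_weeks) - 2 * inf$dV2_hat),
            1e-9)
})

test_that("undefined estimators flag instead of erroring", {
  # every relapse exactly 1 week: log(tau_disease) = 0
  p <- series_from_episodes(data.frame(
    state = rep(c("relapse", "remission"), 4),
    start_week = cumsum(c(0, head(rep(c(1, 10), 4), -1))),
    duration_weeks = rep(c(1, 10), 4)), patient_id = "edge")
  inf <- analyze_patient(p)
  expect_true(any(grepl("undefined", inf$flags)))
  expect_true(is.na(inf$beta_hat))
  # single-episode course: no complete episodes
  inf2 <- analyze_patient(patient_course("one", rep(1L, 30)))
  expect_true(any(grepl("partial", inf2$flags)))
})

test_that("end-to-end recovery: generated durations return the generator ratio", {
  # long span makes the complete-episode means consistent
  p <- generate_patient(4.3, 100, span_weeks = 1e5, seed = 29)
  inf <- analyze_patient(p)
  s <- duration_summary(p)
  target <- log(1 / (1 - exp(-0.01))) / log(1 / (1 - exp(-1 / 4.3)))
  se_ratio <- 3 * (sd(s$remission_weeks) / sqrt(s$n_remissions) /
                     s$mean_remission_weeks) * inf$barrier_ratio
  expect_lt(abs(inf$barrier_ratio - target), max(se_ratio, 0.15))
})

test_that("model-loop inference underestimates beta by the documented prefactor bias", {
  # the closed-form exit times omit the attempt-frequency prefactor, which
  # inflates both simulated means ~4x and compresses the log-ratio, so the
  # recovered beta is systematically below the generating one
  for (b_star in c(0.12, 0.19)) {
    p <- generate_from_model(dw_params(1, b_star), epsilon = 0.15,
                             span_weeks = 6e4, seed = 99)
    inf <- analyze_patient(p)
    expect_false(is.na(inf$beta_hat))
    expect_lt(inf$beta_hat, b_star)
    expect_gt(inf$beta_hat, 0.25 * b_star)
  }
})

test_that("cohort analysis pools episodes before taking the ratio", {
  coh <- generate_cohort(cohort_config(n_patients = 12, seed = 6))
  rep <- analyze_cohort(coh)
  expect_length(rep$patients, 12)
  pooled_rem <- unlist(lapply(coh, function(p)
    duration_summary(p)$remission_weeks))
  expect_equal(rep$pooled$tau_health_weeks, mean(pooled_rem))
  expect_equal(rep$pooled$n_health, length(pooled_rem))
  # pooled ratio is the ratio of pooled means, not the mean of patient ratios
  expect_equal(rep$pooled$barrier_ratio,
               log(rep$pooled$tau_health_weeks) /
                 log(rep$pooled$tau_disease_weeks))
  # single-patient cohort: pooled equals the per-patient inference
  one <- analyze_cohort(coh[1])
  expect_equal(one$pooled$tau_health_weeks,
               one$patients[[1]]$tau_health_weeks)
  expect_equal(one$pooled$barrier_ratio, one$patients[[1]]$barrier_ratio)
  expect_error(analyze_cohort(list()), "empty")
})

test_that("reports serialise to JSON with provenance", {
  coh <- generate_cohort(cohort_config(n_patients = 6, seed = 14))
  rep <- analyze_cohort(coh)
  f <- tempfile(fileext = ".json")
  write_report_json(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$provenance$n_patients, 6)
  expect_equal(back$provenance$generator_config$seed, 14)
  expect_equal(back$pooled$tau_health_weeks, rep$pooled$tau_health_weeks,
               tolerance = 1e-12)
  unlink(f)
})

test_that("reconstructed potentials annotate the fitted geometry", {
  pot <- reconstruct_potential(0.19)
  expect_named(pot, c("x", "V"))
  g <- attr(pot, "geometry")
  expect_equal(g$dV1 / g$dV2, 5.273121, tolerance = 1e-6)
  # symmetric case: even function on the grid
  pot0 <- reconstruct_potential(0, x_grid = seq(-2, 2, by = 0.01))
  expect_equal(pot0$V, rev(pot0$V))
  # finite-difference gradient vanishes at the stationary points
  for (xs in c(g$x_health, g$x_saddle, g$x_disease)) {
    h <- 1e-7
    grad <- (dw_potential(xs + h, dw_params(1, 0.19)) -
               dw_potential(xs - h, dw_params(1, 0.19))) / (2 * h)
    expect_lt(abs(grad), 1e-6)
  }
  # from a fitted patient
  p <- generate_patient(4.3, 100, span_weeks = 5000, seed = 2)
  inf <- analyze_patient(p)
  pot2 <- reconstruct_potential(inf)
  expect_equal(attr(pot2, "beta"), inf$beta_hat)
  expect_error(reconstruct_potential(analyze_patient(
    patient_course("one", rep(1L, 30)))), "no beta fit")
})
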