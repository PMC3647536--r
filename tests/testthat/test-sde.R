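test_that("identical configs give bit-identical trajectories", {
  cfg <- sim_config(dw_params(1, 0.08), epsilon = 0.13, n_steps = 2000,
                    seed = 11)
  t1 <- simulate_trajectory(cfg)
  t2 <- simulate_trajectory(cfg)
  expect_identical(t1$states, t2$states)
  expect_length(t1$states, 2001)
  expect_equal(diff(t1$times), rep(cfg$dt, 2000))
  t3 <- simulate_trajectory(sim_config(dw_params(1, 0.08), epsilon = 0.13,
                                       n_steps = 2000, seed = 12))
  expect_false(identical(t1$states, t3$states))
})

test_that("the deterministic limit stays in a well and relaxes along the drift", {
  # started at a stable root with no noise: constant
  cfg <- sim_config(dw_params(1, 0), epsilon = 0, n_steps = 5000,
                    x_init = -1, seed = 1)
  traj <- simulate_trajectory(cfg)
  expect_true(all(abs(traj$states + 1) < 1e-9))
  expect_equal(residence_times(label_states(traj), cfg$dt)$n_transitions, 0L)
  # started inside the right basin: converges to +1, never transitions
  cfg2 <- sim_config(dw_params(1, 0), epsilon = 0, n_steps = 5000,
                     x_init = 0.5, seed = 1)
  traj2 <- simulate_trajectory(cfg2)
  expect_lt(abs(traj2$states[5001] - 1), 1e-6)
  expect_equal(residence_times(label_states(traj2), cfg2$dt)$n_transitions, 0L)
})

test_that("step-size guards reject unstable or diverging configurations", {
  expect_error(sim_config(dw_params(1, 0), epsilon = 0.1, dt = 0.2,
                          n_steps = 10), "dt")
  cfg <- sim_config(dw_params(1, 0), epsilon = 0.1, dt = 0.04,
                    n_steps = 1e4, x_init = 9.9, seed = 1)
  expect_error(simulate_trajectory(cfg), "diverged")
})

test_that("hysteresis labelling commits only at the minima", {
  fake_traj <- function(x) {
    structure(list(times = seq_along(x) - 1, states = x,
                   config = list(geometry = steady_states(dw_params(1, 0)),
                                 dt = 1)),
              class = "dw_trajectory")
  }
  g <- steady_states(dw_params(1, 0))
  # constant at the health minimum: all health
  expect_true(all(label_states(fake_traj(rep(-1, 10)), g) == "health"))
  # monotone sweep: one committed transition
  sweep <- fake_traj(seq(-1, 1, length.out = 21))
  labs <- label_states(sweep, g)
  expect_identical(unique(labs), c("health", "disease"))
  expect_equal(residence_times(labs, 1)$n_transitions, 1L)
  # excursion to the saddle and back never reaching the disease well: no transition
  excursion <- fake_traj(c(-1, -0.5, 0.1, -0.5, -1, -1))
  labs2 <- label_states(excursion, g)
  expect_true(all(labs2 == "health"))
  expect_equal(residence_times(labs2, 1)$n_transitions, 0L)
  # samples before any commitment are transit
  drifting <- fake_traj(c(0.2, 0.5, 0.99, 1.0, 1.2))
  expect_identical(label_states(drifting, g),
                   c("transit", "transit", "transit", "disease", "disease"))
})

test_that("residence times drop the censored tail and attribute transit backwards", {
  labs <- rep(c("health", "disease", "health"), c(100, 10, 50))
  rs <- residence_times(labs, dt = 1)
  expect_equal(rs$health_durations, 100)
  expect_equal(rs$disease_durations, 10)
  expect_equal(rs$n_transitions, 2L)
  expect_equal(rs$mean_health, 100)
  # no complete residence at all
  rs0 <- residence_times(rep("health", 50), dt = 0.5)
  expect_equal(rs0$n_transitions, 0L)
  expect_length(rs0$health_durations, 0)
  expect_true(is.nan(rs0$mean_health))
  # leading transit is excluded; first committed run still counts
  labs2 <- rep(c("transit", "health", "disease", "health"), c(5, 40, 8, 3))
  rs2 <- residence_times(labs2, dt = 1)
  expect_equal(rs2$health_durations, 40)
  expect_equal(rs2$disease_durations, 8)
})

test_that("online residence collection matches the trajectory pipeline draw for draw", {
  params <- dw_params(1, 0.05)
  n_steps <- 3e5
  cfg <- sim_config(params, epsilon = 0.18, n_steps = n_steps, seed = 21)
  traj <- simulate_trajectory(cfg)
  rs_r <- residence_times(label_states(traj), cfg$dt)
  rs_c <- collect_exit_times(params, epsilon = 0.18, n_exits = 1e9,
                             dt = cfg$dt, x_init = cfg$x_init, seed = 21,
                             max_steps = n_steps)
  expect_gt(rs_r$n_transitions, 5)
  expect_equal(rs_c$health_durations, rs_r$health_durations)
  expect_equal(rs_c$disease_durations, rs_r$disease_durations)
  expect_equal(rs_c$n_transitions, rs_r$n_transitions)
})

test_that("asymmetry makes health residences longer than disease residences", {
  for (eps in c(0.1, 0.2)) {
    rs <- collect_exit_times(dw_params(1, 0.08), epsilon = eps,
                             n_exits = 301, seed = 31)
    expect_gt(length(rs$health_durations), 100)
    expect_gt(rs$mean_health, rs$mean_disease)
  }
})

test_that("mean exit times are stable under halving dt", {
  params <- dw_params(1, 0)
  run <- function(dt, seed) collect_exit_times(params, epsilon = 0.16,
                                               n_exits = 301, dt = dt,
                                               seed = seed)
  a <- run(0.01, 41)
  b <- run(0.005, 42)
  pool_a <- c(a$health_durations, a$disease_durations)
  pool_b <- c(b$health_durations, b$disease_durations)
  se <- sqrt(sd(pool_a)^2 / length(pool_a) + sd(pool_b)^2 / length(pool_b))
  expect_lt(abs(mean(pool_a) - mean(pool_b)), 2.5 * se)
})

test_that("trajectory export is a tidy table with labels", {
  cfg <- sim_config(dw_params(1, 0), epsilon = 0.13, n_steps = 500, seed = 3)
  df <- trajectory_table(simulate_trajectory(cfg))
  expect_named(df, c("time_weeks", "x", "label"))
  expect_equal(nrow(df), 501)
  f <- tempfile(fileext = ".csv")
  trajectory_table(simulate_trajectory(cfg), f)
  expect_true(file.exists(f))
  unlink(f)
})
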