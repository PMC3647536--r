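# Independent oracles used across the suite.

# Brute-force stationary points: sign changes of the drift on a dense grid.
scan_roots <- function(alpha, beta, n = 1e6, lo = -3, hi = 3) {
  x <- seq(lo, hi, length.out = n)
  f <- x * (1 - alpha * x^2) - beta
  i <- which(f[-1] * f[-length(f)] <= 0)
  i <- i[c(TRUE, diff(i) > 1)]  # an exact zero on the grid flags twice
  (x[i] + x[i + 1]) / 2
}

# Random valid weekly course (starts with a relapse).
random_course <- function(id, n_episodes = NULL) {
  if (is.null(n_episodes)) n_episodes <- sample(1:8, 1)
  dur <- sample(1:12, n_episodes, replace = TRUE)
  vals <- rep_len(c(1L, -1L), n_episodes)
  patient_course(id, rep(vals, dur))
}
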