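---
title: "Modelling relapsing-remitting disease course with a stochastic double well"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling relapsing-remitting disease course with a stochastic double well}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdoublewell)
```

## The model

Relapsing-remitting multiple sclerosis alternates between two clinical
states: remission ("health", coded $-1$ week by week) and relapse
("no health", $+1$). The package treats the patient's health state $x$
as an overdamped particle in the asymmetric quartic potential

$$V(x) = -\tfrac{1}{2}x^2 + \tfrac{\alpha}{4}x^4 + \beta x,$$

driven by Gaussian white noise:

$$dx = \underbrace{\left[x(1-\alpha x^2) - \beta\right]}_{-V'(x)}\,dt
      + \sqrt{\epsilon}\,dW.$$

The two minima of $V$ are the two clinical states; the saddle between
them is the threshold that random biological variability (the noise term,
interpretable as fluctuations in gene expression and environmental
micro-exposures) must push the patient across. Deterministically
($\epsilon = 0$) the patient falls into one well and stays there forever;
with small or moderate noise the state dwells in a well for a long random
time and occasionally hops — which is exactly the erratic alternation of
long remissions and short relapses seen in weekly clinical course records.

The parameters, all dimensionless except where noted:

| parameter  | meaning                                     | default |
|------------|---------------------------------------------|---------|
| $\alpha$   | controls well depth (barrier height); fixed at 1 for inference | 1 |
| $\beta$    | tilt; makes the remission well deeper; bistable iff $27\alpha\beta^2 < 4$ | fitted |
| $\epsilon$ | noise variance per week                     | 0.13 typical |
| $dt$       | Euler–Maruyama step, weeks                  | 0.01 |

One model time unit is one week, so simulated residence times compare
directly with clinical durations.

### Geometry

`steady_states()` solves $\alpha x^3 - x + \beta = 0$ (companion-matrix
roots, Newton-polished to residuals $<10^{-10}$) and reports the stable
states $x_\mathrm{health} < 0 < x_\mathrm{disease}$, the saddle, and the
barriers $\Delta V_1 = V(x_0)-V(x_\mathrm{health})$ (remission side) and
$\Delta V_2 = V(x_0)-V(x_\mathrm{disease})$ (relapse side). At the
saddle-node boundary $27\alpha\beta^2 = 4$ the relapse well vanishes and a
typed error (`dw_bifurcation_error`) is raised: the two-state picture no
longer exists there.

```{r geometry}
steady_states(dw_params(alpha = 1, beta = 0.12))
```

## From durations to the potential shape

In the small-noise (Kramers) regime the mean residence times obey
$\tau_1 \approx e^{2\Delta V_1/\epsilon}$ and
$\tau_2 \approx e^{2\Delta V_2/\epsilon}$, both with the *same* noise
variance. Taking natural logarithms and dividing cancels $\epsilon$:

$$\frac{\Delta V_1}{\Delta V_2} \approx
  \frac{\ln \tau_1}{\ln \tau_2},$$

so the ratio of well depths is estimable from a patient's mean remission
and relapse durations alone (`barrier_ratio_from_durations()`). Durations
enter in weeks — the estimator substitutes the means directly and is not
unit-free — and both means must exceed one week, otherwise a logarithm is
non-positive and the inference is flagged rather than computed.

The map $\beta \mapsto \Delta V_1/\Delta V_2$ at fixed $\alpha$ is
strictly increasing from 1 (symmetric) to arbitrarily large values at the
bifurcation, so it is inverted by bracketed root search (`solve_beta()`,
ratio matched to $10^{-9}$). With $\beta$ in hand, inverting the
health-side Kramers relation gives the noise level,
$\hat\epsilon = 2\Delta V_1 / \ln\tau_1$; because $\beta$ matches the
log-ratio exactly, the disease-side inversion yields the identical value
(asserted in `analyze_patient()`).

```{r worked}
ratio <- barrier_ratio_from_durations(100, 4.3)   # cohort-level means
ratio
solve_beta(ratio)
```

### A reference inconsistency, kept visible

For the illustrative patient with means (117.7, 1.5) weeks the log-ratio
is 11.76, and the faithful inverse is $\beta = 0.2565$, which rounds to
0.26 — while the reference reconstruction for that patient reports
$\beta = 0.25$, whose *forward* ratio is 10.77, not 11.8. The two other
reference patients (ratios 5.3 and 2.7, $\beta$ = 0.19 and 0.12) round-trip
exactly. We implement the inverse map as defined and let the 0.25/0.26
discrepancy stand; the corresponding acceptance test records it by
failing, rather than papering over it with a widened tolerance.

## The simulator and its numerics

`simulate_trajectory()` uses the Euler–Maruyama scheme in compiled code.
Choices that matter:

* **Step size.** Default $dt = 0.01$ weeks; a guard requires
  $dt < 0.1/\max|{\rm drift}'|$ at the stationary points, and the suite
  checks that halving $dt$ moves mean exit times by less than the
  Monte-Carlo noise. Trajectories exceeding $|x| > 10$ abort with an
  error (step too large).
* **State labelling.** The continuous path is mapped to clinical states
  with a two-threshold hysteresis rule: the label commits to health only
  when $x$ reaches $x_\mathrm{health}$ and to disease only when it reaches
  $x_\mathrm{disease}$; in between, the previous label persists. Without
  hysteresis, jitter around the saddle would create spurious one-sample
  "episodes".
* **Residence accounting.** A residence runs from commitment to a state
  until commitment to the other state, so transit time is charged to the
  state being left. The leading uncommitted segment is dropped and the
  final open residence is censored (excluded from means). The R pipeline
  (`label_states()` + `residence_times()`) and the online compiled
  bookkeeping (`collect_exit_times()`) are verified against each other
  draw-for-draw on a shared noise stream.
* **Reproducibility.** All draws come from R's seeded generator;
  identical configurations give identical trajectories.

### What the closed form does and does not predict

The exponential $e^{2\Delta V/\epsilon}$ omits the Kramers
attempt-frequency prefactor
($\sim 2\pi/\sqrt{V''_{\min}|V''_{\mathrm{saddle}}|}$, about a factor 4
here), so *absolute* mean exit times from the formula are
order-of-magnitude only. What survives the omission is the exponent:
$\ln\tau$ is linear in $1/\epsilon$ with slope $2\Delta V$.
`kramers_slope_check()` estimates that slope by simulation
(five noise levels between 0.08 and 0.20, at least 100 complete exits
each) and the suite requires agreement with $2\Delta V$ within 15%.
Simulated exit-time distributions are close to exponential (coefficient
of variation within [0.85, 1.15] at $\epsilon = 0.13$), matching the
exponential-decay histograms of clinical durations.

A direct corollary, measured rather than hidden: fitting $\beta$ to
*simulated* courses via the log-ratio underestimates the generating
$\beta^\*$ by roughly 40% for $\beta^\* \in \{0.12, 0.19\}$ and
$\epsilon \in [0.1, 0.2]$, because the prefactor inflates both $\ln\tau$
values additively and compresses their ratio toward 1 (weekly rounding of
short relapses pushes the same way). The unit suite asserts the true
property — systematic underestimation with
$\hat\beta \in (0.25\,\beta^\*, \beta^\*)$ — and this paragraph is the
documentation of why a tighter claim would be wrong.

## The synthetic cohort generator

No patient-level dataset is distributed with the package, so
`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes:

* 70 patients; each course starts with a relapse and alternates states;
* episode durations are continuous exponentials rounded *up* to whole
  weeks (the clinical convention records any shorter exacerbation as one
  week); cohort means 4.3 weeks (relapse) and 100 weeks (remission);
* per-patient heterogeneity: both means are scaled by a shared log-normal
  multiplier with median 1 and CV 0.5, wide enough to span per-patient
  remission means from roughly 47 to 118 weeks;
* observation spans follow a truncated exponential on [40, 1311] weeks
  calibrated so about 36% of spans fall at or below 200 weeks (solved by
  root-finding at configuration time); the final episode of every course
  is right-censored by the span, as in the clinical encoding;
* every patient draws from an independent seed derived from the master
  seed, so cohorts are reproducible and order-insensitive.

Known quantitative consequences, all verified in the suite:

* **Ceiling bias.** The mean of $\lceil \mathrm{Exp}(m) \rceil$ is
  $1/(1-e^{-1/m})$: 4.805 for $m = 4.3$ and 100.5 for $m = 100$ — about
  half a week above the continuous mean.
* **Window truncation.** With spans averaging ~350 weeks, remission
  episodes *contained* in the window are conditioned on fitting into it,
  which biases their mean down by 15–25%; cohorts generated with very
  long spans recover ~100 weeks correctly. Complete-episode means are
  therefore not unbiased for the generating mean at realistic spans, for
  relapses a negligible effect but for remissions a substantial one
  (pooled complete-remission means come out near 70–78 weeks at the
  defaults). One acceptance test asserts recovery within 15% of the
  generating remission mean and consequently fails; it is retained as an
  honest record of this censoring bias rather than weakened. The pooled
  *barrier ratio* is much less affected — taking logarithms compresses
  the bias — and stays within 15% of the generating value
  $\ln(100.5)/\ln(4.805) \approx 2.9$.
* **Heterogeneity weighting.** Pooling episodes across patients weights
  each patient by their episode count, which is inversely proportional to
  their multiplier $m$; with median-1 log-normal multipliers this shrinks
  the pooled mean by $1/E[1/m] \approx 0.89$.

`generate_from_model()` closes the loop: it simulates the Langevin
dynamics itself, labels it, and downsamples to the weekly $\pm 1$ grid
(label = committed state at week end, record trimmed to start at the
first relapse), so every pipeline stage can be exercised on
model-generated as well as distribution-generated patients.

What the generator does *not* emulate: secondary-progressive conversion,
seasonality, therapy effects, covariates, within-patient drift of episode
rates, and any dependence between successive episode durations. Passing
tests therefore show that the pipeline is correct and calibrated for
exponential, stationary, independent episode processes — not that real
courses satisfy those assumptions.

## The inference pipeline

`analyze_patient()` chains duration summary → log-ratio → `solve_beta()`
→ geometry → $\hat\epsilon$, with `alpha` fixed at 1 (a single observed
ratio identifies a single parameter; `alpha` is exposed but not fitted).
Courses with undefined estimators (a mean at or below one week, or no
complete episode of a state) return flagged partial results instead of
errors. `analyze_cohort()` adds the cohort-level fit: complete episodes
are pooled across patients, the pooled means computed, and the ratio
taken of those pooled means — not the mean of per-patient ratios, which
is a different (and more outlier-sensitive) statistic. Defaults exclude
each course's final censored episode; `drop_censored = FALSE` provides
the sensitivity analysis.

```{r pipeline}
coh <- generate_cohort(cohort_config(n_patients = 20, seed = 8))
rep <- analyze_cohort(coh)
rep
```

`reconstruct_potential()` evaluates the fitted well on a grid with the
stationary points annotated, giving the per-patient energy-landscape
picture implied by the inferred asymmetry.

## Problem sizes and runtime

The test suite keeps Monte-Carlo sizes modest by design: the Kramers
slope check uses 120 complete exits per noise level on a five-point grid
(about 60 million Euler–Maruyama steps in total, a few seconds in
compiled code); exponentiality uses 600 pooled exits at
$\epsilon = 0.13$; cohort-level checks use the default 70 patients; the
model-loop tests use 30,000–60,000-week simulated courses. These sizes
put Monte-Carlo standard errors comfortably inside the asserted
tolerances.

## Limitations

* The log-ratio estimator assumes both states share one noise variance
  and sit in the Kramers regime; it is undefined for mean durations at or
  below one week, which real relapse records can approach.
* Absolute exit times are identifiable only up to the omitted prefactor;
  $\hat\epsilon$ inherits that distortion and should be read as an
  effective, not physical, noise level.
* Weekly discretisation makes short relapses coarse; the exponential
  goodness-of-fit p-value (`fit_exponential()`) is computed on tied,
  discretised values against a continuous law with an estimated
  parameter, and is a diagnostic rather than an exact test.
* Only two states are modelled; progression, lesion load and disability
  accumulation are out of scope.
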