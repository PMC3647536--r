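#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Euler-Maruyama integration of
//   dx = [x(1 - alpha x^2) - beta] dt + sqrt(epsilon) dW
// with online two-threshold (hysteresis) residence bookkeeping: the label
// commits to "health" only when x first reaches x_health and to "disease"
// only when x first reaches x_disease; between commitments the previous
// label persists, so saddle jitter never counts as a transition.
//
// Noise draws come from R's RNG (norm_rand), so results are reproducible
// under set.seed() in the calling R code. A residence is recorded when the
// label flips: its duration runs from this state's commitment step to the
// other state's commitment step (transit time is attributed to the state
// being left). The final, still-open residence is censored and not
// recorded. If max_exits > 0, integration stops once that many residences
// have been recorded, which keeps long Kramers runs memory-free
// (keep_path should then be false).
//
// [[Rcpp::export]]
List em_core(double x0, double alpha, double beta, double epsilon,
             double dt, double n_steps, bool keep_path,
             double x_health, double x_disease, double max_exits) {
  const R_xlen_t n = static_cast<R_xlen_t>(n_steps);
  const double sig = std::sqrt(epsilon * dt);
  NumericVector path;
  if (keep_path) path = NumericVector(n + 1);

  std::vector<double> health_dur, disease_dur;
  double x = x0;
  if (keep_path) path[0] = x;

  int label = 0;               // -1 health, +1 disease, 0 uncommitted
  R_xlen_t commit_step = 0;
  int n_trans = 0;
  bool diverged = false;
  if (x <= x_health) label = -1;
  else if (x >= x_disease) label = +1;

  R_xlen_t k = 0;
  for (k = 1; k <= n; ++k) {
    const double drift = x * (1.0 - alpha * x * x) - beta;
    x += drift * dt + sig * norm_rand();
    if (keep_path) path[k] = x;
    if (std::fabs(x) > 10.0) { diverged = true; break; }
    int newlab = label;
    if (x <= x_health) newlab = -1;
    else if (x >= x_disease) newlab = +1;
    if (newlab != label) {
      if (label != 0) {
        const double dur = static_cast<double>(k - commit_step) * dt;
        if (label == -1) health_dur.push_back(dur);
        else disease_dur.push_back(dur);
        ++n_trans;
      }
      label = newlab;
      commit_step = k;
      if (max_exits > 0.0 &&
          static_cast<double>(health_dur.size() + disease_dur.size()) >= max_exits)
        break;
    }
    if ((k & 0xFFFFF) == 0) checkUserInterrupt();
  }

  return List::create(
    _["path"] = keep_path ? static_cast<RObject>(path)
                          : static_cast<RObject>(R_NilValue),
    _["health_durations"] = health_dur,
    _["disease_durations"] = disease_dur,
    _["n_transitions"] = n_trans,
    _["diverged"] = diverged,
    _["steps_run"] = static_cast<double>(k > n ? n : k));
}
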