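#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <limits>
#include <random>
#include <vector>

using namespace Rcpp;

// Two-state TASEP with extended particles (footprint ell codons).
// Each ribosome is (A-site position p, bound flag). Ribosomes are stored
// leader-first: index 0 is closest to the 3' end, the last element is the
// most recently initiated (smallest p). Exclusion: footprints
// [p, min(p+ell-1, L)] are disjoint; order is preserved (no overtaking).
//
// Events and propensities:
//   initiation (rate alpha)  iff codons 1..ell are all free
//   tRNA arrival  (rate k[p]) for each ribosome awaiting its tRNA
//   translocation (rate gamma) for each bound ribosome at p < L with
//                 codon p+ell free (or p+ell > L)
//   termination   (rate beta) for the bound ribosome at p == L
//
// RNG: 64-bit xorshift-free Mersenne twister, uniform doubles built from the
// top 53 bits so the stream is identical across compilers.

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {
    // in [2^-54, 1 - 2^-54]; never exactly 0 or 1
    return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rexp(double rate) { return -std::log(unif()) / rate; }
};

struct Lattice {
  std::vector<int> pos;     // A-site positions, leader first (descending)
  std::vector<char> bound;  // 0 = awaiting tRNA, 1 = tRNA bound
  int L, ell;

  bool init_enabled() const {
    return pos.empty() || pos.back() > ell;
  }
  // can ribosome i move one codon forward?
  bool can_step(size_t i) const {
    int target = pos[i] + ell;  // codon newly covered after the step
    if (target > L) return true;
    if (i == 0) return true;
    return pos[i - 1] > target;
  }
};

}  // namespace

// [[Rcpp::export(name = ".simulate_tasep_cpp")]]
List simulate_tasep_cpp(NumericVector k_site, double alpha, double gamma,
                        double beta, int footprint, double burn_time,
                        int burn_terminations, double target_terminations,
                        double max_time, int min_batches, double seed) {
  const int L = k_site.size();
  const int ell = footprint;
  if (L < ell) stop("lattice shorter than the ribosome footprint");
  Rng rng(static_cast<uint64_t>(seed));
  Lattice lat;
  lat.L = L;
  lat.ell = ell;

  std::vector<double> prop;  // 0 = initiation, then one per ribosome
  prop.reserve(L / ell + 2);

  long long n_term_total = 0;

  // one Gillespie step; returns event code: 0 none (dt only, capped),
  // 1 initiation, 2 termination, 3 other. t advanced; if t + dt would pass
  // t_stop the state is frozen at t_stop (exact by memorylessness).
  // rho_acc, when non-null, accumulates A-site residence time.
  auto step = [&](double &t, double t_stop, double *rho_acc) -> int {
    const size_t n = lat.pos.size();
    prop.assign(1, lat.init_enabled() ? alpha : 0.0);
    double total = prop[0];
    for (size_t i = 0; i < n; ++i) {
      double a;
      if (!lat.bound[i]) a = k_site[lat.pos[i] - 1];
      else if (lat.pos[i] == L) a = beta;
      else a = lat.can_step(i) ? gamma : 0.0;
      prop.push_back(a);
      total += a;
    }
    double dt = (total > 0.0) ? rng.rexp(total) : (t_stop - t);
    bool fire = true;
    if (t + dt >= t_stop || total <= 0.0) {
      dt = t_stop - t;
      fire = false;
    }
    if (rho_acc) {
      for (size_t i = 0; i < n; ++i) rho_acc[lat.pos[i] - 1] += dt;
    }
    t += dt;
    if (!fire) return 0;

    double r = rng.unif() * total;
    size_t idx = 0;
    double cum = prop[0];
    while (cum < r && idx + 1 < prop.size()) cum += prop[++idx];
    if (idx == 0) {
      lat.pos.push_back(1);
      lat.bound.push_back(0);
      return 1;
    }
    size_t i = idx - 1;
    if (!lat.bound[i]) {
      lat.bound[i] = 1;
    } else if (lat.pos[i] == L) {
      lat.pos.erase(lat.pos.begin());
      lat.bound.erase(lat.bound.begin());
      ++n_term_total;
      return 2;
    } else {
      lat.pos[i] += 1;
      lat.bound[i] = 0;
    }
    return 3;
  };

  const double inf = std::numeric_limits<double>::infinity();

  // ---- burn-in: discard until both the time and termination rules are met
  double t = 0.0;
  while (t < burn_time || n_term_total < burn_terminations) {
    double t_stop = (n_term_total >= burn_terminations) ? burn_time : inf;
    if (step(t, t_stop, nullptr) == 0 && t >= burn_time &&
        n_term_total >= burn_terminations)
      break;
    if (t > burn_time && n_term_total >= burn_terminations) break;
    // safety: an empty propensity set cannot occur (initiation or an enabled
    // ribosome always exists), so no livelock check is needed
  }

  // ---- pilot: estimate J to size the measurement batches
  double pilot_t = 0.0;
  long long pilot_n0 = n_term_total;
  double pilot_target = std::max(1.0, target_terminations / 10.0);
  double pilot_cap = max_time / 10.0;
  {
    double tp = 0.0;
    while ((n_term_total - pilot_n0) < pilot_target && tp < pilot_cap) {
      step(tp, pilot_cap, nullptr);
      if (tp >= pilot_cap) break;
    }
    pilot_t = tp;
  }
  long long pilot_n = n_term_total - pilot_n0;
  double j_est = (pilot_n > 0 && pilot_t > 0) ? pilot_n / pilot_t : 0.0;

  double span = (j_est > 0.0)
                    ? std::min(max_time, target_terminations / j_est)
                    : max_time;
  double batch_len = span / min_batches;

  // ---- measurement: whole batches until the termination target or time cap
  std::vector<double> batch_term;
  std::vector<std::vector<double>> batch_rho;
  std::vector<double> rho_acc(L, 0.0);
  long long meas_n0 = n_term_total, n_init = 0;
  double t_meas = 0.0;
  int b = 0;
  const int max_batches = 40 * min_batches;
  while (true) {
    std::vector<double> rho_b(L, 0.0);
    long long nb0 = n_term_total;
    double tb = 0.0;
    while (tb < batch_len) {
      int ev = step(tb, batch_len, rho_b.data());
      if (ev == 1) ++n_init;
    }
    t_meas += batch_len;
    batch_term.push_back(static_cast<double>(n_term_total - nb0));
    for (int i = 0; i < L; ++i) rho_acc[i] += rho_b[i];
    batch_rho.push_back(std::move(rho_b));
    ++b;
    long long meas_n = n_term_total - meas_n0;
    if (b >= min_batches &&
        (meas_n >= target_terminations || t_meas + batch_len > max_time ||
         b >= max_batches))
      break;
  }

  long long n_term = n_term_total - meas_n0;
  double J = n_term / t_meas;
  double mean_b = 0.0, var_b = 0.0;
  for (double x : batch_term) mean_b += x / batch_len;
  mean_b /= b;
  for (double x : batch_term) {
    double d = x / batch_len - mean_b;
    var_b += d * d;
  }
  var_b /= (b - 1);
  double J_se = std::sqrt(var_b / b);

  NumericVector rho(L);
  double mean_rib = 0.0;
  for (int i = 0; i < L; ++i) {
    rho[i] = rho_acc[i] / t_meas;
    mean_rib += rho[i];
  }
  NumericMatrix rho_batches(b, L);
  for (int bi = 0; bi < b; ++bi)
    for (int i = 0; i < L; ++i) rho_batches(bi, i) = batch_rho[bi][i] / batch_len;

  return List::create(
      _["J"] = J, _["J_se"] = J_se, _["rho"] = rho,
      _["rho_batch"] = rho_batches, _["mean_ribosomes"] = mean_rib,
      _["n_initiations"] = static_cast<double>(n_init),
      _["n_terminations"] = static_cast<double>(n_term),
      _["measured_time"] = t_meas, _["n_batches"] = b,
      _["ribosomes_on_lattice"] = static_cast<int>(lat.pos.size()));
}
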