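// 1D circular-track model: cells hop clockwise on a ring of L sites, are
// slowed by spores already sitting at the target site (pass prob P^n), gain
// C-signal by a basal increment plus transfer from motile neighbours one site
// ahead/behind, and freeze into spores at a concentration threshold.
//
// All randomness comes from R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct TrackPar {
  int L;
  double P, T, basal, thr;
};

// Fisher-Yates shuffle using R's RNG
void shuffle_idx(std::vector<int>& v) {
  for (int k = (int)v.size() - 1; k > 0; --k) {
    int j = (int)std::floor(unif_rand() * (k + 1));
    if (j > k) j = k;
    std::swap(v[k], v[j]);
  }
}

// One full step: movement (shuffled sequential), synchronous signaling,
// then threshold conversion. sporeAt holds per-site spore counts.
void step_inner(std::vector<int>& pos, std::vector<double>& conc,
                std::vector<char>& spore, std::vector<int>& sporeAt,
                const TrackPar& p) {
  const int N = (int)pos.size();
  const int L = p.L;

  std::vector<int> order;
  order.reserve(N);
  for (int i = 0; i < N; ++i)
    if (!spore[i]) order.push_back(i);
  shuffle_idx(order);

  for (size_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    int target = (pos[i] + 1) % L;
    int n = sporeAt[target];
    bool pass;
    if (n == 0) {
      pass = true;
    } else if (p.P <= 0.0) {
      pass = false;
    } else if (p.P >= 1.0) {
      pass = true;
    } else {
      pass = (unif_rand() < std::pow(p.P, (double)n));
    }
    if (pass) pos[i] = target;
  }

  // signaling: computed from pre-update concentrations (synchronous);
  // same-site cells contribute nothing, spores are excluded from cbar
  std::vector<double> sum(L, 0.0);
  std::vector<int> cnt(L, 0);
  for (int i = 0; i < N; ++i)
    if (!spore[i]) {
      sum[pos[i]] += conc[i];
      cnt[pos[i]]++;
    }
  std::vector<double> newc(conc);
  for (int i = 0; i < N; ++i) {
    if (spore[i]) continue;
    int ahead = (pos[i] + 1) % L;
    int behind = (pos[i] - 1 + L) % L;
    double s = sum[ahead] + sum[behind];
    int c = cnt[ahead] + cnt[behind];
    double transfer = (c > 0) ? p.T * (s / (double)c) : 0.0;
    newc[i] = conc[i] + p.basal + transfer;
  }
  conc.swap(newc);

  // tolerance absorbs accumulated rounding of the repeated basal increments
  const double thrEff = p.thr - 1e-9;
  for (int i = 0; i < N; ++i) {
    if (!spore[i] && conc[i] >= thrEff) {
      spore[i] = 1;
      sporeAt[pos[i]]++;
    }
  }
}

void unpack(const IntegerVector& position, const NumericVector& concentration,
            const LogicalVector& isSpore, int L, std::vector<int>& pos,
            std::vector<double>& conc, std::vector<char>& spore,
            std::vector<int>& sporeAt) {
  int N = position.size();
  pos.assign(position.begin(), position.end());
  conc.assign(concentration.begin(), concentration.end());
  spore.resize(N);
  sporeAt.assign(L, 0);
  for (int i = 0; i < N; ++i) {
    spore[i] = isSpore[i] ? 1 : 0;
    if (spore[i]) sporeAt[pos[i]]++;
  }
}

}  // namespace

// [[Rcpp::export(name = ".track_init_cpp")]]
List track_init_cpp(int L, int N, double cmin, double cmax) {
  RNGScope scope;
  IntegerVector pos(N);
  NumericVector conc(N);
  for (int i = 0; i < N; ++i) {
    int p = (int)std::floor(unif_rand() * L);
    if (p >= L) p = L - 1;
    pos[i] = p;
  }
  for (int i = 0; i < N; ++i) conc[i] = cmin + unif_rand() * (cmax - cmin);
  return List::create(_["position"] = pos, _["concentration"] = conc);
}

// [[Rcpp::export(name = ".track_pass_cpp")]]
LogicalVector track_pass_cpp(int nSpores, double P, int nTrials) {
  RNGScope scope;
  LogicalVector out(nTrials);
  double pe = (nSpores == 0) ? 1.0 : std::pow(P, (double)nSpores);
  for (int i = 0; i < nTrials; ++i) out[i] = (unif_rand() < pe) || pe >= 1.0;
  return out;
}

// [[Rcpp::export(name = ".track_step_cpp")]]
List track_step_cpp(IntegerVector position, NumericVector concentration,
                    LogicalVector isSpore, int L, double P, double T,
                    double basal, double threshold, int nSteps) {
  RNGScope scope;
  TrackPar par{L, P, T, basal, threshold};
  std::vector<int> pos;
  std::vector<double> conc;
  std::vector<char> spore;
  std::vector<int> sporeAt;
  unpack(position, concentration, isSpore, L, pos, conc, spore, sporeAt);
  for (int s = 0; s < nSteps; ++s) step_inner(pos, conc, spore, sporeAt, par);
  int N = position.size();
  IntegerVector outPos(N);
  NumericVector outConc(N);
  LogicalVector outSpore(N);
  for (int i = 0; i < N; ++i) {
    outPos[i] = pos[i];
    outConc[i] = conc[i];
    outSpore[i] = spore[i] != 0;
  }
  return List::create(_["position"] = outPos, _["concentration"] = outConc,
                      _["spore"] = outSpore);
}

// Apply the signaling update alone (no movement, no conversion).
// [[Rcpp::export(name = ".track_signals_cpp")]]
NumericVector track_signals_cpp(IntegerVector position,
                                NumericVector concentration,
                                LogicalVector isSpore, int L, double T,
                                double basal) {
  int N = position.size();
  std::vector<double> sum(L, 0.0);
  std::vector<int> cnt(L, 0);
  for (int i = 0; i < N; ++i)
    if (!isSpore[i]) {
      sum[position[i]] += concentration[i];
      cnt[position[i]]++;
    }
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    if (isSpore[i]) {
      out[i] = concentration[i];
      continue;
    }
    int ahead = (position[i] + 1) % L;
    int behind = (position[i] - 1 + L) % L;
    double s = sum[ahead] + sum[behind];
    int c = cnt[ahead] + cnt[behind];
    double transfer = (c > 0) ? T * (s / (double)c) : 0.0;
    out[i] = concentration[i] + basal + transfer;
  }
  return out;
}

// Run an initialized state to completion (all spores); bounded by
// ceil(threshold/basal) + 1 steps, which basal production guarantees.
// [[Rcpp::export(name = ".track_run_cpp")]]
List track_run_cpp(IntegerVector position, NumericVector concentration,
                   LogicalVector isSpore, int L, double P, double T,
                   double basal, double threshold) {
  RNGScope scope;
  TrackPar par{L, P, T, basal, threshold};
  std::vector<int> pos;
  std::vector<double> conc;
  std::vector<char> spore;
  std::vector<int> sporeAt;
  unpack(position, concentration, isSpore, L, pos, conc, spore, sporeAt);
  const int N = position.size();
  int maxSteps = (int)std::ceil(threshold / basal) + 1;
  int steps = 0;
  bool anyMotile = false;
  for (int i = 0; i < N; ++i)
    if (!spore[i]) anyMotile = true;
  while (anyMotile && steps < maxSteps) {
    step_inner(pos, conc, spore, sporeAt, par);
    ++steps;
    anyMotile = false;
    for (int i = 0; i < N; ++i)
      if (!spore[i]) {
        anyMotile = true;
        break;
      }
  }
  IntegerVector counts(L);
  for (int j = 0; j < L; ++j) counts[j] = sporeAt[j];
  return List::create(_["sporeCounts"] = counts, _["steps"] = steps,
                      _["completed"] = !anyMotile);
}
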