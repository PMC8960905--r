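#include <Rcpp.h>
using namespace Rcpp;

// Draws follow a fixed order (jump?, source, target, replace?, index) so the
// pure-R reference step in R/simulator.R consumes the same RNG stream.

static inline int draw_index(int N) {
  int i = (int)(unif_rand() * N);
  return i >= N ? N - 1 : i; // guard against unif_rand() == 1.0
}

static inline void micro_step(std::vector<int>& order, double tau, double nu,
                              int& next_id) {
  const int N = (int)order.size();
  if (unif_rand() < tau) {
    int src = draw_index(N);
    int dst = draw_index(N);
    if (src != dst) {
      int id = order[src];
      order.erase(order.begin() + src);
      order.insert(order.begin() + dst, id);
    }
  }
  if (unif_rand() < nu) {
    order[draw_index(N)] = next_id++;
  }
}

// Simulate the displacement-replacement model: N elements, N micro-steps of
// length 1/N per observation, record the top N0 ids at t = 0..T-1.
// tau and nu are per-interval vectors (length T-1) so rate schedules
// (e.g. a mid-series shock) reuse the same engine.
// [[Rcpp::export]]
IntegerMatrix cpp_simulate(int N, int N0, NumericVector tau,
                           NumericVector nu, int T) {
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i + 1;
  int next_id = N + 1;
  IntegerMatrix out(T, N0);
  for (int j = 0; j < N0; ++j) out(0, j) = order[j];
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < N; ++s)
      micro_step(order, tau[t - 1], nu[t - 1], next_id);
    for (int j = 0; j < N0; ++j) out(t, j) = order[j];
  }
  return out;
}

// Track one focal element (start_rank, 1-based) through the full-system
// dynamics in O(1) per micro-step: only the focal rank and its survival
// matter, the other elements are exchangeable.  Replaced focals stop being
// counted (they form the mass deficit of the displacement histogram).
// [[Rcpp::export]]
List cpp_track(int N, double tau, double nu, IntegerVector lags,
               int start_rank, int n_real) {
  const int n_lags = lags.size();
  int max_lag = 0;
  for (int i = 0; i < n_lags; ++i) if (lags[i] > max_lag) max_lag = lags[i];
  IntegerMatrix counts(n_lags, N);
  IntegerVector surv(n_lags), nojump(n_lags);
  for (int rep = 0; rep < n_real; ++rep) {
    int f = start_rank; // 1-based rank of the focal element
    bool alive = true, jumped = false;
    for (int t = 1; t <= max_lag && alive; ++t) {
      for (int s = 0; s < N; ++s) {
        if (unif_rand() < tau) {
          int src = draw_index(N) + 1;
          int dst = draw_index(N) + 1;
          if (src == f) {
            f = dst;
            jumped = true;
          } else {
            if (src < f) --f;   // removal shifts ranks below src up by one
            if (dst <= f) ++f;  // insertion shifts ranks at/after dst down
          }
        }
        if (unif_rand() < nu) {
          if (draw_index(N) + 1 == f) { alive = false; break; }
        }
      }
      if (alive) {
        for (int li = 0; li < n_lags; ++li) {
          if (lags[li] == t) {
            counts(li, f - 1)++;
            surv[li]++;
            if (!jumped) nojump[li]++;
          }
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["survivors"] = surv,
                      _["never_jumped"] = nojump);
}
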