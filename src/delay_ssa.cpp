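// Exact stochastic simulation of marked gene-state chains with a
// deterministic completion delay for the produced species (delay SSA).
// Markovian firings are drawn by the direct method; every production
// event pushes a completion scheduled at t + tau onto a FIFO queue (all
// delays are equal so the queue stays time ordered), and a queued
// completion is executed whenever it precedes the next stochastic firing.
// Ties (completion time equal to the next firing time) execute the
// completion first. Uses R's RNG so results are reproducible via set.seed.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static int sample_state(const NumericVector& probs) {
  double u = unif_rand(), acc = 0.0;
  for (int i = 0; i < probs.size(); ++i) {
    acc += probs[i];
    if (u <= acc) return i;
  }
  return probs.size() - 1;
}

// [[Rcpp::export]]
IntegerMatrix cpp_dssa_counts(NumericMatrix D0, NumericMatrix D1,
                              double d, double tau, double horizon,
                              int n_samples, NumericVector init_probs,
                              bool completion_to_M, bool track_M) {
  const int ns = D0.nrow();
  IntegerMatrix out(n_samples, 2);
  const double INF = R_PosInf;

  for (int s = 0; s < n_samples; ++s) {
    int g = sample_state(init_probs);
    long A = 0, M = 0;
    double t = 0.0;
    std::queue<double> done;  // completion times, monotone (fixed tau)

    while (true) {
      // propensities: unmarked gene moves, marked productions, M decay
      double rtot = 0.0;
      for (int j = 0; j < ns; ++j) {
        if (j != g) rtot += D0(g, j);
        rtot += D1(g, j);
      }
      double rdecay = (track_M && d > 0.0) ? d * (double)M : 0.0;
      rtot += rdecay;

      double tnext = (rtot > 0.0) ? t + exp_rand() / rtot : INF;
      double tq = done.empty() ? INF : done.front();

      if (tq <= tnext && tq <= horizon) {  // completion fires first
        t = tq;
        done.pop();
        --A;
        if (completion_to_M) ++M;
        continue;
      }
      if (tnext >= horizon || !R_FINITE(tnext)) break;
      t = tnext;

      double u = unif_rand() * rtot, acc = 0.0;
      int fired = -1;   // 0..ns-1 unmarked to j, ns..2ns-1 marked, 2ns decay
      for (int j = 0; j < ns && fired < 0; ++j) {
        if (j != g) {
          acc += D0(g, j);
          if (u <= acc) fired = j;
        }
      }
      if (fired < 0) {
        for (int j = 0; j < ns && fired < 0; ++j) {
          acc += D1(g, j);
          if (u <= acc) fired = ns + j;
        }
      }
      if (fired < 0) fired = 2 * ns;

      if (fired < ns) {
        g = fired;
      } else if (fired < 2 * ns) {
        g = fired - ns;  // marked transitions may change state (mechanistic)
        if (tau > 0.0) {
          ++A;
          done.push(t + tau);
        } else {
          ++M;
        }
      } else {
        --M;
      }
    }
    out(s, 0) = (int)A;
    out(s, 1) = (int)M;
  }
  return out;
}

// One long trajectory; returns the times of the first n_events
// production-marked firings (for waiting-time statistics).
// [[Rcpp::export]]
NumericVector cpp_dssa_events(NumericMatrix D0, NumericMatrix D1,
                              NumericVector init_probs, int n_events) {
  const int ns = D0.nrow();
  NumericVector times(n_events);
  int g = sample_state(init_probs), got = 0;
  double t = 0.0;

  while (got < n_events) {
    double rtot = 0.0;
    for (int j = 0; j < ns; ++j) {
      if (j != g) rtot += D0(g, j);
      rtot += D1(g, j);
    }
    if (rtot <= 0.0) stop("chain has an absorbing state; no further events");
    t += exp_rand() / rtot;

    double u = unif_rand() * rtot, acc = 0.0;
    int fired = -1;
    for (int j = 0; j < ns && fired < 0; ++j) {
      if (j != g) {
        acc += D0(g, j);
        if (u <= acc) fired = j;
      }
    }
    if (fired >= 0) {
      g = fired;
    } else {
      int jmax = 0;
      for (int j = 0; j < ns; ++j) {
        if (D1(g, j) > D1(g, jmax)) jmax = j;
        acc += D1(g, j);
        if (fired < 0 && u <= acc) fired = ns + j;
      }
      if (fired < 0) fired = ns + jmax;  // rounding guard at the boundary
      g = fired - ns;
      times[got++] = t;
    }
  }
  return times;
}
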