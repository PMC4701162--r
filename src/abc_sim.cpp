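#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Attrition simulation kernel shared by the single-battle entry point and
// the batched ABC distance computation. Model codes: 1 linear, 2 squared,
// 3 logarithmic, 4 fatigue. Termination codes: 1 historical casualties
// reached, 2 annihilation/stall, 3 max_steps guard.

struct Outcome {
  double cas_blue;
  double cas_red;
  int steps;
  int termination;
};

static inline void losses(int code, double B, double R, double b, double r,
                          int t, double &lb, double &lr) {
  switch (code) {
  case 1: lb = r * B * R; lr = b * R * B; break;
  case 2: lb = r * R;     lr = b * B;     break;
  case 3: lb = r * B;     lr = b * R;     break;
  default: {
    double damp = std::log(M_E + (double)t);
    lb = r * B / damp; lr = b * R / damp;
  }
  }
}

static Outcome simulate_one(int code, double B0, double R0, double hb,
                            double hr, double P, int max_steps,
                            bool interpolate) {
  double b = (code == 1) ? 100.0 / (B0 * R0) : 100.0 / std::max(B0, R0);
  double r = b * P;
  double B = B0, R = R0, cb = 0.0, cr = 0.0;
  int t = 0;
  int term = 3;
  while (t < max_steps) {
    double lb, lr;
    losses(code, B, R, b, r, t, lb, lr);
    if (lb > B) lb = B;
    if (lr > R) lr = R;
    if (lb <= 0.0 && lr <= 0.0) { term = 2; break; }
    if (cb + lb >= hb || cr + lr >= hr) {
      ++t;
      if (interpolate) {
        double fb = (lb > 0.0 && cb + lb >= hb) ? (hb - cb) / lb : R_PosInf;
        double fr = (lr > 0.0 && cr + lr >= hr) ? (hr - cr) / lr : R_PosInf;
        double frac = std::min(fb, fr);
        if (frac < 0.0) frac = 0.0;
        cb += frac * lb;
        cr += frac * lr;
      } else {
        cb += lb;
        cr += lr;
      }
      term = 1;
      break;
    }
    B -= lb; R -= lr;
    cb += lb; cr += lr;
    ++t;
  }
  Outcome out;
  out.cas_blue = std::min(cb, B0);
  out.cas_red = std::min(cr, R0);
  out.steps = t;
  out.termination = term;
  return out;
}

// Mean-over-sides relative casualty distance with casualty-ratio
// relabeling: the lower-ratio side of the simulation is compared with the
// lower-ratio (Red) side of the canonical historical record.
static inline double battle_dist(double sim_cb, double sim_cr, double B0,
                                 double R0, double hb, double hr) {
  double sim_lo, sim_hi;
  if (sim_cr / R0 <= sim_cb / B0) {
    sim_lo = sim_cr; sim_hi = sim_cb;
  } else {
    sim_lo = sim_cb; sim_hi = sim_cr;
  }
  return 0.5 * (std::fabs(sim_hi - hb) / hb + std::fabs(sim_lo - hr) / hr);
}

// [[Rcpp::export]]
NumericVector simulate_battle_cpp(int code, double B0, double R0, double hb,
                                  double hr, double P, int max_steps,
                                  bool interpolate) {
  Outcome o = simulate_one(code, B0, R0, hb, hr, P, max_steps, interpolate);
  return NumericVector::create(o.cas_blue, o.cas_red, (double)o.steps,
                               (double)o.termination);
}

// P is an n_runs x n_battles matrix of per-battle odds-ratio draws; model
// is the per-run model code. Returns the per-run mean battle distance.
// [[Rcpp::export]]
NumericVector run_distances_cpp(IntegerVector model, NumericMatrix P,
                                NumericVector size_blue,
                                NumericVector size_red,
                                NumericVector cas_blue,
                                NumericVector cas_red, int max_steps,
                                bool interpolate) {
  int n_runs = P.nrow();
  int n_battles = P.ncol();
  if (model.size() != n_runs)
    stop("model vector length must equal nrow(P)");
  if (size_blue.size() != n_battles)
    stop("battle vectors must have length ncol(P)");
  NumericVector out(n_runs);
  for (int i = 0; i < n_runs; ++i) {
    double acc = 0.0;
    int code = model[i];
    for (int j = 0; j < n_battles; ++j) {
      Outcome o = simulate_one(code, size_blue[j], size_red[j], cas_blue[j],
                               cas_red[j], P(i, j), max_steps, interpolate);
      acc += battle_dist(o.cas_blue, o.cas_red, size_blue[j], size_red[j],
                         cas_blue[j], cas_red[j]);
    }
    out[i] = acc / n_battles;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
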