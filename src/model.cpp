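#include <Rcpp.h>
#include <cmath>
#include <random>
#include "wfpt.h"
using namespace Rcpp;

// Task codes: 0 = discriminative choice, 1 = match recognition.
// Model codes: 0 = simple, 1 = simple asymmetric, 2 = transfer,
//              3 = transfer asymmetric.
// Learning rates are always passed as a 4-vector
// (eta_c_pos, eta_c_neg, eta_o_pos, eta_o_neg); symmetric variants pass
// equal pos/neg entries, so rate selection by feedback sign is uniform.
//
// Response coding: discriminative choice 0 = left, 1 = right;
// match recognition 1 = "match", 0 = "non-match"; -1 = omission.
// Feedback coding: 1 positive, 0 negative, -1 neutral.

static inline double clamp01(double x) {
  const double e = 1e-6;
  return std::min(std::max(x, e), 1.0 - e);
}

// odds-ratio style normalisation of the two competing pair values
static inline double norm_first(double vc, double vo) {
  const double c = clamp01(vc), o = clamp01(vo);
  const double num = c * (1.0 - o);
  return num / (num + o * (1.0 - c));
}

struct TrialStep {
  double drift;     // fixed option frame: left-minus-right / match-minus-nonmatch
  double v_chosen;  // value of the chosen (presented) pair before updating
  double v_other;   // value of the other presented pair (NA in match recognition)
  double rpe;       // learning signal minus prior value (NA without feedback)
};

// One trial of the forward pass: computes the drift rate from the current
// value table, then applies the Rescorla-Wagner update for the delivered
// feedback.  V is the n_at x n_vis value table in row-major order.
static TrialStep step_trial(int task, int model, int n_at, int n_vis,
                            std::vector<double> &V,
                            int s, int vm, int vo, int side,
                            int resp, int fb,
                            double ecp, double ecn, double eop, double eon,
                            double vmod) {
  TrialStep out;
  out.v_chosen = NA_REAL;
  out.v_other = NA_REAL;
  out.rpe = NA_REAL;

  if (task == 0) { // discriminative choice: pairs (s,vm) and (s,vo)
    const double Vm = V[s * n_vis + vm], Vo = V[s * n_vis + vo];
    const double VL = (side == 0) ? Vm : Vo;
    const double VR = (side == 0) ? Vo : Vm;
    const double nl = norm_first(VL, VR);
    out.drift = (2.0 * nl - 1.0) * vmod; // nl - (1 - nl)

    if (resp >= 0) {
      const int cv = (resp == 0) ? ((side == 0) ? vm : vo)
                                 : ((side == 0) ? vo : vm);
      const int ov = (cv == vm) ? vo : vm;
      out.v_chosen = V[s * n_vis + cv];
      out.v_other = V[s * n_vis + ov];
      if (fb >= 0) {
        const double R = (double)fb;
        out.rpe = R - V[s * n_vis + cv];
        const double ec = (fb == 1) ? ecp : ecn;
        V[s * n_vis + cv] += ec * (R - V[s * n_vis + cv]);
        if (model >= 2) { // other presented pair moves toward the complement
          const double eo = (fb == 1) ? eop : eon;
          V[s * n_vis + ov] += eo * ((1.0 - R) - V[s * n_vis + ov]);
        }
      }
    }
  } else { // match recognition: single presented pair (s,vm)
    const double Vp = V[s * n_vis + vm];
    out.drift = (2.0 * Vp - 1.0) * vmod;
    out.v_chosen = Vp;
    if (resp >= 0 && fb >= 0) {
      // learning signal: 1 iff the pair was signalled as matching
      // (match response confirmed, or non-match response disconfirmed)
      const int Rp = (resp == fb) ? 1 : 0;
      out.rpe = (double)Rp - Vp;
      const double ec = (fb == 1) ? ecp : ecn;
      V[s * n_vis + vm] += ec * ((double)Rp - V[s * n_vis + vm]);
      if (model >= 2 && fb == 1) {
        // overlapping pairs move toward 0, only after positive feedback
        for (int i = 0; i < n_at; i++)
          for (int j = 0; j < n_vis; j++)
            if ((i == s || j == vm) && !(i == s && j == vm))
              V[i * n_vis + j] += eop * (0.0 - V[i * n_vis + j]);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List forward_cpp(int task, int model, int n_at, int n_vis,
                 IntegerVector at, IntegerVector vm, IntegerVector vo,
                 IntegerVector side, IntegerVector resp, IntegerVector fb,
                 NumericVector etas, double vmod) {
  const int n = at.size();
  std::vector<double> V((size_t)n_at * n_vis, 0.5);
  NumericVector drift(n), v_chosen(n), v_other(n), rpe(n);
  for (int t = 0; t < n; t++) {
    TrialStep st = step_trial(task, model, n_at, n_vis, V,
                              at[t], vm[t], vo[t], side[t], resp[t], fb[t],
                              etas[0], etas[1], etas[2], etas[3], vmod);
    drift[t] = st.drift;
    v_chosen[t] = st.v_chosen;
    v_other[t] = st.v_other;
    rpe[t] = st.rpe;
  }
  return List::create(_["drift"] = drift, _["v_chosen"] = v_chosen,
                      _["v_other"] = v_other, _["rpe"] = rpe,
                      _["v_final"] = NumericVector(V.begin(), V.end()));
}

// Negative log-likelihood of choices and reaction times under the
// reinforcement-learning diffusion model.  Values evolve over every
// feedback trial; only trials flagged in `include` (and with a response)
// contribute likelihood terms.  Upper boundary = left / match response.
// [[Rcpp::export]]
double nll_cpp(int task, int model, int n_at, int n_vis,
               IntegerVector at, IntegerVector vm, IntegerVector vo,
               IntegerVector side, IntegerVector resp, IntegerVector fb,
               LogicalVector include, NumericVector rt,
               NumericVector etas, double vmod, double a, double tau) {
  const int n = at.size();
  if (!(a > 0.0) || tau < 0.0 || !R_finite(vmod)) return R_PosInf;
  std::vector<double> V((size_t)n_at * n_vis, 0.5);
  double nll = 0.0;
  for (int t = 0; t < n; t++) {
    TrialStep st = step_trial(task, model, n_at, n_vis, V,
                              at[t], vm[t], vo[t], side[t], resp[t], fb[t],
                              etas[0], etas[1], etas[2], etas[3], vmod);
    if (!include[t] || resp[t] < 0) continue;
    const bool upper = (task == 0) ? (resp[t] == 0) : (resp[t] == 1);
    const double td = rt[t] - tau;
    double lik;
    if (td <= 0.0) {
      lik = 1e-10; // floor keeps the optimisation surface finite
    } else {
      const double vv = upper ? -st.drift : st.drift;
      lik = wfpt_lower(td, vv, a, 0.5, 1e-10);
      if (lik < 1e-300) lik = 1e-300;
    }
    nll -= std::log(lik);
  }
  return nll;
}

// Forward generative simulation of one run: diffusion responses and
// reaction times with feedback delivery (honouring scheduled reversals and
// neutral feedback for omissions) and trial-wise value updating.
// is_match: 1/0 for match recognition, ignored for discriminative choice.
// window: per-trial response deadline in seconds (omission beyond it).
// [[Rcpp::export]]
List simulate_cpp(int task, int model, int n_at, int n_vis,
                  IntegerVector at, IntegerVector vm, IntegerVector vo,
                  IntegerVector side, IntegerVector is_match,
                  IntegerVector fb_valid, NumericVector window,
                  NumericVector etas, double vmod, double a, double tau,
                  double dt, double seed) {
  const int n = at.size();
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  std::uniform_real_distribution<double> ud(0.0, 1.0);
  const double sdt = std::sqrt(dt);

  std::vector<double> V((size_t)n_at * n_vis, 0.5);
  IntegerVector resp(n), fb(n);
  NumericVector rt(n), drift(n);

  for (int t = 0; t < n; t++) {
    // drift from the current value table (no update yet)
    double v;
    if (task == 0) {
      const int s = at[t];
      const double Vm = V[s * n_vis + vm[t]], Vo = V[s * n_vis + vo[t]];
      const double VL = (side[t] == 0) ? Vm : Vo;
      const double VR = (side[t] == 0) ? Vo : Vm;
      v = (2.0 * norm_first(VL, VR) - 1.0) * vmod;
    } else {
      v = (2.0 * V[at[t] * n_vis + vm[t]] - 1.0) * vmod;
    }
    drift[t] = v;

    // first passage by Euler-Maruyama with bridge correction
    double x = 0.5 * a, td = 0.0;
    int b = -1;
    for (long step = 0; step < 100000000L; step++) {
      const double xn = x + v * dt + sdt * nd(rng);
      td += dt;
      if (xn <= 0.0) { b = 0; break; }
      if (xn >= a)   { b = 1; break; }
      const double pl = std::exp(-2.0 * x * xn / dt);
      const double pu = std::exp(-2.0 * (a - x) * (a - xn) / dt);
      const double udraw = ud(rng);
      if (udraw < pl) { b = 0; break; }
      if (udraw < pl + pu) { b = 1; break; }
      x = xn;
    }
    const double rtt = td + tau;

    int r, R;
    if (rtt > window[t]) { // omission: neutral feedback, no update
      r = -1; R = -1; rt[t] = NA_REAL;
    } else {
      r = (task == 0) ? ((b == 1) ? 0 : 1)   // upper boundary = left
                      : ((b == 1) ? 1 : 0);  // upper boundary = match
      const bool correct = (task == 0) ? (r == side[t]) : (r == is_match[t]);
      R = fb_valid[t] ? (correct ? 1 : 0) : (correct ? 0 : 1);
      rt[t] = rtt;
    }
    resp[t] = r;
    fb[t] = R;
    step_trial(task, model, n_at, n_vis, V, at[t], vm[t], vo[t], side[t],
               r, R, etas[0], etas[1], etas[2], etas[3], vmod);
  }
  return List::create(_["response"] = resp, _["rt"] = rt, _["feedback"] = fb,
                      _["drift"] = drift);
}
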