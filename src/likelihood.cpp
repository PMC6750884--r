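// Compiled likelihood for the two-stage task agent families.
//
// Mirrors the R reference path (trial_loglik + update_state) exactly;
// tests assert agreement to 1e-10. Encodings: actions L=0, R=1; states
// S1=0, S2=1. With this encoding the discriminative action index of a
// stage-2 state equals the state index, and the second press of the
// sequence starting with press a is 1-a.
//
// Full parameter layout (must match PARAM_SLOTS in R/models.R):
// 0 alpha1, 1 alpha2, 2 alpha_seq, 3 alpha_T, 4 lam, 5 beta1, 6 beta2,
// 7 w, 8 p_int, 9 b_disc, 10 eps, 11 q0, 12 t_common0

#include <Rcpp.h>
using namespace Rcpp;

static inline double tf(double x, int code) {
  switch (code) {
  case 1: return 1.0 / (1.0 + std::exp(-x));        // logit -> (0,1)
  case 2: return std::exp(x);                        // log -> (0,inf)
  case 3: return 0.5 / (1.0 + std::exp(-x));         // logit -> (0,0.5)
  default: return x;                                 // identity
  }
}

static inline void lapse_softmax2(double u0, double u1, double eps,
                                  double* p) {
  double m = u0 > u1 ? u0 : u1;
  double e0 = std::exp(u0 - m), e1 = std::exp(u1 - m);
  double s = e0 + e1;
  p[0] = (1.0 - eps) * e0 / s + eps / 2.0;
  p[1] = (1.0 - eps) * e1 / s + eps / 2.0;
}

// negative log posterior (or likelihood) of theta for one spec on a
// trial array; state resets where newsess is TRUE, aborted trials
// (a2 == NA) are skipped.
// [[Rcpp::export]]
double cpp_neg_log_post(NumericVector theta, List data, List cspec,
                        bool include_prior) {
  IntegerVector a1 = data["a1"], s2 = data["s2"], a2 = data["a2"],
    rew = data["reward"];
  LogicalVector newsess = data["newsess"];
  IntegerVector common_state = data["common_state"];  // per action
  int n = a1.size();

  bool is_flat = cspec["is_flat"], has_single = cspec["has_single"],
    has_seq = cspec["has_seq"], uses_mf = cspec["uses_mf"],
    uses_mb = cspec["uses_mb"];
  IntegerVector slot_ptr = cspec["slot_ptr"], slots = cspec["slots"],
    trans = cspec["transform"];
  NumericVector pmean = cspec["prior_mean"], psd = cspec["prior_sd"],
    fixed = cspec["fixed_full"];
  int d = theta.size();

  double par[13];
  for (int k = 0; k < 13; ++k) par[k] = fixed[k];
  double nlp = 0.0;
  for (int j = 0; j < d; ++j) {
    double nat = tf(theta[j], trans[j]);
    for (int s = slot_ptr[j]; s < slot_ptr[j + 1]; ++s) par[slots[s]] = nat;
    if (include_prior) {
      double z = (theta[j] - pmean[j]) / psd[j];
      nlp += 0.5 * z * z + std::log(psd[j]) + 0.5 * std::log(2.0 * M_PI);
    }
  }
  const double alpha1 = par[0], alpha2 = par[1], alpha_seq = par[2],
    alpha_T = par[3], lam = par[4], beta1 = par[5], beta2 = par[6],
    w = par[7], p_int = par[8], b_disc = par[9], eps = par[10],
    q0 = par[11], t_common0 = par[12];

  double Q2[2][2], Q1mf[2], T[2][2], Qseq[2], Qflat[2];
  double nll = 0.0;

  for (int i = 0; i < n; ++i) {
    if (newsess[i]) {
      for (int s = 0; s < 2; ++s)
        for (int a = 0; a < 2; ++a) Q2[s][a] = q0;
      for (int a = 0; a < 2; ++a) {
        Q1mf[a] = q0; Qseq[a] = q0; Qflat[a] = q0;
        int cs = common_state[a];
        T[a][cs] = t_common0; T[a][1 - cs] = 1.0 - t_common0;
      }
    }
    if (a2[i] == NA_INTEGER) continue;  // aborted: no likelihood, no update
    int x1 = a1[i], st = s2[i], x2 = a2[i];
    double r = (double) rew[i];

    if (is_flat) {
      double p1[2], p2[2];
      lapse_softmax2(beta1 * Qflat[0], beta1 * Qflat[1], eps, p1);
      double pa1 = p1[x1];
      Qflat[x1] += alpha1 * (0.0 - Qflat[x1]);
      lapse_softmax2(beta1 * Qflat[0], beta1 * Qflat[1], eps, p2);
      double pobs = pa1 * p2[x2];
      if (!(pobs > 0.0)) return 1e10;
      nll -= std::log(pobs);
      Qflat[x2] += alpha1 * (r - Qflat[x2]);
      continue;
    }

    // stage-1 option values: order L, R, LR, RL
    double v[4];
    int nopt = 0;
    double p1[4];
    if (has_single) {
      for (int a = 0; a < 2; ++a) {
        double vmb = 0.0;
        if (uses_mb) {
          double b0 = Q2[0][0] > Q2[0][1] ? Q2[0][0] : Q2[0][1];
          double b1 = Q2[1][0] > Q2[1][1] ? Q2[1][0] : Q2[1][1];
          vmb = T[a][0] * b0 + T[a][1] * b1;
        }
        v[nopt++] = w * vmb + (1.0 - w) * Q1mf[a];
      }
    }
    int seq_base = nopt;  // index of Qseq[0] (= sequence starting with L)
    if (has_seq) { v[nopt++] = Qseq[0]; v[nopt++] = Qseq[1]; }

    double m = v[0];
    for (int k = 1; k < nopt; ++k) if (v[k] > m) m = v[k];
    double ssum = 0.0;
    for (int k = 0; k < nopt; ++k) { p1[k] = std::exp(beta1 * v[k] - beta1 * m); ssum += p1[k]; }
    for (int k = 0; k < nopt; ++k) p1[k] = (1.0 - eps) * p1[k] / ssum + eps / nopt;

    double u0 = beta2 * Q2[st][0] + (st == 0 ? b_disc : 0.0);
    double u1 = beta2 * Q2[st][1] + (st == 1 ? b_disc : 0.0);
    double p2[2];
    lapse_softmax2(u0, u1, eps, p2);

    double pobs = 0.0, pselected = 0.0;
    if (has_single) pobs += p1[x1] * p2[x2];
    if (has_seq) {
      double pseq = p1[seq_base + x1];
      double pcomplete = pseq * (1.0 - p_int) * ((x2 == 1 - x1) ? 1.0 : 0.0);
      pselected = pcomplete + pseq * p_int * p2[x2];
      pobs += pselected;
    }
    if (!(pobs > 0.0)) return 1e10;
    nll -= std::log(pobs);
    // reward is credited to the selected option, interrupted or not
    double resp = pselected / pobs;

    // updates (pre-update stage-2 value feeds the cached stage-1 update)
    double q2_pre = Q2[st][x2];
    Q2[st][x2] += alpha2 * (r - q2_pre);
    if (uses_mf)
      Q1mf[x1] += alpha1 * (q2_pre - Q1mf[x1]) + alpha1 * lam * (r - q2_pre);
    if (uses_mb) {
      T[x1][st] += alpha_T * (1.0 - T[x1][st]);
      T[x1][1 - st] = 1.0 - T[x1][st];
    }
    if (has_seq)
      Qseq[x1] += resp * alpha_seq * (r - Qseq[x1]);
  }
  return nll + nlp;
}
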