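#include <Rcpp.h>
using namespace Rcpp;

// Session-level choice-probability engine.
//
// Computes, for every trial of a session in chronological order, the
// probability of each option in the sampling sequence being chosen, under
// any model of the family, propagating carried values across trials for
// the global / two-level / overt-only carry modes.
//
// model: 0 none, 1 H1 (+lam/s), 2 H1a (+lam^s), 3 H1b (*(1+lam/s)),
//        4 H1.1, 5 bonus (H2/H2.1 via first_bonus), 6 pruning,
//        7 saliency, 8 probabilistic bonus
// carry: 0 local, 1 global, 2 two_level, 3 overt_only
// par:   beta, lam, lam1, delta, delta_overt, gamma, beta_c
// seqm:  n_trials x max_len matrix of 1-based item indices, 0-padded;
//        sequences must not contain revisits (the R engine handles those).
// chosen: 1-based chosen item index per trial (0 if unknown), used only
//        for the overt-choice bonus.

static void softmax_row(std::vector<double>& v, double beta,
                        NumericMatrix& out, int row) {
  int n = v.size();
  double m = R_NegInf;
  for (int i = 0; i < n; ++i) { double z = beta * v[i]; if (z > m) m = z; }
  double s = 0.0;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) { e[i] = std::exp(beta * v[i] - m); s += e[i]; }
  for (int i = 0; i < n; ++i) out(row, i) = e[i] / s;
}

static inline double plogis2(double beta, double a, double b) {
  return 1.0 / (1.0 + std::exp(-beta * (a - b)));
}

// deterministic bonus updating (H2/H2.1); ties: incumbent wins
static void bonus_update(std::vector<double>& v, const std::vector<double>& r0,
                         double delta, bool first_bonus, bool winner_initial) {
  int n = v.size();
  int best = 0;
  if (first_bonus) v[0] += delta;
  for (int k = 1; k < n; ++k) {
    double a = winner_initial ? r0[k] : v[k];
    double b = winner_initial ? r0[best] : v[best];
    if (a > b) { v[k] += delta; v[best] -= delta; best = k; }
    else       { v[best] += delta; v[k] -= delta; }
  }
}

// [[Rcpp::export]]
NumericMatrix cc_engine(int model, int carry, NumericVector ratings,
                        IntegerMatrix seqm, IntegerVector len,
                        IntegerVector chosen, NumericVector par,
                        bool first_bonus, bool winner_initial) {
  const double beta = par[0], lam = par[1], lam1 = par[2], delta = par[3],
               delta_o = par[4], gamma = par[5], beta_c = par[6];
  int n_tr = seqm.nrow(), max_len = seqm.ncol();
  NumericMatrix out(n_tr, max_len);
  std::vector<double> carried(ratings.begin(), ratings.end());

  for (int t = 0; t < n_tr; ++t) {
    int n = len[t];
    std::vector<double> v0(n), r0(n);
    std::vector<int> idx(n);
    for (int k = 0; k < n; ++k) {
      idx[k] = seqm(t, k) - 1;
      v0[k] = carried[idx[k]];
      r0[k] = ratings[idx[k]];
    }
    std::vector<double> v(v0);

    switch (model) {
    case 0: break;                                         // none
    case 1: for (int k = 0; k < n; ++k) v[k] += lam / (k + 1.0); break;
    case 2: for (int k = 0; k < n; ++k) v[k] += std::pow(lam, k + 1.0); break;
    case 3: for (int k = 0; k < n; ++k) v[k] *= 1.0 + lam / (k + 1.0); break;
    case 4: for (int k = 0; k < n; ++k) v[k] += lam / (k + 1.0);
            v[0] += lam1; break;
    case 5: bonus_update(v, r0, delta, first_bonus, winner_initial); break;
    case 7: {                                              // saliency
      int best = 0;
      for (int k = 1; k < n; ++k) if (v[k] > v[best]) best = k;
      v[best] *= 1.0 + gamma;
      break;
    }
    default: break;
    }

    if (model == 6) {                                      // pruning
      std::vector<double> surv(n, 0.0);
      surv[0] = 1.0;
      for (int k = 1; k < n; ++k) {
        double pnew = 0.0;
        for (int i = 0; i < k; ++i) {
          double q = plogis2(beta, v0[k], v0[i]);
          pnew += surv[i] * q;
          surv[i] *= 1.0 - q;
        }
        surv[k] = pnew;
      }
      for (int k = 0; k < n; ++k) out(t, k) = surv[k];
    } else if (model == 8) {                               // probabilistic bonus
      int n_paths = 1 << (n - 1);
      std::vector<double> acc(n, 0.0), e(n);
      for (int m = 0; m < n_paths; ++m) {
        std::vector<double> pv(v0);
        int best = 0;
        if (first_bonus) pv[0] += delta;
        double pp = 1.0;
        for (int k = 1; k < n; ++k) {
          double pwin = plogis2(beta_c, pv[k], pv[best]);
          bool new_wins = (m >> (k - 1)) & 1;
          pp *= new_wins ? pwin : 1.0 - pwin;
          if (new_wins) { pv[k] += delta; pv[best] -= delta; best = k; }
          else          { pv[best] += delta; pv[k] -= delta; }
        }
        double mx = R_NegInf, s = 0.0;
        for (int k = 0; k < n; ++k) { double z = beta * pv[k]; if (z > mx) mx = z; }
        for (int k = 0; k < n; ++k) { e[k] = std::exp(beta * pv[k] - mx); s += e[k]; }
        for (int k = 0; k < n; ++k) acc[k] += pp * e[k] / s;
      }
      for (int k = 0; k < n; ++k) out(t, k) = acc[k];
    } else {
      softmax_row(v, beta, out, t);
    }

    // cross-trial carry-over
    if (carry == 1 && model == 5)
      for (int k = 0; k < n; ++k) carried[idx[k]] = v[k];
    if ((carry == 2 || carry == 3) && chosen[t] > 0)
      carried[chosen[t] - 1] += delta_o;
  }
  return out;
}
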