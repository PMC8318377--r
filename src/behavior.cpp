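#include <Rcpp.h>
using namespace Rcpp;

// Rescorla-Wagner forward pass over a trial sequence.
//
// trial_type: 0 = learning, 1 = generalization
// choice:     1 = M-terminal arm chosen, 0 = N-terminal arm chosen
// outcome:    1 = shock, 0 = safe, NA on generalization trials
// value_coding: 0 = safety (decision value 1 - V), 1 = literal (V)
//
// Values are shock expectancies, initialised at 0.5. Learning trials
// update only the chosen terminal's value with a prediction-error step,
// using alpha_plus when the prediction error is positive and alpha_minus
// when it is negative. Generalization trials never update values; their
// choice probabilities use values shrunk towards 0.5 by G.

static inline double option_score(double u, double beta) {
  // exp(b*u) / (exp(b*u) + exp(b*(1-u))) = logistic(b*(2u - 1))
  return 1.0 / (1.0 + std::exp(-beta * (2.0 * u - 1.0)));
}

static inline double p_choose_M(double vM, double vN, double beta, double G,
                                int trial_type, int value_coding) {
  double eM = vM, eN = vN;
  if (trial_type == 1) {
    eM = 0.5 + (vM - 0.5) * G;
    eN = 0.5 + (vN - 0.5) * G;
  }
  double uM = (value_coding == 0) ? 1.0 - eM : eM;
  double uN = (value_coding == 0) ? 1.0 - eN : eN;
  double sM = option_score(uM, beta);
  double sN = option_score(uN, beta);
  return sM / (sM + sN);
}

// [[Rcpp::export(name = ".behavior_forward")]]
List behavior_forward(IntegerVector trial_type, IntegerVector choice,
                      NumericVector outcome,
                      double alpha_plus, double alpha_minus,
                      double beta, double G, int value_coding) {
  int n = trial_type.size();
  NumericVector ll(n), pe(n), p(n);
  NumericMatrix V(n, 2);
  double vM = 0.5, vN = 0.5;
  for (int t = 0; t < n; ++t) {
    V(t, 0) = vM;
    V(t, 1) = vN;
    double pM = p_choose_M(vM, vN, beta, G, trial_type[t], value_coding);
    p[t] = pM;
    double pc = (choice[t] == 1) ? pM : 1.0 - pM;
    if (pc < 1e-12) pc = 1e-12;
    ll[t] = std::log(pc);
    if (trial_type[t] == 0) {
      double v = (choice[t] == 1) ? vM : vN;
      double delta = outcome[t] - v;
      pe[t] = delta;
      double alpha = (delta > 0) ? alpha_plus : alpha_minus;
      double vnew = v + alpha * delta;
      if (choice[t] == 1) vM = vnew; else vN = vnew;
    } else {
      pe[t] = NA_REAL;
    }
  }
  return List::create(_["ll"] = ll, _["p_M"] = p, _["V"] = V, _["pe"] = pe);
}

// [[Rcpp::export(name = ".behavior_nll")]]
double behavior_nll(IntegerVector trial_type, IntegerVector choice,
                    NumericVector outcome,
                    double alpha_plus, double alpha_minus,
                    double beta, double G, int value_coding) {
  int n = trial_type.size();
  double nll = 0.0;
  double vM = 0.5, vN = 0.5;
  for (int t = 0; t < n; ++t) {
    double pM = p_choose_M(vM, vN, beta, G, trial_type[t], value_coding);
    double pc = (choice[t] == 1) ? pM : 1.0 - pM;
    if (pc < 1e-12) pc = 1e-12;
    nll -= std::log(pc);
    if (trial_type[t] == 0) {
      double v = (choice[t] == 1) ? vM : vN;
      double delta = outcome[t] - v;
      double alpha = (delta > 0) ? alpha_plus : alpha_minus;
      double vnew = v + alpha * delta;
      if (choice[t] == 1) vM = vnew; else vN = vnew;
    }
  }
  return nll;
}

// Pointwise log-likelihood for a matrix of posterior parameter draws
// (columns: alpha_plus, alpha_minus, beta, G). Returns draws x trials.
// [[Rcpp::export(name = ".behavior_ll_draws")]]
NumericMatrix behavior_ll_draws(IntegerVector trial_type, IntegerVector choice,
                                NumericVector outcome, NumericMatrix draws,
                                int value_coding) {
  int n = trial_type.size(), d = draws.nrow();
  NumericMatrix out(d, n);
  for (int k = 0; k < d; ++k) {
    double ap = draws(k, 0), am = draws(k, 1), beta = draws(k, 2), G = draws(k, 3);
    double vM = 0.5, vN = 0.5;
    for (int t = 0; t < n; ++t) {
      double pM = p_choose_M(vM, vN, beta, G, trial_type[t], value_coding);
      double pc = (choice[t] == 1) ? pM : 1.0 - pM;
      if (pc < 1e-12) pc = 1e-12;
      out(k, t) = std::log(pc);
      if (trial_type[t] == 0) {
        double v = (choice[t] == 1) ? vM : vN;
        double delta = outcome[t] - v;
        double alpha = (delta > 0) ? ap : am;
        double vnew = v + alpha * delta;
        if (choice[t] == 1) vM = vnew; else vN = vnew;
      }
    }
  }
  return out;
}
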