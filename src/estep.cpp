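#include <Rcpp.h>
using namespace Rcpp;

// E-step of the mixture adjacent-category model over a (class x node) grid.
//
// For every respondent the joint posterior over (class g, node q) is formed
// from the class prior, the node weight and the item-response likelihood;
// the function accumulates the marginal log-likelihood, the posterior mass
// n_gq per grid cell, and the posterior-weighted response counts
// W[category, item, g, q] -- the complete-data sufficient statistics that the
// M-step and (via Fisher's identity) the score vector are computed from.
//
// delta_beta is the flattened [G, I, S] array (column-major, S = C - 1).
// y holds 0-based category codes.
// [[Rcpp::export]]
List mix_estep_cpp(IntegerMatrix y, NumericVector delta_beta,
                   NumericVector disc, NumericVector trait_sd,
                   NumericVector log_prior, NumericVector nodes,
                   NumericVector log_w, int n_categories,
                   bool want_posterior, bool want_joint) {
  const int N = y.nrow(), I = y.ncol(), G = trait_sd.size(),
            Q = nodes.size(), C = n_categories, S = C - 1;
  const int GQ = G * Q;

  // item-category log-probabilities per grid cell, laid out so that for a
  // fixed grid cell k = g + G*q the I*C block is contiguous:
  // logp[c + C*(i + I*k)]
  std::vector<double> logp((size_t)C * I * GQ);
  std::vector<double> prob((size_t)C * I * GQ);
  std::vector<double> cum(C);
  for (int q = 0; q < Q; ++q) {
    for (int g = 0; g < G; ++g) {
      const int k = g + G * q;
      const double t = trait_sd[g] * nodes[q];
      for (int i = 0; i < I; ++i) {
        const double at = disc[i] * t;
        cum[0] = 0.0;
        double mx = 0.0;
        for (int s = 0; s < S; ++s) {
          cum[s + 1] = cum[s] + delta_beta[g + G * i + G * I * s] + at;
          if (cum[s + 1] > mx) mx = cum[s + 1];
        }
        double tot = 0.0;
        for (int c = 0; c < C; ++c) tot += std::exp(cum[c] - mx);
        const double lse = mx + std::log(tot);
        double *lp = &logp[(size_t)C * (i + (size_t)I * k)];
        double *pp = &prob[(size_t)C * (i + (size_t)I * k)];
        for (int c = 0; c < C; ++c) {
          lp[c] = cum[c] - lse;
          pp[c] = std::exp(cum[c] - lse);
        }
      }
    }
  }

  // responses column-major for stride-1 access per respondent
  std::vector<int> yv((size_t)N * I);
  for (int i = 0; i < I; ++i)
    for (int v = 0; v < N; ++v) yv[(size_t)i + (size_t)I * v] = y(v, i);

  std::vector<double> prior_w(GQ);
  for (int q = 0; q < Q; ++q)
    for (int g = 0; g < G; ++g)
      prior_w[g + G * q] = log_prior[g] + log_w[q];

  NumericVector n_gq(GQ);
  NumericVector W((size_t)C * I * GQ);
  NumericMatrix post(want_posterior ? N : 0, want_posterior ? G : 0);
  NumericMatrix joint(want_joint ? N : 0, want_joint ? GQ : 0);
  NumericVector ll_i(N);
  std::vector<double> lp(GQ);
  double *Wp = REAL(W);
  double *ngq = REAL(n_gq);
  double ll = 0.0;

  for (int v = 0; v < N; ++v) {
    const int *yr = &yv[(size_t)I * v];
    double m = R_NegInf;
    for (int k = 0; k < GQ; ++k) {
      const double *lpk = &logp[(size_t)C * I * k];
      double s = prior_w[k];
      for (int i = 0; i < I; ++i) s += lpk[C * i + yr[i]];
      lp[k] = s;
      if (s > m) m = s;
    }
    double tot = 0.0;
    for (int k = 0; k < GQ; ++k) {
      const double e = std::exp(lp[k] - m);
      lp[k] = e;
      tot += e;
    }
    ll_i[v] = m + std::log(tot);
    ll += ll_i[v];
    const double inv = 1.0 / tot;
    for (int k = 0; k < GQ; ++k) {
      const double p = lp[k] * inv;
      ngq[k] += p;
      if (want_posterior) post(v, k % G) += p;
      if (want_joint) joint(v, k) = p;
      double *Wk = Wp + (size_t)C * I * k;
      for (int i = 0; i < I; ++i) Wk[C * i + yr[i]] += p;
    }
  }

  // reorder prob and W back to the documented [C, I, G, Q] array layout
  // (identical: c + C*i + C*I*(g + G*q) == c + C*(i + I*k)), nothing to do.
  List out = List::create(
    Named("loglik") = ll, Named("loglik_i") = ll_i,
    Named("n_gq") = n_gq, Named("W") = W,
    Named("prob") = NumericVector(prob.begin(), prob.end()));
  if (want_posterior) out["posterior"] = post;
  if (want_joint) out["joint"] = joint;
  return out;
}
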