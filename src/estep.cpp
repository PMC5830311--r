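#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over the flattened hidden-configuration chain.
//
// ktrans: (H x G x E) kernel array; entry (h, g, e) is the joint probability
//         of configuration h and the trial's response given its inputs and
//         the previous configuration's cross-source projection g.
// kinit:  (H x E) initial-slice kernel.
// chains: list of integer vectors of 1-based evidence-combination indices.
// gmap:   length-H 1-based projection of configurations onto cross groups.
//
// Returns total and per-chain log-likelihoods plus expected transition
// counts N (H x G x E) and initial counts N0 (H x E). A zero forward
// normalizer makes the affected chain's log-likelihood -Inf and skips its
// counts.
// [[Rcpp::export]]
List fb_estep(NumericVector ktrans, NumericVector kinit, List chains,
              IntegerVector gmap, int G, int H, int E) {
  NumericVector N((size_t)G * H * E);
  NumericVector N0((size_t)H * E);
  const double* KT = &ktrans[0];
  const double* KI = &kinit[0];
  double* Np = &N[0];
  double* N0p = &N0[0];
  int nch = chains.size();
  NumericVector ll_chain(nch);
  double ll_total = 0.0;

  std::vector<double> alpha;      // T x H scaled forward variables
  std::vector<double> ag;         // T x G group-projected forward variables
  std::vector<double> cvec;      // per-trial normalizers
  std::vector<double> beta(H), beta_prev(H), bk(G);
  std::vector<int> gm(H);
  for (int h = 0; h < H; ++h) gm[h] = gmap[h] - 1;

  for (int c = 0; c < nch; ++c) {
    IntegerVector obs = chains[c];
    int T = obs.size();
    alpha.assign((size_t)T * H, 0.0);
    ag.assign((size_t)T * G, 0.0);
    cvec.assign(T, 0.0);
    bool dead = false;

    // forward
    {
      int e = obs[0] - 1;
      const double* ki = KI + (size_t)H * e;
      double s = 0.0;
      for (int h = 0; h < H; ++h) { alpha[h] = ki[h]; s += ki[h]; }
      if (s <= 0.0) dead = true;
      else {
        cvec[0] = s;
        double inv = 1.0 / s;
        for (int h = 0; h < H; ++h) {
          alpha[h] *= inv;
          ag[gm[h]] += alpha[h];
        }
      }
    }
    for (int t = 1; t < T && !dead; ++t) {
      int e = obs[t] - 1;
      const double* kt = KT + (size_t)H * G * e;
      double* at = &alpha[(size_t)t * H];
      const double* agp = &ag[(size_t)(t - 1) * G];
      for (int g = 0; g < G; ++g) {
        double a = agp[g];
        if (a == 0.0) continue;
        const double* kg = kt + (size_t)H * g;
        for (int h = 0; h < H; ++h) at[h] += kg[h] * a;
      }
      double s = 0.0;
      for (int h = 0; h < H; ++h) s += at[h];
      if (s <= 0.0) { dead = true; break; }
      cvec[t] = s;
      double inv = 1.0 / s;
      double* agt = &ag[(size_t)t * G];
      for (int h = 0; h < H; ++h) {
        at[h] *= inv;
        agt[gm[h]] += at[h];
      }
    }
    if (dead) {
      ll_chain[c] = R_NegInf;
      ll_total = R_NegInf;
      continue;
    }
    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(cvec[t]);
    ll_chain[c] = ll;
    if (R_finite(ll_total)) ll_total += ll;

    // backward with count accumulation
    std::fill(beta.begin(), beta.end(), 1.0);
    for (int t = T - 1; t >= 1; --t) {
      int e = obs[t] - 1;
      const double* kt = KT + (size_t)H * G * e;
      const double* agp = &ag[(size_t)(t - 1) * G];
      double* Ne = Np + (size_t)H * G * e;
      double inv_c = 1.0 / cvec[t];
      for (int g = 0; g < G; ++g) {
        const double* kg = kt + (size_t)H * g;
        double* Ng = Ne + (size_t)H * g;
        double a = agp[g] * inv_c;
        double s = 0.0;
        for (int h = 0; h < H; ++h) {
          double kb = kg[h] * beta[h];
          Ng[h] += a * kb;               // xi(g, h)
          s += kb;
        }
        bk[g] = s;
      }
      for (int h = 0; h < H; ++h) beta_prev[h] = bk[gm[h]] * inv_c;
      beta.swap(beta_prev);
    }
    {
      int e = obs[0] - 1;
      double* n0 = N0p + (size_t)H * e;
      for (int h = 0; h < H; ++h) n0[h] += alpha[h] * beta[h];  // gamma at trial 1
    }
  }

  N.attr("dim") = IntegerVector::create(H, G, E);
  N0.attr("dim") = IntegerVector::create(H, E);
  return List::create(_["loglik"] = ll_total, _["ll_chain"] = ll_chain,
                      _["N"] = N, _["N0"] = N0);
}
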