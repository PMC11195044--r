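#include <Rcpp.h>
using namespace Rcpp;

// Gibbs core for one block of isoforms sharing no peptides with other blocks.
//
// Per iteration:
//   (PEP mode) eps_i ~ Bernoulli(PEP_i)            -- error indicators
//   for each retained peptide: allocate Y_i(1-eps_i) over its compatible
//     isoforms by a multinomial with weights pi_p / M_p (ratios, so the
//     unnormalized gamma representation of pi can be used directly)
//   gamma_p ~ Gamma(x_p + delta_p, 1)              -- pi = gamma / sum(gamma)
//
// Returns the post-burn-in chains of X and gamma plus the per-iteration total
// retained abundance (for the conservation identity sum_p X_p = sum_i Y_i(1-eps_i),
// which is also hard-asserted every iteration).
//
// Uses R's RNG stream: seeding with set.seed() before the call makes the
// block fully reproducible.

// [[Rcpp::export(name = ".gibbs_block")]]
List gibbs_block(IntegerVector y, NumericVector pep, List psi,
                 IntegerVector m, NumericVector delta,
                 int iterations, int burn_in, bool pep_mode) {
  const int n = y.size();
  const int P = delta.size();
  const int keep = iterations - burn_in;
  if (keep < 1) stop("iterations must exceed burn_in");

  std::vector< std::vector<int> > psiv(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = psi[i];  // 0-based indices into this block's proteins
    psiv[i] = as< std::vector<int> >(s);
    if (psiv[i].empty()) stop("peptide with empty protein set");
  }

  IntegerMatrix x_chain(keep, P);
  NumericMatrix g_chain(keep, P);
  IntegerVector kept_total(keep);

  std::vector<double> gam(P), w;
  std::vector<int> x(P), draw;

  for (int p = 0; p < P; ++p) {
    if (delta[p] <= 0.0) stop("Dirichlet hyper-parameters must be positive");
    gam[p] = R::rgamma(delta[p], 1.0);  // pi initialized from the prior
  }

  for (int it = 0; it < iterations; ++it) {
    std::fill(x.begin(), x.end(), 0);
    long tot = 0;
    for (int i = 0; i < n; ++i) {
      int yi = y[i];
      if (pep_mode && pep[i] > 0.0) {
        if (R::unif_rand() < pep[i]) yi = 0;  // sampled as mistakenly detected
      }
      if (yi == 0) continue;
      tot += yi;
      const std::vector<int>& s = psiv[i];
      const int k = (int) s.size();
      if (k == 1) { x[s[0]] += yi; continue; }
      w.assign(k, 0.0);
      double sw = 0.0;
      for (int j = 0; j < k; ++j) { w[j] = gam[s[j]] / m[s[j]]; sw += w[j]; }
      if (sw <= 0.0) {  // all weights numerically zero: uniform fallback
        for (int j = 0; j < k; ++j) w[j] = 1.0;
        sw = (double) k;
      }
      for (int j = 0; j < k; ++j) w[j] /= sw;
      draw.assign(k, 0);
      rmultinom(yi, w.data(), k, draw.data());
      for (int j = 0; j < k; ++j) x[s[j]] += draw[j];
    }

    long sx = 0;
    for (int p = 0; p < P; ++p) sx += x[p];
    if (sx != tot) stop("internal error: allocation broke abundance conservation");

    for (int p = 0; p < P; ++p) gam[p] = R::rgamma(x[p] + delta[p], 1.0);

    if (it >= burn_in) {
      const int r = it - burn_in;
      for (int p = 0; p < P; ++p) {
        x_chain(r, p) = x[p];
        g_chain(r, p) = gam[p];
      }
      kept_total[r] = (int) tot;
    }
  }

  return List::create(_["x"] = x_chain, _["gamma"] = g_chain,
                      _["kept"] = kept_total);
}
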