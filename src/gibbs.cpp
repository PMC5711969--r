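#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the autologistic model on a 4-neighbour lattice.
//
// alpha: per-pixel unary coefficients (any centred adjustment has already
// been folded in by the caller), lambda >= 0, coding values {L, H}.
// Conditional log-odds of the high class at pixel (i,j):
//   (H - L) * (alpha(i,j) + lambda * sum of neighbour values).
//
// Sweep schemes: chequerboard (two-colour; valid since the lattice is
// bipartite) or raster (column-major sequential). Marginals are estimated
// either as the running mean of each pixel's conditional probability at
// the moment it is updated (Rao-Blackwellised) or as the mean of the
// sampled indicators.
//
// Uses R's RNG so set.seed() upstream controls reproducibility.

// [[Rcpp::export]]
List gibbs_run_cpp(NumericMatrix alpha, double lambda, double L, double H,
                   int burnin, int retained, bool checkerboard,
                   bool rao_blackwell) {
  const int nr = alpha.nrow(), nc = alpha.ncol();
  const int n = nr * nc;
  const double span = H - L;
  const double sl = span * lambda;
  NumericMatrix zm(nr, nc), accm(nr, nc);
  double* z = zm.begin();
  double* acc = accm.begin();

  // premultiplied unary part of the conditional logit
  std::vector<double> sa(n);
  {
    const double* a = alpha.begin();
    for (int k = 0; k < n; ++k) sa[k] = span * a[k];
  }

  // initial state: independent draw from the lambda = 0 model
  for (int k = 0; k < n; ++k)
    z[k] = (unif_rand() < 1.0 / (1.0 + std::exp(-sa[k]))) ? H : L;

  const int total = burnin + retained;
  for (int sweep = 0; sweep < total; ++sweep) {
    const bool keep = sweep >= burnin;
    const int colour_passes = checkerboard ? 2 : 1;
    for (int colour = 0; colour < colour_passes; ++colour) {
      for (int j = 0; j < nc; ++j) {
        const int base = j * nr;
        const int i0 = checkerboard ? (j + colour) % 2 : 0;
        const int step = checkerboard ? 2 : 1;
        for (int i = i0; i < nr; i += step) {
          const int k = base + i;
          double s = 0.0;
          if (i > 0)      s += z[k - 1];
          if (i < nr - 1) s += z[k + 1];
          if (j > 0)      s += z[k - nr];
          if (j < nc - 1) s += z[k + nr];
          const double p = 1.0 / (1.0 + std::exp(-(sa[k] + sl * s)));
          z[k] = (unif_rand() < p) ? H : L;
          if (keep && rao_blackwell) acc[k] += p;
        }
      }
    }
    if (keep && !rao_blackwell) {
      for (int k = 0; k < n; ++k)
        if (z[k] == H) acc[k] += 1.0;
    }
  }

  if (retained > 0) {
    const double inv = 1.0 / retained;
    for (int k = 0; k < n; ++k) acc[k] *= inv;
  }
  return List::create(_["marginal"] = accm, _["state"] = zm);
}
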