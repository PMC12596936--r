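// Fast kernel for the null-model replicate loop: given the coordinate matrix
// and one row-index matrix per simulated fraction (one row per replicate),
// computes per replicate the weighted centroid of the reference fraction,
// both fractions' D statistics against it, and the pairwise E-distance.
// Weights must be normalized to sum to 1 within each fraction (uniform
// weights reproduce the unweighted statistics). The R-level dispersion_d()
// and e_distance() are the independent reference implementations.

#include <Rcpp.h>
using namespace Rcpp;

static inline double pt_dist(const NumericMatrix& x, int a, int b, int p) {
  double acc = 0.0;
  for (int d = 0; d < p; ++d) {
    double t = x(a, d) - x(b, d);
    acc += t * t;
  }
  return std::sqrt(acc);
}

// [[Rcpp::export]]
List null_stats_cpp(NumericMatrix coords, IntegerMatrix ridx,
                    IntegerMatrix cidx, NumericVector wr, NumericVector wc) {
  const int nsim = ridx.nrow(), nr = ridx.ncol(), nc = cidx.ncol(),
            p = coords.ncol();
  NumericVector d_ref(nsim), d_cmp(nsim), e(nsim);
  std::vector<double> mu(p);
  for (int s = 0; s < nsim; ++s) {
    for (int d = 0; d < p; ++d) mu[d] = 0.0;
    for (int i = 0; i < nr; ++i) {
      const int row = ridx(s, i) - 1;
      for (int d = 0; d < p; ++d) mu[d] += wr[i] * coords(row, d);
    }
    double dr = 0.0;
    for (int i = 0; i < nr; ++i) {
      const int row = ridx(s, i) - 1;
      double acc = 0.0;
      for (int d = 0; d < p; ++d) {
        const double t = coords(row, d) - mu[d];
        acc += t * t;
      }
      dr += wr[i] * std::sqrt(acc);
    }
    d_ref[s] = dr;
    double dc = 0.0;
    for (int j = 0; j < nc; ++j) {
      const int row = cidx(s, j) - 1;
      double acc = 0.0;
      for (int d = 0; d < p; ++d) {
        const double t = coords(row, d) - mu[d];
        acc += t * t;
      }
      dc += wc[j] * std::sqrt(acc);
    }
    d_cmp[s] = dc;
    double exy = 0.0, exx = 0.0, eyy = 0.0;
    for (int i = 0; i < nr; ++i) {
      const int ri = ridx(s, i) - 1;
      for (int j = 0; j < nc; ++j) {
        exy += wr[i] * wc[j] * pt_dist(coords, ri, cidx(s, j) - 1, p);
      }
    }
    for (int i = 0; i < nr; ++i) {
      for (int j = i + 1; j < nr; ++j) {
        exx += 2.0 * wr[i] * wr[j] *
          pt_dist(coords, ridx(s, i) - 1, ridx(s, j) - 1, p);
      }
    }
    for (int i = 0; i < nc; ++i) {
      for (int j = i + 1; j < nc; ++j) {
        eyy += 2.0 * wc[i] * wc[j] *
          pt_dist(coords, cidx(s, i) - 1, cidx(s, j) - 1, p);
      }
    }
    e[s] = std::max(2.0 * exy - exx - eyy, 0.0);
  }
  return List::create(_["d_ref"] = d_ref, _["d_cmp"] = d_cmp, _["e"] = e);
}
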