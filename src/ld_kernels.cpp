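#include <Rcpp.h>
using namespace Rcpp;

// Columns of X are standardized dosage vectors in genomic order, scaled to
// unit norm, so the correlation of two SNPs is the plain dot product.
static inline double dot_cols(const NumericMatrix& X, int a, int b) {
  const int n = X.nrow();
  const double* pa = &X(0, a);
  const double* pb = &X(0, b);
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += pa[i] * pb[i];
  return s;
}

// Greedy clumping. ord: 0-based genomic-order indices sorted by ascending
// p-value. Returns absorbed_by: for each SNP (genomic order), the 0-based
// genomic index of the index SNP that absorbed it, -1 for index SNPs.
// [[Rcpp::export(name = ".clump_kernel")]]
IntegerVector clump_kernel(const NumericMatrix& X,
                           const IntegerVector& chrom,
                           const NumericVector& pos,
                           const IntegerVector& ord,
                           double r2_max, double window_bp) {
  const int p = X.ncol();
  IntegerVector absorbed_by(p, -2);  // -2 = not yet visited
  for (int k = 0; k < p; ++k) {
    const int i = ord[k];
    if (absorbed_by[i] != -2) continue;
    absorbed_by[i] = -1;
    int lo = i, hi = i;
    while (lo > 0 && chrom[lo - 1] == chrom[i] &&
           pos[i] - pos[lo - 1] <= window_bp) --lo;
    while (hi < p - 1 && chrom[hi + 1] == chrom[i] &&
           pos[hi + 1] - pos[i] <= window_bp) ++hi;
    for (int j = lo; j <= hi; ++j) {
      if (absorbed_by[j] != -2) continue;
      const double r = dot_cols(X, i, j);
      if (r * r >= r2_max) absorbed_by[j] = i;
    }
  }
  return absorbed_by;
}

// LD-buddy counts: SNPs within window_bp whose r^2 >= r2_min.
// [[Rcpp::export(name = ".buddies_kernel")]]
IntegerVector buddies_kernel(const NumericMatrix& X,
                             const IntegerVector& chrom,
                             const NumericVector& pos,
                             double r2_min, double window_bp) {
  const int p = X.ncol();
  IntegerVector out(p, 0);
  for (int i = 0; i < p; ++i) {
    // count forward pairs only; add to both ends
    for (int j = i + 1; j < p; ++j) {
      if (chrom[j] != chrom[i] || pos[j] - pos[i] > window_bp) break;
      const double r = dot_cols(X, i, j);
      if (r * r >= r2_min) { ++out[i]; ++out[j]; }
    }
  }
  return out;
}

// Sliding-window greedy LD thinning: keep a SNP unless its r^2 with an
// already-kept SNP among the previous `window` SNPs reaches r2_max.
// [[Rcpp::export(name = ".thin_kernel")]]
LogicalVector thin_kernel(const NumericMatrix& X,
                          const IntegerVector& chrom,
                          int window, double r2_max) {
  const int p = X.ncol();
  LogicalVector keep(p, false);
  std::vector<int> kept;
  for (int j = 0; j < p; ++j) {
    bool ok = true;
    for (auto it = kept.rbegin(); it != kept.rend(); ++it) {
      if (*it < j - window) break;
      if (chrom[*it] != chrom[j]) continue;
      const double r = dot_cols(X, *it, j);
      if (r * r >= r2_max) { ok = false; break; }
    }
    if (ok) {
      keep[j] = true;
      kept.push_back(j);
    }
  }
  return keep;
}
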