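#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) recursive inbreeding coefficients.
// sire/dam are 1-based indices into a pedigree sorted so parents precede
// offspring; 0 marks an unknown parent. Unknown parents enter the
// within-family (Mendelian sampling) variance with F = -1, which yields
// d = 1 for founders and d = 0.75 - 0.25 F_known for one known parent.
// [[Rcpp::export]]
NumericVector inbreeding_ml_cpp(const IntegerVector& sire,
                                const IntegerVector& dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> d(n), L(n, 0.0);
  for (int i = 0; i < n; i++) {
    const int s = sire[i] - 1, m = dam[i] - 1;
    const double Fs = s >= 0 ? F[s] : -1.0;
    const double Fd = m >= 0 ? F[m] : -1.0;
    d[i] = 0.5 - 0.25 * (Fs + Fd);
    if (s < 0 || m < 0) { F[i] = 0.0; continue; }
    // back-trace the ancestor tree of i, accumulating A_ii = sum L_j^2 d_j
    double aii = 0.0;
    L[i] = 1.0;
    for (int j = i; j >= 0; j--) {
      const double lj = L[j];
      if (lj == 0.0) continue;
      aii += lj * lj * d[j];
      const int js = sire[j] - 1, jm = dam[j] - 1;
      if (js >= 0) L[js] += 0.5 * lj;
      if (jm >= 0) L[jm] += 0.5 * lj;
      L[j] = 0.0;
    }
    F[i] = aii - 1.0;
  }
  return F;
}
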