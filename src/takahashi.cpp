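#include <Rcpp.h>
using namespace Rcpp;

// Selected inversion (Takahashi equations) for a sparse LDL' factorization.
//
// Given the unit lower-triangular factor L (CSC arrays Lp, Li, Lx with the
// unit diagonal stored) and the diagonal D of A = L D L', computes the
// entries of Z = A^{-1} on the sparsity pattern of L.  The pattern of L is
// closed under elimination (if L[i,j] and L[k,j] are nonzero with i > k > j
// then (i,k) is in the pattern), so every entry the recursion touches is
// stored.  Columns are processed from right to left:
//
//   Z[i,j] = (i==j)/d_j - sum_{k in struct(L[,j]), k>j} L[k,j] * Z[max(i,k), min(i,k)]
//
// The inner sums are accumulated by walking whole stored columns of Z with
// dense scatter workspaces (no searching): for a pair a < b, both in
// struct(L[,j]), the shared entry Z[b,a] lives in column a and contributes
// L[b,j]*Z[b,a] to Z[a,j] and L[a,j]*Z[b,a] to Z[b,j].
// Cost is O(sum_c |col c| * |row c|), the same order as the numeric
// factorization, which is what makes exact REML traces and prediction-error
// variances affordable on pedigree-sized systems.

// [[Rcpp::export(name = ".takahashi_ldl")]]
NumericVector takahashi_ldl(IntegerVector Lp, IntegerVector Li,
                            NumericVector Lx, NumericVector d) {
  const int n = Lp.size() - 1;
  NumericVector Zx(Lx.size());
  std::vector<double> mult(n, 0.0); // L[r,j] scattered for r in struct(j)
  std::vector<double> acc(n, 0.0);  // accumulators for Z[.,j]
  std::vector<char> inj(n, 0);      // membership of struct(j)
  for (int j = n - 1; j >= 0; --j) {
    const int p0 = Lp[j], p1 = Lp[j + 1];
    for (int p = p0; p < p1; ++p) {
      const int r = Li[p];
      mult[r] = Lx[p];
      inj[r] = 1;
      acc[r] = 0.0;
    }
    // walk columns c in struct(j), c > j (skip the diagonal at p0)
    for (int p = p0 + 1; p < p1; ++p) {
      const int c = Li[p];
      const double Lcj = Lx[p]; // == mult[c]
      for (int q = Lp[c]; q < Lp[c + 1]; ++q) {
        const int r = Li[q];
        if (!inj[r]) continue;
        const double zrc = Zx[q];
        acc[r] -= Lcj * zrc;            // term L[c,j] * Z[r,c] for Z[r,j]
        if (r != c)
          acc[c] -= mult[r] * zrc;      // term L[r,j] * Z[r,c] for Z[c,j]
      }
    }
    for (int p = p0 + 1; p < p1; ++p) Zx[p] = acc[Li[p]];
    // diagonal last: needs the freshly stored entries of column j
    double zjj = 1.0 / d[j];
    for (int p = p0 + 1; p < p1; ++p) zjj -= Lx[p] * Zx[p];
    Zx[p0] = zjj;
    for (int p = p0; p < p1; ++p) { mult[Li[p]] = 0.0; inj[Li[p]] = 0; }
  }
  return Zx;
}

// [[Rcpp::export(name = ".sp_lookup_sym")]]
NumericVector sp_lookup_sym(IntegerVector Lp, IntegerVector Li,
                            NumericVector Zx, IntegerVector ri,
                            IntegerVector ci) {
  // look up Z[max(r,c), min(r,c)] for 0-based index pairs
  const int m = ri.size();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    int i = ri[t], j = ci[t];
    if (i < j) { int tmp = i; i = j; j = tmp; }
    int lo = Lp[j], hi = Lp[j + 1] - 1;
    double v = 0.0;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      int r = Li[mid];
      if (r == i) { v = Zx[mid]; break; }
      if (r < i) lo = mid + 1; else hi = mid - 1;
    }
    out[t] = v;
  }
  return out;
}
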