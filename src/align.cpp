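#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of a residue-coded sequence against the
// match columns of a position-specific scoring profile with affine gap
// penalties. Emission scores are log-odds in bits; the local floor makes
// the returned score non-negative.
//
// S:   emission matrix, rows = residue codes (last row is the catch-all
//      'X'/unknown row, typically all zeros), cols = profile match columns.
// seq: 1-based row indices into S.
// Also reports the number of profile columns consumed by the best-scoring
// local path (for bits-per-column normalisation).
// [[Rcpp::export]]
List profile_local_align(NumericMatrix S, IntegerVector seq,
                         double gap_open, double gap_extend) {
  const int C = S.ncol();
  const int L = seq.size();
  const double NEG = -1e18;

  NumericMatrix M(L + 1, C + 1), Ix(L + 1, C + 1), Iy(L + 1, C + 1);
  IntegerMatrix cM(L + 1, C + 1), cIx(L + 1, C + 1), cIy(L + 1, C + 1);
  for (int j = 0; j <= C; ++j) { Ix(0, j) = NEG; Iy(0, j) = NEG; }
  for (int i = 0; i <= L; ++i) { Ix(i, 0) = NEG; Iy(i, 0) = NEG; }

  double best = 0.0;
  int best_cols = 0;
  for (int i = 1; i <= L; ++i) {
    const int code = seq[i - 1] - 1;
    for (int j = 1; j <= C; ++j) {
      const double s = S(code, j - 1);
      // match state: fresh local start scores 0
      double m0 = 0.0; int c0 = 0;
      if (M(i - 1, j - 1) > m0)  { m0 = M(i - 1, j - 1);  c0 = cM(i - 1, j - 1); }
      if (Ix(i - 1, j - 1) > m0) { m0 = Ix(i - 1, j - 1); c0 = cIx(i - 1, j - 1); }
      if (Iy(i - 1, j - 1) > m0) { m0 = Iy(i - 1, j - 1); c0 = cIy(i - 1, j - 1); }
      M(i, j) = m0 + s;
      cM(i, j) = c0 + 1;
      // Ix: profile column j skipped over (deletion in the sequence)
      const double a = M(i, j - 1) - gap_open;
      const double b = Ix(i, j - 1) - gap_extend;
      if (a >= b) { Ix(i, j) = a; cIx(i, j) = cM(i, j - 1) + 1; }
      else        { Ix(i, j) = b; cIx(i, j) = cIx(i, j - 1) + 1; }
      // Iy: sequence residue i unaligned (insertion relative to profile)
      const double p = M(i - 1, j) - gap_open;
      const double q = Iy(i - 1, j) - gap_extend;
      if (p >= q) { Iy(i, j) = p; cIy(i, j) = cM(i - 1, j); }
      else        { Iy(i, j) = q; cIy(i, j) = cIy(i - 1, j); }
      if (M(i, j) > best) { best = M(i, j); best_cols = cM(i, j); }
    }
  }
  return List::create(_["score"] = best, _["columns"] = best_cols);
}
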