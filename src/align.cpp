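#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Global pairwise alignment with affine gaps (Gotoh): a gap of length k
// costs open + k * ext (open, ext passed as positive magnitudes).
// a, b: 0-based residue codes. Returns aligned code vectors with -1 = gap.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double open, double ext) {
  int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: gap in b (a[i] over '-'), Y: gap in a
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = -open - i * ext;
  for (int j = 1; j <= m; ++j) Y(0, j) = -open - j * ext;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(a[i - 1], b[j - 1]);
      double d = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = d + s;
      X(i, j) = std::max(M(i - 1, j) - open - ext,
                std::max(X(i - 1, j) - ext, Y(i - 1, j) - open - ext));
      Y(i, j) = std::max(M(i, j - 1) - open - ext,
                std::max(Y(i, j - 1) - ext, X(i, j - 1) - open - ext));
    }
  }
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  // traceback
  std::vector<int> ra, rb;
  int i = n, j = m;
  char state = (best == M(n, m)) ? 'M' : (best == X(n, m)) ? 'X' : 'Y';
  while (i > 0 || j > 0) {
    if (state == 'M') {
      double s = S(a[i - 1], b[j - 1]);
      double prev = M(i, j) - s;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (prev == M(i, j)) state = 'M';
      else if (prev == X(i, j)) state = 'X';
      else state = 'Y';
      if (i == 0 && j == 0) break;
    } else if (state == 'X') {
      double v = X(i, j);
      ra.push_back(a[i - 1]); rb.push_back(-1);
      if (v == M(i - 1, j) - open - ext) state = 'M';
      else if (v == X(i - 1, j) - ext) state = 'X';
      else state = 'Y';
      --i;
    } else {
      double v = Y(i, j);
      ra.push_back(-1); rb.push_back(b[j - 1]);
      if (v == M(i, j - 1) - open - ext) state = 'M';
      else if (v == Y(i, j - 1) - ext) state = 'Y';
      else state = 'X';
      --j;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && state != 'Y') state = 'Y';
    if (j == 0 && state != 'X') state = 'X';
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best,
                      _["aligned_a"] = IntegerVector(ra.begin(), ra.end()),
                      _["aligned_b"] = IntegerVector(rb.begin(), rb.end()));
}

// Profile-profile global alignment with affine gaps at the profile level.
// A, B: alignments as integer matrices (rows = sequences, cols = columns),
// codes 0..19 residues, 20 = gap. Column-column score = mean pairwise
// substitution score over residue pairs (pairs involving an existing gap
// contribute 0). Returns the merged alignment (rows of A then rows of B).
// [[Rcpp::export(name = ".profile_align_cpp")]]
IntegerMatrix profile_align_cpp(IntegerMatrix A, IntegerMatrix B,
                                NumericMatrix S, double open, double ext) {
  int nA = A.nrow(), nB = B.nrow(), La = A.ncol(), Lb = B.ncol();
  // residue frequency profiles (over 20 residues; gaps drop out)
  NumericMatrix fA(20, La), fB(20, Lb);
  for (int c = 0; c < La; ++c)
    for (int r = 0; r < nA; ++r) if (A(r, c) < 20) fA(A(r, c), c) += 1.0 / nA;
  for (int c = 0; c < Lb; ++c)
    for (int r = 0; r < nB; ++r) if (B(r, c) < 20) fB(B(r, c), c) += 1.0 / nB;
  // premultiply: vA[.,c] = S %*% fA[,c]
  NumericMatrix vA(20, La);
  for (int c = 0; c < La; ++c)
    for (int r = 0; r < 20; ++r) {
      double acc = 0.0;
      for (int s = 0; s < 20; ++s) acc += S(r, s) * fA(s, c);
      vA(r, c) = acc;
    }
  NumericMatrix M(La + 1, Lb + 1), X(La + 1, Lb + 1), Y(La + 1, Lb + 1);
  for (int i = 0; i <= La; ++i)
    for (int j = 0; j <= Lb; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= La; ++i) X(i, 0) = -open - i * ext;
  for (int j = 1; j <= Lb; ++j) Y(0, j) = -open - j * ext;
  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      double s = 0.0;
      for (int r = 0; r < 20; ++r) s += vA(r, i - 1) * fB(r, j - 1);
      double d = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = d + s;
      X(i, j) = std::max(M(i - 1, j) - open - ext,
                std::max(X(i - 1, j) - ext, Y(i - 1, j) - open - ext));
      Y(i, j) = std::max(M(i, j - 1) - open - ext,
                std::max(Y(i, j - 1) - ext, X(i, j - 1) - open - ext));
    }
  }
  double best = std::max(M(La, Lb), std::max(X(La, Lb), Y(La, Lb)));
  // traceback into column operations: 0 = both, 1 = A col + gap in B, 2 = gap in A + B col
  std::vector<int> ops;
  int i = La, j = Lb;
  char state = (best == M(La, Lb)) ? 'M' : (best == X(La, Lb)) ? 'X' : 'Y';
  while (i > 0 || j > 0) {
    if (state == 'M') {
      double s = 0.0;
      for (int r = 0; r < 20; ++r) s += vA(r, i - 1) * fB(r, j - 1);
      double prev = M(i, j) - s;
      ops.push_back(0); --i; --j;
      if (prev == M(i, j)) state = 'M';
      else if (prev == X(i, j)) state = 'X';
      else state = 'Y';
      if (i == 0 && j == 0) break;
    } else if (state == 'X') {
      double v = X(i, j);
      ops.push_back(1);
      if (v == M(i - 1, j) - open - ext) state = 'M';
      else if (v == X(i - 1, j) - ext) state = 'X';
      else state = 'Y';
      --i;
    } else {
      double v = Y(i, j);
      ops.push_back(2);
      if (v == M(i, j - 1) - open - ext) state = 'M';
      else if (v == Y(i, j - 1) - ext) state = 'Y';
      else state = 'X';
      --j;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && state != 'Y') state = 'Y';
    if (j == 0 && state != 'X') state = 'X';
  }
  std::reverse(ops.begin(), ops.end());
  int L = ops.size();
  IntegerMatrix out(nA + nB, L);
  int ca = 0, cb = 0;
  for (int c = 0; c < L; ++c) {
    if (ops[c] == 0) {
      for (int r = 0; r < nA; ++r) out(r, c) = A(r, ca);
      for (int r = 0; r < nB; ++r) out(nA + r, c) = B(r, cb);
      ++ca; ++cb;
    } else if (ops[c] == 1) {
      for (int r = 0; r < nA; ++r) out(r, c) = A(r, ca);
      for (int r = 0; r < nB; ++r) out(nA + r, c) = 20;
      ++ca;
    } else {
      for (int r = 0; r < nA; ++r) out(r, c) = 20;
      for (int r = 0; r < nB; ++r) out(nA + r, c) = B(r, cb);
      ++cb;
    }
  }
  return out;
}

// Pairwise p-distances from an MSA (codes 0..19, 20 = gap), pairwise
// deletion: d = mismatches / columns where both rows are residues
// (d = 1 when no comparable column exists).
// [[Rcpp::export(name = ".msa_pdist_cpp")]]
NumericMatrix msa_pdist_cpp(IntegerMatrix msa) {
  int n = msa.nrow(), L = msa.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int comp = 0, mism = 0;
      for (int c = 0; c < L; ++c) {
        int a = msa(i, c), b = msa(j, c);
        if (a < 20 && b < 20) { ++comp; if (a != b) ++mism; }
      }
      double d = comp > 0 ? (double)mism / comp : 1.0;
      D(i, j) = d; D(j, i) = d;
    }
  }
  return D;
}
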