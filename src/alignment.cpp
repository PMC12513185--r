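#include <Rcpp.h>
using namespace Rcpp;

// Alignment DP kernels. Gap convention throughout: a run of L gap characters
// scores gap_open + (L-1)*gap_extend (both <= 0), i.e. the first character of
// a run is charged the opening score only.

static const double NEG = -1e18;

// Traceback helper shared by the two affine aligners. State machine over the
// H/E/F pointer matrices; E consumes rows (gap in b), F consumes columns.
static IntegerMatrix traceback_affine(const IntegerMatrix& PH,
                                      const IntegerMatrix& PE,
                                      const IntegerMatrix& PF,
                                      int bi, int bj, bool global) {
  std::vector<int> ia, ja;
  int i = bi, j = bj, state = 0;
  while (true) {
    if (global && i == 0 && j == 0) break;
    if (state == 0) {
      int p = PH(i, j);
      if (p == 0) break;                       // local: stop cell
      if (p == 1) { ia.push_back(i); ja.push_back(j); --i; --j; }
      else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      int p = PE(i, j); --i; if (p == 1) state = 0;
    } else {
      int p = PF(i, j); --j; if (p == 1) state = 0;
    }
  }
  int k = ia.size();
  IntegerMatrix pairs(k, 2);
  for (int t = 0; t < k; ++t) {               // reverse into ascending order
    pairs(t, 0) = ia[k - 1 - t];
    pairs(t, 1) = ja[k - 1 - t];
  }
  return pairs;
}

// Smith-Waterman local alignment with affine gaps.
// Tie-break: diagonal over up (gap in b) over left (gap in a); the start cell
// is the first maximal cell in row-major order. 'X' never matches anything.
// [[Rcpp::export]]
List sw_affine_cpp(std::string a, std::string b, double match, double mismatch,
                   double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix PH(n + 1, m + 1), PE(n + 1, m + 1), PF(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eH = H(i - 1, j) + gap_open, eE = E(i - 1, j) + gap_extend;
      if (eH >= eE) { E(i, j) = eH; PE(i, j) = 1; } else { E(i, j) = eE; PE(i, j) = 2; }
      double fH = H(i, j - 1) + gap_open, fF = F(i, j - 1) + gap_extend;
      if (fH >= fF) { F(i, j) = fH; PF(i, j) = 1; } else { F(i, j) = fF; PF(i, j) = 2; }
      double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'X') ? match : mismatch;
      double diag = H(i - 1, j - 1) + s;
      double v; int p;
      if (diag >= E(i, j) && diag >= F(i, j)) { v = diag; p = 1; }
      else if (E(i, j) >= F(i, j)) { v = E(i, j); p = 2; }
      else { v = F(i, j); p = 3; }
      if (v <= 0) { v = 0; p = 0; }
      H(i, j) = v; PH(i, j) = p;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  IntegerMatrix pairs = (best > 0)
    ? traceback_affine(PH, PE, PF, bi, bj, false)
    : IntegerMatrix(0, 2);
  return List::create(_["score"] = best, _["pairs"] = pairs);
}

// Needleman-Wunsch global alignment with the same affine-gap convention.
// [[Rcpp::export]]
List nw_affine_cpp(std::string a, std::string b, double match, double mismatch,
                   double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix PH(n + 1, m + 1), PE(n + 1, m + 1), PF(n + 1, m + 1);
  E(0, 0) = NEG; F(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    E(i, 0) = gap_open + (i - 1) * gap_extend;
    PE(i, 0) = (i == 1) ? 1 : 2;
    H(i, 0) = E(i, 0); PH(i, 0) = 2;
    F(i, 0) = NEG;
  }
  for (int j = 1; j <= m; ++j) {
    F(0, j) = gap_open + (j - 1) * gap_extend;
    PF(0, j) = (j == 1) ? 1 : 2;
    H(0, j) = F(0, j); PH(0, j) = 3;
    E(0, j) = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eH = H(i - 1, j) + gap_open, eE = E(i - 1, j) + gap_extend;
      if (eH >= eE) { E(i, j) = eH; PE(i, j) = 1; } else { E(i, j) = eE; PE(i, j) = 2; }
      double fH = H(i, j - 1) + gap_open, fF = F(i, j - 1) + gap_extend;
      if (fH >= fF) { F(i, j) = fH; PF(i, j) = 1; } else { F(i, j) = fF; PF(i, j) = 2; }
      double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'X') ? match : mismatch;
      double diag = H(i - 1, j - 1) + s;
      double v; int p;
      if (diag >= E(i, j) && diag >= F(i, j)) { v = diag; p = 1; }
      else if (E(i, j) >= F(i, j)) { v = E(i, j); p = 2; }
      else { v = F(i, j); p = 3; }
      H(i, j) = v; PH(i, j) = p;
    }
  }
  IntegerMatrix pairs = traceback_affine(PH, PE, PF, n, m, true);
  return List::create(_["score"] = H(n, m), _["pairs"] = pairs);
}

// Monotone correspondence maximizing the sum of a similarity matrix with
// zero gap penalty (used in TM-score-style refinement). Tie-break diagonal
// over up over left.
// [[Rcpp::export]]
IntegerMatrix nw_maxsim_cpp(NumericMatrix S) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) P(i, 0) = 2;
  for (int j = 1; j <= m; ++j) P(0, j) = 3;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double up = H(i - 1, j), left = H(i, j - 1);
      if (diag >= up && diag >= left) { H(i, j) = diag; P(i, j) = 1; }
      else if (up >= left) { H(i, j) = up; P(i, j) = 2; }
      else { H(i, j) = left; P(i, j) = 3; }
    }
  }
  std::vector<int> ia, ja;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p = P(i, j);
    if (p == 1) { ia.push_back(i); ja.push_back(j); --i; --j; }
    else if (p == 2) --i;
    else --j;
  }
  int k = ia.size();
  IntegerMatrix pairs(k, 2);
  for (int t = 0; t < k; ++t) {
    pairs(t, 0) = ia[k - 1 - t];
    pairs(t, 1) = ja[k - 1 - t];
  }
  return pairs;
}
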