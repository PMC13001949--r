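#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gap costs over an arbitrary
// single-character alphabet.  A gap run of length k costs open + k * extend
// (both nonnegative; subtracted from the score).  Three-state DP
// (M = match/mismatch, X = gap in b / consume a, Y = gap in a / consume b)
// with a deterministic traceback preferring, in order: diagonal, up, left.
// With free_ends, leading and trailing gap runs cost nothing (semi-global).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".cpp_align_affine")]]
List cpp_align_affine(std::string a, std::string b,
                      NumericMatrix scores, std::string alphabet,
                      double gap_open, double gap_extend,
                      bool free_ends) {
  const int n = a.size(), m = b.size();
  int lookup[256];
  for (int k = 0; k < 256; ++k) lookup[k] = -1;
  for (size_t k = 0; k < alphabet.size(); ++k)
    lookup[(unsigned char)alphabet[k]] = (int)k;
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lookup[(unsigned char)a[i]];
    if (ai[i] < 0) stop("letter '%s' not covered by the score matrix",
                        std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = lookup[(unsigned char)b[j]];
    if (bi[j] < 0) stop("letter '%s' not covered by the score matrix",
                        std::string(1, b[j]));
  }

  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // back pointers: previous state (0=M,1=X,2=Y) entering this cell's state
  std::vector<signed char> bM((n + 1) * W, -1), bX((n + 1) * W, -1),
      bY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = free_ends ? 0.0 : -(gap_open + i * gap_extend);
    bX[i * W] = 1;
  }
  bX[1 * W] = 0;
  for (int j = 1; j <= m; ++j) {
    Y[j] = free_ends ? 0.0 : -(gap_open + j * gap_extend);
    bY[j] = 2;
  }
  bY[1] = 0;

  for (int i = 1; i <= n; ++i) {
    const double srow_gap_open = gap_open + gap_extend;
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: diagonal move; tie order M, X, Y
      double best = M[d];
      signed char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = best + scores(ai[i - 1], bi[j - 1]);
      bM[c] = arg;
      // X: consume a[i-1] against a gap (vertical / "up")
      double xo = M[u] - srow_gap_open, xx = X[u] - gap_extend,
             xy = Y[u] - srow_gap_open;
      best = xo; arg = 0;
      if (xx > best) { best = xx; arg = 1; }
      if (xy > best) { best = xy; arg = 2; }
      X[c] = best; bX[c] = arg;
      // Y: consume b[j-1] against a gap (horizontal / "left")
      double yo = M[l] - srow_gap_open, yx = X[l] - srow_gap_open,
             yy = Y[l] - gap_extend;
      best = yo; arg = 0;
      if (yx > best) { best = yx; arg = 1; }
      if (yy > best) { best = yy; arg = 2; }
      Y[c] = best; bY[c] = arg;
    }
  }

  // trailing free gaps: add zero-cost tail from the best cell on the last
  // row/column to the corner
  int ei = n, ej = m;
  if (free_ends) {
    double best = NEG_INF;
    int bi_ = n, bj_ = m;
    for (int i = 0; i <= n; ++i) {
      double v = std::max(M[i * W + m], std::max(X[i * W + m], Y[i * W + m]));
      if (v > best) { best = v; bi_ = i; bj_ = m; }
    }
    for (int j = 0; j <= m; ++j) {
      double v = std::max(M[n * W + j], std::max(X[n * W + j], Y[n * W + j]));
      if (v > best) { best = v; bi_ = n; bj_ = j; }
    }
    ei = bi_; ej = bj_;
  }

  const int corner = ei * W + ej;
  double score = M[corner];
  int state = 0;
  if (X[corner] > score) { score = X[corner]; state = 1; }
  if (Y[corner] > score) { score = Y[corner]; state = 2; }

  std::string ra, rb;
  // free trailing tail
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 && j == 0) break;
      signed char prev = bM[i * W + j];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      signed char prev = bX[i * W + j];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      state = prev;
    } else {
      signed char prev = bY[i * W + j];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}

// Same three-state DP over a precomputed column-pair score matrix S
// (n x m): aligns "columns" 1..n of one profile with 1..m of another.
// Returns the aligned column index paths (0 = gap) and the score.
// [[Rcpp::export(name = ".cpp_align_profile")]]
List cpp_align_profile(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol(), W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<signed char> bM((n + 1) * W, -1), bX((n + 1) * W, -1),
      bY((n + 1) * W, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) { X[i * W] = -(gap_open + i * gap_extend); bX[i * W] = 1; }
  if (n >= 1) bX[W] = 0;
  for (int j = 1; j <= m; ++j) { Y[j] = -(gap_open + j * gap_extend); bY[j] = 2; }
  if (m >= 1) bY[1] = 0;
  const double go = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      double best = M[d]; signed char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = best + S(i - 1, j - 1); bM[c] = arg;
      double xo = M[u] - go, xx = X[u] - gap_extend, xy = Y[u] - go;
      best = xo; arg = 0;
      if (xx > best) { best = xx; arg = 1; }
      if (xy > best) { best = xy; arg = 2; }
      X[c] = best; bX[c] = arg;
      double yo = M[l] - go, yx = X[l] - go, yy = Y[l] - gap_extend;
      best = yo; arg = 0;
      if (yx > best) { best = yx; arg = 1; }
      if (yy > best) { best = yy; arg = 2; }
      Y[c] = best; bY[c] = arg;
    }
  }
  const int corner = n * W + m;
  double score = M[corner];
  int state = 0;
  if (X[corner] > score) { score = X[corner]; state = 1; }
  if (Y[corner] > score) { score = Y[corner]; state = 2; }
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char prev = bM[i * W + j];
      pa.push_back(i); pb.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      signed char prev = bX[i * W + j];
      pa.push_back(i); pb.push_back(0); --i; state = prev;
    } else {
      signed char prev = bY[i * W + j];
      pa.push_back(0); pb.push_back(j); --j; state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["ia"] = IntegerVector(pa.begin(), pa.end()),
                      _["ib"] = IntegerVector(pb.begin(), pb.end()),
                      _["score"] = score);
}
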