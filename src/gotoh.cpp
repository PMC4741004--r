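// Affine-gap pairwise alignment (Gotoh), global and glocal modes.
//
// Conventions (shared with the plain-R oracle in the test suite):
//   - a gap of length L costs gap_open + L * gap_extend
//   - state transitions do not allow an insertion immediately following a
//     deletion (X from {M,X}, Y from {M,Y})
//   - glocal: the whole pattern is aligned, subject prefix/suffix are free
//
// Score rows are rolled (two rows live at a time); full byte matrices keep
// only the traceback choices, so memory traffic stays low for long inputs.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const double NEG = -1e30;

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string a, std::string b,
                     NumericMatrix score_matrix, std::string alphabet,
                     double gap_open, double gap_extend, bool glocal) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  std::vector<int> lut(256, -1);
  for (int k = 0; k < (int)alphabet.size(); ++k) {
    lut[(unsigned char)alphabet[k]] = k;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("character '%s' not in scoring alphabet",
                        std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("character '%s' not in scoring alphabet",
                        std::string(1, b[j]));
  }
  const int K = score_matrix.ncol();
  std::vector<double> sm(K * K);
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < K; ++c) sm[r * K + c] = score_matrix(r, c);

  const double go = gap_open + gap_extend;
  const int W = m + 1;
  std::vector<double> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<double> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  // traceback choices: 0 = from M, 1 = from X, 2 = from Y, -1 = invalid
  std::vector<signed char> tM((size_t)(n + 1) * W, -1),
      tX((size_t)(n + 1) * W, -1), tY((size_t)(n + 1) * W, -1);

  // row 0
  Mp[0] = 0.0;
  if (glocal) {
    for (int j = 1; j <= m; ++j) Mp[j] = 0.0;
  } else {
    for (int j = 1; j <= m; ++j) {
      Yp[j] = -(gap_open + j * gap_extend);
      tY[j] = (j == 1) ? 0 : 2;
    }
  }

  double best_score = NEG;
  int best_i = n, best_j = m;
  signed char best_state = 0;

  for (int i = 1; i <= n; ++i) {
    // column 0
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = -(gap_open + i * gap_extend);
    tX[(size_t)i * W] = (i == 1) ? 0 : 1;
    const double* srow = &sm[(size_t)ai[i - 1] * K];
    const size_t base = (size_t)i * W;
    for (int j = 1; j <= m; ++j) {
      const double s = srow[bi[j - 1]];
      // M from diagonal of previous row
      double best = Mp[j - 1]; signed char tb = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; tb = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; tb = 2; }
      if (best > NEG / 2) { Mc[j] = best + s; tM[base + j] = tb; }
      else Mc[j] = NEG;
      // X: gap in b (consume a), from previous row same column
      const double xm = Mp[j] - go, xx = Xp[j] - gap_extend;
      if (xm >= xx) {
        if (xm > NEG / 2) { Xc[j] = xm; tX[base + j] = 0; } else Xc[j] = NEG;
      } else { Xc[j] = xx; tX[base + j] = 1; }
      // Y: gap in a (consume b), from same row previous column
      const double ym = Mc[j - 1] - go, yy = Yc[j - 1] - gap_extend;
      if (ym >= yy) {
        if (ym > NEG / 2) { Yc[j] = ym; tY[base + j] = 0; } else Yc[j] = NEG;
      } else { Yc[j] = yy; tY[base + j] = 2; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  // after the loop, row n lives in the "previous" buffers
  if (glocal) {
    for (int j = 0; j <= m; ++j) {
      if (Mp[j] > best_score) { best_score = Mp[j]; best_state = 0; best_j = j; }
      if (Xp[j] > best_score) { best_score = Xp[j]; best_state = 1; best_j = j; }
    }
  } else {
    best_score = Mp[m]; best_state = 0;
    if (Xp[m] > best_score) { best_score = Xp[m]; best_state = 1; }
    if (Yp[m] > best_score) { best_score = Yp[m]; best_state = 2; }
  }

  // traceback over the choice matrices
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = best_i, j = best_j;
  signed char state = best_state;
  const int sub_end = glocal ? best_j : m;
  while (i > 0 || j > 0) {
    if (glocal && i == 0) break;
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      if (i == 0 && j == 0) break;
      const signed char tb = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = tb;
    } else if (state == 1) {
      const signed char tb = tX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = tb;
    } else {
      const signed char tb = tY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = tb;
    }
  }
  const int sub_start = glocal ? (j + 1) : 1;
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = best_score,
                      _["aligned_a"] = ra,
                      _["aligned_b"] = rb,
                      _["subject_start"] = sub_start,
                      _["subject_end"] = sub_end);
}
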