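#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequences arrive as IUPAC bitmasks (A=1, C=2, G=4, T=8; ambiguity codes are
// unions). Two symbols are scored as a match when their sets intersect, so N
// matches everything. Gap cost convention: a gap run of length L costs
// gap_open + L * gap_ext.

static inline double pair_score(int a, int b, double match, double mismatch) {
  return (a & b) ? match : mismatch;
}

// Affine-gap global alignment (Gotoh three-state DP) with deterministic
// traceback: ties prefer the diagonal (substitution) state, then the
// gap-in-second state ("up"), then gap-in-first ("left"). Score rows are
// rolled (O(m) memory); per-cell traceback bytes pack the predecessor state
// of M, X and Y into one byte (2 bits each).
// [[Rcpp::export(name = ".nw_pair_cpp")]]
List nw_pair_cpp(IntegerVector a, IntegerVector b,
                 double match, double mismatch,
                 double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double gi = gap_open + gap_ext;  // cost of first gapped position

  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);  // previous row
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);  // current row
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = -(gap_open + j * gap_ext);
    tb[j] = (2u << 4);  // Y came from Y
  }

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = -(gap_open + i * gap_ext);
    unsigned char *trow = &tb[(size_t)i * (m + 1)];
    trow[0] = (1u << 2);  // X came from X
    const int ai = av[i - 1];
    for (int j = 1; j <= m; ++j) {
      double s = (ai & bv[j - 1]) ? match : mismatch;
      // M from diagonal
      double best = Mp[j - 1]; unsigned char sM = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; sM = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; sM = 2; }
      Mc[j] = best + s;
      // X from row above
      double xm = Mp[j] - gi, xx = Xp[j] - gap_ext, xy = Yp[j] - gi;
      best = xm; unsigned char sX = 0;
      if (xx > best) { best = xx; sX = 1; }
      if (xy > best) { best = xy; sX = 2; }
      Xc[j] = best;
      // Y from left
      double ym = Mc[j - 1] - gi, yx = Xc[j - 1] - gi, yy = Yc[j - 1] - gap_ext;
      best = ym; unsigned char sY = 0;
      if (yx > best) { best = yx; sY = 1; }
      if (yy > best) { best = yy; sY = 2; }
      Yc[j] = best;
      trow[j] = sM | (sX << 2) | (sY << 4);
    }
    Mp.swap(Mc); Xp.swap(Xc); Yp.swap(Yc);
  }

  double sMf = Mp[m], sXf = Xp[m], sYf = Yp[m];
  double score = sMf; int state = 0;
  if (sXf > score) { score = sXf; state = 1; }
  if (sYf > score) { score = sYf; state = 2; }

  // traceback; emit 0 where a gap sits
  std::vector<int> ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      ra.push_back(av[i - 1]); rb.push_back(bv[j - 1]);
      --i; --j; state = t & 3u;
    } else if (state == 1) {
      ra.push_back(av[i - 1]); rb.push_back(0);
      --i; state = (t >> 2) & 3u;
    } else {
      ra.push_back(0); rb.push_back(bv[j - 1]);
      --j; state = (t >> 4) & 3u;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = wrap(ra), _["b"] = wrap(rb),
                      _["score"] = score);
}

// Profile-profile global alignment for progressive MSA. Profiles are 4 x L
// matrices of base fractions (rows A,C,G,T; columns may sum to < 1 when gaps
// or ambiguities are present). Column pair score is the expected
// match/mismatch score under independent draws; affine gap costs as above.
// Returns the merge path: 0 = both advance, 1 = column from A only (gap
// inserted into B), 2 = column from B only.
// [[Rcpp::export(name = ".nw_profile_cpp")]]
IntegerVector nw_profile_cpp(NumericMatrix fa, NumericMatrix fb,
                             double match, double mismatch,
                             double gap_open, double gap_ext) {
  const int n = fa.ncol(), m = fb.ncol();
  const double NEG = -1e30;
  const double gi = gap_open + gap_ext;

  std::vector<double> ta(n), tb(m);
  for (int i = 0; i < n; ++i) {
    double s = 0; for (int k = 0; k < 4; ++k) s += fa(k, i);
    ta[i] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0; for (int k = 0; k < 4; ++k) s += fb(k, j);
    tb[j] = s;
  }

  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tMv((n + 1) * (m + 1), 0),
      tXv((n + 1) * (m + 1), 0), tYv((n + 1) * (m + 1), 0);
  #define IDX(i, j) ((i) * (m + 1) + (j))
  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) { X[IDX(i, 0)] = -(gap_open + i * gap_ext); tXv[IDX(i, 0)] = 1; }
  for (int j = 1; j <= m; ++j) { Y[IDX(0, j)] = -(gap_open + j * gap_ext); tYv[IDX(0, j)] = 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double same = 0;
      for (int k = 0; k < 4; ++k) same += fa(k, i - 1) * fb(k, j - 1);
      double s = match * same + mismatch * (ta[i - 1] * tb[j - 1] - same);

      double dm = M[IDX(i - 1, j - 1)], dx = X[IDX(i - 1, j - 1)], dy = Y[IDX(i - 1, j - 1)];
      double best = dm; unsigned char tbk = 0;
      if (dx > best) { best = dx; tbk = 1; }
      if (dy > best) { best = dy; tbk = 2; }
      M[IDX(i, j)] = best + s; tMv[IDX(i, j)] = tbk;

      double xm = M[IDX(i - 1, j)] - gi, xx = X[IDX(i - 1, j)] - gap_ext,
             xy = Y[IDX(i - 1, j)] - gi;
      best = xm; tbk = 0;
      if (xx > best) { best = xx; tbk = 1; }
      if (xy > best) { best = xy; tbk = 2; }
      X[IDX(i, j)] = best; tXv[IDX(i, j)] = tbk;

      double ym = M[IDX(i, j - 1)] - gi, yx = X[IDX(i, j - 1)] - gi,
             yy = Y[IDX(i, j - 1)] - gap_ext;
      best = ym; tbk = 0;
      if (yx > best) { best = yx; tbk = 1; }
      if (yy > best) { best = yy; tbk = 2; }
      Y[IDX(i, j)] = best; tYv[IDX(i, j)] = tbk;
    }
  }

  double sM = M[IDX(n, m)], sX = X[IDX(n, m)], sY = Y[IDX(n, m)];
  int state = 0; double sc = sM;
  if (sX > sc) { sc = sX; state = 1; }
  if (sY > sc) { sc = sY; state = 2; }

  std::vector<int> path;
  path.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) { int p = tMv[IDX(i, j)]; path.push_back(0); --i; --j; state = p; }
    else if (state == 1) { int p = tXv[IDX(i, j)]; path.push_back(1); --i; state = p; }
    else { int p = tYv[IDX(i, j)]; path.push_back(2); --j; state = p; }
  }
  std::reverse(path.begin(), path.end());
  #undef IDX
  return wrap(path);
}
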