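#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Pairwise alignment with affine gaps (Gotoh). Semi-global: end gaps may be
// declared free per direction. free_x = runs of gap characters in the second
// sequence's row at either end of the alignment (i.e. overhangs of the first
// sequence) cost nothing; free_y likewise for the second sequence.
// A gap run of length k costs gap_open + (k-1) * gap_extend.

static const double NEG_INF = -1e18;

struct SubLookup {
  int idx[256];
  const NumericMatrix *mat;
  SubLookup(const NumericMatrix &m, const CharacterVector &alpha) : mat(&m) {
    std::memset(idx, -1, sizeof(idx));
    for (int i = 0; i < alpha.size(); ++i) {
      const char *s = CHAR(STRING_ELT(alpha, i));
      idx[(unsigned char)s[0]] = i;
    }
  }
  double score(char a, char b) const {
    int ia = idx[(unsigned char)a], ib = idx[(unsigned char)b];
    if (ia < 0 || ib < 0) stop("character not in substitution alphabet");
    return (*mat)(ia, ib);
  }
};

// state codes for traceback: 0 = M (diagonal), 1 = X (gap in b, consume a),
// 2 = Y (gap in a, consume b)
// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string a, std::string b, NumericMatrix submat,
                     CharacterVector alphabet, double gap_open,
                     double gap_extend, bool free_x, bool free_y) {
  const int m = (int)a.size(), n = (int)b.size();
  SubLookup sub(submat, alphabet);
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG_INF), X((m + 1) * W, NEG_INF),
      Y((m + 1) * W, NEG_INF);
  // traceback: predecessor state for each cell/state
  std::vector<signed char> pM((m + 1) * W, -1), pX((m + 1) * W, -1),
      pY((m + 1) * W, -1);
  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    // leading X run lives in column j = 0
    double o = free_x ? 0.0 : gap_open;
    double e = free_x ? 0.0 : gap_extend;
    X[i * W] = (i == 1) ? -o : X[(i - 1) * W] - e;
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    double o = free_y ? 0.0 : gap_open;
    double e = free_y ? 0.0 : gap_extend;
    Y[j] = (j == 1) ? -o : Y[j - 1] - e;
    pY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, up = (i - 1) * W + j, lf = i * W + (j - 1),
                dg = (i - 1) * W + (j - 1);
      double s = sub.score(a[i - 1], b[j - 1]);
      double best = M[dg];
      signed char p = 0;
      if (X[dg] > best) { best = X[dg]; p = 1; }
      if (Y[dg] > best) { best = Y[dg]; p = 2; }
      M[c] = best + s;
      pM[c] = p;
      // X: consume a[i-1] against a gap; trailing free when j == n
      double ox = (free_x && j == n) ? 0.0 : gap_open;
      double ex = (free_x && j == n) ? 0.0 : gap_extend;
      double fromM = M[up] - ox, fromY = Y[up] - ox, fromX = X[up] - ex;
      if (fromM >= fromX && fromM >= fromY) { X[c] = fromM; pX[c] = 0; }
      else if (fromX >= fromY)             { X[c] = fromX; pX[c] = 1; }
      else                                 { X[c] = fromY; pX[c] = 2; }
      double oy = (free_y && i == m) ? 0.0 : gap_open;
      double ey = (free_y && i == m) ? 0.0 : gap_extend;
      double gM = M[lf] - oy, gX = X[lf] - oy, gY = Y[lf] - ey;
      if (gM >= gY && gM >= gX) { Y[c] = gM; pY[c] = 0; }
      else if (gY >= gX)        { Y[c] = gY; pY[c] = 2; }
      else                      { Y[c] = gX; pY[c] = 1; }
    }
  }
  const int end = m * W + n;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }
  // traceback
  std::string ra, rb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    int c = i * W + j;
    signed char prev;
    if (state == 0) {
      prev = pM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = pX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
    } else {
      prev = pY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
    }
    state = prev;
  }
  std::string al_a(ra.rbegin(), ra.rend()), al_b(rb.rbegin(), rb.rend());
  return List::create(_["score"] = score, _["aligned_a"] = al_a,
                      _["aligned_b"] = al_b);
}

// Exhaustive scorer over every alignment path, used as an independent check
// of the DP above. Enumerates all interleavings of consume-a / consume-b /
// consume-both moves and scores each path's gap runs directly; exponential,
// intended for strings of length <= 10.
struct Enum {
  const std::string &a, &b;
  const SubLookup &sub;
  double open, ext;
  bool free_x, free_y;
  double best;
  std::vector<char> ops;
  Enum(const std::string &a_, const std::string &b_, const SubLookup &s,
       double o, double e, bool fx, bool fy)
      : a(a_), b(b_), sub(s), open(o), ext(e), free_x(fx), free_y(fy),
        best(NEG_INF) {}
  double score_path() {
    double sc = 0.0;
    size_t i = 0, j = 0, k = 0;
    const size_t L = ops.size();
    while (k < L) {
      char op = ops[k];
      size_t run = k;
      while (run < L && ops[run] == op) ++run;
      size_t len = run - k;
      if (op == 'S') {
        for (size_t t = 0; t < len; ++t) {
          sc += sub.score(a[i], b[j]);
          ++i; ++j;
        }
      } else {
        bool terminal = (k == 0) || (run == L);
        bool free_run = terminal && ((op == 'D' && free_x) || (op == 'I' && free_y));
        if (!free_run) sc -= open + (double)(len - 1) * ext;
        if (op == 'D') i += len; else j += len;
      }
      k = run;
    }
    return sc;
  }
  void rec(size_t i, size_t j) {
    if (i == a.size() && j == b.size()) {
      double s = score_path();
      if (s > best) best = s;
      return;
    }
    if (i < a.size() && j < b.size()) {
      ops.push_back('S'); rec(i + 1, j + 1); ops.pop_back();
    }
    if (i < a.size()) { ops.push_back('D'); rec(i + 1, j); ops.pop_back(); }
    if (j < b.size()) { ops.push_back('I'); rec(i, j + 1); ops.pop_back(); }
  }
};

// [[Rcpp::export(name = ".bruteforce_align_cpp")]]
double bruteforce_align_cpp(std::string a, std::string b, NumericMatrix submat,
                            CharacterVector alphabet, double gap_open,
                            double gap_extend, bool free_x, bool free_y) {
  if (a.size() > 10 || b.size() > 10)
    stop("exhaustive alignment enumeration is limited to length 10");
  SubLookup sub(submat, alphabet);
  Enum en(a, b, sub, gap_open, gap_extend, free_x, free_y);
  if (a.empty() && b.empty()) return 0.0;
  en.rec(0, 0);
  return en.best;
}
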