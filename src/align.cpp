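#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) over integer-encoded residues.
// A gap run of length k costs gap_open + k * gap_extend.
// Tie-break during traceback: diagonal > vertical (gap in b) > horizontal
// (gap in a), both for the end state and for predecessor states, so the
// optimum returned is unique and deterministic.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = X (vertical, consume a), 2 = Y (horizontal, consume b)
static inline int best3(double m, double x, double y, double &out) {
  // preference M > X > Y on ties
  out = m; int s = 0;
  if (x > out) { out = x; s = 1; }
  if (y > out) { out = y; s = 2; }
  return s;
}

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF),
                      X((n + 1) * (m + 1), NEG_INF),
                      Y((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> tM((n + 1) * (m + 1), -1),
                           tX((n + 1) * (m + 1), -1),
                           tY((n + 1) * (m + 1), -1);
  #define IX(i, j) ((i) * (m + 1) + (j))

  M[IX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IX(i, 0)] = -(gap_open + i * gap_extend);
    tX[IX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IX(0, j)] = -(gap_open + j * gap_extend);
    tY[IX(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = S(a[i - 1], b[j - 1]);
      double best;
      int st = best3(M[IX(i - 1, j - 1)], X[IX(i - 1, j - 1)], Y[IX(i - 1, j - 1)], best);
      M[IX(i, j)] = (best == NEG_INF) ? NEG_INF : best + s;
      tM[IX(i, j)] = st;

      st = best3(M[IX(i - 1, j)] - gap_open - gap_extend,
                 X[IX(i - 1, j)] - gap_extend,
                 Y[IX(i - 1, j)] - gap_open - gap_extend, best);
      X[IX(i, j)] = best;
      tX[IX(i, j)] = st;

      st = best3(M[IX(i, j - 1)] - gap_open - gap_extend,
                 X[IX(i, j - 1)] - gap_open - gap_extend,
                 Y[IX(i, j - 1)] - gap_extend, best);
      Y[IX(i, j)] = best;
      tY[IX(i, j)] = st;
    }
  }

  double score;
  int state = best3(M[IX(n, m)], X[IX(n, m)], Y[IX(n, m)], score);

  // traceback
  std::vector<int> ai, bi;
  ai.reserve(n + m); bi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0) {
      prev = tM[IX(i, j)];
      ai.push_back(a[i - 1]); bi.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = tX[IX(i, j)];
      ai.push_back(a[i - 1]); bi.push_back(-1);
      --i;
    } else {
      prev = tY[IX(i, j)];
      ai.push_back(-1); bi.push_back(b[j - 1]);
      --j;
    }
    state = prev;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  #undef IX
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi), _["score"] = score);
}

// Global profile-to-sequence alignment score. P has one row per profile
// position and 20 columns (standard amino acids); a residue code of 20 (X)
// scores 0 at every position. Gap model identical to nw_align_cpp.
// [[Rcpp::export]]
double profile_align_cpp(NumericMatrix P, IntegerVector b,
                         double gap_open, double gap_extend) {
  const int n = P.nrow(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF),
                      X((n + 1) * (m + 1), NEG_INF),
                      Y((n + 1) * (m + 1), NEG_INF);
  #define IX(i, j) ((i) * (m + 1) + (j))
  M[IX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[IX(i, 0)] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Y[IX(0, j)] = -(gap_open + j * gap_extend);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int code = b[j - 1];
      const double s = (code < 20) ? P(i - 1, code) : 0.0;
      double best;
      best3(M[IX(i - 1, j - 1)], X[IX(i - 1, j - 1)], Y[IX(i - 1, j - 1)], best);
      M[IX(i, j)] = (best == NEG_INF) ? NEG_INF : best + s;
      best3(M[IX(i - 1, j)] - gap_open - gap_extend,
            X[IX(i - 1, j)] - gap_extend,
            Y[IX(i - 1, j)] - gap_open - gap_extend, best);
      X[IX(i, j)] = best;
      best3(M[IX(i, j - 1)] - gap_open - gap_extend,
            X[IX(i, j - 1)] - gap_open - gap_extend,
            Y[IX(i, j - 1)] - gap_extend, best);
      Y[IX(i, j)] = best;
    }
  }
  double score;
  best3(M[IX(n, m)], X[IX(n, m)], Y[IX(n, m)], score);
  #undef IX
  return score;
}
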