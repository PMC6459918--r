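#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP).
//
// Gap cost model: a gap of length L costs open + (L - 1) * extend.
// When end_gaps_penalized is false, leading and trailing gaps are free
// and the optimum is taken over the last row and column.
//
// Tie-breaking is deterministic: at equal score the diagonal (match)
// state is preferred over a gap in b (consuming a, "up"), which is
// preferred over a gap in a ("left").  Traceback pointers are recorded
// during the forward pass, so no floating-point equality is re-derived.
//
// a, b: 1-based residue indices into the score matrix; smat: integer
// substitution scores.  Returns the optimal score and the aligned index
// vectors (0 = gap).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y
static inline int argmax3(double m, double x, double y) {
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export]]
List gotoh_align(IntegerVector a, IntegerVector b, IntegerMatrix smat,
                 double gap_open, double gap_extend,
                 bool end_gaps_penalized) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix PM(n + 1, m + 1), PX(n + 1, m + 1), PY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = end_gaps_penalized ? -(gap_open + (i - 1) * gap_extend) : 0.0;
    PX(i, 0) = 1;  // chain of leading gaps in b
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = end_gaps_penalized ? -(gap_open + (j - 1) * gap_extend) : 0.0;
    PY(0, j) = 2;  // chain of leading gaps in a
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = smat(a[i - 1] - 1, b[j - 1] - 1);
      int pm = argmax3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1));
      double d = (pm == 0) ? M(i - 1, j - 1)
               : (pm == 1) ? X(i - 1, j - 1) : Y(i - 1, j - 1);
      M(i, j) = d + s; PM(i, j) = pm;

      int px = argmax3(M(i - 1, j) - gap_open, X(i - 1, j) - gap_extend,
                       Y(i - 1, j) - gap_open);
      X(i, j) = (px == 0) ? M(i - 1, j) - gap_open
              : (px == 1) ? X(i - 1, j) - gap_extend
                          : Y(i - 1, j) - gap_open;
      PX(i, j) = px;

      int py = argmax3(M(i, j - 1) - gap_open, X(i, j - 1) - gap_open,
                       Y(i, j - 1) - gap_extend);
      Y(i, j) = (py == 0) ? M(i, j - 1) - gap_open
              : (py == 1) ? X(i, j - 1) - gap_open
                          : Y(i, j - 1) - gap_extend;
      PY(i, j) = py;
    }
  }

  // Locate the optimum end cell.  With penalized end gaps it is (n, m);
  // otherwise also scan the last column and row, keeping the first hit
  // starting from the corner so ties resolve deterministically.
  int ei = n, ej = m;
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  if (!end_gaps_penalized) {
    for (int i = n - 1; i >= 0; --i) {
      double v = std::max(M(i, m), std::max(X(i, m), Y(i, m)));
      if (v > best) { best = v; ei = i; ej = m; }
    }
    for (int j = m - 1; j >= 0; --j) {
      double v = std::max(M(n, j), std::max(X(n, j), Y(n, j)));
      if (v > best) { best = v; ei = n; ej = j; }
    }
  }

  std::vector<int> ra, rb;  // built back-to-front
  for (int i = n; i > ei; --i) { ra.push_back(i); rb.push_back(0); }
  for (int j = m; j > ej; --j) { ra.push_back(0); rb.push_back(j); }

  int i = ei, j = ej;
  int state = argmax3(M(i, j), X(i, j), Y(i, j));
  while (i > 0 || j > 0) {
    if (state == 0) {
      ra.push_back(i); rb.push_back(j);
      state = PM(i, j); --i; --j;
    } else if (state == 1) {
      ra.push_back(i); rb.push_back(0);
      state = PX(i, j); --i;
    } else {
      ra.push_back(0); rb.push_back(j);
      state = PY(i, j); --j;
    }
  }

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best,
                      _["a_idx"] = wrap(ra), _["b_idx"] = wrap(rb));
}
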