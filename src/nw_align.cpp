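#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch global alignment with affine gaps (Gotoh).
// Gap cost convention: a gap run of length L costs open + ext * L.
// End gaps are penalized (true global alignment).
// Traceback tie-break: aligned pair (diagonal) > gap in seqB (up) >
// gap in seqA (left), applied both when choosing the final state and at
// every state transition, so the returned alignment is deterministic.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double open, double ext) {
  const int n = a.size(), m = b.size();
  // states: 0 = M (pair), 1 = X (gap in B, consume A, "up"), 2 = Y (gap in A, "left")
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -(open + ext * i);
    tX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -(open + ext * j);
    tY(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      // M: predecessor at (i-1, j-1), preference M > X > Y
      {
        double best = M(i - 1, j - 1); int st = 0;
        if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); st = 1; }
        if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); st = 2; }
        M(i, j) = best + s; tM(i, j) = st;
      }
      // X: consume a[i-1], predecessor at (i-1, j)
      {
        double bM = M(i - 1, j) - (open + ext);
        double bX = X(i - 1, j) - ext;
        double bY = Y(i - 1, j) - (open + ext);
        double best = bM; int st = 0;
        if (bX > best) { best = bX; st = 1; }
        if (bY > best) { best = bY; st = 2; }
        X(i, j) = best; tX(i, j) = st;
      }
      // Y: consume b[j-1], predecessor at (i, j-1)
      {
        double bM = M(i, j - 1) - (open + ext);
        double bX = X(i, j - 1) - (open + ext);
        double bY = Y(i, j - 1) - ext;
        double best = bM; int st = 0;
        if (bX > best) { best = bX; st = 1; }
        if (bY > best) { best = bY; st = 2; }
        Y(i, j) = best; tY(i, j) = st;
      }
    }
  }

  double score = M(n, m); int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  // traceback
  std::vector<int> pa, pb;           // aligned pairs, reversed
  std::vector<int> ga, gb;           // gapped alignment columns, reversed (0 = gap)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      ga.push_back(i); gb.push_back(j);
      state = tM(i, j); --i; --j;
    } else if (state == 1) {
      ga.push_back(i); gb.push_back(0);
      state = tX(i, j); --i;
    } else {
      ga.push_back(0); gb.push_back(j);
      state = tY(i, j); --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["score"] = score,
                      _["pair_a"] = wrap(pa), _["pair_b"] = wrap(pb),
                      _["col_a"] = wrap(ga), _["col_b"] = wrap(gb));
}
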