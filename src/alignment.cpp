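#include <Rcpp.h>
using namespace Rcpp;

// Integer sequence encoding used throughout:
//   1..4 = A,C,G,T; 0 = N/ambiguous (mismatches everything, including itself);
//   values >= 100 are sticky intron meta-symbols (100 + intron rank).
// Meta symbols may only pair with meta symbols; base<->meta pairing is
// forbidden outright (not merely penalised).

static const double NEG_INF = -1e18;

inline bool is_meta(int x) { return x >= 100; }

inline double pair_score(int x, int y, double match, double mismatch,
                         double meta_bonus) {
  bool mx = is_meta(x), my = is_meta(y);
  if (mx && my) return meta_bonus;
  if (mx || my) return NEG_INF;
  if (x == 0 || y == 0) return mismatch;
  return (x == y) ? match : mismatch;
}

// Global (Needleman-Wunsch) alignment over the extended alphabet with a
// linear gap penalty. Returns the optimal score and the list of aligned
// meta-symbol pairs (1-based positions in each input).
// [[Rcpp::export(name = ".nw_sticky_cpp")]]
List nw_sticky_cpp(IntegerVector a, IntegerVector b,
                   double match = 1.0, double mismatch = -1.0,
                   double gap = -2.0, double meta_bonus = 10.0) {
  int n = a.size(), m = b.size();
  const int* pa = INTEGER(a); const int* pb = INTEGER(b);
  std::vector<double> prev(m + 1), cur(m + 1);
  // traceback: 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
  std::vector<signed char> T((size_t)(n + 1) * (m + 1), 0);
  for (int i = 1; i <= n; ++i) T[(size_t)i * (m + 1)] = 1;
  for (int j = 1; j <= m; ++j) { prev[j] = j * gap; T[j] = 2; }
  double final_score = (n == 0) ? m * gap : 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    signed char* Trow = &T[(size_t)i * (m + 1)];
    int ai = pa[i - 1];
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + pair_score(ai, pb[j - 1],
                                          match, mismatch, meta_bonus);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      // deterministic preference: diag, then up, then left
      double best = d; signed char dir = 0;
      if (u > best) { best = u; dir = 1; }
      if (l > best) { best = l; dir = 2; }
      cur[j] = best; Trow[j] = dir;
    }
    std::swap(prev, cur);
    if (i == n) final_score = prev[m];
  }
  std::vector<int> ma, mb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int dir = T[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      if (is_meta(a[i - 1]) && is_meta(b[j - 1])) {
        ma.push_back(i); mb.push_back(j);
      }
      --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(ma.begin(), ma.end());
  std::reverse(mb.begin(), mb.end());
  return List::create(_["score"] = final_score,
                      _["meta_a"] = wrap(ma), _["meta_b"] = wrap(mb));
}

// Plain global alignment of two base sequences (no meta symbols), returning
// the score plus transition / transversion / aligned-site counts over
// non-gap columns (columns containing N are excluded from the counts).
// [[Rcpp::export(name = ".nw_pair_counts_cpp")]]
List nw_pair_counts_cpp(IntegerVector a, IntegerVector b,
                        double match = 1.0, double mismatch = -1.0,
                        double gap = -2.0) {
  int n = a.size(), m = b.size();
  const int* pa = INTEGER(a); const int* pb = INTEGER(b);
  // two-row DP for the score, one-byte traceback for the path
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<signed char> T((size_t)(n + 1) * (m + 1), 0);
  for (int i = 1; i <= n; ++i) T[(size_t)i * (m + 1)] = 1;
  for (int j = 1; j <= m; ++j) { prev[j] = j * gap; T[j] = 2; }
  double final_score = (n == 0) ? m * gap : 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    signed char* Trow = &T[(size_t)i * (m + 1)];
    int ai = pa[i - 1];
    for (int j = 1; j <= m; ++j) {
      int bj = pb[j - 1];
      double ps = (ai == 0 || bj == 0 || ai != bj) ? mismatch : match;
      double d = prev[j - 1] + ps;
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double best = d; signed char dir = 0;
      if (u > best) { best = u; dir = 1; }
      if (l > best) { best = l; dir = 2; }
      cur[j] = best; Trow[j] = dir;
    }
    std::swap(prev, cur);
    if (i == n) final_score = prev[m];
  }
  // purine = A(1),G(3); pyrimidine = C(2),T(4)
  auto purine = [](int x) { return x == 1 || x == 3; };
  long sites = 0, ts = 0, tv = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int dir = T[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      int x = a[i - 1], y = b[j - 1];
      if (x != 0 && y != 0) {
        ++sites;
        if (x != y) {
          if (purine(x) == purine(y)) ++ts; else ++tv;
        }
      }
      --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["score"] = final_score, _["sites"] = (double)sites,
                      _["transitions"] = (double)ts,
                      _["transversions"] = (double)tv);
}

// Forward affine-gap Smith-Waterman (Gotoh), linear memory. A gap of
// length L costs gap_open + L * gap_ext. Returns best score and its end
// cell (1-based, 0 if the best score is 0).
static void sw_forward(const IntegerVector& a, const IntegerVector& b,
                       double match, double mismatch,
                       double gap_open, double gap_ext,
                       double& best, int& bi, int& bj) {
  int n = a.size(), m = b.size();
  const int* pa = INTEGER(a); const int* pb = INTEGER(b);
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG_INF);
  best = 0.0; bi = 0; bj = 0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;     // H[i-1][j-1]
    double F = NEG_INF;    // gap in b along row i
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - gap_open - gap_ext, E[j] - gap_ext);
      F = std::max(H[j - 1] - gap_open - gap_ext, F - gap_ext);
      int x = pa[i - 1], y = pb[j - 1];
      double ps = (x == 0 || y == 0 || x != y) ? mismatch : match;
      // masked sentinel (-1) never matches anything
      if (x < 0 || y < 0) ps = mismatch;
      double h = diag + ps;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
}

// Optimal local alignment via two-pass Gotoh: forward pass locates the end
// cell, a reverse pass on the reversed prefixes locates the start cell.
// Returns score and 1-based inclusive intervals on each sequence.
// [[Rcpp::export(name = ".sw_top_hit_cpp")]]
List sw_top_hit_cpp(IntegerVector a, IntegerVector b,
                    double match = 1.0, double mismatch = -1.0,
                    double gap_open = -4.0, double gap_ext = -1.0) {
  double best; int bi, bj;
  // gap parameters arrive as penalties (negative); sw_forward expects costs
  double go = -gap_open, ge = -gap_ext;
  sw_forward(a, b, match, mismatch, go, ge, best, bi, bj);
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  }
  IntegerVector ar(bi), br(bj);
  for (int i = 0; i < bi; ++i) ar[i] = a[bi - 1 - i];
  for (int j = 0; j < bj; ++j) br[j] = b[bj - 1 - j];
  double best2; int ri, rj;
  sw_forward(ar, br, match, mismatch, go, ge, best2, ri, rj);
  int as = bi - ri + 1, bs = bj - rj + 1;
  return List::create(_["score"] = best,
                      _["a_start"] = as, _["a_end"] = bi,
                      _["b_start"] = bs, _["b_end"] = bj);
}
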