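#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman. A gap run of length L costs open + L * ext
// (both penalties passed as positive numbers). Returns the single best
// local alignment with a deterministic traceback: diagonal preferred over
// gap states, and among equal-scoring end cells the smallest (i, j) wins.
// [[Rcpp::export(name = ".sw_align_c")]]
List sw_align_c(std::string a, std::string b,
                int match, int mismatch, int gap_open, int gap_ext) {
  const int n = a.size(), m = b.size();
  const int NEG = -1000000000;
  // DP rows kept fully (traceback needs pointers over the whole matrix)
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0),
      tbE((n + 1) * (m + 1), 0), tbF((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  int best = 0, bi_ = 0, bj_ = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int id = idx(i, j);
      // E: gap in a, consumes b[j-1]
      int e_open = H[idx(i, j - 1)] - gap_open - gap_ext;
      int e_ext = E[idx(i, j - 1)] - gap_ext;
      if (e_open >= e_ext) { E[id] = e_open; tbE[id] = 0; }
      else { E[id] = e_ext; tbE[id] = 1; }
      // F: gap in b, consumes a[i-1]
      int f_open = H[idx(i - 1, j)] - gap_open - gap_ext;
      int f_ext = F[idx(i - 1, j)] - gap_ext;
      if (f_open >= f_ext) { F[id] = f_open; tbF[id] = 0; }
      else { F[id] = f_ext; tbF[id] = 1; }
      int s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      int diag = H[idx(i - 1, j - 1)] + s;
      int h = 0; unsigned char ptr = 0;            // 0 = local start
      if (diag > h) { h = diag; ptr = 1; }
      if (E[id] > h) { h = E[id]; ptr = 2; }
      if (F[id] > h) { h = F[id]; ptr = 3; }
      H[id] = h; tbH[id] = ptr;
      if (h > best) { best = h; bi_ = i; bj_ = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["ai"] = IntegerVector(0),
                        _["bi"] = IntegerVector(0));

  // traceback from (bi_, bj_)
  std::vector<int> ai, bi;
  int i = bi_, j = bj_;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (true) {
    const int id = idx(i, j);
    if (state == 0) {
      unsigned char p = tbH[id];
      if (p == 0) break;
      if (p == 1) { ai.push_back(i - 1); bi.push_back(j - 1); --i; --j; }
      else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ai.push_back(-1); bi.push_back(j - 1);
      state = tbE[id] == 0 ? 0 : 1;
      --j;
    } else {
      ai.push_back(i - 1); bi.push_back(-1);
      state = (tbF[id] == 0) ? 0 : 2;
      --i;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best, _["ai"] = wrap(ai), _["bi"] = wrap(bi));
}

static inline int pair_score(char x, char y, int wc, int gu) {
  if ((x == 'A' && y == 'T') || (x == 'T' && y == 'A') ||
      (x == 'G' && y == 'C') || (x == 'C' && y == 'G')) return wc;
  if ((x == 'G' && y == 'T') || (x == 'T' && y == 'G')) return gu;
  return 0;
}

// Intermolecular duplex DP: best-scoring annealed block between a and rb
// (rb = reverse of the second strand, so antiparallel pairing is monotone).
// Two states per cell: M = last column paired, U = last column unpaired
// (bulge on either strand or an interior-loop column consuming both).
// A run of unpaired columns costs open + (run length) * ext... opening an
// unpaired run costs `open`, each column in it costs `ext`. The duplex must
// begin and end with a paired column.
// [[Rcpp::export(name = ".duplex_align_c")]]
List duplex_align_c(std::string a, std::string rb, int wc, int gu,
                    int open_pen, int ext_pen) {
  const int n = a.size(), m = rb.size();
  const int NEG = -1000000000;
  std::vector<int> M((n + 1) * (m + 1), NEG), U((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0),
      tbU((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  int best = NEG, bi_ = 0, bj_ = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int id = idx(i, j), dg = idx(i - 1, j - 1);
      int ps = pair_score(a[i - 1], rb[j - 1], wc, gu);
      if (ps > 0) {
        int v = 0; unsigned char p = 0;                  // start fresh
        if (M[dg] > v) { v = M[dg]; p = 1; }
        if (U[dg] > v) { v = U[dg]; p = 2; }
        M[id] = v + ps; tbM[id] = p;
        if (M[id] > best) { best = M[id]; bi_ = i; bj_ = j; }
      } else {
        M[id] = NEG; tbM[id] = 0;
      }
      // U transitions: consume a only (up), rb only (left), or both (diag)
      int u = NEG; unsigned char p = 0;
      const int up = idx(i - 1, j), lf = idx(i, j - 1);
      if (M[up] - open_pen - ext_pen > u) { u = M[up] - open_pen - ext_pen; p = 1; }
      if (U[up] - ext_pen > u) { u = U[up] - ext_pen; p = 2; }
      if (M[lf] - open_pen - ext_pen > u) { u = M[lf] - open_pen - ext_pen; p = 3; }
      if (U[lf] - ext_pen > u) { u = U[lf] - ext_pen; p = 4; }
      if (M[dg] - open_pen - ext_pen > u) { u = M[dg] - open_pen - ext_pen; p = 5; }
      if (U[dg] - ext_pen > u) { u = U[dg] - ext_pen; p = 6; }
      U[id] = u; tbU[id] = p;
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["ai"] = IntegerVector(0),
                        _["bi"] = IntegerVector(0),
                        _["paired"] = LogicalVector(0));

  std::vector<int> ai, bi;
  std::vector<int> paired;
  int i = bi_, j = bj_, state = 0;  // 0 = M, 1 = U
  while (true) {
    const int id = idx(i, j);
    if (state == 0) {
      ai.push_back(i - 1); bi.push_back(j - 1); paired.push_back(1);
      unsigned char p = tbM[id];
      --i; --j;
      if (p == 0) break;
      state = (p == 1) ? 0 : 1;
    } else {
      unsigned char p = tbU[id];
      if (p == 1 || p == 2) { ai.push_back(i - 1); bi.push_back(-1); --i; }
      else if (p == 3 || p == 4) { ai.push_back(-1); bi.push_back(j - 1); --j; }
      else { ai.push_back(i - 1); bi.push_back(j - 1); --i; --j; }
      paired.push_back(0);
      state = (p % 2 == 1) ? 0 : 1;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  std::reverse(paired.begin(), paired.end());
  return List::create(_["score"] = best, _["ai"] = wrap(ai),
                      _["bi"] = wrap(bi),
                      _["paired"] = LogicalVector(paired.begin(), paired.end()));
}
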