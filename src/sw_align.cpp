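#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-state DP).
//
// Gap of length k costs gap_open + k * gap_extend; gap states extend
// themselves or open from the match state (no direct Ix <-> Iy switch).
// The optimal local alignment always ends (and starts) in the match state,
// since trailing or leading gap columns only lower the score.
//
// Determinism: the traceback start is the first maximal match-state cell in
// row-major order (smallest query index, then smallest target index); at
// each step ties are broken diagonal > up (gap in target, consumes query)
// > left.
//
// q, t: 0-based integer codes into the scoring matrix; xcode marks residues
// that must never be counted as identities (X / ambiguity).

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix mat,
                  int gap_open, int gap_extend, int xcode) {
  const int n = q.size(), m = t.size();
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend;

  // full (n+1) x (m+1) matrices; desk-scale proteins keep this small
  std::vector<int> M((n + 1) * (m + 1), 0);
  std::vector<int> Ix((n + 1) * (m + 1), NEG);  // gap in target (up)
  std::vector<int> Iy((n + 1) * (m + 1), NEG);  // gap in query (left)
  const int W = m + 1;

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      const int diag = (i - 1) * W + (j - 1);
      int prev = M[diag];
      if (Ix[diag] > prev) prev = Ix[diag];
      if (Iy[diag] > prev) prev = Iy[diag];
      if (prev < 0) prev = 0;
      M[idx] = prev + mat(q[i - 1], t[j - 1]);

      const int up = (i - 1) * W + j;
      int ix = M[up] - open_cost;
      if (Ix[up] - gap_extend > ix) ix = Ix[up] - gap_extend;
      Ix[idx] = ix;

      const int left = i * W + (j - 1);
      int iy = M[left] - open_cost;
      if (Iy[left] - gap_extend > iy) iy = Iy[left] - gap_extend;
      Iy[idx] = iy;

      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }

  if (best <= 0)
    return List::create(_["score"] = 0, _["hit"] = false);

  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  int overlap = 0, matches = 0;
  int qend = bi, tend = bj, qstart = bi, tstart = bj;
  for (;;) {
    const int idx = i * W + j;
    if (state == 0) {
      ++overlap;
      if (q[i - 1] == t[j - 1] && q[i - 1] != xcode) ++matches;
      qstart = i; tstart = j;
      const int diag = (i - 1) * W + (j - 1);
      int prev = M[idx] - mat(q[i - 1], t[j - 1]);
      --i; --j;
      if (prev <= 0) break;                    // local start
      if (M[diag] == prev) state = 0;
      else if (Ix[diag] == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      const int up = (i - 1) * W + j;
      const int cur = Ix[idx];
      --i;
      if (M[up] - open_cost == cur) state = 0;
      else state = 1;                          // extension
    } else {
      const int left = i * W + (j - 1);
      const int cur = Iy[idx];
      --j;
      if (M[left] - open_cost == cur) state = 0;
      else state = 2;
    }
  }

  return List::create(
    _["score"] = best, _["hit"] = true,
    _["overlap"] = overlap, _["matches"] = matches,
    _["query_start"] = qstart, _["query_end"] = qend,
    _["target_start"] = tstart, _["target_end"] = tend);
}
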