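#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) of two integer-encoded peptide
// sequences against a substitution matrix, with optional masking of target
// positions (masked columns can never be part of an alignment). Gap of
// length k costs gap_open + k * gap_extend. Returns the best score, the
// 1-based bounds of the alignment on both sequences, and the aligned index
// vectors (0 encodes a gap).
//
// a, b: 0-based codes into the rows/cols of S. mask_b: length |b|.
// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                  int gap_open, int gap_extend, LogicalVector mask_b) {
  const int m = a.size(), n = b.size();
  const int NEG = -1000000000 / 2;
  const int open_cost = gap_open + gap_extend;

  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_idx"] = IntegerVector(0),
                        _["b_idx"] = IntegerVector(0));
  }

  // full DP matrices ((m+1) x (n+1)) + traceback states
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);  // gap in a (move along b)
  std::vector<int> F((m + 1) * (n + 1), NEG);  // gap in b (move along a)
  // traceback for H: 0 stop, 1 diag, 2 from E, 3 from F
  std::vector<unsigned char> tH((m + 1) * (n + 1), 0);
  // for E/F: 0 opened here (came from H), 1 extended
  std::vector<unsigned char> tE((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tF((m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = i * (n + 1) + j;
      const int up = (i - 1) * (n + 1) + j;
      const int left = idx - 1;
      const int diag = up - 1;

      int e_open = H[left] - open_cost;
      int e_ext = E[left] - gap_extend;
      E[idx] = e_open >= e_ext ? e_open : e_ext;
      tE[idx] = e_open >= e_ext ? 0 : 1;

      int f_open = H[up] - open_cost;
      int f_ext = F[up] - gap_extend;
      F[idx] = f_open >= f_ext ? f_open : f_ext;
      tF[idx] = f_open >= f_ext ? 0 : 1;

      int sub = mask_b[j - 1] ? NEG : S(ai, b[j - 1]);
      int d = H[diag] + sub;
      int h = 0; unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      if (mask_b[j - 1]) { h = 0; t = 0; E[idx] = NEG; }
      H[idx] = h; tH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> ai_rev, bi_rev;
  int i = bi, j = bj;
  int state = 0;  // 0 in H, 1 in E, 2 in F
  while (i > 0 && j > 0) {
    const int idx = i * (n + 1) + j;
    if (state == 0) {
      unsigned char t = tH[idx];
      if (t == 0) break;
      if (t == 1) { ai_rev.push_back(i); bi_rev.push_back(j); --i; --j; }
      else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {      // E: gap in a, consume b
      unsigned char t = tE[idx];
      ai_rev.push_back(0); bi_rev.push_back(j);
      --j;
      if (t == 0) state = 0;
    } else {                      // F: gap in b, consume a
      unsigned char t = tF[idx];
      ai_rev.push_back(i); bi_rev.push_back(0);
      --i;
      if (t == 0) state = 0;
    }
  }

  const int len = (int) ai_rev.size();
  IntegerVector a_idx(len), b_idx(len);
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  for (int p = 0; p < len; ++p) {
    a_idx[p] = ai_rev[len - 1 - p];
    b_idx[p] = bi_rev[len - 1 - p];
    if (a_idx[p] > 0) { if (a_start == 0) a_start = a_idx[p]; a_end = a_idx[p]; }
    if (b_idx[p] > 0) { if (b_start == 0) b_start = b_idx[p]; b_end = b_idx[p]; }
  }
  return List::create(_["score"] = best, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end, _["a_idx"] = a_idx,
                      _["b_idx"] = b_idx);
}
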