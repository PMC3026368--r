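#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment of a sequence against its own reverse
// complement, restricted to the half-domain i + j <= L so that the two
// back-mapped arms of any reported alignment are disjoint on the original
// molecule (a base may only pair with a strictly downstream base).
//
// q: 1..5 codes (A,C,G,U,N) of the original sequence
// t: 1..5 codes of its reverse complement
// sub: 5x5 integer scoring matrix indexed (query, target); NOT symmetric
// gap: linear per-column gap penalty (negative)
//
// Tie-breaking: the traceback starts from the max-scoring cell with the
// smallest (row, column) in lexicographic order; within the DP fill, moves
// are preferred diagonal > up (gap in target) > left (gap in query).
//
// Returns score 0 when no positive-scoring local alignment exists; otherwise
// score plus the per-column query/target positions (0 marks a gap).
// [[Rcpp::export(name = ".sw_self_align")]]
List sw_self_align(IntegerVector q, IntegerVector t, IntegerMatrix sub, int gap) {
  const int L = q.size();
  if (t.size() != L) stop("query and target lengths differ");
  const int W = L + 1;
  std::vector<int> H(static_cast<size_t>(W) * W, 0);
  std::vector<unsigned char> ptr(static_cast<size_t>(W) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    const int jmax = L - i;  // enforce i + j <= L
    for (int j = 1; j <= jmax; ++j) {
      const int s = sub(q[i - 1] - 1, t[j - 1] - 1);
      const int diag = H[(i - 1) * W + (j - 1)] + s;
      const int up = H[(i - 1) * W + j] + gap;
      const int left = H[i * W + (j - 1)] + gap;
      int v = diag;
      unsigned char p = 1;
      if (up > v) { v = up; p = 2; }
      if (left > v) { v = left; p = 3; }
      if (v <= 0) { v = 0; p = 0; }
      H[i * W + j] = v;
      ptr[i * W + j] = p;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return List::create(Named("score") = 0);
  std::vector<int> qi, tj;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H[i * W + j] > 0) {
    const unsigned char p = ptr[i * W + j];
    if (p == 0) break;
    if (p == 1) { qi.push_back(i); tj.push_back(j); --i; --j; }
    else if (p == 2) { qi.push_back(i); tj.push_back(0); --i; }
    else { qi.push_back(0); tj.push_back(j); --j; }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(tj.begin(), tj.end());
  return List::create(Named("score") = best, Named("qpos") = wrap(qi),
                      Named("tpos") = wrap(tj));
}
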