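#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman, score only, linear memory.
// Sequences are 0-based integer encodings into the substitution matrix
// alphabet. Gap of length L costs gapOpen + L * gapExt (NCBI convention).
static int sw_score_one(const int *q, int nq, const int *s, int m,
                        const int *sub, int nst, int gapOpen, int gapExt,
                        std::vector<int> &H, std::vector<int> &E) {
  const int NEG = INT_MIN / 4;
  std::fill(H.begin(), H.begin() + nq + 1, 0);
  std::fill(E.begin(), E.begin() + nq + 1, NEG);
  int best = 0;
  const int go = gapOpen + gapExt;
  for (int i = 1; i <= m; ++i) {
    int diag = 0, F = NEG;
    const int *scol = sub + (size_t)s[i - 1] * nst;
    for (int j = 1; j <= nq; ++j) {
      const int h = H[j];
      int e = E[j] - gapExt;
      const int eo = h - go;
      if (eo > e) e = eo;
      E[j] = e;
      int f = F - gapExt;
      const int fo = H[j - 1] - go;
      if (fo > f) f = fo;
      F = f;
      int v = diag + scol[q[j - 1]];
      if (v < 0) v = 0;
      if (e > v) v = e;
      if (f > v) v = f;
      if (v > best) best = v;
      diag = h;
      H[j] = v;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_matrix")]]
IntegerMatrix sw_score_matrix(List queries, List subjects,
                              IntegerMatrix submat, int gapOpen, int gapExt) {
  const int nq = queries.size(), ns = subjects.size();
  const int nst = submat.nrow();
  if (submat.ncol() != nst) stop("substitution matrix must be square");
  IntegerMatrix out(nq, ns);
  std::vector<std::vector<int>> Q(nq);
  int maxlen = 1;
  for (int i = 0; i < nq; ++i) {
    IntegerVector v = queries[i];
    Q[i] = as<std::vector<int>>(v);
    if ((int)Q[i].size() > maxlen) maxlen = Q[i].size();
  }
  std::vector<int> H(maxlen + 1), E(maxlen + 1);
  const int *sub = submat.begin();
  for (int s = 0; s < ns; ++s) {
    IntegerVector sv = subjects[s];
    std::vector<int> S = as<std::vector<int>>(sv);
    for (int i = 0; i < nq; ++i) {
      out(i, s) = sw_score_one(Q[i].data(), Q[i].size(), S.data(), S.size(),
                               sub, nst, gapOpen, gapExt, H, E);
    }
  }
  return out;
}
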