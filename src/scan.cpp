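#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -1e12;

// Best local alignment of an integer-encoded protein against a profile of
// per-position log-odds columns, with affine gaps (a gap of length L costs
// open + L * ext, matching the pairwiseAlignment convention).
//
// prof: 20 x L numeric matrix of column scores (rows = residues 1..20).
// seq:  integer vector, 1..20; 0 marks a residue outside the alphabet.
// mask: logical vector, TRUE = position may not take part in an alignment.
//
// Returns c(score, seq_start, seq_end, col_start, col_end) with 0-based
// half-open coordinates, or score 0 and -1 coordinates when no positive-score
// local alignment exists. Local alignments start and end in match state.
// [[Rcpp::export]]
NumericVector cpp_scan_local(NumericMatrix prof, IntegerVector seq,
                             LogicalVector mask, double open, double ext) {
  const int n = seq.size();
  const int L = prof.ncol();
  // three states: M (match), X (gap in profile, consumes seq), Y (gap in seq)
  std::vector<double> M((n + 1) * (L + 1), NEG_INF), X = M, Y = M;
  // start coordinates of the local alignment ending at each cell
  std::vector<int> Ms((n + 1) * (L + 1), -1), Mc = Ms, Xs = Ms, Xc = Ms,
                   Ys = Ms, Yc = Ms;
  double best = 0.0;
  int bi = -1, bj = -1, b_si = -1, b_sj = -1;
  const double open_cost = open + ext;

#define IDX(i, j) ((i) * (L + 1) + (j))
  for (int i = 1; i <= n; ++i) {
    const bool bad = mask[i - 1] || seq[i - 1] < 1 || seq[i - 1] > 20;
    for (int j = 1; j <= L; ++j) {
      const int idx = IDX(i, j);
      if (!bad) {
        const double s = prof(seq[i - 1] - 1, j - 1);
        // best previous state at (i-1, j-1), or a fresh start (score 0)
        double prev = 0.0;
        int psi = i - 1, psj = j - 1;
        const int pid = IDX(i - 1, j - 1);
        if (M[pid] > prev) { prev = M[pid]; psi = Ms[pid]; psj = Mc[pid]; }
        if (X[pid] > prev) { prev = X[pid]; psi = Xs[pid]; psj = Xc[pid]; }
        if (Y[pid] > prev) { prev = Y[pid]; psi = Ys[pid]; psj = Yc[pid]; }
        M[idx] = prev + s;
        Ms[idx] = psi; Mc[idx] = psj;
        if (M[idx] > best) {
          best = M[idx]; bi = i; bj = j; b_si = Ms[idx]; b_sj = Mc[idx];
        }
        // gap in profile (insertion in the protein)
        const int up = IDX(i - 1, j);
        double xo = M[up] - open_cost, xe = X[up] - ext;
        if (xo >= xe) { X[idx] = xo; Xs[idx] = Ms[up]; Xc[idx] = Mc[up]; }
        else          { X[idx] = xe; Xs[idx] = Xs[up]; Xc[idx] = Xc[up]; }
      }
      // gap in the protein (profile column skipped); allowed over any i
      const int lf = IDX(i, j - 1);
      double yo = M[lf] - open_cost, ye = Y[lf] - ext;
      if (yo >= ye) { Y[idx] = yo; Ys[idx] = Ms[lf]; Yc[idx] = Mc[lf]; }
      else          { Y[idx] = ye; Ys[idx] = Ys[lf]; Yc[idx] = Yc[lf]; }
    }
  }
#undef IDX
  NumericVector out(5);
  out[0] = best;
  if (bi < 0) {
    out[1] = out[2] = out[3] = out[4] = -1;
  } else {
    out[1] = b_si;      // seq start (0-based)
    out[2] = bi;        // seq end (exclusive)
    out[3] = b_sj;      // profile column start
    out[4] = bj;        // profile column end (exclusive)
  }
  return out;
}
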