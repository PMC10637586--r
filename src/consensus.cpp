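#include <Rcpp.h>
using namespace Rcpp;

// Accumulate co-sampling (S) and co-clustering (M) counts for one consensus
// resampling replicate. `idx` holds 0-based row indices of the sampled
// items sorted ascending, `labels` the cluster assignment of each sampled
// item (already permuted to match). Both matrices are updated in place
// (upper triangle only); the caller allocates them fresh. The inner loop
// writes one column at a time for cache locality.
// [[Rcpp::export]]
void cpp_consensus_accumulate(NumericMatrix M, NumericMatrix S,
                              IntegerVector idx, IntegerVector labels) {
  const int m = idx.size();
  const int n = M.nrow();
  double *mp = M.begin();
  double *sp = S.begin();
  const int *ip = idx.begin();
  const int *lp = labels.begin();
  for (int b = 1; b < m; ++b) {
    const int jb = ip[b];
    const int lb = lp[b];
    double *scol = sp + (R_xlen_t) jb * n;
    double *mcol = mp + (R_xlen_t) jb * n;
    for (int a = 0; a < b; ++a) {
      scol[ip[a]] += 1.0;
      if (lp[a] == lb) mcol[ip[a]] += 1.0;
    }
  }
}
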