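#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Block-bootstrap overlap statistics within one region.
//
// a, b: 0/1 occupancy vectors of the two annotations over the region.
// The region is partitioned into destination tiles of `block_len`
// positions (last tile possibly shorter); in each bootstrap replicate
// every tile of A is refilled from a uniformly chosen source block of
// the same length, preserving A's within-block structure, and the
// statistic against the fixed B annotation is recomputed.
//
// stat_bp: total base-pair overlap.  stat_count: number of maximal runs
// of the resampled A that touch at least one B base.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List block_boot_region_cpp(IntegerVector a, IntegerVector b,
                           int block_len, int n_rep, bool count_stat) {
  const int L = a.size();
  if (block_len < 1) block_len = 1;
  if (block_len > L) block_len = L;
  const int n_tiles = (L + block_len - 1) / block_len;

  NumericVector bp(n_rep), cnt(n_rep);
  std::vector<int> aa(L);

  for (int r = 0; r < n_rep; ++r) {
    for (int t = 0; t < n_tiles; ++t) {
      const int dest = t * block_len;
      const int len = std::min(block_len, L - dest);
      const int src = (int)(unif_rand() * (L - len + 1));
      for (int q = 0; q < len; ++q) aa[dest + q] = a[src + q];
    }
    double s = 0.0;
    for (int i = 0; i < L; ++i) s += aa[i] && b[i];
    bp[r] = s;
    if (count_stat) {
      double c = 0.0;
      bool in_run = false, hit = false;
      for (int i = 0; i < L; ++i) {
        if (aa[i]) {
          if (!in_run) { in_run = true; hit = false; }
          if (b[i]) hit = true;
        } else if (in_run) {
          if (hit) c += 1.0;
          in_run = false;
        }
      }
      if (in_run && hit) c += 1.0;
      cnt[r] = c;
    }
  }
  return List::create(_["bp"] = bp, _["count"] = cnt);
}
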