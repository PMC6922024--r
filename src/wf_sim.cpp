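#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Gene-drop one chromosome through an explicit pedigree.
//
// H: S x 2N0 matrix of founder-haplotype ids (haplotypes in columns;
//    individual i owns columns 2i, 2i+1).
// pos_M: SNP positions on the genetic map (Morgans), ascending.
// L: chromosome length in Morgans; crossovers are a Poisson(L) process
//    with uniform positions and a random start phase.
// pedigree: list over generations; element g is a K_g x 2 integer matrix
//    of 1-based diploid parent indices (sire, dam) into generation g-1.
//
// Each meiosis copies whole between-crossover segments (memcpy) from the
// chosen parental haplotype, so cost is dominated by memory bandwidth.
// Uses R's RNG throughout: set.seed() on the R side governs everything.
// Returns the final generation as an S x 2*K_last matrix.
// [[Rcpp::export]]
IntegerMatrix drop_pedigree_chrom(IntegerMatrix H, NumericVector pos_M,
                                  double L, List pedigree) {
  const int S = pos_M.size();
  const double* pm = REAL(pos_M);
  std::vector<int> cur(H.begin(), H.end());
  int curN = H.ncol() / 2;                 // diploids in current generation
  std::vector<int> nxt;
  std::vector<double> cx;

  for (int g = 0; g < pedigree.size(); ++g) {
    IntegerMatrix pairs = pedigree[g];
    const int K = pairs.nrow();
    nxt.resize((size_t)2 * K * S);
    for (int k = 0; k < K; ++k) {
      for (int side = 0; side < 2; ++side) {
        const int parent = pairs(k, side) - 1;
        if (parent < 0 || parent >= curN)
          stop("pedigree parent index out of range");
        int* out = nxt.data() + (size_t)(2 * k + side) * S;
        const int* h[2] = {cur.data() + (size_t)(2 * parent) * S,
                           cur.data() + (size_t)(2 * parent + 1) * S};
        const int ncx = (int) R::rpois(L);
        cx.resize(ncx);
        for (int c = 0; c < ncx; ++c) cx[c] = unif_rand() * L;
        std::sort(cx.begin(), cx.end());
        int phase = (unif_rand() < 0.5) ? 0 : 1;
        int start = 0;
        for (int c = 0; c < ncx; ++c) {
          const int stop_at = (int)(std::upper_bound(pm + start, pm + S, cx[c]) - pm);
          if (stop_at > start) {
            std::memcpy(out + start, h[phase] + start,
                        (size_t)(stop_at - start) * sizeof(int));
            start = stop_at;
          }
          phase ^= 1;
        }
        if (start < S)
          std::memcpy(out + start, h[phase] + start,
                      (size_t)(S - start) * sizeof(int));
      }
    }
    cur.swap(nxt);
    curN = K;
  }

  IntegerMatrix res(S, 2 * curN);
  std::copy(cur.begin(), cur.end(), res.begin());
  return res;
}
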