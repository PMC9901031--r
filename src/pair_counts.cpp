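#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Fixed-radius proximal-pair counting for one cell (one z-plane).
//
// Points are binned on a uniform grid of side d; each unordered transcript
// pair at Euclidean distance <= d is visited exactly once by scanning the
// 3x3 neighborhood of each point's bin. Equivalent to the naive all-pairs
// scan (the R-side oracle) but O(n) for bounded local density.
//
// Returns:
//   n_prox   - number of proximal unordered transcript pairs (any genes,
//              same-gene pairs included, self-pairs excluded)
//   pair_i/j - 1-based gene indices (i < j) of cross-gene pairs with K > 0
//   K        - proximal cross-gene transcript-pair counts per gene pair
//   region   - (optional) 4-column tally (Nuc, PN, Cyt, CP) per gene pair;
//              each member of a proximal pair contributes 1/2 to its region

typedef std::pair<long long, double> acc_t;

// [[Rcpp::export(name = ".pair_counts_cpp")]]
List pair_counts_cpp(NumericVector x, NumericVector y, IntegerVector gene,
                     int n_genes, double d, IntegerVector region) {
  const int n = x.size();
  const double d2 = d * d;
  const bool have_region = region.size() == n;

  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<long long> binkey(n);
  // +2e6 offset keeps bin indices positive so they pack into one 64-bit key
  double inv = 1.0 / d;
  for (int i = 0; i < n; ++i) {
    long long bx = (long long)std::floor(x[i] * inv) + 2000000;
    long long by = (long long)std::floor(y[i] * inv) + 2000000;
    long long key = bx * 4000000LL + by;
    binkey[i] = key;
    grid[key].push_back(i);
  }

  long long n_prox = 0;
  std::unordered_map<long long, double> K;        // gene-pair -> count
  std::unordered_map<long long, double> reg[4];   // region tallies

  for (int i = 0; i < n; ++i) {
    long long bx = binkey[i] / 4000000LL;
    long long by = binkey[i] % 4000000LL;
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        long long key = (bx + dx) * 4000000LL + (by + dy);
        std::unordered_map<long long, std::vector<int> >::iterator it =
            grid.find(key);
        if (it == grid.end()) continue;
        const std::vector<int>& bucket = it->second;
        for (size_t b = 0; b < bucket.size(); ++b) {
          int j = bucket[b];
          if (j <= i) continue;  // each unordered pair once
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy > d2) continue;
          ++n_prox;
          int gi = gene[i], gj = gene[j];
          if (gi == gj) continue;
          int a = gi < gj ? gi : gj, bb = gi < gj ? gj : gi;
          long long pk = (long long)(a - 1) * n_genes + (bb - 1);
          K[pk] += 1.0;
          if (have_region) {
            int ri = region[i], rj = region[j];
            if (ri >= 1 && ri <= 4) reg[ri - 1][pk] += 0.5;
            if (rj >= 1 && rj <= 4) reg[rj - 1][pk] += 0.5;
          }
        }
      }
    }
  }

  const int np = K.size();
  IntegerVector pi_(np), pj_(np);
  NumericVector kk(np);
  NumericMatrix rt(have_region ? np : 0, 4);
  int idx = 0;
  for (std::unordered_map<long long, double>::iterator it = K.begin();
       it != K.end(); ++it, ++idx) {
    long long pk = it->first;
    pi_[idx] = (int)(pk / n_genes) + 1;
    pj_[idx] = (int)(pk % n_genes) + 1;
    kk[idx] = it->second;
    if (have_region) {
      for (int r = 0; r < 4; ++r) {
        std::unordered_map<long long, double>::iterator rit = reg[r].find(pk);
        rt(idx, r) = (rit == reg[r].end()) ? 0.0 : rit->second;
      }
    }
  }

  return List::create(_["n_prox"] = (double)n_prox, _["pair_i"] = pi_,
                      _["pair_j"] = pj_, _["K"] = kk, _["region"] = rt);
}
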