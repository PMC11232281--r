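#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis Monte-Carlo titration over a grid of solution conditions.
// gmat: n_sites x n_cond matrix of per-site occupation free energies (meV)
//       already evaluated at each condition (solution potential / pH).
// W: symmetric n x n interaction matrix (meV), zero diagonal.
// pairs: 2 x npairs (0-based site indices) of strongly coupled pairs that get
//        joint double-flip moves in addition to single flips.
// Uses R's RNG so set.seed() in R makes runs reproducible.
// Returns mean occupancy and block-averaged standard error per site/condition.
// [[Rcpp::export]]
List mc_titrate_cpp(NumericMatrix gmat, NumericMatrix W,
                    int n_steps, int n_equil, int n_blocks, double kT,
                    IntegerMatrix pairs) {
  const int n = gmat.nrow(), ncond = gmat.ncol();
  const int npairs = pairs.ncol();
  const int nmoves = n + npairs;
  NumericMatrix mean_occ(n, ncond), se_occ(n, ncond);
  if (n_blocks < 2) stop("n_blocks must be >= 2");
  const int block_len = n_steps / n_blocks;
  if (block_len < 1) stop("n_steps too small for block averaging");
  std::vector<int> x(n);
  std::vector<double> field(n); // sum_j x_j W_ij, kept incrementally
  std::vector<double> bsum(n), bmean((std::size_t)n * n_blocks);

  for (int c = 0; c < ncond; ++c) {
    // start all reduced/deprotonated
    std::fill(x.begin(), x.end(), 0);
    std::fill(field.begin(), field.end(), 0.0);
    const int total = n_equil + block_len * n_blocks;
    int blk = 0, in_blk = 0;
    std::fill(bsum.begin(), bsum.end(), 0.0);
    for (int step = 0; step < total; ++step) {
      const int mv = (int)std::floor(unif_rand() * nmoves);
      if (mv < n) {
        const int i = mv;
        const double dG = (1 - 2 * x[i]) * (gmat(i, c) + field[i]);
        if (dG <= 0.0 || unif_rand() < std::exp(-dG / kT)) {
          const int d = 1 - 2 * x[i];
          x[i] = 1 - x[i];
          for (int j = 0; j < n; ++j) field[j] += d * W(i, j);
        }
      } else {
        const int i = pairs(0, mv - n), j = pairs(1, mv - n);
        const int di = 1 - 2 * x[i], dj = 1 - 2 * x[j];
        double dG = di * (gmat(i, c) + field[i]) +
                    dj * (gmat(j, c) + field[j]) + di * dj * W(i, j);
        if (dG <= 0.0 || unif_rand() < std::exp(-dG / kT)) {
          x[i] = 1 - x[i];
          x[j] = 1 - x[j];
          for (int k = 0; k < n; ++k) field[k] += di * W(i, k) + dj * W(j, k);
        }
      }
      if (step >= n_equil) {
        for (int i = 0; i < n; ++i) bsum[i] += x[i];
        if (++in_blk == block_len) {
          for (int i = 0; i < n; ++i) {
            bmean[i + (std::size_t)n * blk] = bsum[i] / block_len;
            bsum[i] = 0.0;
          }
          in_blk = 0;
          ++blk;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      double m = 0.0;
      for (int b = 0; b < n_blocks; ++b) m += bmean[i + (std::size_t)n * b];
      m /= n_blocks;
      double v = 0.0;
      for (int b = 0; b < n_blocks; ++b) {
        const double d = bmean[i + (std::size_t)n * b] - m;
        v += d * d;
      }
      mean_occ(i, c) = m;
      se_occ(i, c) = std::sqrt(v / (n_blocks - 1.0) / n_blocks);
    }
  }
  return List::create(_["mean"] = mean_occ, _["se"] = se_occ);
}
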