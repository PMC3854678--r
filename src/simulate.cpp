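#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Imitation kernels, matching the R-side definitions.
static inline double g_fermi(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double g_erf(double x)   { return 0.5 * std::erfc(-x); }

// Full stochastic mutation-selection process for a symmetric matrix game
// under pairwise comparison updating. One elementary step: pick a focal
// individual uniformly; with probability mu it adopts a uniformly chosen
// strategy (possibly its own), otherwise it compares payoffs with a model
// drawn uniformly from the other N - 1 individuals and adopts the model's
// strategy with probability g(beta * (pi_model - pi_focal)). Payoffs
// assume everyone interacts with everyone else, self excluded.
//
// Returns time-averaged strategy frequencies after burn-in, per-block
// frequency means (for block-bootstrap errors), and the fraction of time
// the population is monomorphic.
// [[Rcpp::export]]
List simulate_pairwise_cpp(NumericMatrix payoffs, int N, double beta,
                           double mu, double steps_d, double burnin_d,
                           std::string rule, int nblocks) {
  const int n = payoffs.nrow();
  const long long steps = (long long) steps_d;
  const long long burnin = (long long) burnin_d;
  if (payoffs.ncol() != n) stop("payoff matrix must be square");
  if (N < 2) stop("N must be at least 2");
  const bool fermi = (rule == "fermi");
  if (!fermi && rule != "erf") stop("rule must be 'fermi' or 'erf'");

  std::vector<long long> counts(n, 0);
  counts[0] = N;  // start monomorphic in strategy 1

  RNGScope scope;  // ties into R's RNG so set.seed() governs runs

  std::vector<double> occ(n, 0.0);
  std::vector<long long> mono_occ(n, 0);   // time monomorphic in each strategy
  long long mono_time = 0;
  long long switches = 0;                  // monomorphic-state changes
  int prev_mono = -1;
  const long long block_len = std::max(1LL, steps / nblocks);
  NumericMatrix block_means(nblocks, n);
  NumericMatrix block_mono(nblocks, n + 1); // per-block mono counts + total
  std::vector<double> block_acc(n, 0.0);
  std::vector<long long> block_mono_acc(n + 1, 0);
  long long in_block = 0;
  int block = 0;

  // payoff of a strategy-s individual given current counts (self excluded)
  auto payoff_of = [&](int s) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j) tot += payoffs(s, j) * counts[j];
    tot -= payoffs(s, s);
    return tot / (N - 1);
  };
  auto sample_strategy = [&](int exclude_one_of) {
    // draw an individual uniformly (optionally excluding one individual of
    // strategy exclude_one_of) and return its strategy
    double u = unif_rand() * (exclude_one_of >= 0 ? N - 1 : N);
    long long acc = 0;
    for (int s = 0; s < n; ++s) {
      long long c = counts[s] - (s == exclude_one_of ? 1 : 0);
      acc += c;
      if (u < (double) acc) return s;
    }
    return n - 1;
  };

  for (long long t = 0; t < burnin + steps; ++t) {
    int focal = sample_strategy(-1);
    if (unif_rand() < mu) {
      int to = (int) (unif_rand() * n);
      if (to == n) to = n - 1;
      counts[focal]--; counts[to]++;
    } else {
      int model = sample_strategy(focal);
      if (model != focal) {
        double dpi = payoff_of(model) - payoff_of(focal);
        double p = fermi ? g_fermi(beta * dpi) : g_erf(beta * dpi);
        if (unif_rand() < p) { counts[focal]--; counts[model]++; }
      }
    }
    if (t >= burnin) {
      for (int s = 0; s < n; ++s) {
        double f = (double) counts[s] / N;
        occ[s] += f;
        block_acc[s] += f;
        if (counts[s] == N) {
          mono_time++;
          mono_occ[s]++;
          block_mono_acc[s]++;
          block_mono_acc[n]++;
          if (prev_mono >= 0 && prev_mono != s) switches++;
          prev_mono = s;
        }
      }
      if (++in_block == block_len && block < nblocks) {
        for (int s = 0; s < n; ++s) {
          block_means(block, s) = block_acc[s] / in_block;
          block_acc[s] = 0.0;
        }
        for (int s = 0; s <= n; ++s) {
          block_mono(block, s) = (double) block_mono_acc[s];
          block_mono_acc[s] = 0;
        }
        in_block = 0;
        ++block;
      }
    }
  }

  NumericVector freq(n), mono_freq(n);
  for (int s = 0; s < n; ++s) {
    freq[s] = occ[s] / steps;
    mono_freq[s] = mono_time > 0 ? (double) mono_occ[s] / mono_time : NA_REAL;
  }
  return List::create(_["freq"] = freq,
                      _["mono_freq"] = mono_freq,
                      _["block_means"] = block_means,
                      _["block_mono"] = block_mono,
                      _["blocks_filled"] = block,
                      _["switches"] = (double) switches,
                      _["mono_fraction"] = (double) mono_time / steps);
}
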