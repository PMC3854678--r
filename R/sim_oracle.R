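#' Explicit birth-death chain for one invading strategy
#'
#' Per-state transition probabilities of the pairwise-comparison process:
#' T_plus(i) = i (N - i) / N^2 * g(beta delta_i) and
#' T_minus(i) = i (N - i) / N^2 * g(-beta delta_i). The neutral factor
#' i (N - i) / N^2 cancels from every fixation formula but is kept here so
#' this chain is the literal process, usable as an independent reference.
#'
#' @param profile a [pairwise_profile()].
#' @param rule an [imitation_rule()].
#' @return Object of class `birth_death_chain` with `N`, `T_plus`,
#'   `T_minus` (each of length N - 1).
#' @export
birth_death_chain <- function(profile, rule) {
  stopifnot(inherits(profile, "pairwise_profile"),
            inherits(rule, "imitation_rule"))
  N <- profile$N
  i <- seq_len(N - 1)
  neutral <- i * (N - i) / N^2
  x <- rule$beta * profile$delta
  structure(list(N = N,
                 T_plus = neutral * rule$g(x),
                 T_minus = neutral * rule$g(-x)),
            class = "birth_death_chain")
}

#' Absorption probability by direct linear solve
#'
#' Independent reference for the fixation probability: solves the
#' first-step equations u_i = T_plus(i) u_{i+1} + T_minus(i) u_{i-1} +
#' (1 - T_plus(i) - T_minus(i)) u_i with u_0 = 0, u_N = 1 as a dense
#' linear system and returns u_1. No product/log-space formula is used, so
#' this cross-validates [fixation_probability()] by a different derivation.
#'
#' @param chain a [birth_death_chain()] (or any list with `N`, `T_plus`,
#'   `T_minus`).
#' @return absorption probability at fixation starting from one mutant.
#' @export
solve_fixation <- function(chain) {
  N <- chain$N
  Tp <- chain$T_plus; Tm <- chain$T_minus
  if (any(Tp <= 0)) stop("interior state with T_plus = 0: chain absorbs internally")
  m <- N - 1
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (i in seq_len(m)) {
    A[i, i] <- Tp[i] + Tm[i]
    if (i > 1) A[i, i - 1] <- -Tm[i]
    if (i < m) A[i, i + 1] <- -Tp[i]
  }
  b[m] <- Tp[m]
  u <- solve(A, b)
  u[1]
}

#' Stochastic simulation of the full mutation-selection process
#'
#' Simulates the pairwise-comparison imitation process with mutation for a
#' matrix game (compiled implementation; the RNG is R's, so `set.seed()`
#' makes runs reproducible). Reports time-averaged strategy frequencies
#' with block standard errors (the chain is strongly autocorrelated, so
#' errors come from a block bootstrap over `nblocks` contiguous blocks) and
#' the fraction of time the population is monomorphic — the diagnostic for
#' the small-mutation regime in which the embedded-chain approximation is
#' valid.
#'
#' @param game a [matrix_game()].
#' @param rule an [imitation_rule()] (`"fermi"` or `"erf"`).
#' @param N population size.
#' @param mu per-step mutation probability in (0, 1). A warning is issued
#'   when `N * mu * log(N)` is not small, since the embedded-chain
#'   comparison then loses its meaning.
#' @param steps recorded steps after burn-in (>= 1e6 recommended for
#'   N <= 30).
#' @param burnin discarded initial steps.
#' @param nblocks blocks for the bootstrap.
#' @param boot bootstrap resamples.
#' @return list with `freq` (mean abundance of each strategy) and `se`;
#'   `mono_freq` (fraction of monomorphic time spent in each monomorphic
#'   state — the quantity the embedded chain's stationary distribution
#'   predicts) and `mono_se`; `mono_fraction`; `block_means`.
#' @export
simulate_stationary <- function(game, rule, N, mu = 1e-3,
                                steps = 1e7, burnin = steps / 10,
                                nblocks = 100, boot = 200) {
  stopifnot(inherits(game, "matrix_game"), inherits(rule, "imitation_rule"))
  if (!(rule$kind %in% c("fermi", "erf"))) {
    stop("the compiled simulator supports the fermi and erf rules")
  }
  if (mu <= 0 || mu >= 1) stop("mu must be in (0, 1)")
  if (N * mu * log(N) > 0.5) {
    warning("N * mu * log(N) = ", signif(N * mu * log(N), 3),
            " is not small; embedded-chain comparisons will be biased")
  }
  res <- simulate_pairwise_cpp(game$payoffs, as.integer(N), rule$beta,
                               mu, steps, burnin, rule$kind,
                               as.integer(nblocks))
  bm <- res$block_means[seq_len(res$blocks_filled), , drop = FALSE]
  bmono <- res$block_mono[seq_len(res$blocks_filled), , drop = FALSE]
  B <- nrow(bm)
  n <- ncol(bm)
  draws <- vapply(seq_len(boot), function(b) {
    pick <- sample.int(B, B, replace = TRUE)
    c(colMeans(bm[pick, , drop = FALSE]),
      colSums(bmono[pick, seq_len(n), drop = FALSE]) /
        max(1, sum(bmono[pick, n + 1])))
  }, numeric(2 * n))
  se <- apply(draws, 1, stats::sd)
  list(freq = stats::setNames(as.numeric(res$freq), game$strategies),
       se = stats::setNames(se[seq_len(n)], game$strategies),
       mono_freq = stats::setNames(as.numeric(res$mono_freq), game$strategies),
       mono_se = stats::setNames(se[n + seq_len(n)], game$strategies),
       mono_fraction = res$mono_fraction,
       switches = res$switches,
       block_means = bm)
}
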