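# Brute-force payoff oracle for matrix games: list every individual, make it
# play every other individual once, average.
enumerate_matrix_payoffs <- function(payoffs, A, B, i, N) {
  pop <- c(rep(A, i), rep(B, N - i))
  per_ind <- vapply(seq_len(N), function(f) {
    mean(payoffs[pop[f], pop[-f]])
  }, numeric(1))
  c(pi_A = mean(per_ind[seq_len(i)]), pi_B = mean(per_ind[i + seq_len(N - i)]))
}

# Exhaustive group-formation oracle for multiplayer tables: average the focal
# payoff over all choose(N-1, d-1) co-player subsets.
enumerate_group_payoff <- function(tab, focal_is_A, i, N) {
  pop <- c(rep(1L, i), rep(0L, N - i))  # 1 = A
  focal <- if (focal_is_A) 1L else i + 1L
  others <- setdiff(seq_len(N), focal)
  groups <- utils::combn(others, tab$d - 1)
  mean(apply(groups, 2, function(gr) {
    k <- sum(pop[gr])
    if (focal_is_A) tab$a[k + 1] else tab$b[k + 1]
  }))
}

# A random pairwise profile of the given size (payoffs attached so the
# linear Moran map is usable when entries are positive).
random_profile <- function(N, positive = FALSE) {
  pi_A <- if (positive) runif(N - 1, 0.1, 2) else rnorm(N - 1)
  pi_B <- if (positive) runif(N - 1, 0.1, 2) else rnorm(N - 1)
  pairwise_profile(N, pi_A = pi_A, pi_B = pi_B)
}

# Random (profile, rule) pair inside the dense absorbing-chain solve's
# validity domain: that oracle's linear system has condition number growing
# like e^(cumulative log-ratio span), so absolute agreement at 1e-10
# requires the span to stay below roughly a dozen e-folds. The log-space
# implementation itself has no such limit.
random_bounded_instance <- function(N, beta, max_efolds = 12) {
  repeat {
    prof <- random_profile(N)
    rule <- imitation_rule(sample(c("fermi", "erf"), 1), beta = beta)
    S <- cumsum(rule$log_g(-beta * prof$delta) - rule$log_g(beta * prof$delta))
    if (max(abs(S)) <= max_efolds) return(list(profile = prof, rule = rule))
  }
}
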