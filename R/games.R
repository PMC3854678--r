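#' Symmetric two-player matrix game
#'
#' Container for an n-strategy symmetric game. Entry `payoffs[i, j]` is the
#' payoff to a player using strategy `i` against an opponent using strategy
#' `j`.
#'
#' @param payoffs square numeric matrix (n >= 2), all entries finite.
#' @param strategies optional character vector of strategy names; defaults to
#'   the matrix dimnames or `"S1"`, `"S2"`, ...
#' @return An object of class `matrix_game` with elements `payoffs`,
#'   `strategies` and `n`.
#' @examples
#' g <- matrix_game(rbind(c(3, 0), c(5, 1)), strategies = c("C", "D"))
#' g$n
#' @export
matrix_game <- function(payoffs, strategies = NULL) {
  payoffs <- as.matrix(payoffs)
  if (!is.numeric(payoffs)) stop("payoff entries must be numeric")
  if (nrow(payoffs) != ncol(payoffs)) {
    stop("payoff matrix must be square, got ", nrow(payoffs), "x", ncol(payoffs))
  }
  n <- nrow(payoffs)
  if (n < 2) stop("a game needs at least 2 strategies")
  if (!all(is.finite(payoffs))) stop("all payoff entries must be finite")
  if (is.null(strategies)) {
    strategies <- rownames(payoffs)
    if (is.null(strategies)) strategies <- paste0("S", seq_len(n))
  }
  if (length(strategies) != n) stop("need one name per strategy")
  dimnames(payoffs) <- list(strategies, strategies)
  structure(list(payoffs = payoffs, strategies = strategies, n = n),
            class = "matrix_game")
}

#' @export
print.matrix_game <- function(x, ...) {
  cat("Symmetric 2-player game with", x$n, "strategies\n")
  print(x$payoffs)
  invisible(x)
}

#' d-player two-strategy payoff table
#'
#' Payoffs for a group game between two types A and B, indexed by the number
#' of A-players among the d - 1 co-players of the focal individual:
#' `a[k + 1]` is the payoff to an A-player with `k` A co-players and
#' `b[k + 1]` the payoff to a B-player with `k` A co-players, k = 0..d-1.
#'
#' @param a,b numeric vectors of equal length d >= 2, finite entries.
#' @return Object of class `multiplayer_table` with elements `a`, `b`, `d`.
#' @export
multiplayer_table <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have the same length d")
  d <- length(a)
  if (d < 2) stop("group size d must be at least 2")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("payoffs must be finite")
  structure(list(a = a, b = b, d = d), class = "multiplayer_table")
}

#' Swap the roles of the two types in a multiplayer table
#'
#' If `tab` describes types (A, B), the result describes (B, A): a B-player
#' with k B co-players faces d - 1 - k A co-players.
#'
#' @param tab a [multiplayer_table()].
#' @return the reversed `multiplayer_table`.
#' @export
reverse_table <- function(tab) {
  stopifnot(inherits(tab, "multiplayer_table"))
  multiplayer_table(a = rev(tab$b), b = rev(tab$a))
}

#' Bundle of pairwise multiplayer tables for n strategies
#'
#' In the rare-mutation regime only two strategies ever coexist, so an
#' n-strategy d-player game is specified by one [multiplayer_table()] per
#' unordered strategy pair.
#'
#' @param tables named list of `multiplayer_table` objects; names must be
#'   `"A-B"` with `A`, `B` strategy names, one entry per unordered pair.
#' @param strategies character vector of strategy names.
#' @return Object of class `multiplayer_game`.
#' @export
multiplayer_game <- function(tables, strategies) {
  n <- length(strategies)
  if (n < 2) stop("need at least 2 strategies")
  d <- unique(vapply(tables, function(t) t$d, integer(1)))
  if (length(d) != 1) stop("all tables must share the same group size d")
  need <- utils::combn(strategies, 2, paste, collapse = "-")
  have <- names(tables)
  for (key in need) {
    parts <- strsplit(key, "-", fixed = TRUE)[[1]]
    rkey <- paste(rev(parts), collapse = "-")
    if (!(key %in% have) && !(rkey %in% have)) {
      stop("missing table for strategy pair ", key)
    }
  }
  structure(list(tables = tables, strategies = strategies, n = n, d = d),
            class = "multiplayer_game")
}

#' @export
print.multiplayer_game <- function(x, ...) {
  cat("d-player game: d =", x$d, ", strategies:",
      paste(x$strategies, collapse = ", "), "\n")
  invisible(x)
}

# Table for the ordered pair (A, B), reversing a stored (B, A) table if needed.
pair_table <- function(game, A, B) {
  key <- paste(A, B, sep = "-")
  if (!is.null(game$tables[[key]])) return(game$tables[[key]])
  rkey <- paste(B, A, sep = "-")
  if (!is.null(game$tables[[rkey]])) return(reverse_table(game$tables[[rkey]]))
  stop("no table for pair ", A, "/", B)
}

#' Pairwise invasion profile
#'
#' The payoff-difference sequence for a mutant strategy A against a resident
#' B in a population of size N: `delta[i]` is pi_A(i) - pi_B(i) when there
#' are i mutants, i = 1..N-1. This is the universal input to all fixation
#' computations.
#'
#' @param N population size (>= 2).
#' @param delta numeric vector of length N - 1, finite.
#' @param pi_A,pi_B optional per-state payoffs (needed for the Moran process
#'   with a linear payoff-to-fitness map, where absolute payoffs matter).
#' @return Object of class `pairwise_profile`.
#' @export
pairwise_profile <- function(N, delta = NULL, pi_A = NULL, pi_B = NULL) {
  N <- as.integer(N)
  if (N < 2) stop("population size N must be at least 2")
  if (is.null(delta)) {
    if (is.null(pi_A) || is.null(pi_B)) stop("supply delta or both pi_A and pi_B")
    delta <- pi_A - pi_B
  }
  if (length(delta) != N - 1) stop("delta must have length N - 1")
  if (!all(is.finite(delta))) stop("delta entries must be finite")
  structure(list(N = N, delta = as.numeric(delta),
                 pi_A = pi_A, pi_B = pi_B),
            class = "pairwise_profile")
}

#' Reduce a matrix game to a pairwise invasion profile
#'
#' With i mutants of strategy A among N players and everyone interacting
#' with everyone else (self-interaction excluded), average payoffs are
#' pi_A(i) = (a_AA (i-1) + a_AB (N-i)) / (N-1) and
#' pi_B(i) = (a_BA i + a_BB (N-i-1)) / (N-1).
#'
#' @param game a [matrix_game()].
#' @param A,B distinct strategy indices or names (mutant A, resident B).
#' @param N population size.
#' @return a [pairwise_profile()] carrying `delta`, `pi_A` and `pi_B`.
#' @export
matrix_pair_profile <- function(game, A, B, N) {
  stopifnot(inherits(game, "matrix_game"))
  A <- strategy_index(game, A); B <- strategy_index(game, B)
  if (A == B) stop("mutant and resident strategies must differ")
  N <- as.integer(N)
  if (N < 2) stop("population size N must be at least 2")
  i <- seq_len(N - 1)
  p <- game$payoffs
  pi_A <- (p[A, A] * (i - 1) + p[A, B] * (N - i)) / (N - 1)
  pi_B <- (p[B, A] * i + p[B, B] * (N - i - 1)) / (N - 1)
  pairwise_profile(N, pi_A = pi_A, pi_B = pi_B)
}

strategy_index <- function(game, s) {
  if (is.character(s)) {
    idx <- match(s, game$strategies)
    if (is.na(idx)) stop("unknown strategy: ", s)
    return(idx)
  }
  s <- as.integer(s)
  if (s < 1 || s > game$n) stop("strategy index out of range: ", s)
  s
}

#' Reduce a d-player two-strategy game to a pairwise invasion profile
#'
#' Groups of size d are formed by sampling co-players without replacement
#' from the remaining N - 1 individuals, so the number of A co-players of a
#' focal player is hypergeometric. With i mutants,
#' pi_A(i) = sum_k H(k; i-1, N-i, d-1) a_k and
#' pi_B(i) = sum_k H(k; i, N-i-1, d-1) b_k.
#'
#' @param table a [multiplayer_table()].
#' @param N population size (>= d).
#' @return a [pairwise_profile()].
#' @export
multiplayer_pair_profile <- function(table, N) {
  stopifnot(inherits(table, "multiplayer_table"))
  N <- as.integer(N)
  d <- table$d
  if (N < d) stop("population size N must be at least the group size d")
  i <- seq_len(N - 1)
  pi_A <- numeric(N - 1)
  pi_B <- numeric(N - 1)
  # dhyper computes the weights through lgamma internally, so this stays
  # exact in the tails for N up to 1e4.
  for (k in 0:(d - 1)) {
    pi_A <- pi_A + stats::dhyper(k, i - 1, N - i, d - 1) * table$a[k + 1]
    pi_B <- pi_B + stats::dhyper(k, i, N - i - 1, d - 1) * table$b[k + 1]
  }
  pairwise_profile(N, pi_A = pi_A, pi_B = pi_B)
}

#' Mirror a pairwise profile
#'
#' Exchanges the roles of mutant and resident:
#' delta_BA(i) = -delta_AB(N - i).
#'
#' @param profile a [pairwise_profile()].
#' @return the mirrored `pairwise_profile`.
#' @export
mirror_profile <- function(profile) {
  stopifnot(inherits(profile, "pairwise_profile"))
  N <- profile$N
  rev_or_null <- function(v) if (is.null(v)) NULL else rev(v)
  pairwise_profile(N,
                   delta = -rev(profile$delta),
                   pi_A = rev_or_null(profile$pi_B),
                   pi_B = rev_or_null(profile$pi_A))
}

#' Payoff in a public goods game with punishment
#'
#' Group of size d with `nc` cooperators, `nd` defectors and `np` punishers.
#' Contributors (cooperators and punishers) each put `c` into the pool; the
#' pool is multiplied by `r` and shared equally among all d members.
#' Punishers additionally pay `punish_cost` per defector; defectors are
#' fined `fine` per punisher.
#'
#' @param strat one of `"C"`, `"D"`, `"P"` (the focal player's strategy).
#' @param nc,nd,np group composition including the focal player.
#' @param d group size; must equal `nc + nd + np`.
#' @param r pool multiplication factor.
#' @param c contribution cost.
#' @param fine fine per punisher imposed on each defector.
#' @param punish_cost cost per defector paid by each punisher.
#' @return the focal player's payoff.
#' @export
pgg_payoff <- function(strat, nc, nd, np, d, r, c, fine, punish_cost) {
  if (nc + nd + np != d) stop("group composition must sum to d")
  pool <- r * c * (nc + np) / d
  switch(strat,
         C = pool - c,
         D = pool - fine * np,
         P = pool - c - punish_cost * nd,
         stop("strategy must be one of C, D, P"))
}

#' Public goods game with punishment as a 3-strategy multiplayer game
#'
#' Cooperators (C) contribute to a common pool, defectors (D) free-ride,
#' punishers (P) contribute and additionally fine defectors at a cost to
#' themselves. Returns the pairwise invasion tables for the ordered pairs
#' (C, D), (C, P) and (D, P), bundled as a [multiplayer_game()].
#'
#' @param d group size (>= 2).
#' @param r pool multiplication factor; a warning is issued unless 1 < r < d
#'   (outside that range the public goods dilemma degenerates).
#' @param c contribution cost (> 0).
#' @param fine fine per punisher imposed on each defector (>= 0).
#' @param punish_cost cost per defector paid by each punisher (>= 0).
#' @return a `multiplayer_game` with strategies C, D, P; its `tables` hold
#'   the (C,D), (C,P) and (D,P) payoff tables.
#' @examples
#' g <- pgg_punishment_game(d = 5, r = 3, c = 1, fine = 1, punish_cost = 0.3)
#' g$tables[["C-D"]]$a  # cooperator payoffs vs defectors
#' @export
pgg_punishment_game <- function(d, r, c, fine = 0, punish_cost = 0) {
  d <- as.integer(d)
  if (d < 2) stop("group size d must be at least 2")
  if (c <= 0) stop("contribution cost c must be positive")
  if (fine < 0 || punish_cost < 0) stop("fine and punish_cost must be >= 0")
  if (r <= 1 || r >= d) {
    warning("r outside (1, d): the public goods game is degenerate")
  }
  k <- 0:(d - 1)
  tab <- function(sa, sb) {
    # k = number of A co-players of the focal individual
    a <- vapply(k, function(kk) {
      n_of <- c(A = kk + 1, B = d - 1 - kk)
      counts <- c(C = 0, D = 0, P = 0)
      counts[sa] <- n_of[["A"]]; counts[sb] <- n_of[["B"]]
      pgg_payoff(sa, counts[["C"]], counts[["D"]], counts[["P"]],
                 d, r, c, fine, punish_cost)
    }, numeric(1))
    b <- vapply(k, function(kk) {
      n_of <- c(A = kk, B = d - kk)
      counts <- c(C = 0, D = 0, P = 0)
      counts[sa] <- n_of[["A"]]; counts[sb] <- n_of[["B"]]
      pgg_payoff(sb, counts[["C"]], counts[["D"]], counts[["P"]],
                 d, r, c, fine, punish_cost)
    }, numeric(1))
    multiplayer_table(a, b)
  }
  multiplayer_game(
    tables = list("C-D" = tab("C", "D"),
                  "C-P" = tab("C", "P"),
                  "D-P" = tab("D", "P")),
    strategies = c("C", "D", "P"))
}
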