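#' Selection-intensity grid
#'
#' @param from,to positive endpoints (`from < to`).
#' @param n number of grid points (>= 2).
#' @param scale `"log"` (default; rank changes typically spread over orders
#'   of magnitude of beta) or `"linear"`.
#' @return Object of class `beta_grid` with `values`, `beta_max`, `scale`.
#' @export
beta_grid <- function(from = 1e-3, to = 1e3, n = 200, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (from <= 0 || to <= from) stop("need 0 < from < to")
  values <- if (scale == "log") {
    exp(seq(log(from), log(to), length.out = n))
  } else {
    seq(from, to, length.out = n)
  }
  structure(list(values = values, beta_max = to, scale = scale),
            class = "beta_grid")
}

#' Largest usable selection intensity
#'
#' Finds, by doubling and bisection to 1% relative precision, the largest
#' beta <= cap at which every pairwise fixation computation for the game
#' returns finite log-domain values. For rules evaluated in pure log space
#' (Fermi imitation, exponential Moran) nothing overflows and the cap is
#' returned immediately; a linear Moran map with negative payoffs has a
#' genuine validity boundary which this locates.
#'
#' @param game a [matrix_game()] or [multiplayer_game()].
#' @param process an [imitation_rule()] or [fitness_map()].
#' @param N population size.
#' @param cap upper bound on the returned value (> 0).
#' @param precision relative bisection precision.
#' @return the adjusted beta_max.
#' @export
adaptive_beta_max <- function(game, process, N, cap = 1e3, precision = 0.01) {
  if (cap <= 0) stop("cap must be positive")
  ok <- function(beta) {
    tryCatch({
      lrs <- log_rho_matrices(game, process, N, beta)[[1]]
      all(is.finite(lrs[row(lrs) != col(lrs)]))
    }, error = function(e) FALSE)
  }
  if (ok(cap)) return(cap)
  lo <- min(1e-6, cap)
  if (!ok(lo)) stop("fixation computation overflows already at beta = 1e-6; degenerate game")
  hi <- lo
  while (hi < cap) {
    hi <- min(2 * hi, cap)
    if (!ok(hi)) break
    lo <- hi
  }
  while ((hi - lo) / lo > precision) {
    mid <- sqrt(lo * hi)
    if (ok(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Stationary abundance curve over a selection-intensity grid
#'
#' Computes the stationary distribution of the embedded monomorphic-state
#' chain at every grid point. Pairwise fixation probabilities are evaluated
#' in log space across the whole grid in one pass per strategy pair. For up
#' to 7 strategies the stationary vector is evaluated by the exact
#' log-domain Markov-chain-tree formula, which stays accurate (and
#' label-equivariant) at selection strengths where fixation probabilities
#' underflow and a direct linear solve degrades; beyond 7 strategies the
#' linear solve is used while well conditioned.
#'
#' @param game a [matrix_game()] or [multiplayer_game()].
#' @param process an [imitation_rule()] or [fitness_map()].
#' @param N population size.
#' @param grid a [beta_grid()] (or numeric vector of betas).
#' @return Object of class `abundance_curve`: `beta`, `x` (grid x n matrix,
#'   each row on the simplex), `method` (per-point solver used), plus the
#'   generating `game`, `process`, `N` for refinement.
#' @export
sweep_abundance <- function(game, process, N, grid = beta_grid()) {
  betas <- if (inherits(grid, "beta_grid")) grid$values else as.numeric(grid)
  lrs <- log_rho_matrices(game, process, N, betas)
  n <- game$n
  meth <- if (n <= 7) "logtree" else "auto"
  x <- matrix(NA_real_, length(betas), n)
  method <- character(length(betas))
  for (t in seq_along(betas)) {
    lr <- lrs[[t]]
    if (any(!is.finite(lr[row(lr) != col(lr)]))) {
      overflow_error(paste0("fixation overflow at beta = ", betas[t],
                            "; restrict the grid to adaptive_beta_max"))
    }
    xt <- stationary_logdomain(lr, meth)
    method[t] <- attr(xt, "method")
    x[t, ] <- xt
  }
  colnames(x) <- game$strategies
  structure(list(beta = betas, x = x, method = method,
                 game = game, process = process, N = N,
                 strategies = game$strategies),
            class = "abundance_curve")
}

#' @export
print.abundance_curve <- function(x, ...) {
  cat("abundance curve:", length(x$beta), "grid points, beta in [",
      signif(min(x$beta), 3), ",", signif(max(x$beta), 3), "], strategies:",
      paste(x$strategies, collapse = ", "), "\n")
  invisible(x)
}

#' Detect rank changes along an abundance curve
#'
#' A rank change between strategies i and j is a sign change of
#' x_i(beta) - x_j(beta) between consecutive grid points, with the
#' difference exceeding `tol` in magnitude on both sides. Each crossing is
#' refined by bisection on beta (recomputing full stationary distributions,
#' no interpolation) to relative precision 1e-6. Grid values within `tol`
#' of a tie are flagged degenerate and never counted; tangencies without a
#' sign change are not crossings.
#'
#' @param curve an [sweep_abundance()] result.
#' @param tol absolute tie tolerance on abundance differences.
#' @return Object of class `rank_change_report`: `events` (data frame with
#'   columns `i`, `j`, `beta_lo`, `beta_hi`, `beta_star`, `direction` = the
#'   strategy that overtakes, `top_change`), `total_count`, `top_changes`,
#'   and `degenerate` (count of flagged grid values).
#' @export
detect_crossings <- function(curve, tol = 1e-10) {
  stopifnot(inherits(curve, "abundance_curve"))
  betas <- curve$beta
  if (length(betas) < 2) stop("grid needs at least 2 points")
  n <- ncol(curve$x)
  events <- list()
  degenerate <- 0L
  diff_at <- function(beta, i, j) {
    xb <- abundance_at(curve$game, curve$process, curve$N, beta)[1, ]
    xb[i] - xb[j]
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- curve$x[, i] - curve$x[, j]
    near <- abs(d) <= tol
    degenerate <- degenerate + sum(near)
    for (t in seq_len(length(betas) - 1)) {
      if (near[t] || near[t + 1]) next
      if (sign(d[t]) * sign(d[t + 1]) < 0) {
        lo <- betas[t]; hi <- betas[t + 1]
        flo <- d[t]
        while ((hi - lo) / ((hi + lo) / 2) > 1e-6) {
          mid <- (lo + hi) / 2
          fm <- diff_at(mid, i, j)
          if (fm == 0) { lo <- mid; hi <- mid; break }
          if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
        }
        bstar <- (lo + hi) / 2
        overtaker <- if (d[t] > 0) j else i
        xstar <- abundance_at(curve$game, curve$process, curve$N, bstar)[1, ]
        top <- max(xstar[-c(i, j)], -Inf) < max(xstar[i], xstar[j])
        events[[length(events) + 1]] <- data.frame(
          i = i, j = j, beta_lo = betas[t], beta_hi = betas[t + 1],
          beta_star = bstar, direction = overtaker, top_change = top)
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(i = integer(), j = integer(), beta_lo = numeric(),
               beta_hi = numeric(), beta_star = numeric(),
               direction = integer(), top_change = logical())
  structure(list(events = events,
                 total_count = nrow(events),
                 top_changes = sum(events$top_change),
                 degenerate = degenerate,
                 strategies = curve$strategies),
            class = "rank_change_report")
}

#' @export
print.rank_change_report <- function(x, ...) {
  cat("rank changes:", x$total_count,
      "( most-abundant-strategy changes:", x$top_changes, ")\n")
  if (x$total_count > 0) {
    ev <- x$events
    for (r in seq_len(nrow(ev))) {
      cat(sprintf("  %s overtakes %s at beta* = %.6g\n",
                  x$strategies[ev$direction[r]],
                  x$strategies[ifelse(ev$direction[r] == ev$i[r], ev$j[r], ev$i[r])],
                  ev$beta_star[r]))
    }
  }
  if (x$degenerate > 0) cat("  degenerate (near-tie) grid values:", x$degenerate, "\n")
  invisible(x)
}

# Fast screen for 2-strategy games: x_1(beta) > 1/2 iff
# log rho_{1 in 2} - log rho_{2 in 1} > 0, and that log ratio equals
# -S_{N-1}(beta), the negated full sum of log transition ratios. Returns
# the sign curve of x_1 - 1/2 over `betas`.
two_strategy_sign_curve <- function(process, profile, betas) {
  L <- loggamma_matrix(process, profile, betas)
  if (is.null(dim(L))) L <- matrix(L, nrow = length(betas))
  -rowSums(L)
}

#' Search for a multiplayer game whose ranking depends on the imitation rule
#'
#' Randomly samples d-player two-strategy payoff tables (i.i.d. standard
#' Gaussian entries) until one is found whose abundance ranking never
#' changes under the Fermi rule (which holds for every two-strategy game)
#' but changes at least once under the error-function rule. Candidates
#' located by a cheap sign screen are verified through the full sweep and
#' crossing detector, then re-verified on a 10x denser grid.
#'
#' @param d group size (2 or more). With `d = 2` the search is expected to
#'   fail: ranking invariance holds for two-player two-strategy games under
#'   any imitation function.
#' @param N population size.
#' @param attempts maximum number of sampled tables.
#' @param beta_cap upper end of the selection-intensity grid.
#' @param n_grid verification grid size (screen uses `n_grid`, dense check
#'   `10 * n_grid`).
#' @return list with `found`, and when found: `game` (a
#'   [multiplayer_game()] with strategies A, B), `table`, `N`,
#'   `report_fermi`, `report_erf` (dense-grid reports), `attempt`.
#' @export
find_fig2_game <- function(d = 3, N = 50, attempts = 10000,
                           beta_cap = 1e3, n_grid = 200) {
  screen_betas <- beta_grid(1e-3, beta_cap, n = 60)$values
  erf_rule <- imitation_rule("erf", beta = 1)
  fermi_rule <- imitation_rule("fermi", beta = 1)
  for (att in seq_len(attempts)) {
    tab <- multiplayer_table(stats::rnorm(d), stats::rnorm(d))
    prof <- multiplayer_pair_profile(tab, N)
    sgn <- two_strategy_sign_curve(erf_rule, prof, screen_betas)
    if (any(!is.finite(sgn))) next
    s <- sign(sgn[abs(sgn) > 1e-12])
    if (length(s) < 2 || all(s == s[1])) next
    # candidate: verify with the general machinery
    game <- multiplayer_game(list("A-B" = tab), strategies = c("A", "B"))
    grid <- beta_grid(1e-3, beta_cap, n = n_grid)
    rep_f <- detect_crossings(sweep_abundance(game, fermi_rule, N, grid))
    rep_e <- detect_crossings(sweep_abundance(game, erf_rule, N, grid))
    if (rep_f$total_count == 0 && rep_e$total_count >= 1) {
      dense <- beta_grid(1e-3, beta_cap, n = 10 * n_grid)
      rep_fd <- detect_crossings(sweep_abundance(game, fermi_rule, N, dense))
      rep_ed <- detect_crossings(sweep_abundance(game, erf_rule, N, dense))
      if (rep_fd$total_count == 0 && rep_ed$total_count >= 1) {
        return(list(found = TRUE, game = game, table = tab, N = N,
                    report_fermi = rep_fd, report_erf = rep_ed,
                    attempt = att))
      }
    }
  }
  list(found = FALSE, attempt = attempts)
}

#' Search for a matrix game with hidden intermediate-selection rank changes
#'
#' Randomly samples n-strategy two-player payoff matrices (i.i.d.
#' Uniform(0,1) entries) until one is found whose weak-selection ranking
#' coincides with its strong-selection ranking and yet whose abundance
#' curves cross at least twice at intermediate selection intensities — the
#' ordering leaves the limiting ranking and returns to it. Candidates are
#' screened by comparing the orderings at the grid endpoints, then verified
#' by the full sweep, the weak-selection derivative ranking and a 10x
#' denser grid.
#'
#' @param n number of strategies.
#' @param N population size.
#' @param attempts maximum number of sampled games.
#' @param beta_cap upper end of the grid.
#' @param n_grid sweep grid size.
#' @return list with `found`, and when found: `game`, `N`, `report` (dense
#'   grid), `weak` (weak-selection ranking), `ordering_strong`, `attempt`.
#' @export
find_theorem1_game <- function(n = 3, N = 50, attempts = 10000,
                               beta_cap = 1e3, n_grid = 200) {
  rule <- imitation_rule("fermi", beta = 1)
  for (att in seq_len(attempts)) {
    game <- matrix_game(matrix(stats::runif(n * n), n, n))
    ends <- abundance_at(game, rule, N, c(1e-3, beta_cap))
    o_weak <- order(ends[1, ], decreasing = TRUE)
    o_strong <- order(ends[2, ], decreasing = TRUE)
    if (!identical(o_weak, o_strong)) next
    if (min(abs(diff(sort(ends[1, ])))) < 1e-9) next  # ties: skip
    grid <- beta_grid(1e-3, beta_cap, n = n_grid)
    rep1 <- detect_crossings(sweep_abundance(game, rule, N, grid))
    if (rep1$total_count < 2) next
    weak <- weak_selection_ranking(game, rule, N)
    if (weak$ties || !identical(weak$ordering, o_strong)) next
    dense <- beta_grid(1e-3, beta_cap, n = 10 * n_grid)
    repd <- detect_crossings(sweep_abundance(game, rule, N, dense))
    if (repd$total_count >= 2) {
      return(list(found = TRUE, game = game, N = N, report = repd,
                  weak = weak, ordering_strong = o_strong, attempt = att))
    }
  }
  list(found = FALSE, attempt = attempts)
}
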