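#' All pairwise fixation probabilities of a game
#'
#' For every ordered strategy pair (j, i) the game is reduced to a pairwise
#' invasion profile and the fixation probability of a single j-mutant in a
#' resident-i population is computed. Entry `rho[j, i]` is that
#' probability; `log_rho` carries the same information in log space, which
#' remains finite long after `rho` underflows double precision.
#'
#' @param game a [matrix_game()] or [multiplayer_game()].
#' @param process an [imitation_rule()] or [fitness_map()].
#' @param N population size.
#' @param beta selection intensity; defaults to `process$beta`.
#' @return Object of class `fixation_matrix`: `rho`, `log_rho` (n x n,
#'   diagonal `NA`), `n`, `N`, `beta`, `strategies`.
#' @export
build_fixation_matrix <- function(game, process, N, beta = process$beta) {
  lr <- log_rho_matrices(game, process, N, beta)[[1]]
  if (any(!is.finite(lr[row(lr) != col(lr)]))) {
    bad <- which(!is.finite(lr) & row(lr) != col(lr), arr.ind = TRUE)[1, ]
    overflow_error(paste0("fixation overflow for mutant ", bad[1],
                          " in resident ", bad[2], " at beta = ", beta))
  }
  structure(list(rho = exp(lr), log_rho = lr, n = nrow(lr), N = N,
                 beta = beta, strategies = rownames(lr)),
            class = "fixation_matrix")
}

# Internal: list over betas of n x n log-fixation matrices (entry [j, i] is
# log rho of a j-mutant in resident i). Shared by build_fixation_matrix and
# the sweep; the per-pair beta vectorization happens here.
log_rho_matrices <- function(game, process, N, betas) {
  strategies <- game$strategies
  n <- game$n
  nb <- length(betas)
  out <- array(NA_real_, dim = c(nb, n, n))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      prof <- invasion_profile(game, j, i, N)
      out[, j, i] <- pair_log_rho(process, prof, betas)
    }
  }
  lapply(seq_len(nb), function(t) {
    m <- matrix(out[t, , ], n, n)
    dimnames(m) <- list(strategies, strategies)
    m
  })
}

# Profile of a j-mutant invading resident i for either game class.
invasion_profile <- function(game, mutant, resident, N) {
  if (inherits(game, "matrix_game")) {
    return(matrix_pair_profile(game, mutant, resident, N))
  }
  if (inherits(game, "multiplayer_game")) {
    A <- game$strategies[mutant]; B <- game$strategies[resident]
    return(multiplayer_pair_profile(pair_table(game, A, B), N))
  }
  stop("game must be a matrix_game or multiplayer_game")
}

#' Embedded Markov chain over monomorphic states
#'
#' In the rare-mutation limit the population hops between monomorphic
#' states; from state i a mutant of one of the other n - 1 strategies
#' appears (uniformly) and fixes with its pairwise fixation probability:
#' Lambda[i, j] = rho[j, i] / (n - 1) for j != i.
#'
#' @param fm a [build_fixation_matrix()] result.
#' @return Object of class `embedded_chain` holding the transition matrix
#'   `Lambda` (rows sum to 1) and the log off-diagonal part `log_Lambda`.
#' @export
build_chain <- function(fm) {
  stopifnot(inherits(fm, "fixation_matrix"))
  n <- fm$n
  Lambda <- t(fm$rho) / (n - 1)
  diag(Lambda) <- 0
  diag(Lambda) <- 1 - rowSums(Lambda)
  log_Lambda <- t(fm$log_rho) - log(n - 1)
  structure(list(Lambda = Lambda, log_Lambda = log_Lambda, n = n,
                 N = fm$N, beta = fm$beta, strategies = fm$strategies),
            class = "embedded_chain")
}

#' Stationary distribution of the embedded chain
#'
#' Solves x Lambda = x, sum(x) = 1. The default path appends the
#' normalization row to the rank-deficient linear system and solves it
#' directly; when fixation probabilities underflow double precision (strong
#' selection) the same quantity is evaluated exactly in log space through
#' the Markov chain tree theorem (`method = "logtree"`, n <= 7). An
#' eigenvector route is provided for cross-checking.
#'
#' @param chain an [build_chain()] result.
#' @param method `"auto"`, `"solve"`, `"eigen"` or `"logtree"`.
#' @return named numeric vector on the simplex, with attributes `beta` and
#'   `method`.
#' @export
stationary <- function(chain, method = c("auto", "solve", "eigen", "logtree")) {
  stopifnot(inherits(chain, "embedded_chain"))
  method <- match.arg(method)
  x <- stationary_logdomain(t(chain$log_Lambda) + log(chain$n - 1), method)
  names(x) <- chain$strategies
  attr(x, "beta") <- chain$beta
  x
}

# log_rho: n x n matrix, [j, i] = log fixation of j-mutant in resident i.
stationary_logdomain <- function(log_rho, method = "auto") {
  n <- nrow(log_rho)
  if (method %in% c("solve", "eigen") ||
      (method == "auto" && all(log_rho[row(log_rho) != col(log_rho)] >
                               log(1e-250)))) {
    rho <- exp(log_rho)
    O <- t(rho) / (n - 1)         # off-diagonal Lambda
    diag(O) <- 0
    if (method == "eigen") {
      L <- O; diag(L) <- 1 - rowSums(O)
      e <- eigen(t(L))
      k <- which.min(abs(e$values - 1))
      v <- Re(e$vectors[, k])
      x <- v / sum(v)
    } else {
      A <- t(O)
      diag(A) <- -rowSums(O)      # generator transpose, no cancellation
      A[n, ] <- 1
      b <- c(rep(0, n - 1), 1)
      x <- tryCatch(solve(A, b), error = function(e) rep(NaN, n))
    }
    if (all(is.finite(x)) && min(x) > -1e-10 && abs(sum(x) - 1) < 1e-8) {
      x <- pmax(x, 0)
      x <- x / sum(x)
      attr(x, "method") <- if (method == "eigen") "eigen" else "solve"
      return(x)
    }
    if (method != "auto") stop("stationary solve failed; chain may be reducible")
  }
  x <- stationary_logtree(log_rho)
  attr(x, "method") <- "logtree"
  x
}

# Markov chain tree theorem evaluated with log-sum-exp: x_i is proportional
# to the sum over spanning trees rooted at i of the product of edge weights
# Lambda_{u -> v} = rho[v, u] / (n - 1); the constant factor cancels.
stationary_logtree <- function(log_rho) {
  n <- nrow(log_rho)
  if (n > 7) stop("logtree stationary limited to n <= 7")
  idx <- tree_index(n)
  w <- vapply(seq_len(n), function(r) {
    tw <- rowSums(matrix(log_rho[as.vector(idx[[r]])], nrow = nrow(idx[[r]])))
    m <- max(tw)
    m + log(sum(exp(tw - m)))
  }, numeric(1))
  x <- exp(w - max(w))
  x / sum(x)
}

# Cache of, for each root r, an (n^(n-2)) x (n-1) matrix of linear indices
# into an n x n matrix: entry for oriented edge u -> v indexes [v, u].
.tree_cache <- new.env(parent = emptyenv())

tree_index <- function(n) {
  n <- as.integer(n)
  key <- as.character(n)
  if (!is.null(.tree_cache[[key]])) return(.tree_cache[[key]])
  trees <- spanning_trees(n)
  idx <- lapply(seq_len(n), function(root) {
    t(vapply(trees, function(edges) {
      par <- orient_to_root(edges, n, root)
      u <- setdiff(seq_len(n), root)
      v <- par[u]
      (u - 1L) * n + as.integer(v)   # column-major index of [v, u]
    }, integer(n - 1)))
  })
  .tree_cache[[key]] <- idx
  idx
}

# All labeled spanning trees of the complete graph on n nodes, via Pruefer
# sequences; each tree is a 2 x (n-1) matrix of undirected edges.
spanning_trees <- function(n) {
  if (n == 2) return(list(matrix(c(1L, 2L), 2, 1)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  lapply(seq_len(nrow(seqs)), function(s) prufer_decode(as.integer(seqs[s, ]), n))
}

prufer_decode <- function(code, n) {
  degree <- rep(1L, n)
  for (v in code) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, 2, n - 1)
  ptr <- 0L
  for (v in code) {
    leaf <- which(degree == 1L)[1]
    ptr <- ptr + 1L
    edges[, ptr] <- c(leaf, v)
    degree[leaf] <- 0L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[, n - 1] <- last
  edges
}

orient_to_root <- function(edges, n, root) {
  adj <- vector("list", n)
  for (e in seq_len(ncol(edges))) {
    u <- edges[1, e]; v <- edges[2, e]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  par <- integer(n)
  visited <- logical(n)
  queue <- root; visited[root] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (!visited[v]) {
        visited[v] <- TRUE
        par[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  par
}

# Stationary abundances at each beta in `betas`; rows on the simplex.
# For n <= 7 the exact log-domain tree evaluation is used throughout: it is
# accurate for components far below double-precision underflow of the
# fixation probabilities and is label-equivariant, which the linear solve
# loses once its condition number grows at strong selection.
abundance_at <- function(game, process, N, betas) {
  meth <- if (game$n <= 7) "logtree" else "auto"
  lrs <- log_rho_matrices(game, process, N, betas)
  x <- t(vapply(lrs, function(lr) {
    if (any(!is.finite(lr[row(lr) != col(lr)]))) {
      overflow_error("fixation overflow during abundance evaluation")
    }
    as.numeric(stationary_logdomain(lr, meth))
  }, numeric(game$n)))
  colnames(x) <- game$strategies
  x
}

#' Weak-selection ranking of strategies
#'
#' Orders strategies by the derivative of the stationary distribution with
#' respect to the selection intensity at beta = 0 (where the distribution
#' itself is uniform). The derivative is computed by central finite
#' differences at steps h and h/2 combined by Richardson extrapolation; h is
#' chosen so the stationary distribution deviates from uniform by about
#' 1e-3 to 1e-2, keeping truncation and roundoff balanced.
#'
#' @param game a [matrix_game()] or [multiplayer_game()].
#' @param process an [imitation_rule()] or [fitness_map()]; only the
#'   functional form matters, its `beta` is ignored.
#' @param N population size.
#' @param tie_tol derivatives closer than this are reported as tied.
#' @return list with `derivative` (sums to ~0), `ordering` (strategy indices
#'   from most to least favored), `ties` (logical: any unresolved pair),
#'   `h` (step used) and `converged`.
#' @export
weak_selection_ranking <- function(game, process, N, tie_tol = 1e-8) {
  n <- game$n
  unif <- rep(1 / n, n)
  h <- 1e-3
  for (rep in 1:3) {
    dev <- max(abs(abundance_at(game, process, N, h)[1, ] - unif))
    if (dev > 1e-3 && dev < 1e-2) break
    if (dev == 0) { h <- 1; next }   # neutral game: any h works
    h <- h * 3e-3 / dev
    h <- min(max(h, 1e-8), 1)
  }
  xs <- abundance_at(game, process, N, c(h, -h, h / 2, -h / 2))
  D1 <- (xs[1, ] - xs[2, ]) / (2 * h)
  D2 <- (xs[3, ] - xs[4, ]) / h
  deriv <- (4 * D2 - D1) / 3
  converged <- max(abs(D2 - D1)) <= 1e-4 * max(1, max(abs(D1)))
  if (!converged) {
    warning("weak-selection derivative: step-halving disagreement exceeds 1e-4")
  }
  ord <- order(deriv, decreasing = TRUE)
  sorted <- deriv[ord]
  ties <- any(abs(diff(sorted)) < tie_tol)
  list(derivative = stats::setNames(deriv, game$strategies),
       ordering = ord, ties = ties, h = h, converged = converged)
}

#' Strong-selection limit of the pairwise fixation probabilities
#'
#' Classifies, for every ordered pair, whether the fixation probability
#' stays positive as beta grows without bound. For log-linear rules (Fermi
#' imitation, exponential Moran) the classification is exact: since
#' S_k = -beta * sum_{j<=k} delta_j, the limit is positive (and equals 1)
#' iff every partial payoff-difference sum is positive. For other rules the
#' limit is estimated on a doubling beta ladder with a convergence check.
#'
#' @param game a [matrix_game()] or [multiplayer_game()].
#' @param process an [imitation_rule()] or [fitness_map()].
#' @param N population size.
#' @param ladder beta values used for non-log-linear rules.
#' @return list with `positive` (n x n logical, diagonal `NA`), `rho_inf`
#'   (limit values), `degenerate` (pairs with an exactly-zero partial sum),
#'   `chain` (the limiting embedded chain's transition matrix) and `method`.
#' @export
strong_selection_limit <- function(game, process, N, ladder = 2^(0:15)) {
  n <- game$n
  log_linear <- (inherits(process, "imitation_rule") && process$kind == "fermi") ||
    (inherits(process, "fitness_map") && process$kind == "exponential")
  positive <- matrix(NA, n, n)
  rho_inf <- matrix(NA_real_, n, n)
  degenerate <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    prof <- invasion_profile(game, j, i, N)
    if (log_linear) {
      ps <- cumsum(prof$delta)
      if (all(ps > 0)) {
        positive[j, i] <- TRUE; rho_inf[j, i] <- 1
      } else if (any(ps < 0)) {
        positive[j, i] <- FALSE; rho_inf[j, i] <- 0
      } else {
        degenerate[j, i] <- TRUE
      }
      if (any(ps == 0)) degenerate[j, i] <- TRUE
    } else {
      lr <- pair_log_rho(process, prof, ladder)
      lr <- lr[is.finite(lr)]
      if (length(lr) < 2) { degenerate[j, i] <- TRUE; next }
      r <- exp(lr)
      conv <- abs(diff(r)) / pmax(r[-1], 1e-300) < 1e-9
      rho_inf[j, i] <- r[length(r)]
      positive[j, i] <- rho_inf[j, i] > 1e-12
      if (!any(conv)) degenerate[j, i] <- TRUE
    }
  }
  Lambda <- t(ifelse(is.na(rho_inf), 0, rho_inf)) / (n - 1)
  diag(Lambda) <- 0
  diag(Lambda) <- 1 - rowSums(Lambda)
  dimnames(positive) <- dimnames(rho_inf) <-
    dimnames(Lambda) <- list(game$strategies, game$strategies)
  list(positive = positive, rho_inf = rho_inf,
       degenerate = degenerate, chain = Lambda,
       method = if (log_linear) "sign-rule" else "beta-ladder")
}
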