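#' Fermi imitation function
#'
#' `fermi(x)` = 1 / (1 + exp(-x)), the logistic imitation kernel.
#' `fermi_log(x)` returns log fermi(x) stably for arguments down to -1e4 and
#' beyond (it is exact up to `log1p` accuracy because it never forms the
#' probability itself).
#'
#' @param x numeric vector of (selection-scaled) payoff differences.
#' @return probabilities in (0, 1), or their logarithms.
#' @export
fermi <- function(x) stats::plogis(x)

#' @rdname fermi
#' @export
fermi_log <- function(x) stats::plogis(x, log.p = TRUE)

#' Error-function imitation rule
#'
#' `erf_imitation(x)` = (1 + erf(x)) / 2, an imitation kernel with Gaussian
#' tails: qualitatively similar to the Fermi function but with
#' log-probability falling off like -x^2 instead of -|x|. Evaluated through
#' the normal CDF, (1 + erf(x)) / 2 = pnorm(x * sqrt(2)), whose log-domain
#' form is accurate far into the lower tail.
#'
#' @param x numeric vector.
#' @return probabilities in (0, 1), or their logarithms.
#' @export
erf_imitation <- function(x) stats::pnorm(x * sqrt(2))

#' @rdname erf_imitation
#' @export
erf_imitation_log <- function(x) stats::pnorm(x * sqrt(2), log.p = TRUE)

#' Imitation rule (pairwise-comparison process)
#'
#' A focal individual adopts a model's strategy with probability
#' g(beta * (pi_model - pi_focal)), where g is increasing with g(-Inf) = 0
#' and g(+Inf) = 1 and beta >= 0 is the intensity of selection.
#'
#' @param kind `"fermi"`, `"erf"`, or `"custom"`.
#' @param beta selection intensity, >= 0.
#' @param g for `kind = "custom"`: the imitation function.
#' @param log_g for `kind = "custom"`: its log-domain form; if omitted it is
#'   derived as `log(g(x))`, which loses accuracy for strongly negative
#'   arguments.
#' @return Object of class `imitation_rule` with elements `kind`, `beta`,
#'   `g`, `log_g`.
#' @examples
#' imitation_rule("fermi", beta = 1)
#' @export
imitation_rule <- function(kind = c("fermi", "erf", "custom"), beta,
                           g = NULL, log_g = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || !is.finite(beta)) {
    stop("beta must be a single finite number >= 0")
  }
  if (kind == "fermi") {
    g <- fermi; log_g <- fermi_log
  } else if (kind == "erf") {
    g <- erf_imitation; log_g <- erf_imitation_log
  } else {
    if (is.null(g)) stop("custom rule needs g")
    if (is.null(log_g)) log_g <- function(x) log(g(x))
  }
  structure(list(kind = kind, beta = beta, g = g, log_g = log_g),
            class = "imitation_rule")
}

#' Payoff-to-fitness map for the Moran process
#'
#' Exponential: f = exp(beta * pi). Linear: f = 1 + beta * pi, valid only
#' while the fitness stays positive over the payoffs encountered (checked at
#' use time; the offending state is reported).
#'
#' @param kind `"exponential"` or `"linear"`.
#' @param beta selection intensity, >= 0.
#' @return Object of class `fitness_map`.
#' @export
fitness_map <- function(kind = c("exponential", "linear"), beta) {
  kind <- match.arg(kind)
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || !is.finite(beta)) {
    stop("beta must be a single finite number >= 0")
  }
  structure(list(kind = kind, beta = beta), class = "fitness_map")
}

overflow_error <- function(msg) {
  stop(structure(class = c("selrank_overflow", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Log transition-probability ratio at one population state
#'
#' For an imitation rule, the ratio of the backward to the forward
#' transition probability at a state with payoff difference `delta` is
#' gamma = g(-beta delta) / g(beta delta); this returns log gamma. For the
#' Fermi rule log gamma = -beta * delta exactly.
#'
#' @param rule an [imitation_rule()].
#' @param delta numeric vector of payoff differences.
#' @return log gamma, same length as `delta`.
#' @export
log_gamma_ratio <- function(rule, delta) {
  stopifnot(inherits(rule, "imitation_rule"))
  x <- rule$beta * delta
  lg <- if (rule$kind == "fermi") -x else rule$log_g(-x) - rule$log_g(x)
  if (any(!is.finite(lg))) {
    overflow_error("imitation function underflowed in log space; reduce beta")
  }
  lg
}

# ---- internal log-domain fixation engine -------------------------------

# Log gamma as a (length(betas) x (N-1)) matrix for one invasion profile
# under either process. Non-finite entries signal overflow and are the
# caller's responsibility.
loggamma_matrix <- function(process, profile, betas) {
  delta <- profile$delta
  if (inherits(process, "imitation_rule")) {
    if (process$kind == "fermi") return(-(betas %o% delta))
    M <- betas %o% delta
    return(process$log_g(-M) - process$log_g(M))
  }
  if (inherits(process, "fitness_map")) {
    if (process$kind == "exponential") return(-(betas %o% delta))
    if (is.null(profile$pi_A) || is.null(profile$pi_B)) {
      stop("linear fitness map needs per-state payoffs (pi_A, pi_B) in the profile")
    }
    fA <- 1 + betas %o% profile$pi_A
    fB <- 1 + betas %o% profile$pi_B
    if (any(fA <= 0) || any(fB <= 0)) {
      bad <- which(fA <= 0 | fB <= 0, arr.ind = TRUE)
      stop("linear fitness map non-positive at state i = ", bad[1, 2],
           " (beta = ", signif(betas[bad[1, 1]], 4),
           "); use the exponential map or reduce beta")
    }
    return(log(fB) - log(fA))
  }
  stop("process must be an imitation_rule or a fitness_map")
}

# log rho for each beta from the loggamma matrix, via log-sum-exp over the
# cumulative sums S_k. Returns a vector with NaN where S was non-finite.
logrho_from_loggamma <- function(L) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1)
  S <- t(apply(L, 1, cumsum))
  if (ncol(L) == 1) S <- matrix(S, ncol = 1)
  bad <- !is.finite(S)
  S[bad] <- 0
  m <- pmax(0, apply(S, 1, max))
  logden <- m + log(exp(-m) + rowSums(exp(S - m)))
  logrho <- -logden
  logrho[rowSums(bad) > 0] <- NaN
  logrho
}

# Vectorized fixation over a beta grid; the workhorse behind everything.
pair_log_rho <- function(process, profile, betas) {
  logrho_from_loggamma(loggamma_matrix(process, profile, betas))
}

#' Fixation probability of a single mutant
#'
#' Probability that one mutant following the invasion profile `profile`
#' takes over the resident population under the pairwise-comparison process
#' with imitation rule `rule`:
#' rho = 1 / (1 + sum_{k=1}^{N-1} exp(S_k)), S_k = sum_{j<=k} log gamma_j.
#' All products are carried in log space and summed by log-sum-exp, so the
#' computation never overflows for finite log gamma.
#'
#' @param profile a [pairwise_profile()].
#' @param rule an [imitation_rule()] (its `beta` is used).
#' @return Object of class `fixation_result`: `rho`, `log_rho`, and
#'   `log_terms` (the cumulative sums S_k, a diagnostic).
#' @examples
#' prof <- pairwise_profile(10, delta = rep(0.5, 9))
#' fixation_probability(prof, imitation_rule("fermi", beta = 1))$rho
#' @export
fixation_probability <- function(profile, rule) {
  stopifnot(inherits(profile, "pairwise_profile"),
            inherits(rule, "imitation_rule"))
  fixation_result(loggamma_matrix(rule, profile, rule$beta), profile$N)
}

#' Fixation probability under the Moran process
#'
#' Birth-death Moran process in which one individual reproduces with
#' probability proportional to fitness and replaces a random individual.
#' The transition ratio is gamma_i = f_B(i) / f_A(i), so for the
#' exponential map log gamma_i = -beta * delta_i and the fixation
#' probability coincides with the Fermi imitation process at every beta.
#'
#' @param profile a [pairwise_profile()]; the linear map additionally needs
#'   the per-state payoffs `pi_A`, `pi_B`.
#' @param fmap a [fitness_map()].
#' @return a `fixation_result` (see [fixation_probability()]).
#' @export
moran_fixation <- function(profile, fmap) {
  stopifnot(inherits(profile, "pairwise_profile"),
            inherits(fmap, "fitness_map"))
  fixation_result(loggamma_matrix(fmap, profile, fmap$beta), profile$N)
}

fixation_result <- function(L, N) {
  S <- cumsum(as.numeric(L))
  if (any(!is.finite(S))) {
    overflow_error("non-finite cumulative log ratio; reduce beta")
  }
  m <- max(0, S)
  logden <- m + log(exp(-m) + sum(exp(S - m)))
  structure(list(rho = exp(-logden), log_rho = -logden, log_terms = S, N = N),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat("fixation probability rho =", format(x$rho, digits = 10),
      "(log rho =", format(x$log_rho, digits = 10), ")\n")
  invisible(x)
}
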