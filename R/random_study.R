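#' Draw a random matrix game
#'
#' Entries are i.i.d. Uniform(0,1) (`"uniform01"`) or standard Gaussian
#' (`"gaussian01"`), the two sampling distributions of the random-game
#' studies. Uses the current RNG state.
#'
#' @param dist `"uniform01"` or `"gaussian01"`.
#' @param n number of strategies.
#' @return a [matrix_game()].
#' @export
sample_game <- function(dist = c("uniform01", "gaussian01"), n) {
  dist <- match.arg(dist)
  entries <- switch(dist,
                    uniform01 = stats::runif(n * n),
                    gaussian01 = stats::rnorm(n * n))
  matrix_game(matrix(entries, n, n))
}

#' Configuration of a random-game rank-change study
#'
#' @param n number of strategies (>= 2).
#' @param N population size.
#' @param dist payoff sampling distribution, see [sample_game()].
#' @param samples number of random games.
#' @param rule imitation rule name (`"fermi"` or `"erf"`) or an
#'   [imitation_rule()] / [fitness_map()] object.
#' @param beta_min,beta_cap,grid_points selection-intensity grid: log-spaced
#'   from `beta_min` to the per-game [adaptive_beta_max()] capped at
#'   `beta_cap`.
#' @param seed integer seed; each sample runs on an independently derived
#'   sub-stream so results do not depend on execution order.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n, N = 100, dist = c("uniform01", "gaussian01"),
                         samples = 2000, rule = "fermi",
                         beta_min = 1e-3, beta_cap = 1e3, grid_points = 200,
                         seed = 1) {
  dist <- match.arg(dist)
  if (is.character(rule)) rule <- imitation_rule(rule, beta = 1)
  stopifnot(samples >= 1, n >= 2, N >= 2)
  structure(list(n = as.integer(n), N = as.integer(N), dist = dist,
                 samples = as.integer(samples), rule = rule,
                 beta_min = beta_min, beta_cap = beta_cap,
                 grid_points = as.integer(grid_points),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Monte Carlo study of rank changes in random games
#'
#' For each sampled game: build the selection grid up to the game's own
#' overflow-safe beta_max, sweep the stationary abundances, and count rank
#' changes and changes of the most abundant strategy. Games whose rule
#' overflows early are truncated at their own beta_max (never dropped,
#' which would bias the estimate toward tame games).
#'
#' @param config a [study_config()].
#' @param progress print a progress line every 100 samples.
#' @return Object of class `study_result`: `counts` and `top_counts` per
#'   sample, `P_at_least` / `top_P_at_least` (data frames with k, estimate
#'   and exact binomial 95% CI), `expected_total` with `se`, `histogram`,
#'   `truncated` (number of beta-truncated samples) and the `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  withr_seed <- function(s, expr) { set.seed(s); expr }
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, config$samples)
  counts <- integer(config$samples)
  top_counts <- integer(config$samples)
  beta_max <- numeric(config$samples)
  for (s in seq_len(config$samples)) {
    set.seed(sub_seeds[s])
    game <- sample_game(config$dist, config$n)
    bmax <- adaptive_beta_max(game, config$rule, config$N, cap = config$beta_cap)
    beta_max[s] <- bmax
    grid <- beta_grid(config$beta_min, bmax, n = config$grid_points)
    rep <- detect_crossings(sweep_abundance(game, config$rule, config$N, grid))
    counts[s] <- rep$total_count
    top_counts[s] <- rep$top_changes
    if (progress && s %% 100 == 0) {
      message("study: ", s, "/", config$samples, " samples")
    }
  }
  structure(list(counts = counts, top_counts = top_counts,
                 P_at_least = at_least_table(counts),
                 top_P_at_least = at_least_table(top_counts),
                 expected_total = mean(counts),
                 expected_total_se = stats::sd(counts) / sqrt(length(counts)),
                 histogram = tabulate(counts + 1L, nbins = max(counts) + 1L),
                 truncated = sum(beta_max < config$beta_cap),
                 beta_max = beta_max,
                 config = config),
            class = "study_result")
}

# P(count >= k) for k = 0..max, with exact binomial 95% CI.
at_least_table <- function(counts) {
  kmax <- max(counts, 1L)
  ns <- length(counts)
  do.call(rbind, lapply(0:kmax, function(k) {
    x <- sum(counts >= k)
    ci <- stats::binom.test(x, ns)$conf.int
    data.frame(k = k, estimate = x / ns, lower = ci[1], upper = ci[2],
               successes = x, samples = ns)
  }))
}

#' @export
print.study_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("random-game study: n = %d, N = %d, %s payoffs, %d samples\n",
              cfg$n, cfg$N, cfg$dist, cfg$samples))
  cat(sprintf("P(at least 1 rank change) = %.3f [%.3f, %.3f]\n",
              x$P_at_least$estimate[2], x$P_at_least$lower[2],
              x$P_at_least$upper[2]))
  cat(sprintf("expected rank changes = %.3f (se %.3f)\n",
              x$expected_total, x$expected_total_se))
  invisible(x)
}

#' Serialize a study result
#'
#' @param result a [run_study()] result.
#' @param tsv,json optional output paths; the TSV holds the
#'   `P_at_least` / `top_P_at_least` tables, the JSON the full summary with
#'   a config echo (games are reproducible from the seed).
#' @return invisibly, the summary list written to JSON.
#' @export
study_report <- function(result, tsv = NULL, json = NULL) {
  stopifnot(inherits(result, "study_result"))
  tab <- rbind(cbind(what = "pair", result$P_at_least),
               cbind(what = "top", result$top_P_at_least))
  if (!is.null(tsv)) {
    utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cfg <- result$config
  summary <- list(
    config = list(n = cfg$n, N = cfg$N, dist = cfg$dist,
                  samples = cfg$samples,
                  rule = if (inherits(cfg$rule, "imitation_rule"))
                    cfg$rule$kind else cfg$rule$kind,
                  beta_min = cfg$beta_min, beta_cap = cfg$beta_cap,
                  grid_points = cfg$grid_points, seed = cfg$seed),
    P_at_least = result$P_at_least,
    top_P_at_least = result$top_P_at_least,
    expected_total = result$expected_total,
    expected_total_se = result$expected_total_se,
    histogram = result$histogram,
    truncated = result$truncated)
  if (!is.null(json)) {
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
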