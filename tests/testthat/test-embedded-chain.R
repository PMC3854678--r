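test_that("neutral fixation matrix and chain are uniform", {
  set.seed(2)
  g <- matrix_game(matrix(runif(9), 3, 3))
  fm <- build_fixation_matrix(g, imitation_rule("fermi", 0), N = 15)
  off <- fm$rho[row(fm$rho) != col(fm$rho)]
  expect_equal(off, rep(1 / 15, 6), tolerance = 1e-13)
  ch <- build_chain(fm)
  expect_equal(ch$Lambda[1, 2], 1 / (15 * 2), tolerance = 1e-13)
  expect_equal(unname(rowSums(ch$Lambda)), rep(1, 3), tolerance = 1e-14)
  expect_equal(as.numeric(stationary(ch)), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("relabeling symmetry of symmetric games shows up in rho", {
  m <- rbind(c(1, 4, 0), c(4, 1, 2), c(0, 2, 1))  # a_ij = a_ji, equal diagonal
  g <- matrix_game(m)
  fm <- build_fixation_matrix(g, imitation_rule("fermi", 0.7), N = 10)
  for (i in 1:3) for (j in 1:3) {
    if (i != j) expect_equal(fm$rho[i, j], fm$rho[j, i], tolerance = 1e-12)
  }
})

test_that("fixation matrix entries match the absorbing-chain oracle", {
  set.seed(31)
  g <- matrix_game(matrix(rnorm(9), 3, 3))
  rule <- imitation_rule("fermi", 1)
  fm <- build_fixation_matrix(g, rule, N = 10)
  for (j in 1:3) for (i in 1:3) {
    if (i == j) next
    prof <- matrix_pair_profile(g, j, i, 10)
    expect_equal(fm$rho[j, i], solve_fixation(birth_death_chain(prof, rule)),
                 tolerance = 1e-10)
  }
})

test_that("three-state stationary vector equals the tree-theorem rationals", {
  set.seed(14)
  for (rep in 1:10) {
    g <- matrix_game(matrix(runif(9), 3, 3))
    fm <- build_fixation_matrix(g, imitation_rule("fermi", runif(1, 0.2, 2)), N = 8)
    r <- fm$rho
    # closed-form spanning-tree sums, written out independently
    w1 <- r[1, 2] * r[1, 3] + r[2, 3] * r[1, 2] + r[3, 2] * r[1, 3]
    w2 <- r[2, 1] * r[2, 3] + r[1, 3] * r[2, 1] + r[3, 1] * r[2, 3]
    w3 <- r[3, 1] * r[3, 2] + r[1, 2] * r[3, 1] + r[2, 1] * r[3, 2]
    expect_equal(as.numeric(stationary(build_chain(fm))),
                 c(w1, w2, w3) / (w1 + w2 + w3), tolerance = 1e-10)
  }
})

test_that("two-state stationary distribution is the fixation-rate balance", {
  set.seed(6)
  g <- matrix_game(matrix(runif(4), 2, 2))
  fm <- build_fixation_matrix(g, imitation_rule("erf", 0.9), N = 12)
  x <- stationary(build_chain(fm))
  expect_equal(as.numeric(x[1]), fm$rho[1, 2] / (fm$rho[1, 2] + fm$rho[2, 1]),
               tolerance = 1e-12)
})

test_that("solver routes agree: linear solve, eigen, log-domain trees", {
  set.seed(21)
  for (n in c(3, 4, 5)) {
    g <- matrix_game(matrix(rnorm(n * n), n, n))
    ch <- build_chain(build_fixation_matrix(g, imitation_rule("fermi", 0.6), N = 9))
    xs <- stationary(ch, "solve")
    expect_equal(as.numeric(xs), as.numeric(stationary(ch, "eigen")),
                 tolerance = 1e-10)
    expect_equal(as.numeric(xs), as.numeric(stationary(ch, "logtree")),
                 tolerance = 1e-10)
    expect_equal(sum(xs), 1, tolerance = 1e-12)
  }
})

test_that("stationary distribution is permutation-equivariant and shift-invariant", {
  set.seed(33)
  rule <- imitation_rule("fermi", 1.3)
  for (n in c(3, 4)) {
    m <- matrix(runif(n * n), n, n)
    x <- stationary(build_chain(build_fixation_matrix(matrix_game(m), rule, 11)))
    perm <- sample(n)
    xp <- stationary(build_chain(build_fixation_matrix(
      matrix_game(m[perm, perm]), rule, 11)))
    expect_equal(as.numeric(xp), as.numeric(x[perm]), tolerance = 1e-11)
    xshift <- stationary(build_chain(build_fixation_matrix(
      matrix_game(m + 4.2), rule, 11)))
    expect_equal(as.numeric(xshift), as.numeric(x), tolerance = 1e-11)
  }
})

test_that("weak-selection derivatives sum to zero and rank like small beta", {
  set.seed(55)
  rule <- imitation_rule("fermi", 1)
  for (rep in 1:25) {
    g <- matrix_game(matrix(runif(9), 3, 3))
    w <- suppressWarnings(weak_selection_ranking(g, rule, N = 30))
    expect_lt(abs(sum(w$derivative)), 1e-8)
    if (!w$ties) {
      xs <- selrank:::abundance_at(g, rule, 30, 1e-3)[1, ]
      expect_identical(w$ordering, order(xs, decreasing = TRUE))
    }
  }
  # all-equal game: no selection, no ranking
  w0 <- weak_selection_ranking(matrix_game(matrix(1, 3, 3)), rule, N = 20)
  expect_equal(unname(w0$derivative), rep(0, 3), tolerance = 1e-10)
  expect_true(w0$ties)
})

test_that("strong-selection sign rule matches large-beta fixation numerically", {
  set.seed(60)
  rule <- imitation_rule("fermi", 1)
  for (rep in 1:40) {
    g <- matrix_game(matrix(runif(4), 2, 2))
    cls <- strong_selection_limit(g, rule, N = 20)
    prof <- matrix_pair_profile(g, 1, 2, 20)
    # the rate of convergence to the limit is set by the smallest nonzero
    # partial payoff sum, so probe at a beta large on that scale
    margin <- min(abs(cumsum(prof$delta))[abs(cumsum(prof$delta)) > 0])
    beta_big <- max(500, 100 / margin)
    rho_big <- fixation_probability(prof, imitation_rule("fermi", beta_big))$rho
    if (isTRUE(cls$positive[1, 2])) {
      expect_lt(abs(rho_big - cls$rho_inf[1, 2]), 1e-6)
    } else if (isFALSE(cls$positive[1, 2])) {
      expect_lt(rho_big, 1e-6)
    }
  }
  # dominant strategy: every partial sum positive forces a positive limit
  gd <- matrix_game(rbind(c(2, 2), c(1, 1)))
  expect_true(strong_selection_limit(gd, rule, 10)$positive[1, 2])
})

test_that("strong selection drives the population to the risk-dominant strategy", {
  # coordination games: both pure strategies are strict equilibria, and the
  # chain concentrates on the one with the larger invasion barrier advantage
  rule <- imitation_rule("fermi", 1)
  g1 <- matrix_game(rbind(c(4, 0), c(1, 2)))  # strategy 1 risk dominant (4+0 > 1+2)
  g2 <- matrix_game(rbind(c(2.5, 0), c(1, 2)))  # strategy 2 risk dominant
  for (N in c(20, 60)) {
    x1 <- selrank:::abundance_at(g1, rule, N, 200)[1, ]
    x2 <- selrank:::abundance_at(g2, rule, N, 200)[1, ]
    expect_gt(x1[1], 0.99)
    expect_lt(x2[1], 0.01)
  }
})

test_that("beta-ladder strong-selection classifier works for the erf rule", {
  set.seed(61)
  g <- matrix_game(rbind(c(2, 2), c(1, 1)))  # dominance: limit positive
  cls <- strong_selection_limit(g, imitation_rule("erf", 1), N = 12)
  expect_identical(cls$method, "beta-ladder")
  expect_true(cls$positive[1, 2])
  expect_false(cls$positive[2, 1])
})
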