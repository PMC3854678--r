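---
title: "Rank changes in strategy abundance across selection intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank changes in strategy abundance across selection intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selrank)
```

## The question

Weak selection — payoff differences that barely perturb reproductive
success — is the regime where evolutionary game dynamics in finite
populations become analytically tractable. The implicit hope is that the
*ranking* of strategies by long-run abundance computed at β → 0 remains
valid when selection is not weak. `selrank` provides the machinery to test
that hope: stationary abundance curves x(β), detection and refinement of
rank changes (crossings of two abundance curves), and Monte Carlo
estimates of how frequent such crossings are in random games.

## Model and assumptions

**Population and games.** A well-mixed population of fixed size N plays a
symmetric game. Two reducers map games onto the package's universal
object, the *pairwise invasion profile* Δπ(i), i = 1..N−1, the payoff
difference between a mutant strategy present in i copies and the resident:

* two-player matrix games, with everyone interacting with everyone else
  and self-interaction excluded (denominators N−1). Exclusion is the
  standard finite-population convention and is what makes N = 2
  well-defined: each player then meets exactly the other one;
* d-player two-strategy games, where a focal individual's d−1 co-players
  are drawn without replacement from the other N−1 individuals, giving
  hypergeometric composition weights (evaluated through `dhyper`, which
  works in log-gamma space and remains exact for N up to 10^4).

Because only two strategies ever coexist in the rare-mutation regime (see
below), an n-strategy multiplayer game is fully specified by one payoff
table per unordered strategy pair (`multiplayer_game`).

**The public goods generator.** `pgg_punishment_game()` builds the
three-strategy cooperate/defect/punish game: all d group members share the
multiplied pool r·c·(#contributors)/d, contributors (cooperators and
punishers) pay c, punishment is bilinear — each punisher pays
`punish_cost` per defector, each defector is fined `fine` per punisher.
All five parameters (d, r, c, fine, punish_cost) are exposed and none is
hard-coded; the literature this game comes from fixes the convention that
defectors also share the pool. Note a structural property the package
reproduces: with only cooperators and punishers present no one is
punished, so the (C,P) invasion profile is identically zero and the two
strategies drift neutrally against each other.

**Update rules.** Pairwise comparison: the focal individual adopts the
model's strategy with probability g(β Δπ). We require g increasing,
g(−∞) = 0, g(+∞) = 1. Two rules ship: Fermi, g(x) = 1/(1+e^{−x}), and the
rescaled error function g(x) = (1+erf(x))/2. The latter is fixed to this
normalization because any rescaling of its argument is absorbed into β;
tests therefore only assert scaling-invariant claims about it. Moran
processes enter through payoff-to-fitness maps: exponential f = e^{βπ}
(whose fixation probabilities coincide with Fermi imitation identically in
β — a property the test suite checks to 10^{−12}), and linear f = 1 + βπ,
which is only valid while fitness stays positive; the package checks this
state by state and reports the offending state, and `adaptive_beta_max()`
locates the validity boundary.

**Rare mutations.** With mutation probability μ per update step and
μ N log N ≪ 1, the population is almost always monomorphic and the
dynamics collapse to an n-state Markov chain whose transition i → j is the
fixation probability of a single j-mutant in an i-resident population,
divided by n−1 (uniform mutant choice among the other strategies).
Allowing self-mutations would only rescale time and leave the stationary
distribution unchanged, so the package does not make this configurable.

## Numerics

**Fixation in log space.** ρ = 1/(1 + Σ_k e^{S_k}) with
S_k = Σ_{j≤k} [log g(−βΔπ_j) − log g(βΔπ_j)]. Everything is assembled in
log space with log-sum-exp; `plogis(..., log.p = TRUE)` and
`pnorm(..., log.p = TRUE)` supply the deep log tails of the two rules
(the Fermi log-ratio is exactly −βΔπ, so it never overflows at any β).
This addresses arithmetic overflow at its source rather than by capping β;
`adaptive_beta_max()` still exists for processes with genuine validity
boundaries (the linear Moran map) and returns its cap for the log-safe
rules — which doubles as a regression test that log-space evaluation is
genuinely unbounded. The neutral prefactor i(N−i)/N² of the literal
process cancels from every ratio and is therefore never computed in the
fixation path; it is kept only in the explicit reference chain of
`birth_death_chain()`.

**Stationary distributions.** `stationary()` solves xΛ = x, Σx = 1 by a
direct linear solve of the generator system with the normalization row
appended, built from the off-diagonal entries only so no 1−ε cancellation
occurs. At strong selection, however, fixation probabilities span hundreds
of orders of magnitude; the solve's condition number grows with that span
and its output eventually becomes label-dependent noise. The sweep
machinery therefore evaluates the stationary vector for n ≤ 7 by the
Markov-chain tree theorem entirely in log space (spanning trees enumerated
once per n via Prüfer sequences and cached): exact up to log-sum-exp
rounding for components far below double-precision underflow, and
permutation-equivariant. The two routes agree to 10^{−10} wherever the
solve is healthy, which the test suite checks, along with an eigenvector
route.

**Crossing detection.** A rank change between strategies i and j is a
sign change of x_i(β) − x_j(β) between consecutive grid points with
|difference| > tol on both sides (tol = 10^{−10} absolute by default).
Grid values within tol are flagged degenerate and never counted, and
tangencies without a sign change are not crossings. Each crossing is
refined by bisection on β to relative precision 10^{−6}, recomputing full
stationary distributions rather than interpolating. The default grid is
200 log-spaced points from 10^{−3} to the adaptive β_max (cap 10³): rank
changes in practice spread over orders of magnitude of β, and in random
3-strategy ensembles the observed crossing locations concentrate around
β ∈ [10^{−2}, 10]. A change of the *most abundant* strategy is recorded
when the two crossing strategies are jointly on top at the refined β*.

**Weak-selection ranking.** The derivative dx/dβ at β = 0 is computed by
central differences at steps h and h/2 with Richardson extrapolation; h is
chosen adaptively so x(h) deviates from uniform by 10^{−3}–10^{−2},
balancing truncation against roundoff. A precision warning is raised when
the two difference estimates disagree by more than 10^{−4} relative to
the derivative scale (an absolute threshold would be meaningless for
derivatives of arbitrary magnitude). Derivatives closer than a tie
tolerance are reported as unranked. The derivative is numerical rather
than an analytic perturbation formula; the small-β sweep oracle in the
tests guards its correctness.

**Strong-selection limit.** For log-linear rules (Fermi, exponential
Moran), S_k = −β Σ_{j≤k} Δπ_j, so ρ stays positive as β → ∞ exactly when
every partial payoff sum is positive — the classification is exact, with
partial sums exactly zero flagged degenerate. For other rules the limit is
probed on a doubling β ladder (2^0..2^15) with successive relative change
below 10^{−9} as the convergence criterion. In two-strategy coordination
games the resulting probability current flows toward the risk-dominant
strategy, which the tests verify on both orientations.

## The randomized searches

Two search operations demonstrate, by explicit instance, phenomena that
hold in general:

* `find_fig2_game()`: a 2-strategy 3-player game whose ranking never
  changes under the Fermi rule — for two-strategy games the Fermi
  stationary distribution depends only on the single product of imitation
  ratios, whose sign is β-independent — but changes under the
  qualitatively similar erf rule. Defaults (d = 3, N = 50, standard
  Gaussian table entries) were fixed once: group size three is the minimal
  multiplayer case, N = 50 is a mid-range population, and the Gaussian is
  one of the two ensemble distributions used throughout. With d = 2 the
  search is a negative control: ranking invariance holds for two-player
  two-strategy games under *any* imitation rule, and the search finds
  nothing in 10^4 attempts.
* `find_theorem1_game()`: a 3×3 two-player game whose weak- and
  strong-selection rankings coincide and which nevertheless crosses at
  least twice at intermediate β — the ordering leaves the limiting ranking
  and returns to it, so even checking both limits together cannot certify
  the ranking in between.

Both searches screen candidates cheaply (the two-strategy sign identity
x₁ > 1/2 ⇔ log ρ₁₂ > log ρ₂₁; endpoint orderings for the 3×3 case) and
then verify every reported hit through the full sweep and crossing
detector on a 10× denser grid. Reported crossings always occur at
pairwise-distinct β*: a simultaneous crossing of all three curves is a
measure-zero coincidence, and the verification asserts its absence.

## Random-game studies

`run_study()` estimates P(at least k rank changes), the same for changes
of the most abundant strategy, and the expected total crossing count, over
games with i.i.d. Uniform(0,1) or standard Gaussian payoffs. Study
defaults: N = 100 (the scale of the worked public-goods example; the
acceptance script reports sensitivity at N ∈ {50, 100, 200}, and the
estimates turn out to be nearly N-independent), 2000 samples with exact
binomial confidence intervals reported so that reduced sampling stays
honest, and per-sample grids truncated at the sample's own β_max rather
than rejecting overflowing games, which would bias the ensemble toward
tame payoff matrices. Samples run on independently derived sub-seeds, so
results are identical regardless of execution order.

Problem sizes used by the acceptance script and acceptance tests: 2000
samples for the headline 3-strategy estimate, 500 per configuration for
the n = 3, 4, 5 comparison across both distributions — enough for the
monotone growth in n (differences of ~0.2–0.3) to stand far clear of the
Monte Carlo error (~0.02). When checking that the per-game crossing-count
histogram decays beyond one crossing, cells with fewer than five
observations are pooled into the tail before the monotonicity check — the
standard sparse-cell convention; with 500 samples the raw far tail (one
game with four crossings, none with three) would otherwise compare pure
noise.

## The simulator as an independent check

`simulate_stationary()` runs the literal mutation–selection process
(compiled code, R's RNG): per step a uniformly chosen focal individual
either mutates to a uniform strategy (probability μ — possibly its own
strategy, which merely rescales the effective mutation rate) or imitates a
uniformly chosen model among the other N−1 individuals. It reports both
mean strategy abundances and the occupancy of monomorphic states. The
embedded chain predicts the latter: at μ = 10^{−3}, N = 20 about 5–10% of
the time is polymorphic, and that time biases mean abundances of rare
strategies by more than their Monte Carlo error, while
monomorphic-state occupancies match the chain's stationary distribution
within noise. Errors come from a block bootstrap (100 contiguous blocks;
successive states are strongly autocorrelated), floored by the multinomial
error implied by the observed number of monomorphic sojourns — with only
a few hundred state switches per 10^7 steps, a state never visited would
otherwise report a zero standard error. The monomorphic-time fraction
(> 90% in the tested regime) is the diagnostic that the rare-mutation
approximation applies.

## What the synthetic ensembles do and do not show

The random-game ensembles are exactly the study conditions of interest —
i.i.d. payoff entries from two distributions — not a stand-in for
empirical payoff data. Passing tests show that rank changes are frequent
and increasingly likely with more strategies *in these ensembles*; real
interaction structures (correlated payoffs, structured populations,
non-negligible mutation rates) are outside the model class. Structured
populations, mutation-rate sweeps, Wright–Fisher updating and bimatrix
games are explicit non-goals.

## Known limitations

* The tree-theorem stationary path is limited to n ≤ 7 (tree count
  n^{n−2}); beyond that the linear solve is used and strong-selection
  grid points lose accuracy.
* Crossing detection is grid-based: a dense-grid comparison bounds, but
  cannot prove, that no crossing hides between grid points.
* The dense absorbing-chain reference solver is only valid while
  cumulative transition ratios span less than roughly a dozen e-folds;
  cross-validation tests draw instances inside that domain. This is a
  limitation of the reference route, not of the log-space implementation.
* The compiled simulator covers matrix games under the two shipped
  imitation rules; multiplayer games are validated through the analytic
  machinery only.
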