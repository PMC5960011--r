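---
title: "Symmetrized CHSH analysis of bipartite coincidence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetrized CHSH analysis of bipartite coincidence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bellcog)
```

## The problem

In a two-outcome bipartite coincidence experiment, four joint measurements
AB, AB′, A′B, A′B′ each produce one outcome pair per trial, giving a 2 × 2
probability block per measurement. Two statistics on such data carry the
physics (and, in quantum cognition, the psychology):

* the **CHSH combination** S = E(A,B) − E(A,B′) + E(A′,B) + E(A′,B′), with
  E(X,Y) = p11 − p12 − p21 + p22. Experimentally separated (local) systems
  satisfy |S| ≤ 2; quantum product measurements on an entangled state reach
  at most 2√2 (Tsirelson); the algebraic maximum is 4.
* the **marginal law** (no-signaling): each side's outcome marginals must
  not depend on which measurement is performed on the other side — eight
  equalities, whose signed residuals `marginal_residuals()` reports.

The motivating data set, shipped as `windrose_data()` and as the plain-text
fixture `extdata/windrose_observed.csv`, comes from a concept-combination
experiment in which 85 respondents chose pairs of wind directions on the
eight-direction windrose (A = North/South, A′ = East/West, B =
Northeast/Southwest, B′ = Southeast/Northwest). Those data violate CHSH
(|S| = 2.48 by exact arithmetic on the printed two-decimal cells) *and* the
marginal law — unlike ideal quantum spin data, which violate only CHSH.

## Rotation symmetrization

The marginal-law violation can be read as a symmetry artifact: wind
directions, unlike space directions, are not perceived isotropically. The
package implements the two mixing protocols that restore the symmetry:

* `symmetrize_180()` — a coin flip selects the original or the
  180°-rotated measurement configuration;
* `symmetrize_octahedral()` — an eight-faced die selects one of the eight
  45° rotations.

Neither requires new data. Under the **consistency assumption** — a
respondent selects the same unordered pair of compass directions whichever
rotated configuration presents it — each rotated slot's probability can be
read off the unrotated table at the unique slot showing the same unordered
direction pair (`correspondence()`, `rotated_table()`). The worked
correspondences published for the 45°, 90°, 135° and 180° rotations are all
reproduced by this rule, and it is the only bijection consistent with them.

Two exact algebraic facts make the protocols interesting, and both are
enforced as invariants in the test suite on ensembles of random tables:

* every outcome marginal of a symmetrized table is exactly 1/2, so the
  marginal law holds exactly;
* S is *unchanged* by either protocol (each octahedral expectation equals
  ±S/4), so the CHSH violation survives symmetrization untouched.

Mixing is exact cellwise averaging of stored probabilities. The stochastic
counterpart — actually rolling the die per respondent — lives in the
synthetic-respondent sampler, not here.

```{r}
obs <- windrose_data()
oct <- symmetrize_octahedral(obs)
chsh(oct)
```

## The singlet-state quantum model

A table that obeys the marginal law and has the index-swap symmetry
p11 = p22, p12 = p21 in every block can be modeled with the two-qubit
singlet state (0, 1, −1, 0)/√2 and product spin observables
(σ·**a**) ⊗ (σ·**b**) along four unit directions **a**, **a′**, **b**,
**b′**. The Born rule gives the closed forms (1 ∓ **x**·**y**)/4 for
equal/opposite outcome signs, so E(X,Y) = −**x**·**y**;
`singlet_probability()` evaluates both this closed form and the explicit
four-dimensional inner product with the eigenvectors of the product
observable (half-angle phase convention), and the two agree to 1e−12 —
another tested invariant.

`solve_directions()` inverts the model: given a symmetric target table it
returns directions whose predicted table matches it. Only the four cross
dot products **a**·**b**, **a**·**b′**, **a′**·**b**, **a′**·**b′** are
constrained by data; a global rotation is unphysical, so the gauge is fixed
as θ_a = 0, φ_a = φ_b = 0. Three routes are tried in order:

1. **Symmetric closed form** (primary): additionally sets φ_b′ = φ_a′, the
   structure of the fully symmetrized windrose solution, solving
   θ_b = arccos(1 − 4 p11^AB), θ_b′ = arccos(1 − 4 p11^AB′),
   θ_a′ = θ_b′ − arccos(1 − 4 p11^A′B′), then φ_a′ from the A′B block. The
   branch θ_a′ = θ_b′ − α(a′,b′) follows the published solution; the
   unresolved sign of |θ_b′ − θ_a′| is recorded in the returned object. On
   the octahedrally symmetrized windrose table this reproduces the
   published geometry: θ_b = 51.68°, φ_a′ = φ_b′ = 51.37°.
2. **Geometric construction**: the equal-azimuth structure cannot represent
   every realizable target (it forces **a′**·**b′** = cos(θ_b′ − θ_a′)).
   Writing t = **a**·**a′** (a free invariant), the existence of **a′** on
   the circle **a′**·**b** = c and of **b′** meeting its two constraints
   reduce to two concave quadratics in t, so the feasible set is an
   interval intersection; the midpoint yields an exact solution in closed
   form. This is what makes the solve→predict round trip exact (residual
   < 1e−9) for arbitrary direction sets.
3. **Least squares** (last resort): multi-start (8 starts, internally
   seeded, caller RNG state untouched) bounded L-BFGS-B over the five free
   spherical angles.

If the best residual still exceeds the tolerance — e.g. for a PR-box-like
table beyond the Tsirelson bound — a structured `infeasible_target_error`
is raised. Tolerances: `0.011` for hand-entered two-decimal tables (one
unit in the second decimal per cell, accumulated over a four-cell block),
`1e-9` for program-generated ones.

## The generalized rigid-rod model

The mechanical model shows that CHSH violation and marginal-law violation
have independent mechanisms. Two unit spheres each hold a point particle;
measurement X stretches an elastic band along a diameter, breakable
uniformly only on [d_X − ε_X, d_X + ε_X] (the (ε, d)-elastic; (1, 0)
reproduces Born statistics). A rigid rod keeps the two particles antipodal
until the first measurement completes, creating anticorrelations; the
second particle then lands at ±cos θ on its elastic, where θ is the angle
between the two bands. The model assumes the landing point is always
breakable: |cos θ| ≤ ε − |d| on whichever side is measured second
(`assumption_error` otherwise).

`sequential_probs()` gives the closed-form four-cell distribution of one
measurement order; `mixed_probs()` averages the two orders, which is the
normative definition used throughout (the order-mixed closed forms are
tested cell-by-cell against it and against an independent Monte-Carlo
oracle). The marginal sums (`rod_marginals()`) carry violation terms
d_Y cos θ / (4 ε_X ε_Y): asymmetric elastics (d ≠ 0) break the marginal law
through order effects. With identical elastics,
E = −cos θ/ε + d²/ε², and at the quantum Bell-test angle set (cosines
±√2/2) the CHSH quantity is |S| = 2|√2/ε − d²/ε²|: symmetric elastics with
ε = 1 give 2√2, the minimal admissible ε = √2/2 gives the algebraic maximum
4 with the marginal law fully intact, and increasing |d| *lowers* |S| while
violating the marginal law — the dissociation the model exists to exhibit.

One sign subtlety: with the CHSH minus sign on the AB′ term, the
maximal-violation geometry needs cos θ_AB′ = −√2/2 and +√2/2 for the other
three pairs; `rod_maximal_config()` uses orientations A = 0, B = π/4,
A′ = π/2, B′ = 3π/4, which realize exactly that. |S| does not depend on
which term carries the minus sign.

`simulate_rod()` is a vectorized trial-by-trial simulator of the mechanism
(uniform break point on the breakable segment; outcome +1 iff the break
point is at or below the particle; ties — a probability-zero event — go to
+1 for determinism; per-trial order randomization under `"uniform-mix"`).
It records its seed and generator name, and its empirical cells match the
closed forms within 3σ binomial bounds at 10⁶ trials in the test suite.

## Synthetic respondents

`sample_plain()` emulates the study design: each of n respondents (default
85, the study size) answers all four joint measurements, with one
categorical draw per block. Within-respondent choices across the four
measurements are independent given the table — the design is
within-subject, but nothing in the printed data constrains the dependence
structure, so independence is the default and the only implemented
coupling. `apply_consistency()` maps each respondent's choice to the
rotated replica deterministically (no new randomness), so building the
empirical table and rotating commute exactly. `sample_mixed_protocol()`
draws a rotation per respondent (coin: {0°, 180°}; die: all eight) and
records the consistency image, estimating the corresponding symmetrized
table; `bootstrap_statistic()` resamples respondents (keeping their four
answers together) and returns percentile intervals.

What passing tests show — and what they do not: the sampler reproduces the
generating table in expectation (checked against pooled 3σ binomial bounds
over 200 seeds) and realizes the mixed-protocol claim (marginal law up to
noise, CHSH violation tracking the plain table's). It idealizes perfect
respondent consistency; real respondents would deviate slightly, so real
mixed-protocol data would obey the marginal law only approximately. Order
effects, response times, and learning across the four questions are out of
scope.

## Numerical choices and problem sizes

* Probabilities are stored at full double precision; two-decimal rounding
  happens only in print methods.
* Normalization tolerance: 1e−9 for program-generated tables, 0.011 for
  hand-entered two-decimal tables.
* File round trips use 17-significant-digit decimal formatting, so
  CSV → JSON → CSV is byte-identical and doubles survive exactly.
* Property tests run on 1000 random tables (symmetrization invariants),
  1000 random direction pairs (Born-rule agreement at 1e−12), 10⁶
  Monte-Carlo trials per joint measurement (rod simulator vs closed forms
  at 3σ), and 100 meta-replicates of a 200-replicate participant bootstrap
  (interval coverage ≥ 90%); these sizes keep the whole suite comfortably
  within a coffee break on one CPU while leaving the binomial bounds sharp
  enough to be informative.

## Known limitations

* The published |S| = 2.47 for the observed table comes from unrounded raw
  data that were never printed; exact arithmetic on the printed cells gives
  2.48. The package computes, it does not force agreement.
* `solve_directions()` targets marginal-law-obeying symmetric tables only.
  Tables violating the marginal law (like the raw windrose data) would
  need entangled (non-product) measurements, which are deliberately out of
  scope; the solver raises `infeasible_target_error` instead.
* The rigid-rod closed forms assume the landing-on-breakable-region
  condition; configurations outside it are rejected rather than modeled.
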