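# bellcog

Analysis of two-outcome bipartite coincidence experiments: CHSH
Bell-inequality statistics, marginal-law (no-signaling) diagnostics,
rotation symmetrization, singlet-state quantum modeling, and the
generalized rigid-rod mechanical model.

## Who this is for

Researchers in quantum cognition and foundations of quantum mechanics who
work with joint-probability tables from coincidence experiments — four
joint measurements AB, AB′, A′B, A′B′, each with four outcome pairs. The
motivating data set is the windrose experiment, in which 85 respondents
chose pairs of compass directions as good examples of *Two Different Wind
Directions* (A = North/South, A′ = East/West, B = Northeast/Southwest,
B′ = Southeast/Northwest); the package ships those probabilities as
`windrose_data()` and as plain-text fixtures under `inst/extdata/`.

## The statistics at the core

For each joint measurement, E(X,Y) = p11 − p12 − p21 + p22, and

    S = E(A,B) − E(A,B′) + E(A′,B) + E(A′,B′)

Local (experimentally separated) systems obey |S| ≤ 2; quantum product
measurements on an entangled state reach at most 2√2; the algebraic bound
is 4. The marginal law requires each side's outcome marginals to be
independent of the partner measurement (eight equalities).

The package implements, on top of this data model:

* **Symmetrization** — the 180° coin-flip and octahedral eight-rotation
  mixing protocols, which read rotated-measurement probabilities off the
  unrotated data via the respondent-consistency assumption. Both force
  every marginal to exactly 1/2 while preserving S exactly.
* **Quantum model** — the two-qubit singlet state with product spin
  observables: Born probabilities in closed form and by explicit
  4-dimensional computation, and `solve_directions()`, which recovers
  measurement directions reproducing a symmetric table (closed form, an
  exact geometric construction, and a least-squares fallback).
* **Rigid-rod model** — two Bloch spheres with (ε, d)-elastic measurement
  bands and a rod-enforced anticorrelation: closed-form sequential and
  order-mixed probabilities, marginals, E = −cos θ/ε + d²/ε²,
  |S| = 2|√2/ε − d²/ε²|, and a seeded Monte-Carlo simulator. It violates
  CHSH maximally (|S| = 4 at ε = √2/2, d = 0) while keeping the marginal
  law, and shows marginal-law violation (d ≠ 0) *reduces* |S|.
* **Synthetic respondents** — categorical sampling of per-participant
  choices, the consistency map for rotated replicas, mixed-protocol
  sampling, and a participant bootstrap for any table statistic.

## Worked example

```r
library(bellcog)

obs <- windrose_data()      # the observed 85-respondent table
chsh(obs)
#> CHSH summary
#>   E(AB) = -0.60
#>   E(AB') [minus term] = +0.64
#>   E(A'B) = -0.60
#>   E(A'B') = -0.64
#>   S = -2.48, |S| = 2.48
#>   marginal law violated (max |residual| = 0.17, tol = 1e-09)
```

The raw data violate CHSH *and* the marginal law (largest residual 0.17).
Octahedral symmetrization removes the marginal-law violation without
touching S:

```r
oct <- symmetrize_octahedral(obs)
chsh(oct)
#> CHSH summary
#>   E(AB) = -0.62
#>   E(AB') [minus term] = +0.62
#>   E(A'B) = -0.62
#>   E(A'B') = -0.62
#>   S = -2.48, |S| = 2.48
#>   marginal law obeyed (max |residual| = 0, tol = 1e-09)
```

Every block of `oct` is `[0.095, 0.405; 0.405, 0.095]` up to the AB′ sign
pattern, the symmetric table a singlet state reproduces exactly:

```r
solve_directions(oct)
#> Singlet-model solution (closed-form, residual 5.55e-17)
#>   a   theta =    0.00 deg, phi =    0.00 deg, xyz = (+0.0000, +0.0000, +1.0000)
#>   a'  theta =   76.63 deg, phi =   51.36 deg, xyz = (+0.6075, +0.7599, +0.2312)
#>   b   theta =   51.68 deg, phi =    0.00 deg, xyz = (+0.7846, +0.0000, +0.6200)
#>   b'  theta =  128.32 deg, phi =   51.36 deg, xyz = (+0.4899, +0.6128, -0.6200)
```

Read: pointing four Stern–Gerlach apparatuses along these directions and
measuring a singlet pair reproduces the symmetrized cognitive data — b at
51.68° from a, with E(X,Y) = −x·y = −0.62 for three pairs and +0.62 for
(a, b′). The whole chain (validate → summarize → both symmetrizations →
quantum fit) is one call: `run_full_pipeline(obs, tol = 0.011)`.

The mechanical counterpart:

```r
rod_chsh(elastic_band(1, 0))           # 2.828427  (Tsirelson, Born limit)
rod_chsh(elastic_band(sqrt(2)/2, 0))   # 4         (maximal, marginal law intact)
chsh(simulate_rod(rod_maximal_config(), n_trials = 1e4, seed = 1)$table)$absS
#> [1] 4
```

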