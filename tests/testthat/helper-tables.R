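# Fixture builders shared across test files. Everything is generated in
# code; the observed windrose probabilities are typed in by hand so tests
# do not depend on the package's own copy.

observed_probs <- function() {
  joint_table(list(
    AB   = matrix(c(0.13, 0.55, 0.25, 0.07), 2, 2, byrow = TRUE),
    ABp  = matrix(c(0.47, 0.12, 0.06, 0.35), 2, 2, byrow = TRUE),
    ApB  = matrix(c(0.13, 0.38, 0.42, 0.07), 2, 2, byrow = TRUE),
    ApBp = matrix(c(0.09, 0.44, 0.38, 0.09), 2, 2, byrow = TRUE)
  ), n_participants = 85L)
}

# Expected 180-degree-symmetrized table (halved sums of the observed cells).
sym180_expected <- function() {
  joint_table(list(
    AB   = matrix(c(0.10, 0.40, 0.40, 0.10), 2, 2, byrow = TRUE),
    ABp  = matrix(c(0.41, 0.09, 0.09, 0.41), 2, 2, byrow = TRUE),
    ApB  = matrix(c(0.10, 0.40, 0.40, 0.10), 2, 2, byrow = TRUE),
    ApBp = matrix(c(0.09, 0.41, 0.41, 0.09), 2, 2, byrow = TRUE)
  ))
}

# Expected octahedrally symmetrized table.
octahedral_expected <- function() {
  joint_table(list(
    AB   = matrix(c(0.095, 0.405, 0.405, 0.095), 2, 2, byrow = TRUE),
    ABp  = matrix(c(0.405, 0.095, 0.095, 0.405), 2, 2, byrow = TRUE),
    ApB  = matrix(c(0.095, 0.405, 0.405, 0.095), 2, 2, byrow = TRUE),
    ApBp = matrix(c(0.095, 0.405, 0.405, 0.095), 2, 2, byrow = TRUE)
  ))
}

uniform_table <- function() joint_table(array(0.25, c(2, 2, 4)))

# Deterministic anticorrelated table: p12 = p21 = 0.5 in all four blocks.
anticorrelated_table <- function() {
  joint_table(array(rep(c(0, 0.5, 0.5, 0), 4), c(2, 2, 4)))
}

# Random normalized table (Dirichlet-flat per block).
random_table <- function() {
  p <- array(stats::rexp(16), c(2, 2, 4))
  for (k in 1:4) p[, , k] <- p[, , k] / sum(p[, , k])
  joint_table(p)
}

# Random unit direction, uniform on the sphere.
random_direction <- function() {
  v <- stats::rnorm(3)
  as_bloch_xyz(v / sqrt(sum(v^2)))
}

as_bloch_xyz <- function(v) {
  bloch_direction(acos(min(1, max(-1, v[3]))), atan2(v[2], v[1]))
}

random_direction_set <- function() {
  list(a = random_direction(), ap = random_direction(),
       b = random_direction(), bp = random_direction())
}

# 3-sigma binomial bound for an empirical cell frequency.
binom_bound <- function(p, n, k = 3) k * sqrt(p * (1 - p) / n) + 1e-12
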