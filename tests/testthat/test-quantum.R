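test_that("spin observables are Hermitian with eigenvalues +1 and -1", {
  expect_equal(spin_observable(bloch_direction(0)),
               matrix(c(1, 0, 0, -1), 2, 2) + 0i)
  expect_equal(spin_observable(bloch_direction(pi / 2, 0)),
               matrix(c(0, 1, 1, 0), 2, 2) + 0i)
  set.seed(48)
  for (r in 1:20) {
    d <- random_direction()
    ob <- spin_observable(d)
    expect_equal(ob, Conj(t(ob)))
    expect_equal(sum(diag(ob)), 0 + 0i)
    expect_equal(sort(Re(eigen(ob)$values)), c(-1, 1), tolerance = 1e-12)
  }
  expect_error(spin_observable(c(1, 1, 0)), class = "assumption_error")
})

test_that("joint eigenvectors satisfy the product eigenvalue equation", {
  # at the poles the joint eigenvector is a canonical basis vector
  v <- joint_eigenvector(bloch_direction(0), bloch_direction(0), 1, 1)
  expect_equal(v, c(1, 0, 0, 0) + 0i)
  set.seed(49)
  for (r in 1:20) {
    dL <- random_direction(); dR <- random_direction()
    sL <- sample(c(-1, 1), 1); sR <- sample(c(-1, 1), 1)
    v <- joint_eigenvector(dL, dR, sL, sR)
    expect_equal(sum(Mod(v)^2), 1, tolerance = 1e-12)
    obs <- kronecker(spin_observable(dL), spin_observable(dR))
    expect_equal(as.vector(obs %*% v), sL * sR * v, tolerance = 1e-12)
  }
})

test_that("closed-form singlet probabilities match the explicit Born rule", {
  d0 <- bloch_direction(0)
  db <- bloch_direction(acos(0.62))
  expect_equal(singlet_probability(d0, db, 1, 1), 0.095, tolerance = 1e-12)
  expect_equal(singlet_probability(d0, db, 1, 1, method = "explicit"),
               0.095, tolerance = 1e-12)

  set.seed(50)
  for (r in 1:300) {
    dL <- random_direction(); dR <- random_direction()
    total <- 0
    for (sL in c(-1, 1)) for (sR in c(-1, 1)) {
      pc <- singlet_probability(dL, dR, sL, sR)
      pe <- singlet_probability(dL, dR, sL, sR, method = "explicit")
      expect_lt(abs(pc - pe), 1e-12)
      total <- total + pc
    }
    expect_equal(total, 1, tolerance = 1e-12)
    # perfect anticorrelation along a common axis
    expect_equal(singlet_probability(dL, dL, 1, 1), 0, tolerance = 1e-12)
  }
})

test_that("predicted tables obey the marginal law and E = -dot product", {
  set.seed(51)
  for (r in 1:20) {
    dirs <- random_direction_set()
    tab <- predicted_table(dirs)
    validate_table(tab, tol = 1e-12)
    expect_equal(unname(marginal_residuals(tab)), rep(0, 8),
                 tolerance = 1e-14)
    expect_equal(expectation_value(tab, "AB"),
                 -sum(dirs$a$xyz * dirs$b$xyz), tolerance = 1e-12)
    expect_equal(expectation_value(tab, "ApBp"),
                 -sum(dirs$ap$xyz * dirs$bp$xyz), tolerance = 1e-12)
    expect_lte(chsh(tab)$absS, 2 * sqrt(2) + 1e-9)  # Tsirelson bound
  }
  # orthogonal directions give the uniform block
  tab <- predicted_table(list(a = bloch_direction(0), b = bloch_direction(pi / 2),
                              ap = bloch_direction(pi / 2, pi / 2),
                              bp = bloch_direction(pi)))
  expect_equal(unname(tab$p[, , "AB"]), matrix(0.25, 2, 2))
})

test_that("the predicted table is invariant under global rotations", {
  rot_matrix <- function(axis, angle) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  }
  set.seed(52)
  for (r in 1:10) {
    dirs <- random_direction_set()
    R <- rot_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
    rotated <- lapply(dirs, function(d) {
      v <- as.vector(R %*% d$xyz)
      bloch_direction(acos(min(1, max(-1, v[3]))), atan2(v[2], v[1]))
    })
    expect_equal(predicted_table(rotated)$p, predicted_table(dirs)$p,
                 tolerance = 1e-12)
  }
})

test_that("numeric maximization of |S| over directions attains 2 sqrt(2)", {
  objective <- function(par) {
    dirs <- list(a = bloch_direction(0), b = bloch_direction(par[1]),
                 ap = bloch_direction(par[2], par[4]),
                 bp = bloch_direction(par[3], par[4]))
    -chsh(predicted_table(dirs))$absS
  }
  # the quantum Bell-test geometry is the known optimum; start nearby and far
  fits <- lapply(list(c(0.7, 1.4, 2.2, 0), c(2, 1, 3, 1)), function(st) {
    stats::optim(st, objective, method = "L-BFGS-B",
                 lower = c(0, 0, 0, -pi), upper = c(pi, pi, pi, pi))
  })
  best <- -min(vapply(fits, `[[`, numeric(1), "value"))
  expect_equal(best, 2 * sqrt(2), tolerance = 1e-6)
})

test_that("solving the symmetrized windrose table recovers the known angles", {
  sol <- solve_directions(octahedral_expected())
  expect_equal(sol$method, "closed-form")
  deg <- 180 / pi
  expect_equal(sol$directions$b$theta * deg, 51.68, tolerance = 0.02 / 51)
  expect_equal(sol$directions$bp$theta, acos(-0.62), tolerance = 1e-9)
  expect_equal(sol$directions$ap$phi * deg, 51.37, tolerance = 0.02 / 51)
  expect_equal(sol$directions$bp$phi, sol$directions$ap$phi)
  expect_equal(sol$directions$ap$theta,
               acos(-0.62) - acos(0.62), tolerance = 1e-9)
  expect_lt(sol$residual, 1e-12)
  expect_equal(sol$predicted$p, octahedral_expected()$p, tolerance = 1e-12)
})

test_that("solve/predict round-trips random symmetric targets", {
  set.seed(53)
  for (r in 1:15) {
    dirs <- random_direction_set()
    target <- predicted_table(dirs)
    sol <- solve_directions(target, tol = 1e-9)
    expect_lt(sol$residual, 1e-9)
  }
})

test_that("infeasible targets raise structured errors", {
  # marginal-law violation
  expect_error(solve_directions(observed_probs(), tol = 0.011),
               class = "infeasible_target_error")
  # PR-box-like table: S = 4 exceeds the Tsirelson bound
  pr <- joint_table(list(
    AB   = matrix(c(0, 0.5, 0.5, 0), 2, 2),
    ABp  = matrix(c(0.5, 0, 0, 0.5), 2, 2),
    ApB  = matrix(c(0, 0.5, 0.5, 0), 2, 2),
    ApBp = matrix(c(0, 0.5, 0.5, 0), 2, 2)
  ))
  expect_error(solve_directions(pr, tol = 0.011),
               class = "infeasible_target_error")
})

test_that("pairwise angles reproduce the published direction geometry", {
  printed <- list(a = c(0, 0, 1), b = c(0.78, 0, 0.62),
                  ap = c(0.61, 0.76, 0.23), bp = c(0.49, 0.61, -0.62))
  ang <- pairwise_angles(printed)
  get <- function(p) ang[ang$pair == p, ]
  expect_equal(get("ap,b")$cosine, 0.6184, tolerance = 1e-12)
  expect_equal(get("b,bp")$angle_deg, 90.13, tolerance = 0.02 / 90)
  expect_equal(get("a,b")$cosine, 0.62, tolerance = 1e-12)
  same <- pairwise_angles(list(a = c(0, 0, 1), ap = c(0, 0, 1),
                               b = c(1, 0, 0), bp = c(1, 0, 0)))
  expect_equal(same[same$pair == "a,ap", "angle_deg"], 0)
})
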