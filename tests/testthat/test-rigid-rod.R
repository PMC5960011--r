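# independent Monte-Carlo oracle for the sequential mechanism, written
# directly from the mechanics (not via the package simulator)
mc_sequential <- function(first, second, theta, n) {
  b1 <- stats::runif(n, first$d - first$epsilon, first$d + first$epsilon)
  out1 <- ifelse(b1 <= 0, 1L, 2L)
  land <- ifelse(out1 == 1L, -cos(theta), cos(theta))
  b2 <- stats::runif(n, second$d - second$epsilon, second$d + second$epsilon)
  out2 <- ifelse(b2 <= land, 1L, 2L)
  table(factor(out1, 1:2), factor(out2, 1:2)) / n
}

test_that("sequential probabilities match limits and a Monte-Carlo oracle", {
  u <- elastic_band(1)
  expect_equal(unname(sequential_probs(u, u, 0)),
               matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(unname(sequential_probs(u, u, pi / 2)),
               matrix(0.25, 2, 2))
  p <- sequential_probs(u, u, pi / 3)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  eA <- elastic_band(0.9, 0.05); eB <- elastic_band(0.8, -0.1)
  closed <- sequential_probs(eA, eB, pi / 3)
  set.seed(54)
  n <- 1e6
  emp <- mc_sequential(eA, eB, pi / 3, n)
  for (i in 1:2) for (j in 1:2) {
    expect_lt(abs(emp[i, j] - closed[i, j]), binom_bound(closed[i, j], n))
  }

  # landing assumption: cos(theta) must fit the second breakable segment
  expect_error(sequential_probs(u, elastic_band(0.5), 0),
               class = "assumption_error")
})

test_that("order-mixed probabilities average the two sequential orders", {
  eA <- elastic_band(0.8, 0.1); eB <- elastic_band(0.8, -0.05)
  theta <- pi / 3  # cos = 0.5, inside both breakable reaches
  lr <- sequential_probs(eA, eB, theta)
  rl <- sequential_probs(eB, eA, theta)
  expect_equal(mixed_probs(eA, eB, theta), (lr + t(rl)) / 2)
  expect_equal(sum(mixed_probs(eA, eB, theta)), 1, tolerance = 1e-12)

  # symmetric identical elastics (d = 0): order-independent
  s1 <- elastic_band(0.9)
  expect_equal(mixed_probs(s1, s1, pi / 5),
               sequential_probs(s1, s1, pi / 5), tolerance = 1e-12)
})

test_that("closed-form marginals match cell sums and the violation term", {
  eA <- elastic_band(0.8); eB <- elastic_band(0.8, 0.1)
  theta <- acos(0.5)
  marg <- rod_marginals(eA, eB, theta)
  # d_A = 0 so only the left marginals pick up the violation term
  expect_equal(unname(marg["left1"] - 0.5), 0.1 * 0.5 / (4 * 0.8 * 0.8),
               tolerance = 1e-12)
  expect_equal(unname(marg["left1"] - 0.5), 0.01953125, tolerance = 1e-12)

  set.seed(55)
  for (r in 1:20) {
    e1 <- elastic_band(stats::runif(1, 0.75, 1))
    e1$d <- stats::runif(1, -(1 - e1$epsilon), 1 - e1$epsilon)
    e2 <- elastic_band(stats::runif(1, 0.75, 1))
    e2$d <- stats::runif(1, -(1 - e2$epsilon), 1 - e2$epsilon)
    reach <- min(e1$epsilon - abs(e1$d), e2$epsilon - abs(e2$d))
    theta <- acos(stats::runif(1, -reach, reach))
    m <- mixed_probs(e1, e2, theta)
    marg <- rod_marginals(e1, e2, theta)
    expect_equal(unname(marg),
                 c(sum(m[1, ]), sum(m[2, ]), sum(m[, 1]), sum(m[, 2])),
                 tolerance = 1e-12)
    expect_equal(sum(marg[1:2]), 1, tolerance = 1e-12)
    # d = 0 on one side zeroes that side's opposite-side violation term
    expect_true(all(m >= 0 & m <= 1))
  }

  # symmetric elastics preserve the marginal law for every angle
  s <- elastic_band(0.9)
  for (theta in c(0.5, 1, 2, 2.5)) {
    if (abs(cos(theta)) <= 0.9) {
      expect_equal(unname(rod_marginals(s, s, theta)), rep(0.5, 4))
    }
  }
})

test_that("rod expectation matches the mixed-probability cells", {
  expect_equal(rod_expectation(elastic_band(1), pi / 3), -cos(pi / 3))
  e <- elastic_band(0.8, 0.15)
  expect_equal(rod_expectation(e, pi / 2), 0.15^2 / 0.8^2)
  set.seed(56)
  for (r in 1:20) {
    eps <- stats::runif(1, 0.8, 1)
    d <- stats::runif(1, -(1 - eps), 1 - eps)
    e <- elastic_band(eps, d)
    theta <- acos(stats::runif(1, -(eps - abs(d)), eps - abs(d)))
    m <- mixed_probs(e, e, theta)
    expect_equal(rod_expectation(e, theta),
                 m[1, 1] - m[1, 2] - m[2, 1] + m[2, 2], tolerance = 1e-12)
  }
})

test_that("rod CHSH hits 2 sqrt(2) at (1,0), 4 at (sqrt(2)/2,0), and falls with |d|", {
  expect_equal(rod_chsh(elastic_band(sqrt(2) / 2)), 4, tolerance = 1e-12)
  expect_equal(rod_chsh(elastic_band(1)), 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(rod_chsh(elastic_band(0.9, 0.05)),
               2 * abs(sqrt(2) / 0.9 - 0.0025 / 0.81), tolerance = 1e-12)

  # CHSH from the closed-form tables agrees with the formula
  for (pars in list(c(sqrt(2) / 2, 0), c(1, 0), c(0.85, 0.1))) {
    cfg <- rod_maximal_config(pars[1], pars[2])
    expect_equal(chsh(rod_table(cfg))$absS,
                 rod_chsh(elastic_band(pars[1], pars[2])), tolerance = 1e-12)
  }

  # increasing |d| at fixed epsilon shrinks the violation
  ds <- seq(0, 0.1, by = 0.05)
  s_vals <- vapply(ds, function(d) rod_chsh(elastic_band(0.85, d)), numeric(1))
  expect_true(all(diff(s_vals) < 0))

  expect_error(rod_chsh(elastic_band(0.6, 0)), class = "assumption_error")
})

test_that("the simulator reproduces the closed forms within binomial error", {
  # exact anticorrelation for uniform elastics at theta = 0
  u <- elastic_band(1)
  cfg0 <- rod_config(list(A = u, Ap = u, B = u, Bp = u),
                     c(A = 0, Ap = 0, B = 0, Bp = 0))
  sim0 <- simulate_rod(cfg0, 2e4, seed = 57)
  for (m in c("AB", "ABp", "ApB", "ApBp")) {
    expect_equal(sim0$table$p[1, 2, m] + sim0$table$p[2, 1, m], 1)
  }

  e <- elastic_band(0.9, 0.05)
  cfg <- rod_maximal_config(0.9, 0.05)
  n <- 1e6
  sim <- simulate_rod(cfg, n, seed = 58)
  closed <- rod_table(cfg)
  for (m in c("AB", "ABp", "ApB", "ApBp")) {
    for (i in 1:2) for (j in 1:2) {
      expect_lt(abs(sim$table$p[i, j, m] - closed$p[i, j, m]),
                binom_bound(closed$p[i, j, m], n))
    }
    # empirical marginals vs the closed-form marginal law expressions
    pr_theta <- c(AB = pi / 4, ABp = 3 * pi / 4, ApB = -pi / 4,
                  ApBp = pi / 4)[[m]]
    marg <- rod_marginals(e, e, pr_theta)
    expect_lt(abs(sum(sim$table$p[1, , m]) - marg[["left1"]]),
              binom_bound(marg[["left1"]], n))
    expect_lt(abs(sum(sim$table$p[, 1, m]) - marg[["right1"]]),
              binom_bound(marg[["right1"]], n))
  }
  expect_identical(sim$seed, 58)
  expect_error(simulate_rod(cfg, 0), class = "assumption_error")
})

test_that("trial records stay inside the breakable segments", {
  cfg <- rod_maximal_config(0.9, 0.05)
  sim <- simulate_rod(cfg, 500, seed = 59, keep_records = TRUE)
  for (m in c("AB", "ABp", "ApB", "ApBp")) {
    rec <- sim$records[[m]]
    expect_equal(nrow(rec), 500)
    expect_true(all(abs(rec$break_first - 0.05) <= 0.9))
    expect_true(all(abs(rec$break_second - 0.05) <= 0.9))
    expect_true(all(rec$outcome_left %in% c(-1, 1)))
  }
})

test_that("uniform elastics reproduce the singlet model for coplanar directions", {
  u <- elastic_band(1)
  angles <- c(A = 0, Ap = pi / 2, B = pi / 4, Bp = 3 * pi / 4)
  cfg <- rod_config(list(A = u, Ap = u, B = u, Bp = u), angles)
  dirs <- lapply(angles, function(t) bloch_direction(t, 0))
  names(dirs) <- c("a", "ap", "b", "bp")
  expect_equal(rod_table(cfg)$p, predicted_table(dirs)$p, tolerance = 1e-12)
})

test_that("elastic parameters are recoverable from simulated tables", {
  gen <- c(eps = 0.85, d = 0.08)
  cfg <- rod_maximal_config(gen["eps"], gen["d"])
  n <- 2e5
  sim <- simulate_rod(cfg, n, seed = 60)
  loss <- function(par) {
    if (par[1] > 1 || abs(par[2]) > 1 - par[1] ||
        par[1] - abs(par[2]) <= sqrt(2) / 2 + 1e-9) return(1e6)
    pred <- rod_table(rod_maximal_config(par[1], par[2]))
    sum((pred$p - sim$table$p)^2)
  }
  fit <- stats::optim(c(0.9, 0), loss, method = "Nelder-Mead")
  expect_lt(abs(fit$par[1] - gen[["eps"]]), 0.01)
  expect_lt(abs(fit$par[2] - gen[["d"]]), 0.01)
})
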