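#' Locally uniform elastic band
#'
#' A measurement elastic stretched along a sphere diameter, breakable
#' uniformly only on the segment \[d - epsilon, d + epsilon\] (coordinates in
#' \[-1, 1\]; the +1 end is outcome 1, the -1 end outcome 2) and unbreakable
#' elsewhere. The uniform Born-rule elastic is (epsilon, d) = (1, 0);
#' epsilon < 1 strengthens correlations, d != 0 makes the elastic asymmetric
#' and generates order effects and marginal-law violations.
#'
#' @param epsilon Half-length of the breakable segment, in (0, 1].
#' @param d Center offset of the breakable segment; |d| <= 1 - epsilon.
#' @return Object of class `elastic_band`.
#' @export
elastic_band <- function(epsilon, d = 0) {
  stopifnot(is.numeric(epsilon), is.numeric(d),
            length(epsilon) == 1L, length(d) == 1L)
  if (epsilon <= 0 || epsilon > 1) {
    abort_assumption("epsilon must be in (0, 1]")
  }
  if (abs(d) > 1 - epsilon + 1e-12) {
    abort_assumption("need |d| <= 1 - epsilon so the breakable segment stays inside the sphere")
  }
  structure(list(epsilon = epsilon, d = d), class = "elastic_band")
}

check_landing <- function(first, second, theta) {
  # the second particle lands at +-cos(theta) on the second elastic; the
  # model assumes it always lands on a breakable region
  if (abs(cos(theta)) > second$epsilon - abs(second$d) + 1e-12) {
    abort_assumption(sprintf(
      "|cos(theta)| = %.4g exceeds the breakable reach epsilon - |d| = %.4g of the second elastic",
      abs(cos(theta)), second$epsilon - abs(second$d)))
  }
}

#' Sequential-measurement probabilities of the rigid-rod model
#'
#' Closed-form joint probabilities for measuring the `first` side, letting
#' the rod force the other particle to the antipodal position, then
#' measuring the `second` side whose elastic is rotated by `theta` relative
#' to the first. Returned as a 2 x 2 matrix indexed (first-side outcome,
#' second-side outcome); the four cells sum to 1.
#'
#' @param first,second [elastic_band()]s of the first- and second-measured
#'   side.
#' @param theta Relative angle between the two elastics, radians. Requires
#'   |cos(theta)| <= epsilon_second - |d_second| (the landing assumption).
#' @return 2 x 2 numeric matrix.
#' @examples
#' sequential_probs(elastic_band(1), elastic_band(1), 0)  # perfect anticorrelation
#' @export
sequential_probs <- function(first, second, theta) {
  stopifnot(inherits(first, "elastic_band"), inherits(second, "elastic_band"))
  check_landing(first, second, theta)
  e1 <- first$epsilon;  d1 <- first$d
  e2 <- second$epsilon; d2 <- second$d
  ct <- cos(theta)
  p1 <- (e1 - d1) / (2 * e1)   # first side gives outcome 1
  # landing at -cos(theta) after outcome 1, +cos(theta) after outcome 2
  q1 <- (e2 - d2 - ct) / (2 * e2)  # second side gives outcome 1 | first = 1
  q2 <- (e2 - d2 + ct) / (2 * e2)  # second side gives outcome 1 | first = 2
  matrix(c(p1 * q1, (1 - p1) * q2, p1 * (1 - q1), (1 - p1) * (1 - q2)), 2L, 2L)
}

#' Order-mixed probabilities of the rigid-rod model
#'
#' Uniform average of the two sequential orders ('left then right' and
#' 'right then left'), indexed (left outcome i, right outcome j). This is
#' the table observed when the measurement order is unknown or randomized.
#'
#' @param left,right [elastic_band()]s of the left (A-type) and right
#'   (B-type) side.
#' @param theta Relative angle, radians; the landing assumption must hold
#'   for whichever side is measured second, hence for both.
#' @return 2 x 2 numeric matrix summing to 1.
#' @export
mixed_probs <- function(left, right, theta) {
  lr <- sequential_probs(left, right, theta)
  rl <- sequential_probs(right, left, theta)
  (lr + t(rl)) / 2
}

#' Marginal sums of the order-mixed rigid-rod probabilities
#'
#' The four closed-form marginals of [mixed_probs()]: left outcome 1 and 2
#' row sums, right outcome 1 and 2 column sums. The terms
#' d_right cos(theta) / (4 e_left e_right) (and its mirror) are the
#' marginal-law-violating contributions: they vanish when the elastics are
#' symmetric (d = 0), whatever theta.
#'
#' @inheritParams mixed_probs
#' @return Named numeric vector `left1`, `left2`, `right1`, `right2`.
#' @export
rod_marginals <- function(left, right, theta) {
  check_landing(right, left, theta)
  check_landing(left, right, theta)
  eA <- left$epsilon;  dA <- left$d
  eB <- right$epsilon; dB <- right$d
  ct <- cos(theta)
  c(
    left1  = (eA - dA) / (2 * eA) + dB * ct / (4 * eA * eB),
    left2  = (eA + dA) / (2 * eA) - dB * ct / (4 * eA * eB),
    right1 = (eB - dB) / (2 * eB) + dA * ct / (4 * eA * eB),
    right2 = (eB + dB) / (2 * eB) - dA * ct / (4 * eA * eB)
  )
}

#' Rigid-rod expectation value for identical elastics
#'
#' When both sides share the same (epsilon, d) elastic, the order-mixed
#' correlation is E = -cos(theta) / epsilon + d^2 / epsilon^2. The uniform
#' limit (1, 0) recovers the singlet quantum value -cos(theta).
#'
#' @param e An [elastic_band()] shared by both sides.
#' @param theta Relative angle, radians.
#' @return Numeric scalar.
#' @export
rod_expectation <- function(e, theta) {
  stopifnot(inherits(e, "elastic_band"))
  check_landing(e, e, theta)
  -cos(theta) / e$epsilon + e$d^2 / e$epsilon^2
}

#' Maximal CHSH value of the rigid-rod model
#'
#' With identical (epsilon, d) elastics on all four measurements and the
#' maximal-violation coplanar angle set (cosines +-sqrt(2)/2, the quantum
#' Bell-test geometry), the CHSH quantity is
#' |S| = 2 |sqrt(2)/epsilon - d^2/epsilon^2|. Symmetric elastics (d = 0)
#' give |S| = 2 sqrt(2) / epsilon: at epsilon = 1 the Tsirelson bound, at
#' the minimal admissible epsilon = sqrt(2)/2 the algebraic maximum 4, with
#' the marginal law intact throughout. Asymmetry (d != 0) violates the
#' marginal law yet lowers |S|.
#'
#' @param e An [elastic_band()] shared by all four measurements; the
#'   landing assumption requires epsilon - |d| >= sqrt(2)/2.
#' @return |S|, a nonnegative scalar.
#' @examples
#' rod_chsh(elastic_band(sqrt(2) / 2))  # 4
#' rod_chsh(elastic_band(1))            # 2 * sqrt(2)
#' @export
rod_chsh <- function(e) {
  stopifnot(inherits(e, "elastic_band"))
  if (sqrt(2) / 2 > e$epsilon - abs(e$d) + 1e-12) {
    abort_assumption("maximal-violation angles need epsilon - |d| >= sqrt(2)/2")
  }
  2 * abs(sqrt(2) / e$epsilon - e$d^2 / e$epsilon^2)
}

#' Rigid-rod model configuration
#'
#' One elastic per measurement A, A', B, B' plus an in-plane orientation
#' angle per measurement (radians, measured like compass angles); the
#' relative angle of a joint measurement is the difference of its two
#' orientations. `order_policy` controls which side is measured first in
#' the simulator.
#'
#' @param elastics Named list of four [elastic_band()]s: `A`, `Ap`, `B`,
#'   `Bp`.
#' @param orientations Named numeric vector of four angles (radians) with
#'   the same names.
#' @param order_policy `"uniform-mix"` (default; order randomized per
#'   trial), `"first-left"`, or `"first-right"`.
#' @return Object of class `rod_config`.
#' @export
rod_config <- function(elastics, orientations,
                       order_policy = c("uniform-mix", "first-left", "first-right")) {
  order_policy <- match.arg(order_policy)
  nm <- c("A", "Ap", "B", "Bp")
  stopifnot(is.list(elastics), all(nm %in% names(elastics)),
            is.numeric(orientations), all(nm %in% names(orientations)))
  for (x in elastics[nm]) stopifnot(inherits(x, "elastic_band"))
  cfg <- structure(
    list(elastics = elastics[nm], orientations = orientations[nm],
         order_policy = order_policy),
    class = "rod_config"
  )
  for (m in measurement_ids) {
    pr <- rod_pair(cfg, m)
    check_landing(pr$left, pr$right, pr$theta)
    check_landing(pr$right, pr$left, pr$theta)
  }
  cfg
}

rod_pair <- function(config, m) {
  la <- first_axis_of[[m]]; ra <- second_axis_of[[m]]
  list(left = config$elastics[[la]], right = config$elastics[[ra]],
       theta = unname(config$orientations[[ra]] - config$orientations[[la]]))
}

#' Maximal-violation rod configuration
#'
#' Identical (epsilon, d) elastics on all four measurements with coplanar
#' orientations A = 0, B = pi/4, A' = pi/2, B' = 3 pi/4, giving relative
#' cosines +sqrt(2)/2 for AB, A'B, A'B' and -sqrt(2)/2 for AB' -- the angle
#' set maximizing |S| under the CHSH convention with the minus sign on the
#' AB' term.
#'
#' @param epsilon,d Shared elastic parameters; defaults give |S| = 4.
#' @param order_policy Passed to [rod_config()].
#' @return A [rod_config()].
#' @export
rod_maximal_config <- function(epsilon = sqrt(2) / 2, d = 0,
                               order_policy = "uniform-mix") {
  e <- elastic_band(epsilon, d)
  rod_config(
    elastics = list(A = e, Ap = e, B = e, Bp = e),
    orientations = c(A = 0, Ap = pi / 2, B = pi / 4, Bp = 3 * pi / 4),
    order_policy = order_policy
  )
}

#' Expected (closed-form) table of a rod configuration
#'
#' The [mixed_probs()] (or single-order [sequential_probs()]) table of each
#' joint measurement, assembled into a [joint_table()].
#'
#' @param config A [rod_config()].
#' @return A [joint_table()].
#' @export
rod_table <- function(config) {
  stopifnot(inherits(config, "rod_config"))
  p <- array(NA_real_, c(2L, 2L, 4L))
  for (k in seq_along(measurement_ids)) {
    pr <- rod_pair(config, measurement_ids[k])
    p[, , k] <- switch(config$order_policy,
      "uniform-mix" = mixed_probs(pr$left, pr$right, pr$theta),
      "first-left"  = sequential_probs(pr$left, pr$right, pr$theta),
      "first-right" = t(sequential_probs(pr$right, pr$left, pr$theta))
    )
  }
  joint_table(p)
}

#' Monte-Carlo simulation of the rigid-rod mechanism
#'
#' Simulates the mechanism trial by trial for each joint measurement: the
#' first particle sits at elastic coordinate 0; the elastic breaks at a
#' uniform point of its breakable segment; the outcome is +1 (outcome 1)
#' iff the break point is at or below the particle coordinate. The rod
#' places the second particle antipodally, so it lands at coordinate
#' -(sign) * cos(theta) on the second elastic, which breaks by the same
#' rule. Ties (break exactly at the particle) go to outcome +1; they have
#' probability zero.
#'
#' @param config A [rod_config()].
#' @param n_trials Trials per joint measurement (> 0).
#' @param seed Integer seed; recorded in the result.
#' @param keep_records If `TRUE`, also return the per-trial records
#'   (order, break points, outcomes) for every measurement.
#' @return List with `table` (empirical [joint_table()]), `counts`
#'   (2 x 2 x 4 integer array), `n_trials`, `seed`, `generator`, and, if
#'   requested, `records` (named list of data frames).
#' @examples
#' sim <- simulate_rod(rod_maximal_config(), n_trials = 1e4, seed = 1)
#' chsh(sim$table)$absS  # near 4
#' @export
simulate_rod <- function(config, n_trials, seed = 1L, keep_records = FALSE) {
  stopifnot(inherits(config, "rod_config"))
  if (!is.numeric(n_trials) || n_trials <= 0 || n_trials != round(n_trials)) {
    abort_assumption("n_trials must be a positive integer")
  }
  n_trials <- as.integer(n_trials)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  counts <- array(0L, c(2L, 2L, 4L),
                  dimnames = list(i = c("1", "2"), j = c("1", "2"),
                                  m = measurement_ids))
  records <- if (keep_records) stats::setNames(vector("list", 4L), measurement_ids)
  for (k in seq_along(measurement_ids)) {
    pr <- rod_pair(config, measurement_ids[k])
    left_first <- switch(config$order_policy,
      "uniform-mix" = stats::runif(n_trials) < 0.5,
      "first-left"  = rep(TRUE, n_trials),
      "first-right" = rep(FALSE, n_trials)
    )
    e1 <- ifelse(left_first, pr$left$epsilon, pr$right$epsilon)
    d1 <- ifelse(left_first, pr$left$d, pr$right$d)
    e2 <- ifelse(left_first, pr$right$epsilon, pr$left$epsilon)
    d2 <- ifelse(left_first, pr$right$d, pr$left$d)
    break1 <- stats::runif(n_trials, d1 - e1, d1 + e1)
    out1 <- ifelse(break1 <= 0, 1L, -1L)
    coord2 <- -out1 * cos(pr$theta)
    break2 <- stats::runif(n_trials, d2 - e2, d2 + e2)
    out2 <- ifelse(break2 <= coord2, 1L, -1L)
    out_left  <- ifelse(left_first, out1, out2)
    out_right <- ifelse(left_first, out2, out1)
    i <- ifelse(out_left > 0, 1L, 2L)
    j <- ifelse(out_right > 0, 1L, 2L)
    counts[, , k] <- table(factor(i, 1:2), factor(j, 1:2))
    if (keep_records) {
      records[[k]] <- data.frame(
        order = ifelse(left_first, "left-first", "right-first"),
        break_first = break1, break_second = break2,
        outcome_left = out_left, outcome_right = out_right
      )
    }
  }
  out <- list(
    table = joint_table(counts / n_trials),
    counts = counts, n_trials = n_trials, seed = seed,
    generator = RNGkind()[1L]
  )
  if (keep_records) out$records <- records
  out
}
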