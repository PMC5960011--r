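# Synthetic respondent samples. The primitive record is the per-participant
# choice (one outcome pair per joint measurement); tables are derived views.

new_respondent_sample <- function(choices, n, protocol, seed, scheme) {
  structure(
    list(n = n, choices = choices, protocol = protocol, seed = seed,
         scheme = scheme),
    class = "respondent_sample"
  )
}

#' @export
print.respondent_sample <- function(x, ...) {
  cat(sprintf("Respondent sample: n = %d, protocol = %s, seed = %d\n",
              x$n, x$protocol, x$seed))
  invisible(x)
}

slot_index <- function(i, j) (i - 1L) * 2L + j  # 1..4 within a block
slot_ij <- function(s) cbind(i = (s - 1L) %/% 2L + 1L, j = (s - 1L) %% 2L + 1L)

#' Sample respondents from a joint-probability table
#'
#' Emulates the plain (unrotated) protocol: every participant answers all
#' four joint measurements, drawing one outcome pair per measurement from
#' that block's categorical distribution, independently across measurements
#' given the table.
#'
#' @param table A [joint_table()] of generating probabilities.
#' @param n Number of participants (default 85, the windrose study size).
#' @param seed Integer seed; recorded in the sample.
#' @return A `respondent_sample`: list with `n`, `choices` (data frame with
#'   columns `participant`, `measurement`, `i`, `j`), `protocol`, `seed`,
#'   `scheme`.
#' @export
sample_plain <- function(table, n = 85L, seed = 1L) {
  validate_table(table, tol = 0.011)
  if (!is.numeric(n) || n <= 0 || n != round(n)) {
    abort_assumption("n must be a positive integer")
  }
  n <- as.integer(n)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  choices <- do.call(rbind, lapply(measurement_ids, function(m) {
    pr <- as.vector(t(block(table, m)))  # slot order (1,1),(1,2),(2,1),(2,2)
    s <- sample.int(4L, n, replace = TRUE, prob = pr / sum(pr))
    data.frame(participant = seq_len(n), measurement = m, slot_ij(s))
  }))
  choices <- choices[order(choices$participant), ]
  rownames(choices) <- NULL
  new_respondent_sample(choices, n, "plain", as.integer(seed), table$scheme)
}

#' Empirical joint-probability table of a sample
#'
#' Per-block relative frequencies of the recorded choices.
#'
#' @param sample A `respondent_sample`.
#' @return A [joint_table()] with `n_participants` set.
#' @export
empirical_table <- function(sample) {
  stopifnot(inherits(sample, "respondent_sample"))
  p <- array(0, c(2L, 2L, 4L))
  ch <- sample$choices
  for (k in seq_along(measurement_ids)) {
    sub <- ch[ch$measurement == measurement_ids[k], ]
    p[, , k] <- table(factor(sub$i, 1:2), factor(sub$j, 1:2)) / nrow(sub)
  }
  joint_table(p, scheme = sample$scheme, n_participants = sample$n)
}

#' Apply the consistency assumption to a rotated replica
#'
#' Deterministically maps each participant's unrotated choice to the choice
#' they would record in the `45 * k`-degree rotated experiment: the rotated
#' slot whose unordered direction pair equals the one they originally
#' selected (the inverse image under [correspondence()]). No new randomness
#' is introduced, so the empirical table of the rotated sample equals
#' [rotated_table()] of the original empirical table, exactly.
#'
#' @param sample A `respondent_sample`.
#' @param k Rotation steps (integer, mod 8).
#' @return A `respondent_sample` of the rotated experiment.
#' @export
apply_consistency <- function(sample, k) {
  stopifnot(inherits(sample, "respondent_sample"))
  corr <- correspondence(sample$scheme, k)
  # invert: unrotated slot (m_to,i_to,j_to) -> rotated slot (m,i,j)
  from_key <- paste(corr$m_to, corr$i_to, corr$j_to)
  ch <- sample$choices
  idx <- match(paste(ch$measurement, ch$i, ch$j), from_key)
  ch$measurement <- corr$m[idx]
  ch$i <- corr$i[idx]
  ch$j <- corr$j[idx]
  new_respondent_sample(ch, sample$n, sample$protocol, sample$seed,
                        sample$scheme)
}

#' Sample respondents under a rotation-mixing protocol
#'
#' Emulates the coin-flip (rotations \{0, 4\}) or octahedral-die (rotations
#' 0..7) protocol: each participant is assigned a uniformly drawn rotation,
#' makes latent plain-protocol choices, and records their consistency image
#' in the rotated configuration. The empirical table estimates the
#' corresponding symmetrized table ([symmetrize_180()] /
#' [symmetrize_octahedral()]).
#'
#' @inheritParams sample_plain
#' @param protocol `"plain"`, `"coin"` (180-degree), or `"die"`
#'   (octahedral).
#' @return A `respondent_sample` with a `rotation` column in `choices`.
#' @export
sample_mixed_protocol <- function(table, n = 85L,
                                  protocol = c("coin", "die", "plain"),
                                  seed = 1L) {
  protocol <- match.arg(protocol)
  latent <- sample_plain(table, n = n, seed = seed)
  if (protocol == "plain") return(latent)
  ks <- if (protocol == "coin") c(0L, 4L) else 0:7
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed + 1L)  # independent stream for the rotation draws
  rot <- sample(ks, latent$n, replace = TRUE)
  ch <- latent$choices
  for (k in unique(rot)) {
    if (k == 0L) next
    who <- which(rot == k)
    sub <- latent
    sub$choices <- ch[ch$participant %in% who, ]
    mapped <- apply_consistency(sub, k)$choices
    ch[ch$participant %in% who, c("measurement", "i", "j")] <-
      mapped[, c("measurement", "i", "j")]
  }
  ch$rotation <- rot[ch$participant]
  new_respondent_sample(ch, latent$n, protocol, as.integer(seed),
                        latent$scheme)
}

#' Bootstrap a table statistic over participants
#'
#' Resamples participants with replacement, recomputes the empirical table
#' and the statistic, and returns the point estimate with a percentile
#' interval. Participants are the resampling unit (each keeps their four
#' joint-measurement choices together).
#'
#' @param sample A `respondent_sample`.
#' @param statistic Function mapping a [joint_table()] to a single number,
#'   e.g. `function(t) chsh(t)$absS`.
#' @param reps Number of bootstrap replicates.
#' @param seed Integer seed; recorded in the result.
#' @param conf Confidence level for the percentile interval (default 0.95).
#' @return List with `estimate` (statistic on the full sample), `lower`,
#'   `upper`, `replicates`, `reps`, `seed`.
#' @export
bootstrap_statistic <- function(sample, statistic, reps = 1000L, seed = 1L,
                                conf = 0.95) {
  stopifnot(inherits(sample, "respondent_sample"), is.function(statistic))
  if (reps < 1) abort_assumption("reps must be >= 1")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  ch <- sample$choices
  # fast per-measurement slot matrix: n x 4, entries 1..4
  slots <- matrix(NA_integer_, sample$n, 4L,
                  dimnames = list(NULL, measurement_ids))
  for (m in measurement_ids) {
    sub <- ch[ch$measurement == m, ]
    slots[sub$participant, m] <- slot_index(sub$i, sub$j)
  }
  table_from <- function(idx) {
    p <- array(0, c(2L, 2L, 4L))
    for (k in seq_along(measurement_ids)) {
      cnt <- tabulate(slots[idx, k], nbins = 4L)
      p[, , k] <- matrix(cnt, 2L, 2L, byrow = TRUE) / length(idx)
    }
    joint_table(p, scheme = sample$scheme)
  }
  estimate <- statistic(table_from(seq_len(sample$n)))
  replicates <- vapply(seq_len(reps), function(r) {
    statistic(table_from(sample.int(sample$n, replace = TRUE)))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(replicates, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  list(estimate = estimate, lower = qs[1L], upper = qs[2L],
       replicates = replicates, reps = as.integer(reps),
       seed = as.integer(seed))
}
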