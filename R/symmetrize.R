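#' Slot correspondence under a windrose rotation
#'
#' When the whole measurement scheme is rotated clockwise by `45 * k`
#' degrees, each rotated measurement slot (m, (i, j)) presents a pair of
#' compass directions that also occurs, as an unordered pair, in exactly one
#' slot of the unrotated scheme. Under the consistency assumption -- a
#' participant selects the same unordered pair of directions no matter which
#' rotated configuration presents it -- the rotated-slot probability can be
#' read off the unrotated data at that matching slot.
#'
#' @param scheme A [windrose_scheme()].
#' @param k Rotation: number of 45-degree clockwise steps (integer, mod 8).
#' @return A data frame with 16 rows and columns `m`, `i`, `j` (rotated
#'   slot) and `m_to`, `i_to`, `j_to` (the unrotated slot it maps to). For
#'   `k = 0` the map is the identity.
#' @examples
#' corr <- correspondence(windrose_scheme(), 1)
#' subset(corr, m == "AB" & i == 1 & j == 1)  # maps to (ApB, 1, 1)
#' @export
correspondence <- function(scheme = windrose_scheme(), k = 0L) {
  stopifnot(inherits(scheme, "measurement_scheme"))
  # unordered direction pair -> unrotated slot
  key <- function(d1, d2) paste(sort(c(d1, d2)), collapse = "|")
  slots <- expand.grid(j = 1:2, i = 1:2, m = measurement_ids,
                       stringsAsFactors = FALSE)[, c("m", "i", "j")]
  lookup <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(slots))) {
    d <- slot_directions(scheme, slots$m[r], slots$i[r], slots$j[r])
    assign(key(d[1L], d[2L]), slots[r, ], envir = lookup)
  }
  out <- slots
  out$m_to <- NA_character_; out$i_to <- NA_integer_; out$j_to <- NA_integer_
  for (r in seq_len(nrow(slots))) {
    d <- rotate_direction(
      slot_directions(scheme, slots$m[r], slots$i[r], slots$j[r]), k)
    kk <- key(d[1L], d[2L])
    if (!exists(kk, envir = lookup, inherits = FALSE)) {
      abort_mapping(sprintf(
        "rotated slot (%s, %d, %d) shows direction pair {%s, %s} not present in the scheme",
        slots$m[r], slots$i[r], slots$j[r], d[1L], d[2L]))
    }
    tgt <- get(kk, envir = lookup)
    out$m_to[r] <- tgt$m; out$i_to[r] <- tgt$i; out$j_to[r] <- tgt$j
  }
  rownames(out) <- NULL
  out
}

#' Rotate a joint-probability table
#'
#' Builds the table of the `45 * k`-degree rotated experiment from the
#' unrotated one via [correspondence()]: no new data are needed, only the
#' consistency assumption. Block normalization is preserved exactly since
#' the correspondence permutes the 16 slots.
#'
#' @param table A [joint_table()].
#' @param k Rotation steps (integer, mod 8).
#' @return A [joint_table()] of the rotated experiment.
#' @examples
#' rotated_table(windrose_data(), 4)$p["1", "1", "AB"]  # p(A2,B2) = 0.07
#' @export
rotated_table <- function(table, k) {
  stopifnot(inherits(table, "joint_table"))
  corr <- correspondence(table$scheme, k)
  p <- table$p
  for (r in seq_len(nrow(corr))) {
    p[corr$i[r], corr$j[r], corr$m[r]] <-
      table$p[corr$i_to[r], corr$j_to[r], corr$m_to[r]]
  }
  joint_table(p, scheme = table$scheme, n_participants = table$n_participants)
}

#' Uniform mixture of joint-probability tables
#'
#' Cellwise arithmetic mean: the table of the mixed experiment in which one
#' of the given configurations is selected uniformly at random.
#'
#' @param tables Non-empty list of [joint_table()]s sharing a scheme.
#' @return A [joint_table()].
#' @export
mix_uniform <- function(tables) {
  if (length(tables) == 0L) abort_schema("mix_uniform needs at least one table")
  for (t in tables) stopifnot(inherits(t, "joint_table"))
  p <- Reduce(`+`, lapply(tables, `[[`, "p")) / length(tables)
  joint_table(p, scheme = tables[[1L]]$scheme,
              n_participants = tables[[1L]]$n_participants)
}

#' Symmetrize a table over rotations
#'
#' `symmetrize_180()` is the coin-flip protocol: mix the unrotated experiment
#' with its 180-degree rotation (k in \{0, 4\}). `symmetrize_octahedral()`
#' is the eight-faced-die protocol: mix all eight 45-degree rotations
#' (k in 0..7). Both force all eight outcome marginals to exactly 1/2 --
#' hence zero marginal-law residuals -- while leaving the CHSH statistic S of
#' the input table exactly unchanged.
#'
#' @param table A [joint_table()].
#' @return The symmetrized [joint_table()].
#' @examples
#' symmetrize_octahedral(windrose_data())$p["1", "1", "AB"]  # 0.095
#' @export
symmetrize_180 <- function(table) {
  mix_uniform(lapply(c(0L, 4L), function(k) rotated_table(table, k)))
}

#' @rdname symmetrize_180
#' @export
symmetrize_octahedral <- function(table) {
  mix_uniform(lapply(0:7, function(k) rotated_table(table, k)))
}
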