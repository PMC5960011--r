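#' Joint-probability table for the four coincidence measurements
#'
#' The central container of the package: for each joint measurement
#' AB, AB', A'B, A'B' it stores the four outcome-pair probabilities
#' p(X_i, Y_j), i, j in \{1, 2\}, as a 2 x 2 x 4 array. Each 2 x 2 block is a
#' probability distribution over the four outcome pairs of one coincidence
#' measurement and must sum to 1.
#'
#' @param p Either a 2 x 2 x 4 numeric array (slices in the order AB, ABp,
#'   ApB, ApBp), or a named list of four 2 x 2 matrices with those names.
#'   Matrix rows index the first-slot outcome i, columns the second-slot
#'   outcome j.
#' @param scheme A [windrose_scheme()] object; defaults to the windrose.
#' @param n_participants Optional number of respondents behind the
#'   probabilities.
#' @return An object of class `joint_table` with fields `p` (the array),
#'   `scheme`, and `n_participants`.
#' @seealso [validate_table()], [chsh()], [marginal_residuals()]
#' @examples
#' joint_table(array(0.25, c(2, 2, 4)))
#' @export
joint_table <- function(p, scheme = windrose_scheme(), n_participants = NULL) {
  if (is.list(p) && !is.array(p)) {
    missing <- setdiff(measurement_ids, names(p))
    if (length(missing) > 0L) {
      abort_schema(sprintf("missing measurement block(s): %s",
                           paste(missing, collapse = ", ")))
    }
    arr <- array(NA_real_, c(2L, 2L, 4L))
    for (k in seq_along(measurement_ids)) {
      blk <- p[[measurement_ids[k]]]
      if (!is.numeric(blk) || length(blk) != 4L) {
        abort_schema(sprintf("block %s must be a 2x2 numeric matrix",
                             measurement_ids[k]))
      }
      arr[, , k] <- matrix(as.numeric(blk), 2L, 2L)
    }
    p <- arr
  }
  if (!is.numeric(p) || !identical(dim(p), c(2L, 2L, 4L))) {
    abort_schema("p must be a 2 x 2 x 4 numeric array or a named list of 2x2 blocks")
  }
  dimnames(p) <- list(i = c("1", "2"), j = c("1", "2"), m = measurement_ids)
  stopifnot(inherits(scheme, "measurement_scheme"))
  structure(
    list(p = p, scheme = scheme, n_participants = n_participants),
    class = "joint_table"
  )
}

block <- function(table, m) table$p[, , m]

#' The windrose experiment's observed joint probabilities
#'
#' The empirical two-outcome coincidence probabilities from the 85-participant
#' wind-direction concept-combination experiment, printed at 2 decimals.
#' These data violate both the CHSH inequality and the marginal law.
#'
#' @return A [joint_table()] with `n_participants = 85`.
#' @examples
#' chsh(windrose_data())
#' @export
windrose_data <- function() {
  joint_table(list(
    AB   = matrix(c(0.13, 0.25, 0.55, 0.07), 2L, 2L),
    ABp  = matrix(c(0.47, 0.06, 0.12, 0.35), 2L, 2L),
    ApB  = matrix(c(0.13, 0.42, 0.38, 0.07), 2L, 2L),
    ApBp = matrix(c(0.09, 0.38, 0.44, 0.09), 2L, 2L)
  ), n_participants = 85L)
}

#' Validate a joint-probability table
#'
#' Checks nonnegativity of every cell and normalization of every measurement
#' block within `tol`. Probabilities are never silently renormalized; an
#' out-of-tolerance block is an error.
#'
#' @param table A [joint_table()].
#' @param tol Normalization tolerance on |sum - 1| per block. The default
#'   `1e-9` suits program-generated tables; use `0.011` for hand-entered
#'   2-decimal tables, whose printed cells can be off by rounding.
#' @return The table, unchanged, invisibly usable in pipelines.
#' @export
validate_table <- function(table, tol = 1e-9) {
  stopifnot(inherits(table, "joint_table"))
  for (m in measurement_ids) {
    blk <- block(table, m)
    for (i in 1:2) for (j in 1:2) {
      if (is.na(blk[i, j]) || blk[i, j] < 0) {
        abort_negative_probability(m, i, j, blk[i, j])
      }
    }
    s <- sum(blk)
    if (abs(s - 1) > tol) abort_normalization(m, s, tol)
  }
  invisible(table)
}

#' @export
print.joint_table <- function(x, digits = 3, ...) {
  cat("Joint-probability table (rows: first-slot outcome i; cols: second-slot outcome j)\n")
  if (!is.null(x$n_participants)) {
    cat(sprintf("  n_participants: %d\n", x$n_participants))
  }
  for (m in measurement_ids) {
    cat(sprintf("  %s:\n", gsub("p", "'", m, fixed = TRUE)))
    blk <- round(block(x, m), digits)
    cat(sprintf("    [%s, %s]\n", format(blk[1, 1]), format(blk[1, 2])))
    cat(sprintf("    [%s, %s]\n", format(blk[2, 1]), format(blk[2, 2])))
  }
  invisible(x)
}

#' @export
as.data.frame.joint_table <- function(x, ...) {
  grid <- expand.grid(j = 1:2, i = 1:2, measurement = measurement_ids,
                      stringsAsFactors = FALSE)[, c("measurement", "i", "j")]
  grid$probability <- mapply(function(m, i, j) x$p[i, j, m],
                             grid$measurement, grid$i, grid$j)
  rownames(grid) <- NULL
  grid
}
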