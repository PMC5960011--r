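#' Expectation value of one coincidence measurement
#'
#' For a joint measurement XY with outcome values +1 (outcome 1) and -1
#' (outcome 2) on each side, the correlation is
#' E(X, Y) = p11 - p12 - p21 + p22. It always lies in \[-1, 1\].
#'
#' @param table A [joint_table()].
#' @param m Measurement id: one of `"AB"`, `"ABp"`, `"ApB"`, `"ApBp"`.
#' @return Numeric scalar in \[-1, 1\].
#' @export
expectation_value <- function(table, m) {
  stopifnot(inherits(table, "joint_table"))
  m <- match.arg(m, measurement_ids)
  blk <- block(table, m)
  blk[1, 1] - blk[1, 2] - blk[2, 1] + blk[2, 2]
}

#' CHSH statistic of a joint-probability table
#'
#' Computes the four correlations E(A,B), E(A,B'), E(A',B), E(A',B') and the
#' CHSH combination S in which one term enters with a minus sign (by default
#' the AB' term, the convention used throughout the windrose analysis):
#' S = E(A,B) - E(A,B') + E(A',B) + E(A',B'). Local (experimentally
#' separated) models satisfy |S| <= 2; quantum product measurements on an
#' entangled state reach at most 2*sqrt(2) (the Tsirelson bound); the
#' algebraic maximum is 4.
#'
#' @inheritParams expectation_value
#' @param minus_term Which correlation carries the minus sign; the literature
#'   permutes this, so it is configurable. Default `"ABp"`.
#' @param tol_marg Tolerance for the `marginal_ok` flag of the returned
#'   summary.
#' @return An object of class `chsh_summary`: list with `E` (named length-4
#'   vector), `S`, `absS`, `minus_term`, `marginal_residuals` (length 8),
#'   `marginal_ok`.
#' @examples
#' chsh(windrose_data())$absS
#' @export
chsh <- function(table, minus_term = "ABp", tol_marg = 1e-9) {
  stopifnot(inherits(table, "joint_table"))
  minus_term <- match.arg(minus_term, measurement_ids)
  E <- vapply(measurement_ids, function(m) expectation_value(table, m),
              numeric(1))
  signs <- ifelse(measurement_ids == minus_term, -1, 1)
  S <- sum(signs * E)
  res <- marginal_residuals(table)
  structure(
    list(E = E, S = S, absS = abs(S), minus_term = minus_term,
         marginal_residuals = res,
         marginal_ok = all(abs(res) <= tol_marg), tol_marg = tol_marg),
    class = "chsh_summary"
  )
}

#' Marginal-law (no-signaling) residuals
#'
#' The marginal law requires each sub-system's outcome marginals to be
#' independent of which measurement is performed on the other sub-system;
#' it holds automatically for quantum product measurements. This returns the
#' eight signed differences (left-hand sum minus right-hand sum), in the
#' fixed order: A_i rows (B vs B'), B_i columns (A vs A'), A'_i rows
#' (B vs B'), B'_i columns (A vs A'), i = 1, 2 within each group.
#'
#' @inheritParams expectation_value
#' @return Named numeric vector of length 8.
#' @examples
#' marginal_residuals(windrose_data())[1]  # 0.68 - 0.59 = 0.09
#' @export
marginal_residuals <- function(table) {
  stopifnot(inherits(table, "joint_table"))
  p <- table$p
  row_sum <- function(m, i) sum(p[i, , m])
  col_sum <- function(m, j) sum(p[, j, m])
  res <- c(
    A1  = row_sum("AB", 1) - row_sum("ABp", 1),
    A2  = row_sum("AB", 2) - row_sum("ABp", 2),
    B1  = col_sum("AB", 1) - col_sum("ApB", 1),
    B2  = col_sum("AB", 2) - col_sum("ApB", 2),
    Ap1 = row_sum("ApB", 1) - row_sum("ApBp", 1),
    Ap2 = row_sum("ApB", 2) - row_sum("ApBp", 2),
    Bp1 = col_sum("ABp", 1) - col_sum("ApBp", 1),
    Bp2 = col_sum("ABp", 2) - col_sum("ApBp", 2)
  )
  res
}

#' Summarize a joint-probability table
#'
#' Bundles the four expectation values, the CHSH statistic and the
#' marginal-law residuals into one [chsh()] summary.
#'
#' @param object A [joint_table()].
#' @param minus_term,tol_marg Passed to [chsh()].
#' @param ... Ignored.
#' @return A `chsh_summary`.
#' @export
summary.joint_table <- function(object, minus_term = "ABp", tol_marg = 1e-9, ...) {
  chsh(object, minus_term = minus_term, tol_marg = tol_marg)
}

#' @export
print.chsh_summary <- function(x, ...) {
  pretty <- gsub("p", "'", measurement_ids, fixed = TRUE)
  cat("CHSH summary\n")
  for (k in seq_along(measurement_ids)) {
    cat(sprintf("  E(%s)%s = %+.2f\n", pretty[k],
                if (measurement_ids[k] == x$minus_term) " [minus term]" else "",
                round(x$E[k], 2)))
  }
  cat(sprintf("  S = %+.2f, |S| = %.2f\n", round(x$S, 2), round(x$absS, 2)))
  cat(sprintf("  marginal law %s (max |residual| = %.3g, tol = %g)\n",
              if (x$marginal_ok) "obeyed" else "violated",
              max(abs(x$marginal_residuals)), x$tol_marg))
  invisible(x)
}
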