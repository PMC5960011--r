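# Axis bookkeeping shared by all modules: each of the four joint measurements
# pairs one first-slot axis (A or Ap) with one second-slot axis (B or Bp).

measurement_ids <- c("AB", "ABp", "ApB", "ApBp")
first_axis_of  <- c(AB = "A",  ABp = "A",  ApB = "Ap", ApBp = "Ap")
second_axis_of <- c(AB = "B",  ABp = "Bp", ApB = "B",  ApBp = "Bp")

#' Measurement scheme: four axes on the windrose
#'
#' A measurement scheme assigns to each of the four single-entity
#' measurements A, A', B, B' an oriented axis, i.e. an ordered pair of
#' antipodal compass directions (outcome 1, outcome 2). The default is the
#' windrose scheme of the wind-direction experiment: A = (N, S),
#' A' = (E, W), B = (NE, SW), B' = (SE, NW). Together the four axes must use
#' each of the eight compass directions exactly once.
#'
#' Axis names use ASCII: `Ap` for A', `Bp` for B'.
#'
#' @param A,Ap,B,Bp Character vectors of length 2: the two antipodal outcome
#'   directions of each axis, outcome 1 first.
#' @return An object of class `measurement_scheme`: a named list of the four
#'   axes.
#' @examples
#' windrose_scheme()
#' @export
windrose_scheme <- function(A = c("N", "S"), Ap = c("E", "W"),
                            B = c("NE", "SW"), Bp = c("SE", "NW")) {
  axes <- list(A = as_compass_label(A), Ap = as_compass_label(Ap),
               B = as_compass_label(B), Bp = as_compass_label(Bp))
  for (nm in names(axes)) {
    ax <- axes[[nm]]
    if (length(ax) != 2L) {
      abort_schema(sprintf("axis %s must have exactly 2 outcomes", nm))
    }
    if ((compass_angles[ax[2L]] - compass_angles[ax[1L]]) %% 360 != 180) {
      abort_schema(sprintf("axis %s outcomes %s/%s are not antipodal",
                           nm, ax[1L], ax[2L]))
    }
  }
  used <- unlist(axes, use.names = FALSE)
  if (!setequal(used, compass_labels) || anyDuplicated(used)) {
    abort_schema("the four axes must tile the 8 compass directions, each used once")
  }
  structure(axes, class = "measurement_scheme")
}

#' @export
print.measurement_scheme <- function(x, ...) {
  cat("Measurement scheme (outcome 1, outcome 2):\n")
  for (nm in names(x)) {
    cat(sprintf("  %-3s: (%s, %s)\n", sub("p", "'", nm), x[[nm]][1L], x[[nm]][2L]))
  }
  invisible(x)
}

# Directions (d1, d2) shown in slot (m, i, j) of a scheme.
slot_directions <- function(scheme, m, i, j) {
  c(scheme[[first_axis_of[[m]]]][i], scheme[[second_axis_of[[m]]]][j])
}
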