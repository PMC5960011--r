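#' The eight windrose compass directions
#'
#' Named numeric vector mapping each compass label to its angle in degrees,
#' measured clockwise from North: N = 0, NE = 45, ..., NW = 315.
#'
#' @format Named numeric vector of length 8.
#' @export
compass_angles <- c(
  N = 0, NE = 45, E = 90, SE = 135, S = 180, SW = 225, W = 270, NW = 315
)

#' @rdname compass_angles
#' @export
compass_labels <- names(compass_angles)

as_compass_label <- function(x) {
  x <- as.character(x)
  bad <- setdiff(x, compass_labels)
  if (length(bad) > 0L) {
    abort_schema(sprintf("unknown compass direction(s): %s",
                         paste(bad, collapse = ", ")))
  }
  x
}

#' Rotate a compass direction clockwise by a multiple of 45 degrees
#'
#' The windrose rotation group is the cyclic group of order 8: rotating by
#' `k` steps moves every direction `45 * k` degrees clockwise, and
#' compositions add mod 8.
#'
#' @param d Character vector of compass labels (`"N"`, `"NE"`, ...).
#' @param k Integer number of 45-degree clockwise steps; any integer is
#'   accepted and reduced mod 8.
#' @return Character vector of rotated compass labels.
#' @examples
#' rotate_direction("N", 1)   # "NE"
#' rotate_direction("SW", 4)  # "NE"
#' @export
rotate_direction <- function(d, k) {
  d <- as_compass_label(d)
  stopifnot(length(k) == 1L, k == round(k))
  angle <- (compass_angles[d] + 45 * (as.integer(k) %% 8L)) %% 360
  unname(compass_labels[match(angle, compass_angles)])
}
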