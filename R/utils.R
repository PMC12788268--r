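# Small shared helpers: circular arithmetic in degrees, validation.

#' Wrap angles to (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @keywords internal
wrap_deg <- function(x) {
  w <- ((x + 180) %% 360) - 180
  # %% maps -180 to -180; the convention here is (-180, 180]
  w[w == -180] <- 180
  w
}

#' Circular distance between two angles, degrees
#'
#' Folded to [0, 180].
#' @param a,b angles in degrees (`b` defaults to 0).
#' @keywords internal
circ_dist_deg <- function(a, b = 0) abs(wrap_deg(a - b))

#' Circular deviation from the ideal 120-degree cascade offset
#'
#' Distance from a raw pairwise phase difference to the nearest of +120 or
#' -120 degrees. Using the nearest of the two makes the score invariant to
#' ball relabelling, since a relabel flips the sign of the difference.
#'
#' @param d raw phase differences, degrees.
#' @return deviations in [0, 180] degrees.
#' @keywords internal
dist_to_ideal120 <- function(d) {
  pmin(circ_dist_deg(d, 120), circ_dist_deg(d, -120))
}

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
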