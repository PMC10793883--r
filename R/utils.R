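#' Wrap an angle to (-pi, pi]
#'
#' @param theta angle(s) in radians.
#' @return angle(s) wrapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% maps exact odd multiples of pi to -pi; convention here is (-pi, pi]
  out[out == -pi] <- pi
  out
}

#' Wrap an angle to [-pi, pi)
#'
#' Sector arithmetic uses the lower-closed convention so that every angle
#' belongs to exactly one sector.
#' @param theta angle(s) in radians.
#' @keywords internal
wrap_angle_lower <- function(theta) {
  (theta + pi) %% (2 * pi) - pi
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Population (divide-by-n) standard deviation
#' @keywords internal
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) stop("pop_sd: empty input")
  sqrt(sum((x - mean(x))^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
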