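# Angle helpers: user-facing angles are degrees, trig is done in radians,
# returned angles are normalised to [0, 360).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalise angles to [0, 360)
#'
#' @param theta angles in degrees.
#' @return equivalent angles in `[0, 360)`.
#' @export
wrapAngle <- function(theta) {
  out <- theta %% 360
  # guard against 360 - eps rounding back to 360 exactly
  out[out == 360] <- 0
  out
}

cosd <- function(x) cos(deg2rad(x))
sind <- function(x) sin(deg2rad(x))

# Smallest absolute angular difference a - b in degrees, in [-180, 180);
# NA-safe (propagates NA)
angleDiff <- function(a, b) {
  d <- (a - b) %% 360
  w <- which(d >= 180)
  d[w] <- d[w] - 360
  d
}

# atan2 in degrees, wrapped to [0, 360)
atan2deg <- function(y, x) wrapAngle(rad2deg(atan2(y, x)))

# Truncated-normal draw (rejection at bound; used for strictly positive
# durations so event orderings stay valid)
rnormTrunc <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
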