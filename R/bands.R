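#' Band-wise integrals of an NPS curve
#'
#' Trapezoidal integrals of noise power over three spatial-frequency bands:
#' `[0, f_low]`, `(f_low, f_high]`, `(f_high, f_max]`, with the default band
#' boundaries at the 0.5088 and 1.3084 1/mm crossover frequencies. Boundary
#' points are inserted by linear interpolation so the three bands partition
#' the total integral exactly.
#'
#' @param curve A `nps_curve`.
#' @param f_low,f_high Band boundaries, 1/mm; need
#'   `0 < f_low < f_high < max(frequency)`.
#' @return One-row tibble: `low_band`, `mid_band`, `high_band`, `total`
#'   (HU^2 mm^2 / mm), `f_low`, `f_high`.
#' @export
band_integrals <- function(curve, f_low = 0.5088, f_high = 1.3084) {
  stopifnot(inherits(curve, "nps_curve"))
  f <- curve$frequency
  p <- curve$power
  if (!(f_low > min(f) && f_high > f_low && f_high < max(f))) {
    abort("band boundaries must satisfy min(f) < f_low < f_high < max(f)")
  }
  knots <- sort(unique(c(f, f_low, f_high)))
  pk <- approx(f, p, xout = knots)$y
  trap <- function(lo, hi) {
    idx <- knots >= lo - 1e-12 & knots <= hi + 1e-12
    x <- knots[idx]
    y <- pk[idx]
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  tibble(low_band = trap(min(f), f_low),
         mid_band = trap(f_low, f_high),
         high_band = trap(f_high, max(f)),
         total = trap(min(f), max(f)),
         f_low = f_low, f_high = f_high)
}

#' Relative improvement of a test curve over a reference curve
#'
#' Computed as `100 * (reference - test) / reference` per frequency: positive
#' where the test reconstruction has less noise power than the reference.
#' Frequencies where the reference power is not positive are masked (`NA`).
#'
#' @param reference,test `nps_curve`s on a common frequency grid.
#' @return A `relative` `nps_curve` with power in percent.
#' @export
relative_improvement <- function(reference, test) {
  stopifnot(inherits(reference, "nps_curve"), inherits(test, "nps_curve"))
  if (nrow(reference) != nrow(test) ||
      max(abs(reference$frequency - test$frequency)) > 1e-9) {
    abort("curves must share one frequency grid")
  }
  if (all(reference$power <= 0)) abort("reference curve has no positive power")
  rel <- ifelse(reference$power > 0,
                100 * (reference$power - test$power) / reference$power,
                NA_real_)
  nps_curve(reference$frequency, rel,
            pmin(reference$support_count, test$support_count),
            kind = "relative")
}

#' Zero crossings of a relative-improvement curve
#'
#' Finds the frequencies where the curve changes sign, by linear interpolation
#' between adjacent grid points of opposite sign. Grid points that are exactly
#' zero are reported once; consecutive exact zeros collapse to their midpoint.
#'
#' @param rel A `relative` `nps_curve`.
#' @return Ascending numeric vector of crossover frequencies (possibly empty).
#' @export
find_crossovers <- function(rel) {
  stopifnot(inherits(rel, "nps_curve"))
  if (curve_kind(rel) != "relative") abort("curve must be of kind 'relative'")
  keep <- !is.na(rel$power)
  f <- rel$frequency[keep]
  y <- rel$power[keep]
  out <- numeric(0)
  # runs of exact zeros -> midpoint of the run
  zero <- y == 0
  if (any(zero)) {
    r <- rle(zero)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      out <- c(out, (f[starts[i]] + f[ends[i]]) / 2)
    }
  }
  s <- sign(y)
  for (i in seq_len(length(y) - 1)) {
    if (s[i] != 0 && s[i + 1] != 0 && s[i] != s[i + 1]) {
      out <- c(out, f[i] - y[i] * (f[i + 1] - f[i]) / (y[i + 1] - y[i]))
    }
  }
  sort(out)
}
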