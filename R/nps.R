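#' NPS curves as tibbles
#'
#' One-dimensional noise-power curves are tibbles with columns `frequency`
#' (1/mm, strictly ascending from 0), `power` (HU^2 mm^2, or % for relative
#' curves) and `support_count` (number of samples contributing per frequency),
#' carrying attributes `kind` (`"directional"`, `"angular_mean"`,
#' `"cohort_mean"` or `"relative"`) and, for directional curves, `angle`
#' (degrees).
#'
#' @param frequency,power,support_count Column vectors.
#' @param kind Curve kind.
#' @param angle Angle in degrees (directional curves only).
#' @return A `nps_curve` tibble.
#' @export
nps_curve <- function(frequency, power,
                      support_count = rep(1L, length(frequency)),
                      kind = c("directional", "angular_mean",
                               "cohort_mean", "relative"),
                      angle = NA_real_) {
  kind <- match.arg(kind)
  if (is.unsorted(frequency, strictly = TRUE) || any(frequency < 0)) {
    abort("frequencies must be strictly ascending and start >= 0")
  }
  if (kind != "relative" && any(power < -1e-9, na.rm = TRUE)) {
    abort("power must be >= 0 for non-relative curves")
  }
  out <- tibble(frequency = as.numeric(frequency),
                power = as.numeric(power),
                support_count = as.integer(support_count))
  structure(out, kind = kind, angle = angle,
            class = c("nps_curve", class(out)))
}

curve_kind <- function(curve) attr(curve, "kind") %||% "directional"

#' Ensemble power map by the difference-image method
#'
#' For one slice of a repeated-reconstruction ensemble: the ensemble mean
#' image is subtracted from each repetition; each difference image is Fourier
#' transformed and converted to spectral power
#' `|FT|^2 * pixel_area / pixel_count`; the `n_rep` power maps are averaged
#' and multiplied by `n/(n-1)` to correct the bias from subtracting the
#' sample mean. The result is DC-centred. For white noise of variance
#' `sigma^2` the map is flat at `sigma^2 * pixel_size^2`.
#'
#' @param ens A [noise_ensemble()] with `n_rep >= 2`.
#' @param slice_index Which slice to analyse.
#' @return A `power_map`: list with `values` (H x W, HU^2 mm^2, DC-centred),
#'   `fx`, `fy` (1/mm axes), `pixel_size`, `n_rep_used`.
#' @export
ensemble_power_map <- function(ens, slice_index = 1) {
  stopifnot(inherits(ens, "noise_ensemble"))
  d <- dim(ens$images)
  if (slice_index < 1 || slice_index > d[3]) abort("slice_index out of range")
  n_rep <- d[4]
  if (n_rep < 2) abort("need n_rep >= 2 (no difference signal otherwise)")
  slab <- ens$images[, , slice_index, , drop = FALSE]
  dim(slab) <- c(d[1], d[2], n_rep)
  mean_img <- apply(slab, c(1, 2), mean)
  delta <- ens$pixel_size
  npix <- d[1] * d[2]
  acc <- matrix(0, d[1], d[2])
  for (r in seq_len(n_rep)) {
    diff <- slab[, , r] - mean_img
    acc <- acc + Mod(fft(diff))^2
  }
  values <- fftshift2(acc / n_rep * delta^2 / npix * n_rep / (n_rep - 1))
  structure(list(values = values,
                 fx = freq_axis(d[1], delta),
                 fy = freq_axis(d[2], delta),
                 pixel_size = delta,
                 n_rep_used = n_rep),
            class = "power_map")
}

#' @export
print.power_map <- function(x, ...) {
  cat(sprintf(
    "<power_map>  %d x %d bins, axis extent +/- %.4g /mm, n_rep = %d\n",
    nrow(x$values), ncol(x$values), 1 / (2 * x$pixel_size), x$n_rep_used))
  invisible(x)
}

# Bilinear interpolation of a power map at frequency coordinates (fx, fy).
interp_map <- function(map, fx, fy) {
  dfx <- map$fx[2] - map$fx[1]
  ix <- (fx - map$fx[1]) / dfx + 1
  iy <- (fy - map$fy[1]) / dfx + 1
  i0 <- pmin(pmax(floor(ix), 1), length(map$fx) - 1)
  j0 <- pmin(pmax(floor(iy), 1), length(map$fy) - 1)
  wx <- ix - i0
  wy <- iy - j0
  v <- map$values
  v[cbind(i0, j0)] * (1 - wx) * (1 - wy) +
    v[cbind(i0 + 1, j0)] * wx * (1 - wy) +
    v[cbind(i0, j0 + 1)] * (1 - wx) * wy +
    v[cbind(i0 + 1, j0 + 1)] * wx * wy
}

#' Directional spectrum along one angle
#'
#' Samples the power map along the straight line through DC at the given
#' angle, by bilinear interpolation, at steps of one axis-frequency bin, out
#' to the map boundary. The maximum frequency therefore depends on the angle:
#' along an axis it is the axis Nyquist frequency, on the diagonal up to
#' sqrt(2) times that.
#'
#' @param map A `power_map`.
#' @param angle Angle in degrees, in (0, 180].
#' @return A directional `nps_curve`.
#' @export
directional_spectrum <- function(map, angle) {
  stopifnot(inherits(map, "power_map"))
  if (!is_scalar_number(angle) || angle <= 0 || angle > 180) {
    abort("angle must lie in (0, 180] degrees")
  }
  df <- map$fx[2] - map$fx[1]
  f_edge <- min(max(map$fx), max(map$fy), -min(map$fx), -min(map$fy))
  th <- angle * pi / 180
  cs <- cos(th)
  sn <- sin(th)
  r_max <- f_edge / max(abs(cs), abs(sn))
  k <- 0:floor(r_max / df + 1e-9)
  f <- k * df
  pw <- interp_map(map, f * cs, f * sn)
  nps_curve(f, pw, kind = "directional", angle = angle)
}

#' Angular average of directional spectra
#'
#' Resamples nothing: directional curves produced by [directional_spectrum()]
#' all live on multiples of the axis bin spacing, so the average is taken
#' per frequency over the curves that have support there. Beyond the axis
#' Nyquist frequency only near-diagonal angles contribute; `support_count`
#' records how many, so users can threshold sparsely supported bins.
#'
#' @param curves List of directional `nps_curve`s from one map (default
#'   angles: 10 to 180 degrees in steps of 10).
#' @return An `angular_mean` `nps_curve`.
#' @export
angular_average <- function(curves) {
  if (length(curves) == 0) abort("no curves supplied")
  purrr::walk(curves, function(cv) {
    if (!inherits(cv, "nps_curve")) abort("inputs must be nps_curve objects")
  })
  long <- purrr::map_dfr(curves, function(cv) cv[c("frequency", "power")])
  out <- long |>
    dplyr::group_by(.data$frequency) |>
    dplyr::summarise(support_count = dplyr::n(),
                     power = mean(.data$power), .groups = "drop") |>
    dplyr::arrange(.data$frequency)
  nps_curve(out$frequency, out$power, out$support_count, kind = "angular_mean")
}

#' All 18 directional spectra of a map
#'
#' @param map A `power_map`.
#' @param angles Angles in degrees (default 10, 20, ..., 180).
#' @return List of directional `nps_curve`s.
#' @export
directional_spectra <- function(map, angles = seq(10, 180, by = 10)) {
  purrr::map(angles, function(a) directional_spectrum(map, a))
}

#' Slice-resolved to cohort-mean spectrum
#'
#' Unweighted mean of per-slice curves sharing one frequency grid; emulates
#' averaging the per-slice spectra of all slices covering the cerebrum into a
#' single whole-brain spectrum.
#'
#' @param per_slice_curves List of `nps_curve`s on a common grid.
#' @return A `cohort_mean` `nps_curve`; the slice count is kept in the
#'   `n_slices` attribute and in `support_count` scaling.
#' @export
cohort_nps <- function(per_slice_curves) {
  if (length(per_slice_curves) == 0) abort("no curves supplied")
  f0 <- per_slice_curves[[1]]$frequency
  purrr::walk(per_slice_curves, function(cv) {
    if (length(cv$frequency) != length(f0) ||
        max(abs(cv$frequency - f0)) > 1e-9) {
      abort("curves must share one frequency grid")
    }
  })
  pw <- rowMeans(do.call(cbind, purrr::map(per_slice_curves, "power")))
  sup <- per_slice_curves[[1]]$support_count
  out <- nps_curve(f0, pw, sup, kind = "cohort_mean")
  attr(out, "n_slices") <- length(per_slice_curves)
  out
}

#' Moving-average smoothing of an NPS curve
#'
#' Light spectral smoothing used by the comparison pipeline before crossover
#' detection: a centred odd-width moving average (shrinking symmetrically at
#' the ends). Monte-Carlo fluctuations of ensemble spectra are unbiased and
#' locally uncorrelated, so averaging a few neighbouring bins reduces their
#' standard error by ~ 1/sqrt(window) without displacing zero crossings of a
#' locally linear difference curve.
#'
#' @param curve A `nps_curve`.
#' @param window Odd integer window width in bins (1 = no smoothing).
#' @return A `nps_curve` of the same kind.
#' @export
smooth_nps <- function(curve, window = 7) {
  stopifnot(inherits(curve, "nps_curve"))
  if (window %% 2 != 1 || window < 1) abort("window must be a positive odd integer")
  if (window == 1) return(curve)
  half <- (window - 1) / 2
  n <- nrow(curve)
  pw <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)
    mean(curve$power[(i - h):(i + h)])
  }, numeric(1))
  out <- nps_curve(curve$frequency, pw, curve$support_count,
                   kind = curve_kind(curve), angle = attr(curve, "angle"))
  attr(out, "n_slices") <- attr(curve, "n_slices")
  out
}
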