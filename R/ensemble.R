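#' Noise ensembles of repeated reconstructions
#'
#' A `noise_ensemble` holds `n_rep` repeated reconstructions of the same slice
#' set as an `[H, W, n_slice, n_rep]` HU array, together with the pixel size
#' and provenance (method label, dose fraction, seed, generating profile).
#' The ensemble difference-image method needs at least two repetitions.
#'
#' @param images Numeric 4-d array `[H, W, n_slice, n_rep]`.
#' @param pixel_size Pixel size, mm.
#' @param provenance Named list of free-form provenance entries.
#' @return An object of class `noise_ensemble`.
#' @export
noise_ensemble <- function(images, pixel_size, provenance = list()) {
  if (!is.array(images) || length(dim(images)) != 4) {
    abort("images must be a 4-d array [H, W, n_slice, n_rep]")
  }
  if (dim(images)[4] < 2) abort("an ensemble needs n_rep >= 2")
  if (!is_scalar_number(pixel_size) || pixel_size <= 0) {
    abort("pixel_size must be > 0")
  }
  structure(list(images = images, pixel_size = pixel_size,
                 n_rep = dim(images)[4], provenance = provenance),
            class = "noise_ensemble")
}

#' @export
print.noise_ensemble <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "<noise_ensemble>  %d x %d pixels, %d slice(s) x %d repetition(s), pixel %.3g mm\n",
    d[1], d[2], d[3], d[4], x$pixel_size))
  if (!is.null(x$provenance$method)) {
    cat(sprintf("  method %s, dose fraction %.2f, seed %s\n",
                x$provenance$method,
                x$provenance$dose_fraction %||% 1,
                format(x$provenance$seed %||% NA)))
  }
  invisible(x)
}

# Unshifted (FFT-order) radial frequency matrix for an n x n grid.
fft_radius <- function(n, delta) {
  f <- (seq_len(n) - 1) / (n * delta)
  f[f >= 1 / (2 * delta)] <- f[f >= 1 / (2 * delta)] - 1 / delta
  fx <- matrix(f, n, n)
  sqrt(fx^2 + t(fx)^2)
}

# One zero-mean Gaussian noise field with expected NPS equal to `filter_sq`
# (already in FFT order). Shaping: white field -> FFT -> multiply by
# sqrt(NPS)/pixel_size -> inverse FFT. The radial filter is Hermitian-symmetric
# so the result is real up to rounding.
shaped_noise_field <- function(n, filter_amp) {
  w <- matrix(rnorm(n * n), n, n)
  Re(fft(fft(w) * filter_amp, inverse = TRUE)) / (n * n)
}

#' Synthesize a noise ensemble with a prescribed spectrum
#'
#' Each repetition is the phantom plus an independent zero-mean Gaussian noise
#' field whose expected noise power spectrum equals the profile's target
#' spectrum: white noise is transformed to the frequency domain, multiplied by
#' `sqrt(NPS_t(f)) / pixel_size`, and transformed back. Noise is independent
#' across repetitions and slices and fully reproducible from `seed`. By
#' Parseval's identity the per-pixel noise variance equals the 2-d integral of
#' the target NPS (for a flat spectrum of height `c`, variance
#' `c / pixel_area`).
#'
#' @param phantom An `image_stack` (see [make_head_phantom()]).
#' @param profile A [method_profile()] giving the target NPS.
#' @param n_rep Number of repeated reconstructions (>= 2; the repeated-scan
#'   protocol uses 5).
#' @param seed Integer seed; recorded in provenance.
#' @return A [noise_ensemble()].
#' @export
#' @examples
#' ph <- make_head_phantom(phantom_spec(matrix_size = 64))
#' pr <- default_method_profiles()$ADMIRE
#' ens <- synthesize_ensemble(ph, pr, n_rep = 5, seed = 7)
synthesize_ensemble <- function(phantom, profile, n_rep = 5, seed = 1) {
  stopifnot(inherits(profile, "method_profile"))
  if (!is.array(phantom) || length(dim(phantom)) != 3) {
    abort("phantom must be an [H, W, n_slice] image_stack")
  }
  if (!is_scalar_number(n_rep) || n_rep < 2) abort("n_rep must be >= 2")
  n <- dim(phantom)[1]
  if (dim(phantom)[2] != n) abort("square slices required")
  delta <- attr(phantom, "pixel_size")
  if (is.null(delta)) abort("phantom lacks a pixel_size attribute")
  r <- fft_radius(n, delta)
  filter_amp <- sqrt(nps_target(profile, r)) / delta
  n_slice <- dim(phantom)[3]
  out <- array(0, dim = c(n, n, n_slice, n_rep))
  with_seed(seed, {
    for (rep in seq_len(n_rep)) {
      for (s in seq_len(n_slice)) {
        noise <- if (profile$amplitude == 0) 0 else shaped_noise_field(n, filter_amp)
        out[, , s, rep] <- phantom[, , s] + noise
      }
    }
  })
  noise_ensemble(out, delta, provenance = list(
    method = profile$method_name,
    dose_fraction = profile$dose_fraction,
    seed = seed, profile = profile))
}

#' Simulate a dose reduction on an existing ensemble
#'
#' Quantum-noise model: adds independent noise with the same spectral shape as
#' the ensemble's generating profile and variance `sigma^2 (1/fraction - 1)`,
#' so the total noise variance scales as `1/fraction`. `fraction = 1` returns
#' the input unchanged. Electronic (read-out) noise is deliberately not
#' modelled.
#'
#' @param ens A [noise_ensemble()] whose provenance carries its generating
#'   [method_profile()].
#' @param fraction Dose fraction relative to `ens`, in (0, 1].
#' @param seed Integer seed for the inserted noise.
#' @return A [noise_ensemble()] at the reduced dose.
#' @export
simulate_dose_reduction <- function(ens, fraction, seed = 1) {
  stopifnot(inherits(ens, "noise_ensemble"))
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]")
  }
  if (fraction == 1) return(ens)
  profile <- ens$provenance$profile
  if (is.null(profile)) {
    abort("ensemble provenance lacks the generating profile; cannot match spectral shape")
  }
  n <- dim(ens$images)[1]
  delta <- ens$pixel_size
  r <- fft_radius(n, delta)
  # extra-noise NPS = current NPS * (1/fraction - 1)
  filter_amp <- sqrt(nps_target(profile, r) * (1 / fraction - 1)) / delta
  out <- ens$images
  n_slice <- dim(out)[3]
  with_seed(seed, {
    for (rep in seq_len(ens$n_rep)) {
      for (s in seq_len(n_slice)) {
        out[, , s, rep] <- out[, , s, rep] + shaped_noise_field(n, filter_amp)
      }
    }
  })
  new_profile <- profile
  new_profile$dose_fraction <- profile$dose_fraction * fraction
  noise_ensemble(out, delta, provenance = list(
    method = ens$provenance$method,
    dose_fraction = new_profile$dose_fraction,
    seed = seed, profile = new_profile,
    parent_seed = ens$provenance$seed))
}
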