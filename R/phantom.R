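#' Specification of the synthetic head phantom
#'
#' Parametric stand-in for patient anatomy: an elliptical "skull" outline
#' enclosing a brain-like background, with designated gray-matter (GM,
#' thalamus-like, paired paracentral ellipses) and white-matter (WM, frontal
#' periventricular-like, paired anterior ellipses) regions at fixed Hounsfield
#' unit (HU) levels. Default HU levels follow typical unenhanced head-CT
#' values (GM ~ 39.9 HU, WM ~ 33.5 HU).
#'
#' @param matrix_size Image matrix size in pixels (square), >= 32. Default 512.
#' @param pixel_size Pixel size in mm, > 0. Default 0.429.
#' @param gm_value Gray-matter HU level; must exceed `wm_value`.
#' @param wm_value White-matter HU level.
#' @param background_value HU of the surrounding brain background.
#' @param n_slice Number of (identical) slices in the stack.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 512, pixel_size = 0.429,
                         gm_value = 39.916, wm_value = 33.452,
                         background_value = 30, n_slice = 1) {
  if (!is_scalar_number(matrix_size) || matrix_size < 32) {
    abort("matrix_size must be >= 32 (degenerate geometry below that)")
  }
  if (!is_scalar_number(pixel_size) || pixel_size <= 0) {
    abort("pixel_size must be > 0")
  }
  if (!is_scalar_number(gm_value) || !is_scalar_number(wm_value) ||
      gm_value <= wm_value) {
    abort("gm_value must exceed wm_value")
  }
  if (!is_scalar_number(n_slice) || n_slice < 1) abort("n_slice must be >= 1")
  structure(
    list(matrix_size = as.integer(matrix_size), pixel_size = pixel_size,
         gm_value = gm_value, wm_value = wm_value,
         background_value = background_value, n_slice = as.integer(n_slice)),
    class = "phantom_spec"
  )
}

# Logical mask of an ellipse in pixel coordinates (relative centre/radii).
ellipse_mask <- function(n, cx, cy, rx, ry) {
  x <- (seq_len(n) - (n + 1) / 2) / n
  xx <- matrix(x, n, n)
  yy <- t(xx)
  ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
}

#' Build the noiseless head phantom stack
#'
#' Deterministic (no randomness): two calls with the same spec give
#' bit-identical output. The GM and WM masks are returned as attributes so
#' that downstream ROI sampling hits exactly the designated tissue; by
#' construction the mean over the GM mask equals `gm_value` and the mean over
#' the WM mask equals `wm_value`.
#'
#' @param spec A [phantom_spec()].
#' @return An `image_stack`: numeric array `[H, W, n_slice]` of HU values with
#'   attributes `pixel_size`, `gm_mask`, `wm_mask` (logical `H x W` matrices).
#' @export
#' @examples
#' ph <- make_head_phantom(phantom_spec(matrix_size = 64))
#' mean(ph[, , 1][attr(ph, "gm_mask")])
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$matrix_size
  img <- matrix(-1000, n, n)                       # air
  head <- ellipse_mask(n, 0, 0, 0.42, 0.46)        # skull outline
  brain <- ellipse_mask(n, 0, 0, 0.38, 0.42)
  img[head] <- 600                                  # bone shell
  img[brain] <- spec$background_value
  gm <- ellipse_mask(n, -0.07, 0.02, 0.055, 0.085) |
    ellipse_mask(n, 0.07, 0.02, 0.055, 0.085)      # thalamus-like pair
  wm <- ellipse_mask(n, -0.10, -0.17, 0.05, 0.07) |
    ellipse_mask(n, 0.10, -0.17, 0.05, 0.07)       # frontal periventricular pair
  gm <- gm & brain
  wm <- wm & brain & !gm
  img[gm] <- spec$gm_value
  img[wm] <- spec$wm_value
  stack <- array(img, dim = c(n, n, spec$n_slice))
  structure(stack,
            pixel_size = spec$pixel_size,
            gm_mask = gm, wm_mask = wm,
            class = c("image_stack", "array"))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack>  %d x %d pixels, %d slice(s), pixel %.3g mm\n",
              d[1], d[2], d[3], attr(x, "pixel_size")))
  invisible(x)
}
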