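#' Effective dose from the dose-length product
#'
#' `effective_dose = DLP * k`, with `k` the ICRP region-specific conversion
#' coefficient; the head coefficient 0.0021 mSv/(mGy cm) is the default.
#'
#' @param dlp Dose-length product, mGy cm (>= 0; vectorised).
#' @param k Conversion coefficient, mSv/(mGy cm) (> 0).
#' @return Effective dose, mSv.
#' @export
#' @examples
#' effective_dose(638.4)   # ~1.34 mSv
effective_dose <- function(dlp, k = 0.0021) {
  if (any(!is.finite(dlp)) || any(dlp < 0)) abort("dlp must be finite and >= 0")
  if (!is_scalar_number(k) || k <= 0) abort("k must be > 0")
  dlp * k
}

#' Cohort summary of dose records
#'
#' Mean, SD and range per dose quantity, plus the derived effective dose when
#' a `dlp` column is present.
#'
#' @param records Data frame with any of the columns `ctdi_vol` (mGy), `dlp`
#'   (mGy cm), `effective_mas` (mAs), and optionally `conversion_k`
#'   (mSv/(mGy cm), default 0.0021).
#' @return Tibble with one row per quantity: `quantity`, `mean`, `sd`, `min`,
#'   `max`, `n`.
#' @export
cohort_dose_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  fields <- intersect(c("ctdi_vol", "dlp", "effective_mas"), names(records))
  if (length(fields) == 0) abort("no dose columns found")
  if (any(unlist(records[fields]) < 0, na.rm = TRUE)) {
    abort("dose values must be >= 0")
  }
  rec <- records[fields]
  if ("dlp" %in% fields) {
    k <- records[["conversion_k"]] %||% 0.0021
    rec$effective_dose_msv <- effective_dose(records$dlp, unique(k)[1])
  }
  purrr::map_dfr(names(rec), function(f) {
    x <- rec[[f]][is.finite(rec[[f]])]
    tibble(quantity = f, mean = mean(x),
           sd = if (length(x) > 1) sd(x) else 0,
           min = min(x), max = max(x), n = length(x))
  })
}
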