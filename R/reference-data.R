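#' Reference ROI summary statistics
#'
#' Bundled per-group summary statistics of mean ROI attenuation (HU) for a
#' 21-patient unenhanced head-CT cohort: gray matter (GM, thalamus) and white
#' matter (WM, frontal periventricular) regions, three reconstruction methods
#' (FBP, SAFIRE, ADMIRE) at the original dose and simulated 90% and 70% dose
#' levels. These summaries parameterise the synthetic ROI-table generator and
#' the worked statistical examples.
#'
#' @return Tibble with columns `tissue`, `method`, `dose`, `mean_hu`, `sd_hu`,
#'   `n`.
#' @export
reference_roi_summary <- function() {
  tb <- tibble::tribble(
    ~tissue, ~method, ~dose, ~mean_hu, ~sd_hu,
    "GM", "FBP",    1.0, 39.916, 1.275,
    "GM", "SAFIRE", 1.0, 41.254, 1.251,
    "GM", "ADMIRE", 1.0, 39.967, 1.180,
    "WM", "FBP",    1.0, 33.452, 1.424,
    "WM", "SAFIRE", 1.0, 32.913, 1.703,
    "WM", "ADMIRE", 1.0, 33.542, 1.472,
    "GM", "FBP",    0.9, 39.795, 1.280,
    "GM", "SAFIRE", 0.9, 41.182, 1.335,
    "GM", "ADMIRE", 0.9, 39.870, 1.197,
    "WM", "FBP",    0.9, 33.339, 1.421,
    "WM", "SAFIRE", 0.9, 32.847, 1.673,
    "WM", "ADMIRE", 0.9, 33.444, 1.494,
    "GM", "FBP",    0.7, 39.815, 1.246,
    "GM", "SAFIRE", 0.7, 41.176, 1.317,
    "GM", "ADMIRE", 0.7, 39.843, 1.153,
    "WM", "FBP",    0.7, 33.325, 1.384,
    "WM", "SAFIRE", 0.7, 32.843, 1.626,
    "WM", "ADMIRE", 0.7, 33.417, 1.490
  )
  tb$n <- 21L
  tb
}

#' Reference ordinal image-quality summaries
#'
#' Bundled cell summaries of consensus 10-point Likert scores (10 = best) for
#' the same cohort: five categories (overall quality, detail, noise, contrast,
#' artifacts) by method and dose level, each as median, quartiles, mean and
#' SD over 21 patients. These parameterise the synthetic score-table
#' generator.
#'
#' @return Tibble with columns `category`, `method`, `dose`, `median`, `q1`,
#'   `q3`, `mean`, `sd`, `n`.
#' @export
reference_likert_summary <- function() {
  tb <- tibble::tribble(
    ~category, ~method, ~dose, ~median, ~q1, ~q3, ~mean, ~sd,
    "overall",   "FBP",    1.0, 4, 4,   5, 4.48, 0.51,
    "overall",   "FBP",    0.9, 4, 4,   4, 3.95, 0.25,
    "overall",   "FBP",    0.7, 3, 2,   3, 2.71, 0.46,
    "overall",   "SAFIRE", 1.0, 8, 7,   8, 7.57, 0.51,
    "overall",   "SAFIRE", 0.9, 8, 8,   8, 7.95, 0.21,
    "overall",   "SAFIRE", 0.7, 7, 7,   7, 6.95, 0.20,
    "overall",   "ADMIRE", 1.0, 9, 9,   9, 8.95, 0.22,
    "overall",   "ADMIRE", 0.9, 9, 9,   9, 8.95, 0.22,
    "overall",   "ADMIRE", 0.7, 8, 8,   8, 7.95, 0.19,
    "detail",    "FBP",    1.0, 4, 3,   4, 3.57, 0.51,
    "detail",    "FBP",    0.9, 3, 3,   3, 2.86, 0.36,
    "detail",    "FBP",    0.7, 2, 2, 2.5, 2.24, 0.44,
    "detail",    "SAFIRE", 1.0, 7, 7,   7, 6.95, 0.21,
    "detail",    "SAFIRE", 0.9, 7, 7,   7, 7.05, 0.22,
    "detail",    "SAFIRE", 0.7, 6, 6,   6, 5.95, 0.23,
    "detail",    "ADMIRE", 1.0, 9, 9,   9, 8.95, 0.18,
    "detail",    "ADMIRE", 0.9, 8, 8,   9, 8.48, 0.51,
    "detail",    "ADMIRE", 0.7, 7, 7,   7, 6.95, 0.22,
    "noise",     "FBP",    1.0, 4, 4,   4, 3.95, 0.22,
    "noise",     "FBP",    0.9, 4, 4,   4, 3.95, 0.23,
    "noise",     "FBP",    0.7, 3, 3,   3, 2.95, 0.22,
    "noise",     "SAFIRE", 1.0, 9, 8,   9, 8.67, 0.48,
    "noise",     "SAFIRE", 0.9, 8, 7.5, 8, 7.76, 0.44,
    "noise",     "SAFIRE", 0.7, 7, 7,   7, 6.95, 0.22,
    "noise",     "ADMIRE", 1.0, 9, 8.5, 9, 8.76, 0.44,
    "noise",     "ADMIRE", 0.9, 8, 8,   8, 8.05, 0.22,
    "noise",     "ADMIRE", 0.7, 6, 6,   6, 6.00, 0.45,
    "contrast",  "FBP",    1.0, 5, 5,   5, 4.95, 0.24,
    "contrast",  "FBP",    0.9, 4, 4,   5, 4.48, 0.51,
    "contrast",  "FBP",    0.7, 3, 3,   3, 2.95, 0.24,
    "contrast",  "SAFIRE", 1.0, 9, 9,   9, 9.05, 0.22,
    "contrast",  "SAFIRE", 0.9, 9, 9,   9, 8.95, 0.22,
    "contrast",  "SAFIRE", 0.7, 8, 8,   8, 7.95, 0.24,
    "contrast",  "ADMIRE", 1.0, 7, 7,   7, 6.95, 0.24,
    "contrast",  "ADMIRE", 0.9, 7, 7,   7, 6.95, 0.22,
    "contrast",  "ADMIRE", 0.7, 6, 6,   6, 5.95, 0.22,
    "artifacts", "FBP",    1.0, 7, 7,   7, 6.95, 0.22,
    "artifacts", "FBP",    0.9, 6, 5,   6, 5.48, 0.93,
    "artifacts", "FBP",    0.7, 5, 5,   5, 4.95, 0.21,
    "artifacts", "SAFIRE", 1.0, 5, 5,   6, 5.48, 0.51,
    "artifacts", "SAFIRE", 0.9, 4, 4,   4, 4.19, 0.40,
    "artifacts", "SAFIRE", 0.7, 4, 4,   4, 3.95, 0.22,
    "artifacts", "ADMIRE", 1.0, 9, 9,   9, 8.95, 0.22,
    "artifacts", "ADMIRE", 0.9, 9, 9,   9, 8.95, 0.21,
    "artifacts", "ADMIRE", 0.7, 8, 8,   8, 7.95, 0.24
  )
  tb$n <- 21L
  tb
}

#' Reference acquisition dose summary
#'
#' Cohort dose statistics of the standard head-CT protocol behind the bundled
#' summaries: CTDIvol (mGy), dose-length product (mGy cm) and effective tube
#' current-time product (mAs), as mean, SD and range over 21 patients.
#'
#' @return Tibble with columns `quantity`, `mean`, `sd`, `min`, `max`, `unit`.
#' @export
reference_dose_summary <- function() {
  tibble::tribble(
    ~quantity, ~mean, ~sd, ~min, ~max, ~unit,
    "ctdi_vol",      41.9,   2.9, 36.48,  47.01, "mGy",
    "dlp",          638.4,  65.4, 534.6,  718.0, "mGy cm",
    "effective_mas", 401.6, 28.7, 350.0,  445.0, "mAs"
  )
}
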