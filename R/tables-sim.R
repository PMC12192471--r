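#' Generate a synthetic per-patient ROI table
#'
#' Draws per-subject mean-HU measurements for every method x dose x tissue
#' cell of `group_params` from a normal model with a shared per-subject random
#' offset: all cells are reconstructions of the same scan, so within-subject
#' values are correlated. With intraclass correlation `icc`, the value for
#' subject `s` in cell `c` is
#' `mean_c + sd_c * (sqrt(icc) * z_s + sqrt(1 - icc) * e_sc)`,
#' with independent standard-normal `z_s` and `e_sc`. Marginal cell means and
#' SDs converge to `group_params`; the between-cell correlation within a
#' subject is `icc`.
#'
#' @param group_params Tibble with columns `method`, `dose`, `tissue`
#'   (any subset of these grouping columns is allowed), `mean_hu`, `sd_hu`.
#'   Defaults to [reference_roi_summary()].
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param icc Within-subject intraclass correlation in [0, 1). Default 0.8.
#' @return Long tibble: `subject`, grouping columns, `mean_hu`.
#' @export
#' @examples
#' roi <- generate_roi_table(n_subjects = 21, seed = 1)
#' dplyr::count(roi, method, dose)
generate_roi_table <- function(group_params = reference_roi_summary(),
                               n_subjects = 21, seed = 1, icc = 0.8) {
  stopifnot(is.data.frame(group_params),
            all(c("mean_hu", "sd_hu") %in% names(group_params)))
  if (!is_scalar_number(n_subjects) || n_subjects < 2) {
    abort("n_subjects must be >= 2")
  }
  if (any(group_params$sd_hu <= 0)) abort("all sd_hu must be > 0")
  if (!is_scalar_number(icc) || icc < 0 || icc >= 1) {
    abort("icc must lie in [0, 1)")
  }
  keys <- intersect(c("tissue", "method", "dose"), names(group_params))
  with_seed(seed, {
    z <- rnorm(n_subjects)
    rows <- purrr::map_dfr(seq_len(nrow(group_params)), function(i) {
      e <- rnorm(n_subjects)
      val <- group_params$mean_hu[i] +
        group_params$sd_hu[i] * (sqrt(icc) * z + sqrt(1 - icc) * e)
      out <- tibble(subject = seq_len(n_subjects), mean_hu = val)
      for (k in keys) out[[k]] <- group_params[[k]][i]
      out
    })
  })
  rows[, c("subject", keys, "mean_hu")]
}

# Best integer multiset of size n on [lo, hi] matching a target mean and
# (sample) SD. Exhaustive search in increasing support size: one- and
# two-value compositions first (the common case for tight consensus scores),
# then all three-value supports, then four consecutive values (needed for the
# widest printed SDs). The first support size that achieves both mean and SD
# within `tol` wins, which keeps the canonical two-value solutions unique.
best_score_multiset <- function(mean_target, sd_target, n, lo = 1, hi = 10,
                                tol = 0.05) {
  score_err <- function(counts, values) {
    m <- sum(counts * values) / n
    s <- sqrt(sum(counts * (values - m)^2) / (n - 1))
    c(err = abs(m - mean_target) + abs(s - sd_target),
      feas = abs(m - mean_target) <= tol && abs(s - sd_target) <= tol)
  }
  best <- NULL
  best_err <- Inf
  consider <- function(counts, values) {
    e <- score_err(counts, values)
    if (e[["err"]] < best_err - 1e-12) {
      best_err <<- e[["err"]]
      best <<- rep(values, counts)
    }
  }
  feasible_yet <- function() {
    !is.null(best) && {
      m <- mean(best)
      s <- sd(best)
      abs(m - mean_target) <= tol && abs(s - sd_target) <= tol
    }
  }
  # support size 1 and 2
  for (v in lo:hi) {
    consider(n, v)
    if (v < hi) {
      for (w in (v + 1):hi) {
        for (k in 1:(n - 1)) consider(c(n - k, k), c(v, w))
      }
    }
  }
  # support size 3 (all value triples)
  if (!feasible_yet()) {
    for (v in lo:(hi - 2)) for (w in (v + 1):(hi - 1)) for (u in (w + 1):hi) {
      for (k1 in 1:(n - 2)) for (k2 in 1:(n - 1 - k1)) {
        consider(c(k1, k2, n - k1 - k2), c(v, w, u))
      }
    }
  }
  # support size 4, consecutive values
  if (!feasible_yet()) {
    for (v in lo:(hi - 3)) {
      vals <- v:(v + 3)
      for (k1 in 1:(n - 3)) for (k2 in 1:(n - 2 - k1)) {
        for (k3 in 1:(n - 1 - k1 - k2)) {
          consider(c(k1, k2, k3, n - k1 - k2 - k3), vals)
        }
      }
    }
  }
  m <- mean(best)
  s <- sd(best)
  list(scores = sort(best), mean = m, sd = s,
       feasible = abs(m - mean_target) <= tol && abs(s - sd_target) <= tol)
}

#' Generate a synthetic per-patient ordinal score table
#'
#' For each category x method x dose cell of `cell_summaries`, emits an
#' integer score multiset (1-10) of size `n_subjects` whose mean and SD match
#' the cell's printed summary within 0.05 when such a multiset exists; the
#' search enumerates one- and two-value compositions. When no multiset
#' achieves the summary (e.g. an SD impossible for integers with that mean) a
#' warning is raised and the nearest-achievable multiset is returned.
#'
#' Scores are assigned to subjects concordantly: one latent quality rank is
#' drawn per subject (seeded) and higher-ranked subjects receive the higher
#' scores in every cell, giving positively correlated paired scores across
#' cells, as repeated readings of the same patients produce.
#'
#' @param cell_summaries Tibble with columns `category`, `method`, `dose`
#'   (any subset of grouping columns), `mean`, `sd`. Defaults to
#'   [reference_likert_summary()].
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed for the latent subject ranking.
#' @return Long tibble: `subject`, grouping columns, `score`.
#' @export
generate_likert_table <- function(cell_summaries = reference_likert_summary(),
                                  n_subjects = 21, seed = 1) {
  stopifnot(is.data.frame(cell_summaries),
            all(c("mean", "sd") %in% names(cell_summaries)))
  if (!is_scalar_number(n_subjects) || n_subjects < 2) {
    abort("n_subjects must be >= 2")
  }
  keys <- intersect(c("category", "method", "dose"), names(cell_summaries))
  latent_rank <- with_seed(seed, rank(rnorm(n_subjects), ties.method = "first"))
  rows <- purrr::map_dfr(seq_len(nrow(cell_summaries)), function(i) {
    ms <- best_score_multiset(cell_summaries$mean[i], cell_summaries$sd[i],
                              n_subjects)
    if (!ms$feasible) {
      warn(sprintf(
        "no integer multiset achieves mean %.3g, SD %.3g (n = %d); using nearest (mean %.3g, SD %.3g)",
        cell_summaries$mean[i], cell_summaries$sd[i], n_subjects,
        ms$mean, ms$sd))
    }
    out <- tibble(subject = seq_len(n_subjects),
                  score = as.integer(ms$scores[latent_rank]))
    for (k in keys) out[[k]] <- cell_summaries[[k]][i]
    out
  })
  rows[, c("subject", keys, "score")]
}
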