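#' Cohort NPS of an ensemble
#'
#' Full estimation chain for one ensemble: per-slice power maps by the
#' difference-image method, 18 directional spectra each, angular average, and
#' an unweighted mean over slices.
#'
#' @param ens A [noise_ensemble()].
#' @param angles Sampling angles in degrees.
#' @return A `cohort_mean` `nps_curve`.
#' @export
ensemble_nps <- function(ens, angles = seq(10, 180, by = 10)) {
  n_slice <- dim(ens$images)[3]
  per_slice <- purrr::map(seq_len(n_slice), function(s) {
    angular_average(directional_spectra(ensemble_power_map(ens, s), angles))
  })
  cohort_nps(per_slice)
}

#' Run configuration for the end-to-end pipeline
#'
#' Collects the protocol constants (five repeated reconstructions, simulated
#' dose levels, 0.429 mm pixels, the 0.5088/1.3084 1/mm band boundaries) and
#' run parameters in one validated list. Values may be supplied directly or
#' loaded from a YAML/JSON file via `path`.
#'
#' @param path Optional YAML or JSON file with configuration entries.
#' @param ... Entries overriding the defaults, e.g. `matrix_size = 128`,
#'   `n_slice = 20`, `dose_fractions = c(1, 0.9, 0.7)`, `n_rep = 5`,
#'   `f_low`, `f_high`, `alpha`, `seed`, `n_subjects`, `smooth_window`,
#'   `out_dir`, `input_dir`, `mode`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    mode = "full",
    methods = c("FBP", "SAFIRE", "ADMIRE"),
    dose_fractions = c(1.0, 0.9, 0.7),
    n_rep = 5,
    matrix_size = 128,
    pixel_size = 0.429,
    n_slice = 20,
    n_subjects = 21,
    f_low = 0.5088,
    f_high = 1.3084,
    alpha = 0.05,
    smooth_window = 7,
    seed = 1,
    out_dir = NULL,
    input_dir = NULL
  )
  if (!is.null(path)) {
    loaded <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg[names(loaded)] <- loaded
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!cfg$mode %in% c("simulate", "analyze", "full")) {
    abort("mode must be one of simulate/analyze/full")
  }
  if (any(cfg$dose_fractions <= 0 | cfg$dose_fractions > 1)) {
    abort("dose fractions must lie in (0, 1]")
  }
  if (cfg$n_rep < 2) abort("n_rep must be >= 2")
  if (cfg$smooth_window %% 2 != 1) abort("smooth_window must be odd")
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg)[order(names(cfg))], tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

simulate_ensembles <- function(cfg) {
  spec <- phantom_spec(matrix_size = cfg$matrix_size,
                       pixel_size = cfg$pixel_size, n_slice = cfg$n_slice)
  phantom <- make_head_phantom(spec)
  out <- list()
  i <- 0
  for (dose in cfg$dose_fractions) {
    profiles <- default_method_profiles(dose, cfg$f_low, cfg$f_high)
    for (method in cfg$methods) {
      i <- i + 1
      ens <- synthesize_ensemble(phantom, profiles[[method]],
                                 n_rep = cfg$n_rep,
                                 seed = cfg$seed * 1000L + i)
      out[[sprintf("%s_dose%03.0f", method, 100 * dose)]] <- ens
    }
  }
  out
}

analyze_ensembles <- function(ensembles, cfg) {
  curves <- purrr::map(ensembles, function(e) {
    smooth_nps(ensemble_nps(e), cfg$smooth_window)
  })
  bands <- purrr::imap_dfr(curves, function(cv, nm) {
    dplyr::bind_cols(tibble(run = nm), band_integrals(cv, cfg$f_low, cfg$f_high))
  })
  crossovers <- purrr::map_dfr(cfg$dose_fractions, function(dose) {
    key_s <- sprintf("SAFIRE_dose%03.0f", 100 * dose)
    key_a <- sprintf("ADMIRE_dose%03.0f", 100 * dose)
    if (!all(c(key_s, key_a) %in% names(curves))) return(tibble())
    rel <- relative_improvement(curves[[key_s]], curves[[key_a]])
    fx <- find_crossovers(rel)
    tibble(dose = dose, crossover = fx)
  })
  list(curves = curves, bands = bands, crossovers = crossovers)
}

roi_stat_report <- function(roi, alpha, n_mc = 2000, seed = 1) {
  grid <- dplyr::distinct(roi, .data$tissue, .data$dose)
  assumptions <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sub <- dplyr::filter(roi, .data$tissue == grid$tissue[i],
                         .data$dose == grid$dose[i])
    norm <- purrr::map_dfr(unique(sub$method), function(m) {
      dplyr::bind_cols(
        tibble(method = m, check = "lilliefors_normality"),
        lilliefors_ks(sub$mean_hu[sub$method == m], n_mc = n_mc, seed = seed))
    })
    lev <- dplyr::bind_cols(
      tibble(method = "all", check = "levene_homoscedasticity"),
      levene_test(sub, .data$mean_hu, .data$method))
    dplyr::bind_rows(norm, lev) |>
      dplyr::mutate(tissue = grid$tissue[i], dose = grid$dose[i], .before = 1)
  })
  anova_tab <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sub <- dplyr::filter(roi, .data$tissue == grid$tissue[i],
                         .data$dose == grid$dose[i])
    dplyr::bind_cols(tibble(tissue = grid$tissue[i], dose = grid$dose[i]),
                     oneway_anova(sub, .data$mean_hu, .data$method))
  })
  pairwise <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sub <- dplyr::filter(roi, .data$tissue == grid$tissue[i],
                         .data$dose == grid$dose[i])
    bonferroni_pairwise(sub, .data$mean_hu, .data$method, alpha = alpha) |>
      dplyr::mutate(tissue = grid$tissue[i], dose = grid$dose[i], .before = 1)
  })
  paired <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sub <- dplyr::filter(roi, .data$tissue == grid$tissue[i],
                         .data$dose == grid$dose[i]) |>
      dplyr::arrange(.data$subject)
    a <- sub$mean_hu[sub$method == "ADMIRE"]
    s <- sub$mean_hu[sub$method == "SAFIRE"]
    if (!length(a) || !length(s)) return(tibble())
    dplyr::bind_cols(tibble(tissue = grid$tissue[i], dose = grid$dose[i],
                            comparison = "ADMIRE vs SAFIRE"),
                     paired_t(a, s))
  })
  list(assumptions = assumptions, anova = anova_tab, pairwise = pairwise,
       paired_t = paired)
}

likert_stat_report <- function(lik) {
  descr <- lik |>
    dplyr::group_by(.data$category, .data$method, .data$dose) |>
    dplyr::group_modify(function(d, key) summarize_ordinal(d$score)) |>
    dplyr::ungroup()
  grid <- dplyr::distinct(lik, .data$category, .data$method)
  wilcox <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sub <- dplyr::filter(lik, .data$category == grid$category[i],
                         .data$method == grid$method[i]) |>
      dplyr::arrange(.data$subject)
    orig <- sub$score[sub$dose == 1.0]
    purrr::map_dfr(c(0.9, 0.7), function(dd) {
      red <- sub$score[sub$dose == dd]
      if (!length(red) || !length(orig)) return(tibble())
      res <- tryCatch(wilcoxon_signed_rank(orig, red),
                      error = function(e) {
                        tibble(statistic = NA_real_, z = NA_real_,
                               p_value = NA_real_, n_effective = 0L)
                      })
      dplyr::bind_cols(tibble(category = grid$category[i],
                              method = grid$method[i],
                              comparison = sprintf("original vs %.0f%%", 100 * dd)),
                       res)
    })
  })
  pooled <- lik |>
    dplyr::group_by(.data$subject, .data$method, .data$dose) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    dplyr::mutate(condition = paste(.data$method, .data$dose, sep = "@"))
  rma <- rm_anova_gg(pooled, .data$score, .data$subject, .data$condition)
  list(descriptives = descr, wilcoxon = wilcox, rm_anova = rma)
}

generate_dose_records <- function(n_subjects, seed) {
  ref <- reference_dose_summary()
  with_seed(seed, {
    tibble(
      subject = seq_len(n_subjects),
      ctdi_vol = pmax(0, rnorm(n_subjects,
                               ref$mean[ref$quantity == "ctdi_vol"],
                               ref$sd[ref$quantity == "ctdi_vol"])),
      dlp = pmax(0, rnorm(n_subjects,
                          ref$mean[ref$quantity == "dlp"],
                          ref$sd[ref$quantity == "dlp"])),
      effective_mas = pmax(0, rnorm(n_subjects,
                                    ref$mean[ref$quantity == "effective_mas"],
                                    ref$sd[ref$quantity == "effective_mas"])),
      conversion_k = 0.0021
    )
  })
}

#' Run the end-to-end pipeline
#'
#' `simulate` synthesizes and (if `out_dir` is set) writes the noise
#' ensembles; `analyze` reads previously written ensembles from `input_dir`
#' and estimates spectra; `full` does everything in memory: generate
#' ensembles for every method x dose, estimate cohort NPS curves, band
#' summaries, relative-improvement curves with crossover frequencies,
#' generate ROI and Likert tables and run the statistical battery, and
#' summarise cohort dose. Identical config + seed give identical numeric
#' outputs. A manifest (seed, config hash, package version) accompanies any
#' written output.
#'
#' @param config A [run_config()].
#' @return Invisibly (and visibly in `analyze`/`full` modes), a named list of
#'   result tables and curves.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "analyze") {
    if (is.null(config$input_dir)) abort("analyze mode needs input_dir")
    wanted <- as.vector(outer(config$methods,
                              sprintf("dose%03.0f", 100 * config$dose_fractions),
                              paste, sep = "_"))
    dirs <- file.path(config$input_dir, wanted)
    missing <- dirs[!dir.exists(dirs)]
    if (length(missing)) {
      abort(paste0("analyze mode: missing ensemble directories:\n  ",
                   paste(missing, collapse = "\n  ")))
    }
    ensembles <- setNames(purrr::map(dirs, read_ensemble_nifti), wanted)
  } else {
    ensembles <- simulate_ensembles(config)
    if (config$mode == "simulate" && !is.null(out_dir)) {
      purrr::iwalk(ensembles, function(e, nm) {
        write_ensemble_nifti(e, file.path(out_dir, nm))
      })
    }
  }

  results <- list(config = config, config_hash = config_hash(config))
  if (config$mode != "simulate") {
    spectra <- analyze_ensembles(ensembles, config)
    results$curves <- spectra$curves
    results$bands <- spectra$bands
    results$crossovers <- spectra$crossovers
  }
  if (config$mode == "full") {
    roi_params <- dplyr::filter(reference_roi_summary(),
                                .data$method %in% config$methods,
                                .data$dose %in% config$dose_fractions)
    lik_params <- dplyr::filter(reference_likert_summary(),
                                .data$method %in% config$methods,
                                .data$dose %in% config$dose_fractions)
    roi <- generate_roi_table(roi_params, n_subjects = config$n_subjects,
                              seed = config$seed + 1L)
    lik <- suppressWarnings(
      generate_likert_table(lik_params, n_subjects = config$n_subjects,
                            seed = config$seed + 2L))
    results$roi_table <- roi
    results$likert_table <- lik
    results$roi_stats <- roi_stat_report(roi, config$alpha,
                                         seed = config$seed + 4L)
    results$likert_stats <- likert_stat_report(lik)
    dose_records <- generate_dose_records(config$n_subjects, config$seed + 3L)
    results$dose_records <- dose_records
    results$dose_summary <- cohort_dose_summary(dose_records)
  }

  if (!is.null(out_dir)) {
    if (!is.null(results$curves)) {
      purrr::iwalk(results$curves, function(cv, nm) {
        write_nps_csv(cv, file.path(out_dir, paste0("nps_", nm, ".csv")))
      })
      write.csv(results$bands, file.path(out_dir, "band_summaries.csv"),
                row.names = FALSE)
      write.csv(results$crossovers, file.path(out_dir, "crossovers.csv"),
                row.names = FALSE)
    }
    if (!is.null(results$roi_table)) {
      write.csv(results$roi_table, file.path(out_dir, "roi_table.csv"),
                row.names = FALSE)
      write.csv(results$likert_table, file.path(out_dir, "likert_table.csv"),
                row.names = FALSE)
      write.csv(results$roi_stats$anova, file.path(out_dir, "roi_anova.csv"),
                row.names = FALSE)
      write.csv(results$roi_stats$pairwise,
                file.path(out_dir, "roi_pairwise.csv"), row.names = FALSE)
      write.csv(results$likert_stats$descriptives,
                file.path(out_dir, "likert_descriptives.csv"),
                row.names = FALSE)
      write.csv(results$dose_summary, file.path(out_dir, "dose_summary.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = config$seed, config_hash = results$config_hash,
           package_version = as.character(utils::packageVersion("ctnps")),
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  invisible(results)
}
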