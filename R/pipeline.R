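#' Per-subject Recovery Index series (PAT and oversampled SBP)
#'
#' For each subject: the PAT index is computed from the post-exercise
#' per-cycle medians (outlier cycles stay missing) anchored to the
#' baseline-session mean; the SBP index is computed from the four
#' post-exercise cuff readings anchored to the baseline reading mean, then
#' oversampled to the 11-cycle grid with [oversample_ri_sbp()]. Subjects
#' without valid baseline cycles or with a degenerate normalization are
#' skipped with a warning.
#'
#' @param summaries Per-cycle summaries from [extract_cycles()].
#' @param readings Cuff readings tibble.
#' @return Long tibble `subject_id, kind, cycle, ri_pct` with
#'   `kind %in% c("RI_PAT", "RI_SBP")`.
#' @export
recovery_indices <- function(summaries, readings) {
  subjects <- sort(unique(summaries$subject_id))
  out <- purrr::map(subjects, function(s) {
    sub <- summaries[summaries$subject_id == s, ]
    valid <- sub[!is.na(sub$median_pat_ms) & !sub$is_outlier, ]
    base <- valid$median_pat_ms[valid$session == "baseline"]
    post <- valid[valid$session == "post", ]
    if (length(base) == 0 || nrow(post) == 0) {
      warn(paste0("subject ", s, ": no valid baseline or post cycles; skipped"))
      return(NULL)
    }
    post_vec <- rep(NA_real_, 11)
    post_vec[post$cycle_index] <- post$median_pat_ms
    rd <- readings[readings$subject_id == s, ]
    sbp_base <- mean(rd$sbp_mmHg[rd$session == "baseline"])
    rd_post <- rd[rd$session == "post", ]
    rd_post <- rd_post[order(rd_post$after_cycle), ]
    res <- tryCatch({
      ri_pat <- compute_recovery_index(post_vec, mean(base), "RI_PAT", cycles = 1:11)
      ri_sbp4 <- compute_recovery_index(rd_post$sbp_mmHg, sbp_base, "RI_SBP",
                                        cycles = rd_post$after_cycle)
      ri_sbp <- oversample_ri_sbp(ri_sbp4$ri_pct, x = ri_sbp4$cycle)
      dplyr::bind_rows(
        tibble::tibble(subject_id = s, kind = "RI_PAT",
                       cycle = ri_pat$cycle, ri_pct = ri_pat$ri_pct),
        tibble::tibble(subject_id = s, kind = "RI_SBP",
                       cycle = ri_sbp$cycle, ri_pct = ri_sbp$ri_pct)
      )
    }, error = function(e) {
      warn(paste0("subject ", s, ": ", conditionMessage(e), "; skipped"))
      NULL
    })
    res
  })
  dplyr::bind_rows(out)
}

#' Aggregate post-exercise recovery model comparison
#'
#' Centres every subject's valid post-exercise medians on the subject's
#' baseline mean, takes the across-subject median per cycle index (the
#' aggregated recovery trajectory), and fits and ranks the three recovery
#' models on it.
#'
#' @inheritParams recovery_indices
#' @return A list with `trajectory` (tibble `cycle, value, n_subjects`) and
#'   `models` (ranked tibble from [compare_models()]).
#' @export
aggregate_recovery <- function(summaries) {
  valid <- summaries[!is.na(summaries$median_pat_ms) & !summaries$is_outlier, ]
  centred <- valid |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(any(.data$session == "baseline")) |>
    dplyr::mutate(rel = .data$median_pat_ms -
                    mean(.data$median_pat_ms[.data$session == "baseline"])) |>
    dplyr::ungroup()
  traj <- centred[centred$session == "post", ] |>
    dplyr::group_by(cycle = .data$cycle_index) |>
    dplyr::summarise(value = median(.data$rel), n_subjects = dplyr::n(),
                     .groups = "drop")
  list(trajectory = traj, models = compare_models(traj$cycle, traj$value))
}

#' Full campaign analysis
#'
#' Runs the complete analysis on extracted summaries and cuff readings:
#' phase assignment and statistical battery (PAT, SBP, DBP), aggregate
#' recovery model comparison, per-subject mono-exponential fits, Recovery
#' Index computation with SBP oversampling, subject-wise correlations with
#' z-score screening, and pooled Bland-Altman / concordance agreement over
#' retained subjects.
#'
#' @param summaries Per-cycle summaries from [extract_cycles()].
#' @param readings Cuff readings tibble.
#' @param z_threshold z-score magnitude for excluding correlation outliers.
#' @param alpha Significance level for the omnibus gate.
#' @param baseline_centering Passed to [assign_phases()].
#' @return A `pat_analysis` object: list with `summaries`, `ri`,
#'   `aggregate`, `subject_fits`, `phase_reports`, `screen`, `agreement`
#'   (elements `bland_altman`, `ccc`), and `log`.
#' @export
analyze_summaries <- function(summaries, readings, z_threshold = 2,
                              alpha = 0.05, baseline_centering = TRUE) {
  assignments <- assign_phases(summaries, readings, baseline_centering)
  phase_reports <- purrr::map(
    setNames(c("PAT", "SBP", "DBP"), c("PAT", "SBP", "DBP")),
    function(m) phase_tests(assignments[assignments$measure == m, ], alpha = alpha)
  )

  agg <- aggregate_recovery(summaries)

  valid <- summaries[!is.na(summaries$median_pat_ms) & !summaries$is_outlier, ]
  subject_fits <- purrr::map_dfr(sort(unique(valid$subject_id)), function(s) {
    post <- valid[valid$subject_id == s & valid$session == "post", ]
    if (nrow(post) < 4) return(NULL)
    fit <- tryCatch(fit_recovery_model(post$cycle_index, post$median_pat_ms,
                                       "mono_exp"),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    dplyr::bind_cols(tibble::tibble(subject_id = s), glance(fit),
                     tidyr::pivot_wider(tidy(fit), names_from = "term",
                                        values_from = "estimate"))
  })

  ri <- recovery_indices(summaries, readings)
  cors <- purrr::map_dfr(sort(unique(ri$subject_id)), function(s) {
    pat <- ri[ri$subject_id == s & ri$kind == "RI_PAT", ]
    sbp <- ri[ri$subject_id == s & ri$kind == "RI_SBP", ]
    dplyr::bind_cols(tibble::tibble(subject_id = s), align_and_correlate(pat, sbp))
  })
  screen <- zscore_screen(cors, threshold = z_threshold)

  retained <- screen$correlations$subject_id[
    screen$correlations$ok & !screen$correlations$excluded]
  pooled <- ri |>
    dplyr::filter(.data$subject_id %in% retained) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "ri_pct") |>
    dplyr::filter(is.finite(.data$RI_PAT) & is.finite(.data$RI_SBP))
  ba <- bland_altman(pooled$RI_PAT, pooled$RI_SBP)
  ccc <- concordance_ccc(pooled$RI_PAT, pooled$RI_SBP)

  drop_log <- attr(summaries, "drop_log")
  log <- list(
    n_cycles = nrow(summaries),
    n_missing_median = sum(is.na(summaries$median_pat_ms)),
    n_outlier_flagged = sum(summaries$is_outlier, na.rm = TRUE),
    beat_drop_reasons = drop_log,
    n_subjects_with_ri = length(unique(ri$subject_id)),
    n_subjects_retained = length(retained),
    excluded_subjects = screen$correlations$subject_id[screen$correlations$excluded]
  )

  structure(list(summaries = summaries, ri = ri, aggregate = agg,
                 subject_fits = subject_fits, phase_reports = phase_reports,
                 screen = screen,
                 agreement = list(bland_altman = ba, ccc = ccc, pairs = pooled),
                 log = log),
            class = "pat_analysis")
}

#' @rdname analyze_summaries
#' @param campaign A `pat_campaign`.
#' @param ... Passed to [extract_cycles()].
#' @export
analyze_campaign <- function(campaign, z_threshold = 2, alpha = 0.05, ...) {
  summaries <- extract_cycles(campaign, ...)
  analyze_summaries(summaries, campaign$readings,
                    z_threshold = z_threshold, alpha = alpha)
}

#' @export
print.pat_analysis <- function(x, ...) {
  cat("<pat_analysis>\n")
  cat("cycles:", x$log$n_cycles,
      " missing medians:", x$log$n_missing_median,
      " outlier-flagged:", x$log$n_outlier_flagged, "\n")
  cat("aggregate recovery ranking:",
      paste(x$aggregate$models$model, collapse = " > "),
      sprintf("(best R^2 = %.4f)", x$aggregate$models$r_squared[1]), "\n")
  cat("subject-wise Pearson r: mean", format(x$screen$summary$mean_r, digits = 3),
      "sd", format(x$screen$summary$sd_r, digits = 2),
      sprintf("(%d/%d retained)", x$log$n_subjects_retained,
              x$log$n_subjects_with_ri), "\n")
  ba <- x$agreement$bland_altman
  cat("Bland-Altman bias", format(ba$bias, digits = 3),
      " LoA [", format(ba$loa_low, digits = 4), ",",
      format(ba$loa_high, digits = 4), "]  CCC",
      format(x$agreement$ccc, digits = 3), "\n")
  invisible(x)
}
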