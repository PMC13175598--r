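#' Assign physiological phases to PAT summaries and cuff readings
#'
#' Phases follow the acquisition protocol: every baseline-session cycle is
#' REST; post-exercise cycles 1--3 are EXERCISE (peak cardiovascular stress)
#' and 9--11 are RECOVERY (progressive normalization); post cycles 4--8 are
#' left unassigned. For blood pressure, REST is the per-subject mean of the
#' four baseline readings, EXERCISE the first post-exercise reading and
#' RECOVERY the last one.
#'
#' With `baseline_centering` the PAT values are expressed relative to each
#' subject's baseline mean (valid baseline medians), removing between-subject
#' PAT offsets before pooling. Centering is not applied to BP: REST is each
#' subject's own baseline mean, so centred BP would make every REST value
#' identically zero and degenerate the normality tests.
#'
#' @param summaries Per-cycle summaries from [extract_cycles()] (outlier
#'   cycles and missing medians are excluded).
#' @param readings Cuff readings tibble.
#' @param baseline_centering Express PAT relative to the subject's baseline
#'   mean (default `TRUE`).
#' @return Tibble `measure, phase, subject_id, value` with measures `PAT`,
#'   `SBP`, `DBP`.
#' @export
assign_phases <- function(summaries, readings, baseline_centering = TRUE) {
  valid <- summaries[!is.na(summaries$median_pat_ms) & !summaries$is_outlier, ]
  pat <- purrr::map(unique(valid$subject_id), function(s) {
    sub <- valid[valid$subject_id == s, ]
    base <- sub$median_pat_ms[sub$session == "baseline"]
    if (length(base) == 0) {
      warn(paste0("subject ", s, " has no valid baseline cycles; excluded"))
      return(NULL)
    }
    centre <- if (baseline_centering) mean(base) else 0
    phase <- dplyr::case_when(
      sub$session == "baseline" ~ "REST",
      sub$cycle_index <= 3 ~ "EXERCISE",
      sub$cycle_index >= 9 ~ "RECOVERY",
      TRUE ~ NA_character_
    )
    tibble::tibble(measure = "PAT", phase = phase, subject_id = s,
                   value = sub$median_pat_ms - centre)[!is.na(phase), ]
  })
  bp <- purrr::map(unique(readings$subject_id), function(s) {
    sub <- readings[readings$subject_id == s, ]
    base <- sub[sub$session == "baseline", ]
    post <- sub[sub$session == "post", ]
    post <- post[order(post$after_cycle), ]
    purrr::map2_dfr(c("sbp_mmHg", "dbp_mmHg"), c("SBP", "DBP"), function(col, m) {
      tibble::tibble(measure = m, phase = c("REST", "EXERCISE", "RECOVERY"),
                     subject_id = s,
                     value = c(mean(base[[col]]), post[[col]][1],
                               post[[col]][nrow(post)]))
    })
  })
  dplyr::bind_rows(c(pat, bp))
}

#' Phase-comparison statistical battery for one measure
#'
#' Shapiro-Wilk normality per phase, a Kruskal-Wallis omnibus test across the
#' three phases, and -- only when the omnibus test is significant at `alpha`
#' -- pairwise two-sided Mann-Whitney tests (normal approximation with tie
#' correction) with Bonferroni adjustment over the three phase pairs
#' (`p_adj = min(1, 3p)`). Gating the post-hoc tests on the omnibus result
#' mirrors standard practice (a measure with no omnibus effect, e.g. DBP, is
#' not probed pairwise).
#'
#' @param assignments Phase assignments (from [assign_phases()]) filtered to
#'   a single measure.
#' @param alpha Significance level gating the post-hoc tests.
#' @return A `phase_test_report`: list with `measure`, `shapiro` (tibble
#'   `phase, n, W, p, normality_ok`), `kruskal` (`H`, `df`, `p`),
#'   `posthoc` (tibble `pair, U, p, p_adj`, or `NULL`), `posthoc_run`.
#' @export
phase_tests <- function(assignments, alpha = 0.05) {
  measure <- unique(assignments$measure)
  if (length(measure) != 1) {
    abort("assignments must contain exactly one measure; filter first")
  }
  phases <- c("REST", "EXERCISE", "RECOVERY")
  groups <- purrr::map(phases, function(ph) {
    assignments$value[assignments$phase == ph]
  })
  names(groups) <- phases
  ns <- purrr::map_int(groups, length)
  if (any(ns < 3)) {
    abort(paste0("insufficient data: need >= 3 values per phase, got ",
                 paste(ns, collapse = "/")))
  }
  shap <- purrr::map2_dfr(groups, phases, function(v, ph) {
    res <- tryCatch(shapiro.test(v), error = function(e) NULL)
    tibble::tibble(phase = ph, n = length(v),
                   W = res$statistic[[1]] %||% NA_real_,
                   p = res$p.value %||% NA_real_)
  })
  shap$normality_ok <- !is.na(shap$p) & shap$p > alpha

  kw <- kruskal.test(purrr::flatten_dbl(purrr::map(groups, identity)),
                     factor(rep(phases, ns), levels = phases))
  kruskal <- list(H = unname(kw$statistic), df = unname(kw$parameter),
                  p = kw$p.value)

  posthoc <- NULL
  run <- kruskal$p < alpha
  if (run) {
    pairs <- list(c("REST", "EXERCISE"), c("REST", "RECOVERY"),
                  c("EXERCISE", "RECOVERY"))
    posthoc <- purrr::map_dfr(pairs, function(pr) {
      mw <- suppressWarnings(wilcox.test(groups[[pr[1]]], groups[[pr[2]]],
                                         alternative = "two.sided", exact = FALSE))
      tibble::tibble(pair = paste(pr, collapse = "-"),
                     U = unname(mw$statistic), p = mw$p.value)
    })
    posthoc$p_adj <- p.adjust(posthoc$p, method = "bonferroni")
  }
  structure(list(measure = measure, shapiro = shap, kruskal = kruskal,
                 posthoc = posthoc, posthoc_run = run, alpha = alpha),
            class = "phase_test_report")
}

#' @export
print.phase_test_report <- function(x, ...) {
  cat("<phase_test_report: ", x$measure, ">\n", sep = "")
  cat("Kruskal-Wallis H =", format(x$kruskal$H, digits = 5),
      ", p =", format(x$kruskal$p, digits = 3), "\n")
  if (x$posthoc_run) {
    print(x$posthoc)
  } else {
    cat("post-hoc tests not run (omnibus p >= ", x$alpha, ")\n", sep = "")
  }
  invisible(x)
}

#' @method tidy phase_test_report
#' @export
tidy.phase_test_report <- function(x, ...) {
  if (is.null(x$posthoc)) {
    return(tibble::tibble(pair = character(), U = double(),
                          p = double(), p_adj = double()))
  }
  x$posthoc
}

#' @method glance phase_test_report
#' @export
glance.phase_test_report <- function(x, ...) {
  tibble::tibble(measure = x$measure, H = x$kruskal$H, df = x$kruskal$df,
                 p = x$kruskal$p, posthoc_run = x$posthoc_run)
}

#' Cycle-aligned Pearson correlation between two Recovery Index series
#'
#' Joins the two series on cycle index, drops cycles where either value is
#' missing (outlier-rejected PAT cycles), and computes the two-sided Pearson
#' correlation (p from the t distribution with n-2 df). Fewer than 3 aligned
#' pairs, or a degenerate (constant) series, leaves the correlation undefined
#' and flagged.
#'
#' @param ri_pat,ri_sbp Tibbles with `cycle` and `ri_pct` columns.
#' @return One-row tibble `n_pairs, r, p, ok`.
#' @export
align_and_correlate <- function(ri_pat, ri_sbp) {
  m <- dplyr::inner_join(
    dplyr::rename(ri_pat[, c("cycle", "ri_pct")], a = "ri_pct"),
    dplyr::rename(ri_sbp[, c("cycle", "ri_pct")], b = "ri_pct"),
    by = "cycle"
  )
  m <- m[is.finite(m$a) & is.finite(m$b), ]
  if (nrow(m) < 3) {
    return(tibble::tibble(n_pairs = nrow(m), r = NA_real_, p = NA_real_, ok = FALSE))
  }
  ct <- tryCatch(cor.test(m$a, m$b, method = "pearson"),
                 error = function(e) NULL)
  if (is.null(ct) || is.na(ct$estimate)) {
    return(tibble::tibble(n_pairs = nrow(m), r = NA_real_, p = NA_real_, ok = FALSE))
  }
  tibble::tibble(n_pairs = nrow(m), r = unname(ct$estimate),
                 p = ct$p.value, ok = TRUE)
}

#' Screen subject-wise correlations for moderate outliers
#'
#' Standardizes the subject-wise Pearson coefficients within the cohort
#' (`z = (r - mean r) / sd r`, sample sd over all subjects with a defined
#' correlation) and excludes subjects with `|z| > threshold` from the
#' population-level summary (mean and sd of `r` and of `p` over retained
#' subjects). If the coefficients have zero spread nothing is excluded. The
#' screen is single-pass: z-scores are computed once on the full set.
#'
#' @param correlations Tibble with `subject_id`, `r`, `p` (rows with
#'   undefined `r` are carried through, never excluded by z, and never
#'   summarized).
#' @param threshold z-score magnitude beyond which a subject is excluded.
#' @return A `correlation_screen`: list with `correlations` (input plus `z`,
#'   `excluded`), `summary` (one-row tibble `n, n_retained, mean_r, sd_r,
#'   mean_p, sd_p`) and `threshold`.
#' @export
zscore_screen <- function(correlations, threshold = 2) {
  ok <- is.finite(correlations$r)
  if (sum(ok) < 3) abort("z-score screening requires >= 3 defined correlations")
  mu <- mean(correlations$r[ok])
  s <- sd(correlations$r[ok])
  z <- rep(NA_real_, nrow(correlations))
  z[ok] <- if (s == 0) 0 else (correlations$r[ok] - mu) / s
  excluded <- !is.na(z) & abs(z) > threshold
  out <- correlations
  out$z <- z
  out$excluded <- excluded
  retained <- ok & !excluded
  summary <- tibble::tibble(
    n = sum(ok), n_retained = sum(retained),
    mean_r = mean(out$r[retained]), sd_r = sd(out$r[retained]),
    mean_p = mean(out$p[retained]), sd_p = sd(out$p[retained])
  )
  structure(list(correlations = out, summary = summary, threshold = threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("<correlation_screen: |z| > ", x$threshold, ">\n", sep = "")
  print(x$summary)
  if (any(x$correlations$excluded)) {
    cat("excluded subjects:",
        paste(x$correlations$subject_id[x$correlations$excluded], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy correlation_screen
#' @export
tidy.correlation_screen <- function(x, ...) x$correlations

#' @method glance correlation_screen
#' @export
glance.correlation_screen <- function(x, ...) x$summary

#' Bland-Altman agreement analysis
#'
#' For each pair, the mean `M_i = (x_i + y_i) / 2` and difference
#' `D_i = x_i - y_i`; the bias is the mean difference, and the 95% limits of
#' agreement are `bias +/- 1.96 * sd(D)` (sample sd).
#'
#' @param x,y Paired measurements (e.g. pooled `RI_PAT` and `RI_SBP`); `NA`
#'   pairs are dropped.
#' @return A `bland_altman` object: list with `pairs` (tibble `m, d`),
#'   `bias`, `sd_d`, `loa_low`, `loa_high`, `n_pairs`.
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("Bland-Altman analysis requires >= 2 pairs")
  d <- x - y
  bias <- mean(d)
  sd_d <- sd(d)
  structure(list(pairs = tibble::tibble(m = (x + y) / 2, d = d),
                 bias = bias, sd_d = sd_d,
                 loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
                 n_pairs = length(x)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n =", x$n_pairs, "\n")
  cat("bias =", format(x$bias, digits = 4),
      " LoA = [", format(x$loa_low, digits = 4), ",",
      format(x$loa_high, digits = 4), "]\n")
  invisible(x)
}

#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_d = x$sd_d, loa_low = x$loa_low,
                 loa_high = x$loa_high, n_pairs = x$n_pairs)
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 * s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2)` with moment
#' (population, denominator n) variance and covariance estimates. Combines
#' correlation and accuracy: it equals the Pearson coefficient only when the
#' two series share mean and variance, and `|rho_c| <= |r|` always.
#'
#' @param x,y Paired measurements; `NA` pairs are dropped.
#' @return The concordance correlation coefficient (scalar in `[-1, 1]`).
#' @export
concordance_ccc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("CCC requires >= 2 pairs")
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) abort("CCC undefined: zero total variance")
  2 * sxy / denom
}
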