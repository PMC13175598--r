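#' Per-cycle median PAT
#'
#' The median PAT across the retained beats of one acquisition cycle is the
#' cycle's summary value. With fewer than `min_beats` retained beats the
#' median is reported as missing (`NA`): a couple of beats cannot support a
#' robust cycle estimate.
#'
#' @param beats A `beat_set` tibble from [extract_beats()].
#' @param min_beats Minimum retained-beat count for a valid median.
#' @return A one-row tibble with `median_pat_ms` and `n_beats`.
#' @export
cycle_median_pat <- function(beats, min_beats = 3) {
  pat <- beats$pat_ms[is.na(beats$reason)]
  n <- length(pat)
  tibble::tibble(
    median_pat_ms = if (n >= min_beats) median(pat) else NA_real_,
    n_beats = n
  )
}

#' Rolling-window outlier rejection on per-cycle medians
#'
#' For each valid median in a subject-session series (time ordered), the mean
#' and sample standard deviation (denominator n-1) of the `window - 1`
#' nearest *other* valid medians are computed, and the point is flagged when
#' it deviates from that local mean by strictly more than `k_sd` standard
#' deviations. Missing medians are skipped and never counted as neighbours.
#' Flagging is single-pass: every point is judged against the original
#' series, flagged or not.
#'
#' The first and last valid points of a series are never flagged: a window
#' centred on them does not exist, and judging an endpoint against its two
#' one-sided successors would systematically discard the steepest genuine
#' physiology (the first post-exercise cycle sits far below cycles 2--3 on
#' any brisk recovery curve, and a one-sided 3-sigma rule flags it for
#' recovery rates above about 0.5 per cycle). Quality control is
#' deliberately conservative at the boundaries.
#'
#' The window statistics deliberately exclude the evaluated point: in a
#' 3-point window that *includes* the centre, the deviation from the window
#' mean can never exceed `2/sqrt(3) ~ 1.15` standard deviations, so a
#' 3-sigma rule would be vacuous. Excluding the centre restores the intended
#' behaviour of the rule.
#'
#' @param summaries Tibble with `subject_id`, `session`, `cycle_index`,
#'   `median_pat_ms` (and any other columns, preserved).
#' @param window Rolling window width (default 3, i.e. 2 neighbours).
#' @param k_sd Deviation threshold in standard deviations.
#' @return `summaries` with a logical `is_outlier` column (`FALSE` for
#'   missing medians).
#' @export
reject_outliers <- function(summaries, window = 3, k_sd = 3) {
  n_nb <- window - 1
  flag_group <- function(df) {
    df <- df[order(df$cycle_index), ]
    df$is_outlier <- FALSE
    vi <- which(!is.na(df$median_pat_ms))
    if (length(vi) < window) {
      if (length(vi) > 0) {
        warn(paste0("subject ", df$subject_id[1], " ", df$session[1],
                    ": fewer than ", window,
                    " valid medians; outlier flagging skipped"))
      }
      return(df)
    }
    v <- df$median_pat_ms[vi]
    for (j in 2:(length(vi) - 1)) { # endpoints: no centred window, never flagged
      nb <- order(abs(seq_along(vi) - j))
      nb <- setdiff(nb, j)[seq_len(n_nb)]
      m <- mean(v[nb])
      s <- sd(v[nb])
      if (abs(v[j] - m) > k_sd * s) df$is_outlier[vi[j]] <- TRUE
    }
    df
  }
  parts <- split(summaries,
                 interaction(summaries$subject_id, summaries$session, drop = TRUE))
  dplyr::bind_rows(lapply(parts, flag_group)) |>
    dplyr::arrange(.data$subject_id, .data$session, .data$cycle_index)
}

#' Extract per-cycle median PAT summaries from a campaign
#'
#' Maps [extract_beats()] and [cycle_median_pat()] over every acquisition
#' cycle, then applies the rolling-window quality control
#' ([reject_outliers()]) per subject-session.
#'
#' @param x A `pat_campaign` or a cycles tibble with `ecg`/`ppg` list-columns.
#' @param min_beats Minimum beats for a valid cycle median.
#' @param qc Apply outlier rejection (default `TRUE`).
#' @param window,k_sd Quality-control parameters, see [reject_outliers()].
#' @param pat_bounds PAT plausibility bounds in ms.
#' @param ... Further arguments to [extract_beats()].
#' @return Tibble `subject_id, session, cycle_index, median_pat_ms, n_beats,
#'   is_outlier`, with a `drop_log` attribute counting dropped beats by
#'   reason.
#' @export
extract_cycles <- function(x, min_beats = 3, qc = TRUE, window = 3, k_sd = 3,
                           pat_bounds = c(100, 600), ...) {
  cycles <- if (inherits(x, "pat_campaign")) x$cycles else x
  stopifnot(all(c("ecg", "ppg", "fs_hz") %in% names(cycles)))
  res <- purrr::map(seq_len(nrow(cycles)), function(i) {
    beats <- extract_beats(cycles$ecg[[i]], cycles$ppg[[i]],
                           fs = cycles$fs_hz[i], pat_bounds = pat_bounds, ...)
    med <- cycle_median_pat(beats, min_beats = min_beats)
    list(summary = dplyr::bind_cols(
      cycles[i, c("subject_id", "session", "cycle_index")], med),
      reasons = beats$reason[!is.na(beats$reason)])
  })
  out <- dplyr::bind_rows(purrr::map(res, "summary"))
  reasons <- unlist(purrr::map(res, "reasons"))
  if (qc) {
    out <- reject_outliers(out, window = window, k_sd = k_sd)
  } else {
    out$is_outlier <- FALSE
  }
  attr(out, "drop_log") <- tibble::as_tibble(as.data.frame(table(reason = reasons),
                                                           stringsAsFactors = FALSE))
  out
}
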