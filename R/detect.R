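# Strict-ish local maxima (first sample of any plateau).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Topographic prominence of peak p: height above the higher of the two
# saddle minima separating it from the nearest higher terrain (or signal end).
peak_prominence <- function(x, p) {
  lmin <- x[p]
  j <- p - 1L
  while (j >= 1 && x[j] <= x[p]) {
    if (x[j] < lmin) lmin <- x[j]
    j <- j - 1L
  }
  rmin <- x[p]
  j <- p + 1L
  while (j <= length(x) && x[j] <= x[p]) {
    if (x[j] < rmin) rmin <- x[j]
    j <- j + 1L
  }
  x[p] - max(lmin, rmin)
}

#' Detect ECG R-peaks (Pan-Tompkins)
#'
#' Classic Pan-Tompkins stages on an already band-passed ECG: first
#' difference, squaring, 150 ms moving-window integration, then adaptive
#' dual signal/noise thresholds with a 200 ms refractory period, a 360 ms
#' T-wave discrimination rule (a candidate following a QRS within 360 ms is
#' rejected as a T wave when its maximal slope is below half the preceding
#' QRS slope), and a search-back at half threshold when an RR gap exceeds
#' 1.66 times the running RR average. Accepted detections are refined to the
#' local ECG maximum within +/-25 ms, and a final pass enforces the
#' refractory spacing on the refined peaks.
#'
#' @param ecg_f Filtered ECG (use [bandpass_filter()] 0.5--40 Hz first).
#' @param fs Sampling rate in Hz; detector windows scale with it.
#' @return Strictly increasing integer sample indices of R-peaks (possibly
#'   empty).
#' @export
detect_r_peaks <- function(ecg_f, fs = 1000) {
  n <- length(ecg_f)
  if (n < 2 * fs) {
    abort("signal too short to initialize detector thresholds (need >= 2 s)")
  }
  refr <- round(0.2 * fs)
  deriv <- c(0, diff(ecg_f))
  sq <- deriv^2
  w <- round(0.15 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  cand <- local_maxima(mwi)
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0) return(integer(0))
  # merge candidates closer than the refractory period, keeping the largest
  keep <- cand[order(-mwi[cand])]
  sel <- integer(0)
  for (p in keep) {
    if (all(abs(sel - p) >= refr)) sel <- c(sel, p)
  }
  cand <- sort(sel)

  init <- mwi[1:(2 * fs)]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- npki + 0.25 * (spki - npki)

  slope_at <- function(i) {
    idx <- max(1, i - round(0.05 * fs)):min(n, i + round(0.05 * fs))
    max(abs(deriv[idx]))
  }

  qrs <- integer(0)
  qrs_slope <- numeric(0)
  pending <- integer(0) # sub-threshold candidates since the last acceptance
  rr_buf <- numeric(0)

  accept <- function(i) {
    qrs <<- c(qrs, i)
    qrs_slope <<- c(qrs_slope, slope_at(i))
    spki <<- 0.125 * mwi[i] + 0.875 * spki
    thr1 <<- npki + 0.25 * (spki - npki)
  }

  for (p in cand) {
    if (length(qrs) > 0 && p - tail(qrs, 1) < refr) next
    if (mwi[p] > thr1) {
      if (length(qrs) > 0 && p - tail(qrs, 1) <= round(0.36 * fs) &&
          slope_at(p) < 0.5 * tail(qrs_slope, 1)) {
        npki <- 0.125 * mwi[p] + 0.875 * npki # T wave: treat as noise peak
        thr1 <- npki + 0.25 * (spki - npki)
        next
      }
      if (length(qrs) > 0) {
        gap <- p - tail(qrs, 1)
        if (length(rr_buf) >= 2 && gap > 1.66 * mean(rr_buf)) {
          sb <- pending[mwi[pending] > 0.5 * thr1 &
                          pending - tail(qrs, 1) >= refr & p - pending >= refr]
          if (length(sb) > 0) {
            missed <- sb[which.max(mwi[sb])]
            rr_buf <- c(rr_buf, missed - tail(qrs, 1))
            accept(missed)
            gap <- p - missed
          }
        }
        rr_buf <- c(rr_buf, gap)
        if (length(rr_buf) > 8) rr_buf <- tail(rr_buf, 8)
      }
      accept(p)
      pending <- integer(0)
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      thr1 <- npki + 0.25 * (spki - npki)
      pending <- c(pending, p)
    }
  }
  if (length(qrs) == 0) return(integer(0))

  # refine each detection to the local ECG maximum within +/-25 ms
  half <- round(0.025 * fs)
  refined <- vapply(qrs, function(i) {
    idx <- max(1, i - half):min(n, i + half)
    idx[which.max(ecg_f[idx])]
  }, integer(1))
  refined <- sort(unique(refined))
  # refractory contract on the refined peaks
  out <- integer(0)
  for (p in refined) {
    if (length(out) == 0 || p - tail(out, 1) >= refr) {
      out <- c(out, p)
    } else if (ecg_f[p] > ecg_f[tail(out, 1)]) {
      out[length(out)] <- p
    }
  }
  out
}

#' Detect PPG pulse peaks
#'
#' Local maxima of the filtered PPG with a minimum topographic prominence
#' (default 20% of the cycle's peak-to-peak amplitude) and a minimum spacing
#' of 250 ms (higher peak wins).
#'
#' @param ppg_f Filtered PPG (use [bandpass_filter()] 0.5--10 Hz first).
#' @param fs Sampling rate in Hz.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   peak-to-peak amplitude.
#' @param min_spacing_s Minimum peak spacing in seconds.
#' @return Increasing integer sample indices (possibly empty).
#' @export
detect_ppg_peaks <- function(ppg_f, fs = 1000, min_prominence_frac = 0.2,
                             min_spacing_s = 0.25) {
  cand <- local_maxima(ppg_f)
  if (length(cand) == 0) return(integer(0))
  p2p <- diff(range(ppg_f))
  if (p2p <= 0) return(integer(0))
  prom <- vapply(cand, function(p) peak_prominence(ppg_f, p), numeric(1))
  cand <- cand[prom >= min_prominence_frac * p2p]
  if (length(cand) == 0) return(integer(0))
  spacing <- round(min_spacing_s * fs)
  keep <- cand[order(-ppg_f[cand])]
  sel <- integer(0)
  for (p in keep) {
    if (all(abs(sel - p) >= spacing)) sel <- c(sel, p)
  }
  sort(sel)
}

#' Locate the PPG maximum-slope fiducial for one beat
#'
#' Pairs the R-peak with the first PPG peak strictly after it and at or
#' before the next R-peak, then returns the sample with the steepest first
#' difference on the interval between them (the upper sample of the steepest
#' rise). Beats with no pulse peak in the interval are dropped (`"no_pulse"`,
#' or `"cycle_edge"` when the interval is cut by the end of the record), and
#' beats whose resulting PAT falls outside the plausibility bounds are
#' dropped as `"implausible"`.
#'
#' @param ppg_f Filtered PPG.
#' @param r_peak,next_r_peak Bounding R-peak samples (`next_r_peak` may be
#'   the final sample for the last beat).
#' @param ppg_peaks Peaks from [detect_ppg_peaks()].
#' @param fs Sampling rate in Hz.
#' @param pat_bounds PAT plausibility interval in ms (default 100--600).
#' @return A list with `ppg_md`, `ppg_peak`, `pat_ms` and `reason`
#'   (`NA_character_` when the beat is retained).
#' @export
locate_ppg_md <- function(ppg_f, r_peak, next_r_peak, ppg_peaks, fs = 1000,
                          pat_bounds = c(100, 600)) {
  stopifnot(r_peak < next_r_peak)
  dropped <- function(reason) {
    list(ppg_md = NA_integer_, ppg_peak = NA_integer_,
         pat_ms = NA_real_, reason = reason)
  }
  hit <- ppg_peaks[ppg_peaks > r_peak & ppg_peaks <= next_r_peak]
  if (length(hit) == 0) {
    at_edge <- next_r_peak >= length(ppg_f)
    return(dropped(if (at_edge) "cycle_edge" else "no_pulse"))
  }
  pk <- hit[1]
  steps <- ppg_f[(r_peak + 1):pk] - ppg_f[r_peak:(pk - 1)]
  md <- r_peak + which.max(steps)
  pat <- (md - r_peak) * 1000 / fs
  if (pat < pat_bounds[1] || pat > pat_bounds[2]) return(dropped("implausible"))
  list(ppg_md = as.integer(md), ppg_peak = as.integer(pk),
       pat_ms = pat, reason = NA_character_)
}

#' Beat-by-beat PAT extraction from one synchronized ECG/PPG record
#'
#' Runs the full per-cycle chain: 50 Hz notch on both channels, Butterworth
#' band-pass (0.5--40 Hz ECG, 0.5--10 Hz PPG, both zero-phase),
#' Pan-Tompkins R-peak detection, PPG peak detection, and maximum-slope
#' fiducial localization per beat. `PAT = (ppg_md - r_peak) * 1000 / fs`.
#'
#' @param ecg,ppg Raw synchronized sample vectors of equal length.
#' @param fs Sampling rate in Hz.
#' @param notch_q Notch quality factor.
#' @param ecg_band,ppg_band Band-pass edges in Hz.
#' @param pat_bounds PAT plausibility bounds in ms.
#' @param min_prominence_frac Passed to [detect_ppg_peaks()].
#' @param edge_margin_s Beats too close to the record edges are dropped as
#'   `"cycle_edge"`: a pulse peaking inside the final `2 * edge_margin_s` is
#'   necessarily truncated mid-decay, and a QRS inside the first
#'   `edge_margin_s` is partially cut; both bias the fiducials by several ms
#'   through the (zero-phase) filters' edge response.
#' @return A `beat_set` tibble, one row per detected R-peak: `beat`,
#'   `r_peak`, `ppg_peak`, `ppg_md`, `pat_ms`, `reason` (`NA` for retained
#'   beats).
#' @export
extract_beats <- function(ecg, ppg, fs = 1000, notch_q = 30,
                          ecg_band = c(0.5, 40), ppg_band = c(0.5, 10),
                          pat_bounds = c(100, 600), min_prominence_frac = 0.2,
                          edge_margin_s = 0.15) {
  stopifnot(length(ecg) == length(ppg))
  ecg_f <- bandpass_filter(notch_filter(ecg, fs, 50, notch_q), fs,
                           ecg_band[1], ecg_band[2])
  ppg_f <- bandpass_filter(notch_filter(ppg, fs, 50, notch_q), fs,
                           ppg_band[1], ppg_band[2])
  r <- detect_r_peaks(ecg_f, fs)
  pk <- detect_ppg_peaks(ppg_f, fs, min_prominence_frac = min_prominence_frac)
  nb <- length(r)
  n <- length(ppg_f)
  margin <- round(edge_margin_s * fs)
  rows <- purrr::map(seq_len(nb), function(j) {
    nxt <- if (j < nb) r[j + 1] else n
    loc <- locate_ppg_md(ppg_f, r[j], nxt, pk, fs, pat_bounds)
    if (is.na(loc$reason) &&
        (r[j] <= margin || loc$ppg_peak >= n - 2 * margin)) {
      loc$reason <- "cycle_edge"
      loc$pat_ms <- NA_real_
    }
    tibble::tibble(beat = j, r_peak = r[j], ppg_peak = loc$ppg_peak,
                   ppg_md = loc$ppg_md, pat_ms = loc$pat_ms, reason = loc$reason)
  })
  out <- if (nb == 0) {
    tibble::tibble(beat = integer(), r_peak = integer(), ppg_peak = integer(),
                   ppg_md = integer(), pat_ms = double(), reason = character())
  } else {
    dplyr::bind_rows(rows)
  }
  class(out) <- c("beat_set", class(out))
  attr(out, "fs") <- fs
  out
}
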