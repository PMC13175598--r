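#' Noise-free PAT trajectory implied by a subject profile
#'
#' In the baseline session the true PAT equals `pat_baseline_ms` for every
#' cycle. In the post-exercise session it follows a first-order
#' (mono-exponential) recovery toward the baseline asymptote:
#' `PAT(x) = PAT_inf + dPAT * exp(-k * (x - 1))`, with `PAT_inf` the baseline
#' PAT, `dPAT` the (negative) exercise-induced drop and `k` the recovery rate
#' per cycle index.
#'
#' @param profile A one-row profile tibble from [generate_profile()].
#' @param session `"baseline"` or `"post"`.
#' @param cycle_index Integer vector with values in 1..11.
#' @return Numeric vector of PAT values in ms, one per `cycle_index`.
#' @export
#' @examples
#' p <- generate_profile(degenerate_ranges())
#' true_pat_at(p, "post", 1:11)
true_pat_at <- function(profile, session = c("baseline", "post"), cycle_index) {
  session <- match.arg(session)
  x <- cycle_index
  if (any(x != round(x)) || any(x < 1) || any(x > 11)) {
    abort("cycle_index must be integers in 1..11")
  }
  if (session == "baseline") {
    rep(profile$pat_baseline_ms, length(x))
  } else {
    profile$pat_baseline_ms +
      profile$delta_pat_ms * exp(-profile$recovery_rate_k * (x - 1))
  }
}

#' Degenerate (zero-width) population ranges
#'
#' Pins every profile parameter to a single value: the midpoint of the default
#' range, except the noise terms which are set to 0. Useful for deterministic
#' fixtures and noise-free validation campaigns.
#'
#' @param ... Named overrides, e.g. `pat_jitter_ms = 2`.
#' @return A ranges tibble accepted by [generate_profile()].
#' @export
degenerate_ranges <- function(...) {
  r <- population_ranges()
  mid <- (r$low + r$high) / 2
  zero <- c("pat_jitter_ms", "pat_drift_ms", "ecg_noise_sd", "ppg_noise_sd",
            "powerline_amplitude", "artifact_cycle_prob")
  mid[r$field %in% zero] <- 0
  r$low <- r$high <- mid
  over <- list(...)
  for (f in names(over)) {
    stopifnot(f %in% r$field)
    r$low[r$field == f] <- r$high[r$field == f] <- over[[f]]
  }
  r
}

# Add a Gaussian deflection (apex exactly on `center` sample) to x in place.
add_gauss <- function(x, center, amp, sd_s, fs) {
  half <- ceiling(4 * sd_s * fs)
  lo <- center - half
  hi <- center + half
  if (hi < 1 || lo > length(x)) return(x)
  idx <- max(1L, lo):min(length(x), hi)
  t <- (idx - center) / fs
  x[idx] <- x[idx] + amp * exp(-0.5 * (t / sd_s)^2)
  x
}

# Raised-cosine PPG pulse with an analytically known maximum-slope sample.
# Upstroke spans `rise` sample steps (odd), so the unique steepest first
# difference is the step into sample onset + (rise + 1) / 2.
add_ppg_pulse <- function(x, onset, rise, fall, amp = 1) {
  n <- length(x)
  up_idx <- onset + 0:rise
  up <- amp * 0.5 * (1 - cos(pi * (0:rise) / rise))
  keep <- up_idx >= 1 & up_idx <= n
  x[up_idx[keep]] <- x[up_idx[keep]] + up[keep]
  if (fall > 0) {
    dn_idx <- onset + rise + 1:fall
    dn <- amp * 0.5 * (1 + cos(pi * (1:fall) / fall))
    keep <- dn_idx >= 1 & dn_idx <= n
    x[dn_idx[keep]] <- x[dn_idx[keep]] + dn[keep]
  }
  x
}

#' Synthesize one 10 s synchronized ECG + PPG acquisition cycle
#'
#' Both channels share one 1 kHz time base (sample i is the same instant on
#' both), emulating a hardware-synchronized two-node acquisition. The ECG is a
#' sum of per-beat P/Q/R/S/T Gaussian deflections (QRS width about 20 ms); the
#' PPG is a raised-cosine pulse per beat whose steepest-upstroke sample lands
#' exactly at the beat's R sample plus its true PAT, so the ground-truth
#' fiducial is known by construction rather than estimated. Additive white
#' noise, a 50 Hz powerline sinusoid, and slow baseline wander are then added
#' to both channels.
#'
#' The per-beat true PAT is `true_pat_at(profile, session, cycle_index) +
#' pat_offset_ms + N(0, pat_jitter_ms)`. Beat-to-beat RR intervals carry
#' multiplicative Gaussian jitter (`rr_jitter`) and are floored at 260 ms; the
#' first beat falls at a uniform random offset within one RR so cycles are not
#' phase-locked. The post-exercise heart rate decays linearly from
#' `hr_post_bpm` (cycle 1) to `hr_rest_bpm` (cycle 11).
#'
#' @param profile One-row profile tibble.
#' @param session `"baseline"` or `"post"`.
#' @param cycle_index Integer in 1..11.
#' @param pat_offset_ms Slow-drift offset added to the cycle's true PAT
#'   (supplied by [generate_campaign()]; default 0).
#' @param fs_hz,duration_s Sampling rate and cycle length.
#' @param rr_jitter Multiplicative sd of the RR jitter (default 0.03).
#' @param rise_ms Nominal PPG upstroke duration; coerced to an odd number of
#'   samples so the maximum-slope sample is unique.
#' @param fall_ms Nominal PPG decay duration (shortened per beat so pulses
#'   never overlap, which would displace the analytic fiducial).
#' @return A list with `cycle` (one-row tibble: identity columns plus `ecg`,
#'   `ppg` list-columns) and `truth` (one-row tibble with `beat_times_s`,
#'   `true_pat_ms`, `true_md_sample` list-columns). Sample indices are 1-based;
#'   `true_md_sample == round(t * fs) + round(pat * fs / 1000) + 1`.
#' @export
synthesize_cycle <- function(profile, session = c("baseline", "post"), cycle_index,
                             pat_offset_ms = 0, fs_hz = 1000, duration_s = 10,
                             rr_jitter = 0.03, rise_ms = 151, fall_ms = 400) {
  session <- match.arg(session)
  validate_profile(profile)
  n <- round(fs_hz * duration_s)

  hr <- if (session == "baseline") {
    profile$hr_rest_bpm
  } else {
    profile$hr_post_bpm +
      (profile$hr_rest_bpm - profile$hr_post_bpm) * (cycle_index - 1) / 10
  }
  rr <- 60 / hr

  rise <- round(rise_ms * fs_hz / 1000)
  if (rise %% 2 == 0) rise <- rise + 1L
  if (rr * fs_hz <= rise + 40) {
    abort("beat period shorter than pulse template: reduce heart rate or rise_ms")
  }

  # beat schedule: uniform first-beat phase, jittered RR, floored at 260 ms
  t <- runif(1, 0, rr)
  beat_t <- numeric(0)
  while (t < duration_s) {
    beat_t <- c(beat_t, t)
    t <- t + max(0.26, rr * (1 + rnorm(1, 0, rr_jitter)))
  }
  r_sample <- round(beat_t * fs_hz) + 1L
  keep <- r_sample <= n
  r_sample <- r_sample[keep]
  beat_t <- (r_sample - 1) / fs_hz # snap to the sample grid
  nb <- length(r_sample)

  pat_true <- true_pat_at(profile, session, rep(cycle_index, nb)) +
    pat_offset_ms + rnorm(nb, 0, profile$pat_jitter_ms)
  md_sample <- r_sample + round(pat_true * fs_hz / 1000)

  ecg <- numeric(n)
  ppg <- numeric(n)
  for (j in seq_len(nb)) {
    r <- r_sample[j]
    ecg <- add_gauss(ecg, r, 1, 0.006, fs_hz)                       # R
    ecg <- add_gauss(ecg, r - round(0.025 * fs_hz), -0.15, 0.009, fs_hz) # Q
    ecg <- add_gauss(ecg, r + round(0.025 * fs_hz), -0.20, 0.009, fs_hz) # S
    ecg <- add_gauss(ecg, r - round(0.17 * fs_hz), 0.12, 0.022, fs_hz)   # P
    ecg <- add_gauss(ecg, r + round(0.28 * fs_hz), 0.30, 0.050, fs_hz)   # T
  }
  onset <- md_sample - (rise + 1L) %/% 2L
  fall_n <- round(fall_ms * fs_hz / 1000)
  for (j in seq_len(nb)) {
    limit <- if (j < nb) onset[j + 1] - (onset[j] + rise) - 1L else n - (onset[j] + rise)
    ppg <- add_ppg_pulse(ppg, onset[j], rise, max(0L, min(fall_n, limit)))
  }

  # every scheduled beat is ground truth; a final beat's fiducial may point
  # past the record end (its pulse is truncated and extraction drops it)
  truth <- tibble::tibble(
    subject_id = profile$subject_id, session = session,
    cycle_index = as.integer(cycle_index),
    beat_times_s = list(beat_t),
    true_pat_ms = list(pat_true),
    true_md_sample = list(as.integer(md_sample))
  )

  tvec <- (0:(n - 1)) / fs_hz
  if (profile$powerline_amplitude > 0) {
    ecg <- ecg + profile$powerline_amplitude * sin(2 * pi * 50 * tvec + runif(1, 0, 2 * pi))
    ppg <- ppg + profile$powerline_amplitude * sin(2 * pi * 50 * tvec + runif(1, 0, 2 * pi))
  }
  if (profile$ecg_noise_sd > 0) {
    ecg <- ecg + rnorm(n, 0, profile$ecg_noise_sd) +
      5 * profile$ecg_noise_sd * sin(2 * pi * runif(1, 0.15, 0.3) * tvec + runif(1, 0, 2 * pi))
  }
  if (profile$ppg_noise_sd > 0) {
    ppg <- ppg + rnorm(n, 0, profile$ppg_noise_sd) +
      5 * profile$ppg_noise_sd * sin(2 * pi * runif(1, 0.15, 0.3) * tvec + runif(1, 0, 2 * pi))
  }

  cycle <- tibble::tibble(
    subject_id = profile$subject_id, session = session,
    cycle_index = as.integer(cycle_index), fs_hz = fs_hz,
    duration_s = duration_s, artifact = NA_character_,
    ecg = list(ecg), ppg = list(ppg)
  )
  list(cycle = cycle, truth = truth)
}

#' Simulate intermittent oscillometric cuff readings for one session
#'
#' One reading after each of cycles 1, 4, 7 and 10 (90 s apart under the 30 s
#' cycle schedule). Systolic pressure is inversely coupled to the cycle's mean
#' true PAT, `SBP = SBP_baseline + gamma * (meanPAT - PAT_baseline) + noise`
#' with `gamma < 0`, while diastolic pressure stays near its baseline (DBP is
#' comparatively stable under this kind of perturbation).
#'
#' @param profile One-row profile tibble.
#' @param session `"baseline"` or `"post"`.
#' @param truths Truth tibble (from [synthesize_cycle()]) for this subject and
#'   session, one row per cycle.
#' @param sbp_noise_sd,dbp_noise_sd Measurement noise sd in mmHg.
#' @return A tibble `subject_id, session, after_cycle, sbp_mmHg, dbp_mmHg`.
#' @export
simulate_cuff <- function(profile, session = c("baseline", "post"), truths,
                          sbp_noise_sd = 2, dbp_noise_sd = 1.5) {
  session <- match.arg(session)
  after <- c(1L, 4L, 7L, 10L)
  if (!all(after %in% truths$cycle_index)) {
    abort("truths must cover cycles 1, 4, 7 and 10")
  }
  mpat <- purrr::map_dbl(after, function(ac) {
    mean(truths$true_pat_ms[[which(truths$cycle_index == ac)]])
  })
  sbp <- profile$sbp_baseline_mmHg +
    profile$coupling_gamma_mmHg_per_ms * (mpat - profile$pat_baseline_ms) +
    rnorm(4, 0, sbp_noise_sd)
  dbp <- profile$dbp_baseline_mmHg + rnorm(4, 0, dbp_noise_sd)
  if (any(sbp <= dbp)) {
    warn("simulated SBP <= DBP; raising SBP to keep readings physiological")
    sbp <- pmax(sbp, dbp + 1)
  }
  tibble::tibble(subject_id = profile$subject_id, session = session,
                 after_cycle = after, sbp_mmHg = sbp, dbp_mmHg = dbp)
}

#' Generate a complete synthetic acquisition campaign
#'
#' For each subject: two sessions (baseline, post-exercise) of 11 cycles of
#' 10 s synchronized ECG+PPG at 1 kHz, with four cuff readings per session
#' (after cycles 1, 4, 7, 10). Each cycle occupies a 30 s slot (10 s
#' acquisition + 20 s wireless transfer), recorded in the manifest. A smooth
#' sinusoidal PAT drift (amplitude `pat_drift_ms`, period 14--22 cycles,
#' random phase, drawn per session) is added on top of the recovery curve so
#' per-cycle medians are serially correlated, as real series are.
#'
#' All randomness derives from `seed` through one stream per subject, so
#' increasing `n_subjects` never perturbs earlier subjects' data.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param ranges Population ranges tibble, see [population_ranges()].
#' @param seed Integer root seed.
#' @param artifact_prob If non-`NULL`, overrides each profile's
#'   `artifact_cycle_prob`; corrupted cycles get a random artifact kind from
#'   [inject_artifact()] and are tagged in `cycles$artifact`.
#' @param ... Passed to [synthesize_cycle()] (e.g. `rr_jitter`, `rise_ms`).
#' @return A `pat_campaign` object: list with tibbles `profiles`, `cycles`,
#'   `truths`, `readings`, plus `manifest` and `seed`.
#' @export
#' @examples
#' camp <- generate_campaign(1, seed = 7)
#' camp
generate_campaign <- function(n_subjects, ranges = population_ranges(), seed = 1L,
                              artifact_prob = NULL, ...) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("n_subjects must be >= 1")
  }
  n_subjects <- as.integer(n_subjects)
  profiles <- vector("list", n_subjects)
  cycles <- list()
  truths <- list()
  readings <- list()
  kinds <- c("spike_burst", "signal_dropout", "wander_surge")

  for (s in seq_len(n_subjects)) {
    set.seed((abs(as.integer(seed)) + s * 1000003L) %% 2147483647L)
    profile <- generate_profile(ranges, subject_id = s)
    profiles[[s]] <- profile
    prob <- artifact_prob %||% profile$artifact_cycle_prob
    for (session in c("baseline", "post")) {
      period <- runif(1, 14, 22)
      phase <- runif(1, 0, period)
      drift <- profile$pat_drift_ms * sin(2 * pi * ((1:11) - phase) / period)
      sess_truths <- vector("list", 11)
      for (ci in 1:11) {
        res <- synthesize_cycle(profile, session, ci, pat_offset_ms = drift[ci], ...)
        sess_truths[[ci]] <- res$truth
        cyc <- res$cycle
        if (runif(1) < prob) {
          cyc <- inject_artifact(cyc, sample(kinds, 1))
        }
        cycles[[length(cycles) + 1]] <- cyc
      }
      sess_truths <- dplyr::bind_rows(sess_truths)
      truths[[length(truths) + 1]] <- sess_truths
      readings[[length(readings) + 1]] <- simulate_cuff(profile, session, sess_truths)
    }
  }

  structure(list(
    profiles = dplyr::bind_rows(profiles),
    cycles = dplyr::bind_rows(cycles),
    truths = dplyr::bind_rows(truths),
    readings = dplyr::bind_rows(readings),
    manifest = list(
      n_subjects = n_subjects, n_cycles_per_session = 11L,
      sessions = c("baseline", "post"), cycle_duration_s = 30,
      acquisition_s = 10, transfer_s = 20,
      reading_after_cycles = c(1L, 4L, 7L, 10L),
      reading_spacing_s = 3 * 30
    ),
    seed = as.integer(seed)
  ), class = "pat_campaign")
}

#' @export
print.pat_campaign <- function(x, ...) {
  cat("<pat_campaign>\n")
  cat("  subjects:", x$manifest$n_subjects,
      " cycles:", nrow(x$cycles),
      " cuff readings:", nrow(x$readings), "\n")
  cat("  schedule: 2 sessions x 11 cycles x", x$manifest$acquisition_s,
      "s @ 1 kHz;", x$manifest$cycle_duration_s, "s cycle slot\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Corrupt one acquisition cycle with a localized artifact
#'
#' Produces a corrupted copy (the input cycle is untouched) emulating the
#' transient disturbances that quality control must reject:
#' * `spike_burst` -- dense high-amplitude spikes over a 6 s window on both
#'   channels (electrode/motion transients);
#' * `signal_dropout` -- the PPG collapses to near-zero over 90% of the cycle
#'   (optical sensor detached), leaving too few beats for a valid median;
#' * `wander_surge` -- a large ~1 Hz oscillation over a 6 s window of the PPG
#'   (rhythmic motion), displacing the maximum-slope fiducials.
#'
#' @param cycle One-row cycle tibble (from [synthesize_cycle()] or a campaign).
#' @param kind Artifact kind, see above.
#' @return The corrupted cycle with its `artifact` column set.
#' @export
inject_artifact <- function(cycle, kind = c("spike_burst", "signal_dropout", "wander_surge")) {
  kind <- match.arg(kind)
  ecg <- cycle$ecg[[1]]
  ppg <- cycle$ppg[[1]]
  n <- length(ppg)
  fs <- cycle$fs_hz[1]

  if (kind == "spike_burst") {
    win <- round(8 * fs)
    start <- floor(runif(1, 0, n - win)) + 1L
    n_sp <- 70
    pos <- start + sort(sample.int(win, n_sp)) - 1L
    amp_e <- 4 * max(abs(ecg), 1e-12)
    amp_p <- 4 * max(abs(ppg), 1e-12)
    sgn <- sample(c(-1, 1), n_sp, replace = TRUE)
    # 20-80 ms half-sine transients: wide enough to pass the PPG band-limits
    for (j in seq_len(n_sp)) {
      wid <- round(runif(1, 0.02, 0.08) * fs)
      idx <- pos[j]:min(pos[j] + wid - 1L, n)
      lump <- sin(pi * seq_along(idx) / length(idx))
      ecg[idx] <- ecg[idx] + sgn[j] * amp_e * lump
      ppg[idx] <- ppg[idx] + sgn[j] * amp_p * lump
    }
  } else if (kind == "signal_dropout") {
    len <- round(0.9 * n)
    start <- floor(runif(1, 0, n - len)) + 1L
    idx <- start:(start + len - 1L)
    ppg[idx] <- 0.01 * ppg[idx]
  } else {
    win <- round(0.9 * n)
    start <- floor(runif(1, 0, n - win)) + 1L
    idx <- start:(start + win - 1L)
    f <- runif(1, 0.9, 1.6) # in-band: slower wander is erased by the band-pass
    amp <- 3 * max(abs(ppg), 1e-12)
    tvec <- (idx - 1) / fs
    # flat-top (Tukey) envelope: full strength over the window, smooth edges
    m <- length(idx)
    ramp <- round(0.1 * m)
    taper <- c(sin(pi * (1:ramp) / (2 * ramp))^2, rep(1, m - 2 * ramp),
               cos(pi * (1:ramp) / (2 * ramp))^2)
    ppg[idx] <- ppg[idx] + amp * taper * sin(2 * pi * f * tvec + runif(1, 0, 2 * pi))
  }

  out <- cycle
  out$ecg <- list(ecg)
  out$ppg <- list(ppg)
  out$artifact <- kind
  out
}
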