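#' Default population ranges for synthetic subject profiles
#'
#' Each physiological parameter of a [generate_profile()] draw is sampled
#' uniformly from a `[low, high]` interval. The defaults describe a healthy
#' adult cohort undergoing a moderate treadmill perturbation: resting PAT of
#' 220--300 ms, an exercise-induced PAT drop of 40--80 ms recovering
#' mono-exponentially at 0.25--0.8 per cycle, and an inverse PAT--SBP coupling
#' of -0.8 to -0.4 mmHg/ms so that a 60 ms PAT drop maps to a 24--48 mmHg
#' systolic rise. Noise levels are relative to unit-amplitude R-peaks and PPG
#' pulses. `pat_drift_ms` is the amplitude of a slow, smooth within-session
#' PAT drift (vasomotor/autonomic wander) that makes consecutive per-cycle
#' medians serially correlated, as real baseline series are.
#'
#' @return A tibble with columns `field`, `low`, `high`, one row per
#'   [generate_profile()] parameter.
#' @seealso [generate_profile()], [generate_campaign()]
#' @export
#' @examples
#' population_ranges()
population_ranges <- function() {
  tibble::tribble(
    ~field,                        ~low,  ~high,
    "pat_baseline_ms",             220,   300,
    "delta_pat_ms",                -80,   -40,
    "recovery_rate_k",             0.25,  0.8,
    "hr_rest_bpm",                 55,    75,
    "hr_post_bpm",                 95,    120,
    "sbp_baseline_mmHg",           105,   130,
    "dbp_baseline_mmHg",           65,    85,
    "coupling_gamma_mmHg_per_ms",  -0.8,  -0.4,
    "pat_jitter_ms",               2,     2,
    "pat_drift_ms",                3,     8,
    "ecg_noise_sd",                0.02,  0.05,
    "ppg_noise_sd",                0.01,  0.04,
    "powerline_amplitude",         0.02,  0.08,
    "artifact_cycle_prob",         0,     0
  )
}

profile_fields <- function() population_ranges()$field

#' Draw one synthetic subject profile
#'
#' Samples every physiological parameter uniformly from the supplied ranges
#' and validates the profile invariants: post-exercise PAT stays positive
#' (`pat_baseline_ms + delta_pat_ms > 0`), post-exercise heart rate is not
#' below resting heart rate, and `artifact_cycle_prob` lies in `[0, 1]`.
#'
#' Randomness is taken from the current RNG stream; call `set.seed()` (or use
#' [generate_campaign()], which derives one stream per subject from its root
#' seed) for reproducible draws.
#'
#' @param ranges A tibble of `field`, `low`, `high` rows as returned by
#'   [population_ranges()]. Zero-width ranges (`low == high`) pin a parameter.
#' @param subject_id Integer identifier stored in the profile.
#' @return A one-row tibble with `subject_id` and one column per parameter.
#' @export
#' @examples
#' set.seed(1)
#' generate_profile()
generate_profile <- function(ranges = population_ranges(), subject_id = 1L) {
  stopifnot(is.data.frame(ranges), all(c("field", "low", "high") %in% names(ranges)))
  missing <- setdiff(profile_fields(), ranges$field)
  if (length(missing) > 0) {
    abort(paste0("ranges is missing fields: ", paste(missing, collapse = ", ")))
  }
  bad <- ranges$low > ranges$high
  if (any(bad)) {
    abort(paste0("invalid range (low > high) for: ",
                 paste(ranges$field[bad], collapse = ", ")))
  }
  draws <- purrr::map2_dbl(ranges$low, ranges$high, function(lo, hi) {
    if (lo == hi) lo else runif(1, lo, hi)
  })
  profile <- tibble::as_tibble(as.list(setNames(draws, ranges$field)))
  profile <- dplyr::bind_cols(tibble::tibble(subject_id = as.integer(subject_id)), profile)
  validate_profile(profile)
  profile
}

validate_profile <- function(profile) {
  p <- as.list(profile)
  if (p$pat_baseline_ms + p$delta_pat_ms <= 0) {
    abort("invalid profile: pat_baseline_ms + delta_pat_ms must be > 0")
  }
  if (p$hr_post_bpm < p$hr_rest_bpm) {
    abort("invalid profile: hr_post_bpm must be >= hr_rest_bpm")
  }
  if (p$artifact_cycle_prob < 0 || p$artifact_cycle_prob > 1) {
    abort("invalid profile: artifact_cycle_prob must be in [0, 1]")
  }
  nonneg <- c("pat_baseline_ms", "recovery_rate_k", "hr_rest_bpm", "hr_post_bpm",
              "sbp_baseline_mmHg", "dbp_baseline_mmHg", "pat_jitter_ms",
              "pat_drift_ms", "ecg_noise_sd", "ppg_noise_sd", "powerline_amplitude")
  for (f in nonneg) {
    if (p[[f]] < 0) abort(paste0("invalid profile: ", f, " must be nonnegative"))
  }
  invisible(profile)
}
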