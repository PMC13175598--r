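test_that("cycle synthesis respects the sampling contract and beat schedule", {
  p <- quiet_profile(hr_rest_bpm = 60, hr_post_bpm = 60)
  set.seed(5)
  for (i in 1:10) {
    res <- synthesize_cycle(p, "baseline", 1, rr_jitter = 0)
    expect_length(res$cycle$ecg[[1]], 1000 * 10)
    expect_length(res$cycle$ppg[[1]], 1000 * 10)
    # 60 bpm over 10 s: 10 or 11 beats depending on the first-beat phase
    expect_true(length(res$truth$beat_times_s[[1]]) %in% c(10, 11))
  }
})

test_that("ground truth honours its construction invariants", {
  p <- quiet_profile(pat_jitter_ms = 2)
  set.seed(11)
  for (session in c("baseline", "post")) {
    res <- synthesize_cycle(p, session, 3)
    tr <- res$truth
    bt <- tr$beat_times_s[[1]]
    expect_true(all(diff(bt) >= 0.25))
    expect_identical(
      tr$true_md_sample[[1]],
      as.integer(round(bt * 1000) + round(tr$true_pat_ms[[1]] * 1000 / 1000) + 1L)
    )
  }
})

test_that("noiseless PPG pulses place their steepest step exactly on the truth", {
  p <- quiet_profile(pat_jitter_ms = 2)
  set.seed(21)
  res <- synthesize_cycle(p, "post", 2)
  ppg <- res$cycle$ppg[[1]]
  md <- res$truth$true_md_sample[[1]]
  r <- as.integer(round(res$truth$beat_times_s[[1]] * 1000)) + 1L
  for (j in seq_along(r)) {
    if (md[j] >= length(ppg)) next # truncated final pulse: no complete upstroke
    to <- if (j < length(r)) r[j + 1] else length(ppg)
    est <- r[j] + which.max(ppg[(r[j] + 1):to] - ppg[r[j]:(to - 1)])
    expect_identical(est, md[j])
  }
})

test_that("powerline contamination shows up at 50 Hz and nowhere else needed", {
  clean <- quiet_profile()
  dirty <- quiet_profile(powerline_amplitude = 0.05)
  set.seed(3)
  a <- synthesize_cycle(clean, "baseline", 1)$cycle
  set.seed(3)
  b <- synthesize_cycle(dirty, "baseline", 1)$cycle
  for (ch in c("ecg", "ppg")) {
    p_clean <- power_at(a[[ch]][[1]], 1000, 50)
    p_dirty <- power_at(b[[ch]][[1]], 1000, 50)
    expect_gt(10 * log10(p_dirty / max(p_clean, 1e-30)), 20)
  }
})

test_that("a beat period shorter than the pulse template is a configuration error", {
  p <- quiet_profile()
  expect_error(synthesize_cycle(p, "baseline", 1, rise_ms = 1200),
               "beat period shorter")
})

test_that("cuff readings follow the inverse PAT-SBP coupling law", {
  p <- quiet_profile(pat_jitter_ms = 0)
  truths <- dplyr::bind_rows(lapply(c(1L, 4L, 7L, 10L), function(ci) {
    tibble::tibble(subject_id = 1L, session = "post", cycle_index = ci,
                   beat_times_s = list(seq(0.5, 9.5, by = 1)),
                   true_pat_ms = list(rep(p$pat_baseline_ms - 40, 10)),
                   true_md_sample = list(integer(10)))
  }))
  # gamma = -0.5 mmHg/ms and PAT 40 ms below baseline: SBP 20 mmHg above
  p$coupling_gamma_mmHg_per_ms <- -0.5
  rd <- simulate_cuff(p, "post", truths, sbp_noise_sd = 0, dbp_noise_sd = 0)
  expect_identical(rd$after_cycle, c(1L, 4L, 7L, 10L))
  expect_equal(rd$sbp_mmHg, rep(p$sbp_baseline_mmHg + 20, 4), tolerance = 1e-9)
  expect_true(all(rd$sbp_mmHg > rd$dbp_mmHg))

  # decoupled case: constant SBP at baseline
  p$coupling_gamma_mmHg_per_ms <- 0
  rd0 <- simulate_cuff(p, "post", truths, sbp_noise_sd = 0, dbp_noise_sd = 0)
  expect_equal(rd0$sbp_mmHg, rep(p$sbp_baseline_mmHg, 4), tolerance = 1e-12)

  # baseline session with no jitter sits exactly at baseline SBP
  base_truths <- truths
  base_truths$session <- "baseline"
  base_truths$true_pat_ms <- lapply(1:4, function(i) rep(p$pat_baseline_ms, 10))
  p$coupling_gamma_mmHg_per_ms <- -0.6
  rdb <- simulate_cuff(p, "baseline", base_truths,
                       sbp_noise_sd = 0, dbp_noise_sd = 0)
  expect_equal(rdb$sbp_mmHg, rep(p$sbp_baseline_mmHg, 4), tolerance = 1e-12)
})

test_that("campaign cardinalities and determinism hold", {
  for (n in c(1, 2)) {
    camp <- generate_campaign(n, seed = 4)
    expect_identical(nrow(camp$cycles), as.integer(n * 22))
    expect_identical(nrow(camp$readings), as.integer(n * 8))
    counts <- dplyr::count(camp$readings, subject_id, session)
    expect_true(all(counts$n == 4))
  }
  c1 <- generate_campaign(2, seed = 10)
  c2 <- generate_campaign(2, seed = 10)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_campaign(2, seed = 11)
  expect_false(identical(c1$cycles$ecg[[1]], c3$cycles$ecg[[1]]))
  # growing the cohort must not perturb earlier subjects
  c4 <- generate_campaign(3, seed = 10)
  expect_identical(c1$cycles$ecg[[5]], c4$cycles$ecg[[5]])
  expect_error(generate_campaign(0), "n_subjects")
})
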