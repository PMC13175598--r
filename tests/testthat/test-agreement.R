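toy_summaries <- function() {
  dplyr::bind_rows(
    tibble::tibble(subject_id = 1L, session = "baseline", cycle_index = 1:11,
                   median_pat_ms = 250 + c(1, -1, 0, 2, -2, 1, 0, -1, 1, 0, -1),
                   n_beats = 10L, is_outlier = FALSE),
    tibble::tibble(subject_id = 1L, session = "post", cycle_index = 1:11,
                   median_pat_ms = 250 - 60 * exp(-0.5 * (0:10)),
                   n_beats = 10L, is_outlier = FALSE)
  )
}

toy_readings <- function() {
  dplyr::bind_rows(
    tibble::tibble(subject_id = 1L, session = "baseline",
                   after_cycle = c(1L, 4L, 7L, 10L),
                   sbp_mmHg = c(118, 120, 122, 120), dbp_mmHg = rep(78, 4)),
    tibble::tibble(subject_id = 1L, session = "post",
                   after_cycle = c(1L, 4L, 7L, 10L),
                   sbp_mmHg = c(150, 135, 126, 122), dbp_mmHg = rep(79, 4))
  )
}

test_that("phase assignment follows the protocol spans", {
  ph <- assign_phases(toy_summaries(), toy_readings(), baseline_centering = FALSE)
  pat <- ph[ph$measure == "PAT", ]
  expect_identical(unique(pat$phase[1:11]), "REST") # every baseline cycle
  post <- pat[12:nrow(pat), ]
  expect_identical(nrow(post), 6L) # post cycles 4-8 are unassigned
  expect_identical(post$phase, rep(c("EXERCISE", "RECOVERY"), each = 3))

  sbp <- ph[ph$measure == "SBP", ]
  expect_equal(sbp$value[sbp$phase == "REST"], 120)    # mean of four baselines
  expect_equal(sbp$value[sbp$phase == "EXERCISE"], 150) # first post reading
  expect_equal(sbp$value[sbp$phase == "RECOVERY"], 122) # last post reading
})

test_that("baseline centering makes PAT relative to the subject baseline", {
  ph <- assign_phases(toy_summaries(), toy_readings(), baseline_centering = TRUE)
  pat <- ph[ph$measure == "PAT", ]
  expect_equal(mean(pat$value[pat$phase == "REST"]), 0, tolerance = 1e-12)
  expect_lt(min(pat$value[pat$phase == "EXERCISE"]), -50)
})

test_that("identically distributed phases give H = 0, p = 1 and no post-hoc", {
  vals <- c(3, 1, 4, 1, 5, 9, 2, 6)
  asg <- tibble::tibble(
    measure = "PAT",
    phase = rep(c("REST", "EXERCISE", "RECOVERY"), each = 8),
    subject_id = 1L,
    value = c(vals, rev(vals), sample(vals))
  )
  rep_ <- phase_tests(asg)
  expect_equal(rep_$kruskal$H, 0, tolerance = 1e-12)
  expect_equal(rep_$kruskal$p, 1, tolerance = 1e-12)
  expect_false(rep_$posthoc_run)
  expect_null(rep_$posthoc)
})

test_that("a strong phase shift is detected with Bonferroni-adjusted certainty", {
  set.seed(23)
  for (i in 1:40) {
    asg <- tibble::tibble(
      measure = "PAT",
      phase = rep(c("REST", "EXERCISE", "RECOVERY"), each = 19),
      subject_id = 1L,
      value = c(rnorm(19), rnorm(19, mean = 5), rnorm(19))
    )
    rep_ <- phase_tests(asg)
    expect_true(rep_$posthoc_run)
    adj <- rep_$posthoc$p_adj[rep_$posthoc$pair == "REST-EXERCISE"]
    expect_lt(adj, 1e-4)
    expect_equal(rep_$posthoc$p_adj, pmin(1, 3 * rep_$posthoc$p),
                 tolerance = 1e-12)
  }
})

test_that("insufficient phase data is an error", {
  asg <- tibble::tibble(measure = "PAT",
                        phase = c("REST", "REST", "EXERCISE", "RECOVERY"),
                        subject_id = 1L, value = 1:4)
  expect_error(phase_tests(asg), "insufficient")
})

test_that("aligned correlation handles identity, inversion and hand data", {
  ri <- function(v) tibble::tibble(cycle = seq_along(v), ri_pct = v)
  v <- c(-100, -60, -35, -20, -10, -4, 0, 2, 1, 0, -1)
  expect_equal(align_and_correlate(ri(v), ri(v))$r, 1, tolerance = 1e-12)
  w <- v - mean(v)
  expect_equal(align_and_correlate(ri(w), ri(-w))$r, -1, tolerance = 1e-12)

  # product-moment formula evaluated by hand for (0,0),(1,2),(2,1),(3,3)
  a <- c(0, 1, 2, 3); b <- c(0, 2, 1, 3)
  hand_r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  got <- align_and_correlate(ri(a), ri(b))
  expect_equal(got$r, hand_r, tolerance = 1e-12)
  expect_identical(got$n_pairs, 4L)

  # gaps: cycles missing in RI_PAT are dropped pairwise
  v_gap <- v; v_gap[c(2, 5)] <- NA
  expect_identical(align_and_correlate(ri(v_gap), ri(v))$n_pairs, 9L)
  few <- align_and_correlate(ri(c(1, NA, NA, NA, NA, NA, NA, NA, NA, NA, 2)), ri(v))
  expect_false(few$ok)
  expect_true(is.na(few$r))
})

test_that("z-score screening excludes only genuine cohort outliers", {
  cors <- tibble::tibble(subject_id = 1:18, r = c(rep(0.95, 17), 0.50),
                         p = rep(1e-4, 18), ok = TRUE)
  scr <- zscore_screen(cors)
  # hand z of the 0.50: (0.50 - mean) / sd ~ -4.0
  mu <- mean(cors$r); sdev <- sd(cors$r)
  expect_equal(scr$correlations$z[18], (0.5 - mu) / sdev, tolerance = 1e-12)
  expect_identical(which(scr$correlations$excluded), 18L)
  expect_equal(scr$summary$mean_r, 0.95, tolerance = 1e-12)
  expect_identical(scr$summary$n_retained, 17L)
  # single-pass: every retained subject already satisfies |z| <= 2
  expect_true(all(abs(scr$correlations$z[!scr$correlations$excluded]) <= 2))

  same <- zscore_screen(tibble::tibble(subject_id = 1:5, r = rep(0.9, 5),
                                       p = rep(0.01, 5), ok = TRUE))
  expect_false(any(same$correlations$excluded)) # zero spread: no exclusions
  expect_error(zscore_screen(cors[1:2, ]), ">= 3")
})

test_that("Bland-Altman matches hand computations and its antisymmetry", {
  ident <- bland_altman(1:10, 1:10)
  expect_identical(c(ident$bias, ident$loa_low, ident$loa_high), c(0, 0, 0))

  off <- bland_altman(1:10, (1:10) + 5)
  expect_equal(off$bias, -5, tolerance = 1e-12)
  expect_equal(off$sd_d, 0, tolerance = 1e-12)
  expect_equal(c(off$loa_low, off$loa_high), c(-5, -5), tolerance = 1e-12)

  # hand case: D = (-1, 1, -1), bias -1/3, sample sd 2/sqrt(3)
  ba <- bland_altman(c(0, 2, 4), c(1, 1, 5))
  expect_equal(ba$pairs$d, c(-1, 1, -1), tolerance = 1e-12)
  expect_equal(ba$bias, -1 / 3, tolerance = 1e-12)
  expect_equal(ba$sd_d, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1 / 3 - 1.96 * 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(ba$loa_high, -1 / 3 + 1.96 * 2 / sqrt(3), tolerance = 1e-12)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)

  swapped <- bland_altman(c(1, 1, 5), c(0, 2, 4))
  expect_equal(swapped$bias, -ba$bias, tolerance = 1e-12)
  expect_equal(swapped$loa_low, -ba$loa_high, tolerance = 1e-12)
  expect_equal(swapped$loa_high, -ba$loa_low, tolerance = 1e-12)

  expect_error(bland_altman(1, 2), ">= 2")
})

test_that("the concordance coefficient matches its moment-form definition", {
  expect_equal(concordance_ccc(1:10, 1:10), 1, tolerance = 1e-12)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(concordance_ccc(x, -x), -1, tolerance = 1e-12)
  # hand evaluation for x = (1,2,3), y = (1,2,4): rho_c = 6/7
  expect_equal(concordance_ccc(c(1, 2, 3), c(1, 2, 4)), 6 / 7, tolerance = 1e-12)
  expect_error(concordance_ccc(c(1, 1), c(1, 1)), "zero total variance")
})

test_that("|rho_c| <= |r| always, with equality iff moments match", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- runif(1, -2, 2) * x + rnorm(n, mean = runif(1, -3, 3))
    r <- suppressWarnings(cor(x, y))
    if (is.na(r)) next
    expect_lte(abs(concordance_ccc(x, y)), abs(r) + 1e-12)
  }
  # equal means and variances: rho_c collapses onto Pearson r
  set.seed(56)
  x <- rnorm(50)
  y <- rev(x)
  expect_equal(concordance_ccc(x, y), cor(x, y), tolerance = 1e-12)
})
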