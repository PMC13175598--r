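test_that("exact model data are recovered to numerical precision", {
  x <- 1:11
  y <- 250 - 60 * exp(-0.4 * (x - 1))
  fit <- fit_recovery_model(x, y, "mono_exp")
  expect_equal(unname(fit$params["pat_inf"]), 250, tolerance = 1e-6)
  expect_equal(unname(fit$params["delta_pat"]), -60, tolerance = 1e-6)
  expect_equal(unname(fit$params["k"]), 0.4, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$converged)

  lin <- fit_recovery_model(x, 2 * x + 1, "linear")
  expect_equal(unname(lin$params), c(2, 1), tolerance = 1e-12)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)

  lg <- fit_recovery_model(x, 3 + 2 * log(x), "log")
  expect_equal(unname(lg$params), c(3, 2), tolerance = 1e-9)
})

test_that("degenerate and undersized inputs behave as documented", {
  expect_error(fit_recovery_model(1:3, c(1, 2, 3), "mono_exp"), "insufficient")
  expect_error(fit_recovery_model(1, 2, "linear"), "insufficient")
  expect_error(fit_recovery_model(0:5, rnorm(6), "linear"), ">= 1")
  const <- fit_recovery_model(1:6, rep(5, 6), "log")
  expect_true(is.na(const$r_squared)) # SS_tot = 0: undefined, fit still returned
  expect_equal(unname(const$params["a"]), 5, tolerance = 1e-9)
})

test_that("the bounded fit matches an independent grid-search oracle", {
  sse <- function(par, x, y) sum((y - (par[1] + par[2] * exp(-par[3] * (x - 1))))^2)
  x <- 1:11
  set.seed(42)
  for (i in 1:5) {
    y <- 250 - 60 * exp(-0.4 * (x - 1)) + rnorm(11, 0, 2)
    fit <- fit_recovery_model(x, y, "mono_exp")
    # oracle: coarse grid over k, profiling the two linear parameters exactly
    grid_best <- min(vapply(seq(0.05, 2, by = 0.005), function(k) {
      z <- exp(-k * (x - 1))
      co <- coef(lm(y ~ z))
      sse(c(co[1], co[2], k), x, y)
    }, numeric(1)))
    expect_lte(sse(fit$params, x, y), grid_best + 1e-6)
  }
})

test_that("parameter recovery is accurate under measurement noise", {
  x <- 1:11
  set.seed(7)
  k_hat <- replicate(120, {
    y <- 250 - 60 * exp(-0.4 * (x - 1)) + rnorm(11, 0, 2)
    unname(fit_recovery_model(x, y, "mono_exp")$params["k"])
  })
  expect_lt(abs(median(k_hat) - 0.4) / 0.4, 0.1)
})

test_that("the mono-exponential fit is scale-equivariant", {
  x <- 1:11
  set.seed(13)
  y <- 250 - 60 * exp(-0.55 * (x - 1)) + rnorm(11, 0, 1)
  f1 <- fit_recovery_model(x, y, "mono_exp")
  f2 <- fit_recovery_model(x, 2 * y, "mono_exp")
  expect_equal(unname(f2$params["pat_inf"]), 2 * unname(f1$params["pat_inf"]),
               tolerance = 1e-4)
  expect_equal(unname(f2$params["delta_pat"]), 2 * unname(f1$params["delta_pat"]),
               tolerance = 1e-4)
  expect_equal(unname(f2$params["k"]), unname(f1$params["k"]), tolerance = 1e-4)
})

test_that("model ranking prefers the generating model and breaks ties by size", {
  x <- 1:11
  ranked <- compare_models(x, 250 - 60 * exp(-0.4 * (x - 1)))
  expect_identical(ranked$model[1], "mono_exp")
  expect_equal(ranked$r_squared[1], 1, tolerance = 1e-9)

  ranked_lin <- compare_models(x, 2 * x + 1)
  expect_identical(ranked_lin$model[1], "linear") # R^2 ties at 1; fewer params win
  expect_identical(ranked_lin$rank, 1:3)
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fit_recovery_model(1:11, 250 - 60 * exp(-0.4 * (0:10)), "mono_exp")
  td <- tidy(fit)
  expect_identical(td$term, c("pat_inf", "delta_pat", "k"))
  gl <- glance(fit)
  expect_identical(gl$model, "mono_exp")
  expect_identical(gl$n_points, 11L)
})

test_that("Recovery Index anchors the extremum at -100 and baseline at 0", {
  v <- c(190, 200, 220, 240, 250)
  ri <- compute_recovery_index(v, baseline_mean = 250, kind = "RI_PAT")
  expect_identical(ri$ri_pct[which.min(v)], -100)
  expect_identical(ri$ri_pct[v == 250], 0)
  mid <- compute_recovery_index(c(190, (190 + 250) / 2, 250), 250, "RI_PAT")
  expect_equal(mid$ri_pct[2], -50, tolerance = 1e-12)

  # SBP flavour: the maximum is the perturbation extremum
  sb <- compute_recovery_index(c(150, 140, 130, 120), 120, "RI_SBP")
  expect_identical(sb$ri_pct[1], -100)
  expect_identical(sb$ri_pct[4], 0)

  na_in <- compute_recovery_index(c(190, NA, 250), 250, "RI_PAT")
  expect_true(is.na(na_in$ri_pct[2]))
  expect_error(compute_recovery_index(rep(5, 4), 5, "RI_PAT"), "degenerate")
})

test_that("the Recovery Index is invariant to affine rescaling of the series", {
  set.seed(3)
  v <- 250 - 60 * exp(-0.5 * (0:10)) + rnorm(11, 0, 2)
  base <- 251
  ri0 <- compute_recovery_index(v, base, "RI_PAT")$ri_pct
  for (i in 1:20) {
    a <- runif(1, 0.1, 5); b <- runif(1, -100, 100)
    ri1 <- compute_recovery_index(a * v + b, a * base + b, "RI_PAT")$ri_pct
    expect_equal(ri1, ri0, tolerance = 1e-9)
  }
})

test_that("SBP oversampling reproduces exact curves and degenerate cases", {
  x4 <- c(1, 4, 7, 10)
  truth <- function(x) -100 * exp(-0.45 * (x - 1))
  out <- oversample_ri_sbp(truth(x4))
  expect_equal(out$ri_pct, truth(1:11), tolerance = 1e-6)
  expect_identical(attr(out, "method"), "mono_exp")

  const <- oversample_ri_sbp(rep(3.5, 4))
  expect_equal(const$ri_pct, rep(3.5, 11), tolerance = 1e-8)

  expect_error(oversample_ri_sbp(c(1, 2, NA, 4)), "4 finite")
})

test_that("oversampling stays in a noise-commensurate band around the truth", {
  x4 <- c(1, 4, 7, 10)
  truth <- function(x) -100 * exp(-0.45 * (x - 1))
  set.seed(19)
  errs <- replicate(100, {
    out <- oversample_ri_sbp(truth(x4) + rnorm(4, 0, 2))
    max(abs(out$ri_pct - truth(1:11)))
  })
  expect_gte(mean(errs < 3 * 2 * 2), 0.9) # within a few noise sd almost always
  expect_lt(median(errs), 3 * 2)
})
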