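# Bounded Levenberg-Marquardt fit of asymptote + amplitude * exp(-k(x-1)).
# Uses the nls.lm residual interface: the nls formula front-end can reject
# well-conditioned near-saturated problems (n = 4, 3 parameters) with a
# spurious singular-gradient error.
monoexp_lm <- function(x, y, k_bounds, start = NULL) {
  start <- start %||% c(pat_inf = y[length(y)],
                        delta_pat = y[1] - y[length(y)], k = 0.5)
  fn <- function(p) y - (p[1] + p[2] * exp(-p[3] * (x - 1)))
  res <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = fn,
                       lower = c(-Inf, -Inf, k_bounds[1]),
                       upper = c(Inf, Inf, k_bounds[2]),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(list(params = start, converged = FALSE))
  }
  list(params = setNames(res$par, names(start)), converged = res$info %in% 1:4)
}

#' Fit a post-exercise PAT recovery model
#'
#' Three candidate models for the median-PAT trajectory over post-exercise
#' cycle indices `x`:
#' * `mono_exp`: `PAT(x) = PAT_inf + dPAT * exp(-k * (x - 1))` -- first-order
#'   autonomic recovery toward the asymptote `PAT_inf`; fitted by bounded
#'   Levenberg-Marquardt least squares with `k` constrained to `[0, 20]` and
#'   initial values `PAT_inf = last y`, `dPAT = first y - last y`, `k = 0.5`.
#' * `linear`: `PAT(x) = a * x + b` (closed form).
#' * `log`: `PAT(x) = a + b * log(x)` (closed form; valid since `x >= 1`).
#'
#' `R^2 = 1 - SS_res / SS_tot` is computed on the fitted points themselves.
#' When `y` is constant (`SS_tot = 0`) the ratio is undefined and `r_squared`
#' is returned as `NA` with the fit still reported.
#'
#' @param x Cycle indices (>= 1).
#' @param y Median PAT values (ms); `NA` pairs are dropped.
#' @param model One of `"mono_exp"`, `"linear"`, `"log"`.
#' @param k_bounds Bounds for the mono-exponential rate.
#' @return A `recovery_fit` object with elements `model`, `params` (named
#'   numeric), `r_squared`, `n_points`, `converged`, `data`, `fitted`.
#'   Supports [tidy()], [glance()], [autoplot()] and `predict()`.
#' @export
#' @examples
#' x <- 1:11
#' y <- 250 - 60 * exp(-0.4 * (x - 1))
#' fit_recovery_model(x, y, "mono_exp")
fit_recovery_model <- function(x, y, model = c("mono_exp", "linear", "log"),
                               k_bounds = c(0, 20)) {
  model <- match.arg(model)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (any(x < 1)) abort("x values must be >= 1")
  need <- if (model == "mono_exp") 4 else 2
  if (length(x) < need) {
    abort(paste0("insufficient points for ", model, " fit: need >= ", need))
  }

  converged <- TRUE
  if (model == "mono_exp") {
    res <- monoexp_lm(x, y, k_bounds)
    params <- res$params
    converged <- res$converged
    yhat <- params[["pat_inf"]] + params[["delta_pat"]] * exp(-params[["k"]] * (x - 1))
  } else if (model == "linear") {
    fit <- lm(y ~ x)
    params <- c(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]))
    yhat <- as.numeric(fitted(fit))
  } else {
    lx <- log(x)
    fit <- lm(y ~ lx)
    params <- c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
    yhat <- as.numeric(fitted(fit))
  }

  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot

  structure(list(model = model, params = params, r_squared = r2,
                 n_points = length(x), converged = isTRUE(converged),
                 data = tibble::tibble(x = x, y = y), fitted = yhat),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("<recovery_fit: ", x$model, ">\n", sep = "")
  print(round(x$params, 4))
  cat("R^2 =", format(x$r_squared, digits = 4),
      " n =", x$n_points,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Evaluate a fitted recovery model
#' @param object A `recovery_fit`.
#' @param newdata Optional list/data frame with an `x` element.
#' @param ... Unused.
#' @export
predict.recovery_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  p <- object$params
  switch(object$model,
    mono_exp = p[["pat_inf"]] + p[["delta_pat"]] * exp(-p[["k"]] * (x - 1)),
    linear = p[["a"]] * x + p[["b"]],
    log = p[["a"]] + p[["b"]] * log(x)
  )
}

#' @method tidy recovery_fit
#' @export
tidy.recovery_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @method glance recovery_fit
#' @export
glance.recovery_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r_squared = x$r_squared,
                 n_points = x$n_points, n_params = length(x$params),
                 converged = x$converged)
}

#' Fit and rank all three recovery models
#'
#' Fits the mono-exponential, linear and logarithmic models to the same
#' series and ranks them by `R^2` (descending); ties are broken in favour of
#' the model with fewer parameters.
#'
#' @inheritParams fit_recovery_model
#' @return A tibble `model, r_squared, n_params, rank` with a `fit`
#'   list-column holding the `recovery_fit` objects, ordered by rank.
#' @export
compare_models <- function(x, y) {
  fits <- purrr::map(c("mono_exp", "linear", "log"),
                     function(m) fit_recovery_model(x, y, m))
  tab <- dplyr::bind_rows(purrr::map(fits, glance))
  tab$fit <- fits
  tab <- tab[order(-tab$r_squared, tab$n_params), ]
  tab$rank <- seq_len(nrow(tab))
  tab[, c("model", "r_squared", "n_params", "rank", "fit")]
}

#' Recovery Index: range-based normalization of a post-exercise series
#'
#' Maps a post-exercise series into a shared normalized space in which the
#' maximal perturbation (the post-exercise minimum for PAT, maximum for SBP)
#' sits at -100% and the baseline-session average at 0%:
#' `RI_PAT(i) = (PAT(i) - PAT_min) / (PAT_baseline - PAT_min) * 100 - 100`,
#' and analogously for SBP with `SBP_max` in place of `PAT_min`. The affine
#' map makes PAT and SBP trends directly comparable per subject regardless of
#' units or direction of response. Missing cycles stay missing.
#'
#' @param values Series over post-exercise cycles (may contain `NA`).
#' @param baseline_mean Baseline-session average of the same measure.
#' @param kind `"RI_PAT"` (extremum = minimum) or `"RI_SBP"` (maximum).
#' @param cycles Cycle indices (default `seq_along(values)`).
#' @return A `ri_series` tibble `cycle, ri_pct` with attributes `kind`,
#'   `baseline_mean` and `extremum`.
#' @export
#' @examples
#' compute_recovery_index(c(190, 200, 220, 240, 250), 250, "RI_PAT")
compute_recovery_index <- function(values, baseline_mean,
                                   kind = c("RI_PAT", "RI_SBP"),
                                   cycles = seq_along(values)) {
  kind <- match.arg(kind)
  if (all(is.na(values))) abort("values are all missing")
  extremum <- if (kind == "RI_PAT") min(values, na.rm = TRUE) else max(values, na.rm = TRUE)
  if (baseline_mean == extremum) {
    abort("degenerate normalization: baseline_mean equals the series extremum")
  }
  ri <- (values - extremum) / (baseline_mean - extremum) * 100 - 100
  out <- tibble::tibble(cycle = cycles, ri_pct = ri)
  class(out) <- c("ri_series", class(out))
  attr(out, "kind") <- kind
  attr(out, "baseline_mean") <- baseline_mean
  attr(out, "extremum") <- extremum
  out
}

#' Oversample a 4-point Recovery Index series to the 11-cycle grid
#'
#' Cuff readings provide Recovery Index values only after cycles 1, 4, 7 and
#' 10. To compare SBP and PAT trends cycle-by-cycle, the mono-exponential
#' recovery shape `A + B * exp(-k * (x - 1))` (rate bounded to `[0, 20]`) is
#' fitted to the four points and evaluated on cycles 1..11. If the bounded
#' fit fails, the series falls back to piecewise-linear interpolation (flat
#' beyond the end points, monotonicity-preserving between them) and is
#' flagged via the `method` attribute.
#'
#' @param values Four finite Recovery Index values.
#' @param x Their cycle positions (default `c(1, 4, 7, 10)`).
#' @param grid Output cycle grid (default `1:11`).
#' @return A tibble `cycle, ri_pct` with attribute
#'   `method = "mono_exp"` or `"linear_interp"`.
#' @export
oversample_ri_sbp <- function(values, x = c(1, 4, 7, 10), grid = 1:11) {
  if (length(values) < 4 || any(!is.finite(values))) {
    abort("oversampling requires 4 finite values")
  }
  fit <- monoexp_lm(x, values, k_bounds = c(0, 20))
  if (fit$converged) {
    p <- fit$params
    out <- p[["pat_inf"]] + p[["delta_pat"]] * exp(-p[["k"]] * (grid - 1))
    method <- "mono_exp"
  } else {
    out <- approx(x, values, xout = grid, rule = 2)$y
    method <- "linear_interp"
  }
  res <- tibble::tibble(cycle = grid, ri_pct = as.numeric(out))
  attr(res, "method") <- method
  res
}
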