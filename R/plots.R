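#' Plot a fitted recovery model over its data
#'
#' @param object A `recovery_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recovery_fit
#' @export
autoplot.recovery_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = 200))
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "post-exercise cycle index", y = "median PAT (ms)",
      title = sprintf("%s fit, R² = %.3f", object$model, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot with bias and limits of agreement
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "pair mean", y = "pair difference",
                  title = sprintf("bias %.2f, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Plot Recovery Index trajectories
#'
#' Spaghetti plot of `RI_PAT` and `RI_SBP` over post-exercise cycles, with
#' the baseline (0%) and maximal-perturbation (-100%) anchors marked.
#'
#' @param ri Long tibble `subject_id, kind, cycle, ri_pct` from
#'   [recovery_indices()].
#' @return A ggplot.
#' @export
plot_recovery_indices <- function(ri) {
  ggplot2::ggplot(ri, ggplot2::aes(x = .data$cycle, y = .data$ri_pct,
                                   group = .data$subject_id)) +
    ggplot2::geom_hline(yintercept = c(0, -100), linetype = "dotted") +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "post-exercise cycle", y = "Recovery Index (%)") +
    ggplot2::theme_minimal()
}

#' Plot a few seconds of one synthesized cycle with its fiducials
#'
#' Diagnostic view of the synchronized channels; ground-truth maximum-slope
#' samples are marked when a truth tibble is supplied.
#'
#' @param cycle One-row cycle tibble.
#' @param truth Optional matching one-row truth tibble.
#' @param t_lim Time window in seconds.
#' @return A ggplot.
#' @export
plot_cycle <- function(cycle, truth = NULL, t_lim = c(0, 4)) {
  fs <- cycle$fs_hz[1]
  n <- length(cycle$ecg[[1]])
  df <- tibble::tibble(
    t = rep((0:(n - 1)) / fs, 2),
    value = c(cycle$ecg[[1]], cycle$ppg[[1]]),
    channel = rep(c("ECG", "PPG"), each = n)
  )
  p <- ggplot2::ggplot(df[df$t >= t_lim[1] & df$t <= t_lim[2], ],
                       ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    md_t <- (truth$true_md_sample[[1]] - 1) / fs
    md_t <- md_t[md_t >= t_lim[1] & md_t <= t_lim[2]]
    p <- p + ggplot2::geom_vline(
      data = tibble::tibble(t = md_t, channel = "PPG"),
      ggplot2::aes(xintercept = .data$t),
      colour = "firebrick", linetype = "dashed", linewidth = 0.3
    )
  }
  p
}
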