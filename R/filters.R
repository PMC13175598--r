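#' Zero-phase filtering with odd-reflection padding
#'
#' Applies an IIR filter forward and backward so the net phase response is
#' zero. The input is first extended at both ends by odd (point-mirrored)
#' reflection, which suppresses the start-up transients that a 0.5 Hz
#' high-pass edge would otherwise smear several seconds into the record; the
#' padding is discarded before returning. Zero-phase application matters here
#' because the ECG and PPG pass through filters with different bands: causal
#' filtering would impose different group delays on the two channels and bias
#' every PAT estimate systematically.
#'
#' @param b,a Numerator / denominator filter coefficients.
#' @param x Numeric signal.
#' @param npad Padding length in samples (clamped to `length(x) - 1`).
#' @return Filtered signal, same length as `x`.
#' @keywords internal
filtfilt_pad <- function(b, a, x, npad = 3000) {
  n <- length(x)
  npad <- min(npad, n - 1)
  if (npad > 0) {
    left <- 2 * x[1] - x[(npad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - npad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(npad + 1):(npad + n)])
}

#' Notch filter for powerline interference
#'
#' Second-order IIR notch (constrained biquad) centred at `f0`, applied
#' zero-phase (forward-backward), so the effective magnitude response is the
#' squared single-pass response. DC and the passband are left untouched.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param f0 Notch frequency in Hz (default 50, European mains).
#' @param quality_q Quality factor; the -3 dB bandwidth is `f0 / quality_q`.
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' t <- (0:9999) / 1000
#' x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 50 * t)
#' y <- notch_filter(x, fs = 1000)
notch_filter <- function(x, fs, f0 = 50, quality_q = 30) {
  if (f0 <= 0 || f0 >= fs / 2) {
    abort("f0 must lie strictly between 0 and the Nyquist frequency")
  }
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * quality_q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  filtfilt_pad(b, a, x, npad = round(6 * fs))
}

#' Butterworth band-pass filter, zero-phase
#'
#' Third-order Butterworth band-pass by default (0.5--40 Hz isolates QRS
#' complexes on the ECG; 0.5--10 Hz keeps the pulsatile PPG band while
#' suppressing motion noise), applied forward-backward.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz, `0 < low < high < fs / 2`.
#' @param order Butterworth order of the single-pass prototype.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low, high, order = 3) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("invalid band: need 0 < low < high < fs/2")
  }
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filtfilt_pad(flt$b, flt$a, x, npad = round(6 * fs))
}
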