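# Deterministic fixtures and independent oracles shared across tests.

# Profile with all parameters pinned (noise terms zero).
quiet_profile <- function(...) {
  generate_profile(degenerate_ranges(...))
}

# Population ranges with every additive-noise source zeroed but physiology
# still drawn at random (PAT jitter and drift are part of the ground truth,
# not measurement noise, and stay at their defaults unless overridden).
noise_free_ranges <- function(...) {
  r <- population_ranges()
  for (f in c("ecg_noise_sd", "ppg_noise_sd", "powerline_amplitude")) {
    r$low[r$field == f] <- r$high[r$field == f] <- 0
  }
  over <- list(...)
  for (f in names(over)) {
    r$low[r$field == f] <- r$high[r$field == f] <- over[[f]]
  }
  r
}

# Single raised-cosine upstroke (rise steps, odd) + cosine decay, amplitude 1,
# starting at sample `onset` in a zero vector of length n.
raised_cosine_pulse <- function(n, onset, rise = 151, fall = 300) {
  x <- numeric(n)
  up_idx <- onset + 0:rise
  x[up_idx] <- 0.5 * (1 - cos(pi * (0:rise) / rise))
  dn_idx <- onset + rise + 1:fall
  dn_idx <- dn_idx[dn_idx <= n]
  x[dn_idx] <- 0.5 * (1 + cos(pi * seq_along(dn_idx) / fall))
  x
}

# Gaussian "R wave" centred on sample `center`.
gauss_wave <- function(n, center, amp = 1, sd_s = 0.006, fs = 1000) {
  t <- ((1:n) - center) / fs
  amp * exp(-0.5 * (t / sd_s)^2)
}

# Independent single-pass magnitude response |H(f)| of an IIR filter (b, a).
iir_mag <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(b) - 1))
  num <- sum(b * z)
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(a) - 1))
  den <- sum(a * z)
  Mod(num / den)
}

# Amplitude of a sinusoid at frequency f estimated away from the edges.
mid_amplitude <- function(x, fs, margin_s = 2) {
  seg <- x[(margin_s * fs):(length(x) - margin_s * fs)]
  sqrt(2) * sqrt(mean(seg^2))
}

# Amplitude of the component at frequency f by coherent demodulation of the
# central segment (immune to broadband edge transients, unlike an RMS).
demod_amplitude <- function(x, fs, f, margin_s = 2) {
  seg <- x[(margin_s * fs):(length(x) - margin_s * fs)]
  t <- seq_along(seg) / fs
  2 * Mod(mean(seg * exp(-2i * pi * f * t)))
}

# Power (|FFT|^2) of a signal at an exact DFT frequency bin.
power_at <- function(x, fs, f) {
  n <- length(x)
  bin <- round(f * n / fs) + 1
  Mod(fft(x)[bin])^2
}
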