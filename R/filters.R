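#' Preprocessing filter specification
#'
#' The standard surface-EMG front end: a 10th-order Butterworth band-pass
#' (20-400 Hz) to reject motion artifact and out-of-band noise, followed by a
#' 60 Hz notch for mains interference. Filtering is causal (forward-only)
#' everywhere so that offline preprocessing matches what an online decoder
#' can compute.
#'
#' @param band_low,band_high Band edges in Hz.
#' @param order Band-pass transfer-function order (even; default 10, i.e. an
#'   order-5 low-pass prototype).
#' @param notch_freq Notch center frequency in Hz (default 60).
#' @param notch_q Notch quality factor (default 30: about a 2 Hz -3 dB width
#'   at 60 Hz, sparing the rest of the band).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(band_low = 20, band_high = 400, order = 10,
                        notch_freq = 60, notch_q = 30) {
  if (!(band_low > 0 && band_low < band_high)) {
    abort("Require 0 < band_low < band_high.")
  }
  if (order < 2 || order %% 2 != 0) abort("`order` must be a positive even integer.")
  structure(
    list(
      band_low = band_low, band_high = band_high, order = order,
      notch_freq = notch_freq, notch_q = notch_q
    ),
    class = "filter_spec"
  )
}

# ---- digital filter design ---------------------------------------------
# Butterworth band-pass designed in zero-pole-gain form and realized as
# second-order sections: the order-(order/2) analog low-pass prototype is
# band-transformed, bilinearly mapped with edge prewarping, and conjugate
# pole pairs become biquads. Direct transfer-function coefficients are
# numerically unstable at this order, SOS are not.

butter_bandpass_sos <- function(low_hz, high_hz, fs, order = 10) {
  n <- order / 2 # prototype order
  # analog prototype poles on the unit circle
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # prewarped band edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each prototype pole yields two analog poles
  a <- p_lp * bw / 2
  disc <- sqrt(a^2 - w0^2)
  p_bp <- c(a + disc, a - disc)
  # bilinear transform
  fs2 <- 2 * fs
  p_z <- (1 + p_bp / fs2) / (1 - p_bp / fs2)
  # n zeros at z = 1 (from s = 0) and n at z = -1 (from s = Inf).
  # Pair poles into biquads: complex poles with their conjugates, real poles
  # with each other; every section carries one zero pair (1, -1).
  is_real <- abs(Im(p_z)) < 1e-10
  cplx <- p_z[!is_real & Im(p_z) > 0]
  reals <- sort(Re(p_z[is_real]))
  sections <- list()
  for (p in cplx) {
    sections[[length(sections) + 1L]] <- c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)
  }
  while (length(reals) >= 2) {
    p1 <- reals[1]; p2 <- reals[length(reals)] # pair extremes for balance
    reals <- reals[c(-1, -length(reals))]
    sections[[length(sections) + 1L]] <- c(1, 0, -1, 1, -(p1 + p2), p1 * p2)
  }
  sos <- do.call(rbind, sections)
  sos <- sos[order(-sos[, 6]), , drop = FALSE]
  # normalize to unit gain at the (warped) center frequency
  fc <- w0 / (2 * pi) # analog center, rad/s -> Hz
  zc <- exp(2i * pi * (atan(w0 / fs2) / pi) ) # digital center via bilinear map
  g <- Mod(sos_response(sos, Arg(zc) / (2 * pi) * fs, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  sos
}

# RBJ-cookbook notch biquad.
notch_sos <- function(freq_hz, q, fs) {
  w0 <- 2 * pi * freq_hz / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  matrix(c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
           1, -2 * cos(w0) / a0, (1 - alpha) / a0), nrow = 1)
}

design_sos <- function(spec, fs) {
  if (fs <= 2 * spec$band_high) {
    abort(sprintf(
      "Sampling rate %g Hz too low for band edge %g Hz (need > %g Hz).",
      fs, spec$band_high, 2 * spec$band_high
    ))
  }
  rbind(
    butter_bandpass_sos(spec$band_low, spec$band_high, fs, spec$order),
    notch_sos(spec$notch_freq, spec$notch_q, fs)
  )
}

#' Frequency response of a second-order-section cascade
#'
#' @param sos Sections matrix (rows `b0 b1 b2 a0 a1 a2`).
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @param fs Sampling rate, Hz.
#' @return Complex response values.
#' @export
sos_response <- function(sos, freq_hz, fs) {
  z <- exp(-2i * pi * freq_hz / fs)
  h <- rep(1 + 0i, length(z))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    h <- h * num / den
  }
  h
}

# Stateful causal SOS filtering of a single channel.
sos_filter <- function(sos, x, zi = NULL) {
  if (is.null(zi)) zi <- matrix(0, nrow(sos), 2)
  sosfilt_cpp(sos, x, zi)
}

#' Band-pass and notch filter a recording
#'
#' Applies the causal band-pass + notch cascade per channel. Shape and
#' sampling rate are preserved; ground truth and schedule travel with the
#' recording.
#'
#' @param recording An [emg_recording][simulate_emg].
#' @param spec A [filter_spec()].
#' @return The filtered `emg_recording`.
#' @export
bandpass_notch <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "emg_recording"))
  if (!all(is.finite(recording$samples))) {
    abort("Recording contains non-finite samples.")
  }
  sos <- design_sos(spec, recording$sampling_rate)
  out <- recording
  for (c in seq_len(nrow(recording$samples))) {
    out$samples[c, ] <- sos_filter(sos, recording$samples[c, ])$y
  }
  out$filtered <- TRUE
  out
}
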