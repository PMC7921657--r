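# FIR filtering for oscillatory-potential isolation and trace smoothing.
#
# Filters are linear-phase windowed-sinc designs (Hamming window) applied
# forward and reverse, so the net phase is zero and component peak times are
# not shifted. The OP band-pass follows the conventional 70-300 Hz passband.

# Windowed-sinc low-pass prototype, normalized cutoff fc in cycles/sample.
fir_sinc_lowpass <- function(fc, n_taps) {
  m <- (n_taps - 1) / 2
  k <- seq(0, n_taps - 1) - m
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n_taps - 1) / (n_taps - 1))
  h <- h * w
  h / sum(h)          # unity DC gain before band transformation
}

#' Design a zero-phase FIR band-pass filter for oscillatory potentials
#'
#' Windowed-sinc (Hamming) linear-phase band-pass with band edges at
#' `pass_lo` and `pass_hi` (conventionally 70 and 300 Hz). The design is
#' intended for forward-and-reverse application ([apply_fir()]), which
#' cancels the group delay so peak times are preserved. With the default
#' order, the single-pass magnitude response exceeds 0.95 across the interior
#' of the passband and is below 0.1 (-20 dB) at half the lower edge and at
#' twice the upper edge.
#'
#' @param sampling_rate Sampling rate in Hz; must exceed `2 * pass_hi`.
#' @param pass_lo,pass_hi Passband edges in Hz, `0 < pass_lo < pass_hi`.
#' @param n_taps Odd filter length; default scales with the sampling rate to
#'   keep the transition bands (about 16 Hz wide) rate-independent.
#' @return A `filter_spec` object with elements `coefficients`, `pass_lo`,
#'   `pass_hi`, `n_taps`, `sampling_rate`, `design`, `phase_mode`.
#' @export
design_op_filter <- function(sampling_rate, pass_lo = 70, pass_hi = 300,
                             n_taps = NULL) {
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    abort_invalid("sampling_rate must be positive")
  }
  if (!is_scalar_number(pass_lo) || !is_scalar_number(pass_hi) ||
      pass_lo <= 0 || pass_hi <= pass_lo) {
    abort_invalid("require 0 < pass_lo < pass_hi")
  }
  if (sampling_rate <= 2 * pass_hi) {
    abort_invalid(sprintf(
      "sampling_rate %g Hz violates Nyquist for pass_hi %g Hz",
      sampling_rate, pass_hi))
  }
  if (is.null(n_taps)) {
    # Hamming transition width ~= 3.3 * fs / N; aim for ~16 Hz transitions.
    n_taps <- ceiling(3.3 * sampling_rate / 16)
    if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  }
  if (n_taps %% 2 == 0 || n_taps < 7) {
    abort_invalid("n_taps must be odd and >= 7")
  }
  lo <- fir_sinc_lowpass(pass_lo / sampling_rate, n_taps)
  hi <- fir_sinc_lowpass(pass_hi / sampling_rate, n_taps)
  h <- hi - lo        # band-pass = difference of low-passes
  structure(list(coefficients = h, pass_lo = pass_lo, pass_hi = pass_hi,
                 n_taps = as.integer(n_taps), sampling_rate = sampling_rate,
                 design = "windowed-sinc (Hamming)",
                 phase_mode = "zero_phase"),
            class = "filter_spec")
}

#' Design a zero-phase FIR low-pass filter
#'
#' Used to smooth traces before slow-component (a-wave, b-wave, PhNR) cursor
#' measurements; the default 60 Hz cutoff removes the oscillatory potentials
#' and most recording noise while leaving the slow components essentially
#' untouched.
#'
#' @inheritParams design_op_filter
#' @param cutoff Cutoff frequency in Hz.
#' @return A `filter_spec` object.
#' @export
design_lowpass_filter <- function(sampling_rate, cutoff = 60, n_taps = NULL) {
  if (!is_scalar_number(cutoff) || cutoff <= 0 ||
      cutoff >= sampling_rate / 2) {
    abort_invalid("cutoff must lie in (0, sampling_rate / 2)")
  }
  if (is.null(n_taps)) {
    n_taps <- ceiling(3.3 * sampling_rate / 40)
    if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  }
  h <- fir_sinc_lowpass(cutoff / sampling_rate, n_taps)
  structure(list(coefficients = h, pass_lo = 0, pass_hi = cutoff,
                 n_taps = as.integer(n_taps), sampling_rate = sampling_rate,
                 design = "windowed-sinc (Hamming)",
                 phase_mode = "zero_phase"),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s, %d taps, [%g, %g] Hz at %g Hz, %s\n",
              x$design, x$n_taps, x$pass_lo, x$pass_hi, x$sampling_rate,
              x$phase_mode))
  invisible(x)
}

#' Evaluate the single-pass magnitude response of an FIR filter
#'
#' @param filter A `filter_spec`.
#' @param freq Frequencies in Hz.
#' @return Magnitude |H(f)| of one forward pass (the forward-reverse
#'   application used by [apply_fir()] has magnitude `|H|^2` and zero phase).
#' @export
fir_response <- function(filter, freq) {
  h <- filter$coefficients
  n <- seq_along(h) - 1
  vapply(freq, function(f) {
    om <- 2 * pi * f / filter$sampling_rate
    Mod(sum(h * exp(-1i * om * n)))
  }, numeric(1))
}

# Single forward convolution with reflected-edge padding ("same" alignment,
# causal: output delayed by (n_taps-1)/2 samples).
fir_conv_padded <- function(x, h) {
  n <- length(x); m <- length(h); half <- (m - 1) / 2
  # odd (anti-symmetric) reflection reduces edge transients for trends
  left <- 2 * x[1] - x[seq(half + 1, 2, by = -1)]
  right <- 2 * x[n] - x[seq(n - 1, n - half, by = -1)]
  xp <- c(left, x, right)
  np <- length(xp)
  nfft <- stats::nextn(np + m - 1, 2)
  X <- stats::fft(c(xp, numeric(nfft - np)))
  H <- stats::fft(c(h, numeric(nfft - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[seq(2 * half + 1, length.out = n)]
}

# Matrix analogue of fir_conv_padded: filters every column of `mat` in one
# FFT batch (used by the cohort-scale extraction and noise generation).
batch_fir_conv <- function(mat, h) {
  n <- nrow(mat); m <- length(h); half <- (m - 1) / 2
  top <- 2 * matrix(mat[1, ], half, ncol(mat), byrow = TRUE) -
    mat[seq(half + 1, 2), , drop = FALSE]
  bot <- 2 * matrix(mat[n, ], half, ncol(mat), byrow = TRUE) -
    mat[seq(n - 1, n - half), , drop = FALSE]
  xp <- rbind(top, mat, bot)
  np <- nrow(xp)
  nfft <- stats::nextn(np + m - 1, 2)
  pad <- matrix(0, nfft - np, ncol(mat))
  X <- stats::mvfft(rbind(xp, pad))
  H <- stats::fft(c(h, numeric(nfft - m)))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  y[seq(2 * half + 1, length.out = n), , drop = FALSE]
}

batch_apply_fir <- function(mat, filter) {
  h <- filter$coefficients
  y <- batch_fir_conv(mat, h)
  flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  flip(batch_fir_conv(flip(y), h))
}

#' Apply an FIR filter forward and reverse (zero phase)
#'
#' The trace is padded by odd reflection at both ends, convolved with the
#' filter, reversed and convolved again, so the net transfer function is
#' `|H(f)|^2` with zero phase: waveform extrema keep their positions.
#'
#' @param x Numeric trace (voltage samples).
#' @param filter A `filter_spec` designed at the trace's sampling rate.
#' @return Filtered trace, same length as `x`.
#' @export
apply_fir <- function(x, filter) {
  h <- filter$coefficients
  if (length(x) < (length(h) - 1) / 2 + 2) {
    abort_invalid("trace too short for the requested filter order")
  }
  as.numeric(batch_apply_fir(matrix(x, ncol = 1), filter))
}
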