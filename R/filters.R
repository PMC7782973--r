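## Windowed-sinc FIR filtering and analytic-signal helpers. All EEG/EOG/
## motion filtering in the package goes through fir_filter() (Kaiser window
## by default, Hamming available for the 8-12 Hz alpha band-pass); the
## saccade detector's 20-90 Hz band-pass is the one Butterworth exception.

#' Design a windowed-sinc FIR filter
#'
#' Builds a linear-phase type-I FIR filter by windowing the ideal band
#' impulse response. With `window = "kaiser"` the order and beta follow the
#' standard Kaiser estimates for the requested stopband attenuation.
#'
#' @param fs Sampling rate in Hz.
#' @param low_cut High-pass edge in Hz, or `NULL` for no high-pass.
#' @param high_cut Low-pass edge in Hz, or `NULL` for no low-pass.
#' @param trans_width Transition width in Hz. Default: the smaller of 2 Hz
#'   and the lowest cutoff (so a 1 Hz high-pass never reaches below DC).
#' @param atten_db Target stopband attenuation in dB (Kaiser design).
#' @param window `"kaiser"` or `"hamming"`.
#' @return Numeric vector of filter taps (odd length, symmetric).
#' @export
fir_design <- function(fs, low_cut = NULL, high_cut = NULL,
                       trans_width = NULL, atten_db = 60,
                       window = c("kaiser", "hamming")) {
  window <- match.arg(window)
  nyq <- fs / 2
  for (cut in c(low_cut, high_cut)) {
    if (cut <= 0 || cut >= nyq) {
      stop("filter cutoff ", cut, " Hz outside (0, ", nyq, ") Hz", call. = FALSE)
    }
  }
  if (is.null(trans_width)) {
    trans_width <- min(2, low_cut %||% Inf, high_cut %||% Inf)
  }
  dw <- 2 * pi * trans_width / fs
  if (window == "kaiser") {
    beta <- if (atten_db > 50) {
      0.1102 * (atten_db - 8.7)
    } else if (atten_db >= 21) {
      0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
    } else 0
    m <- ceiling((atten_db - 7.95) / (2.285 * dw))
  } else {
    beta <- 0
    m <- ceiling(6.6 * pi / dw)  # Hamming: ~53 dB, 6.6/tw rule
  }
  if (m %% 2 == 1) m <- m + 1  # even order -> odd tap count
  n <- m + 1
  k <- seq_len(n) - 1 - m / 2
  sinc <- function(fc) {
    h <- sin(2 * pi * fc / fs * k) / (pi * k)
    h[k == 0] <- 2 * fc / fs
    h
  }
  h <- if (is.null(low_cut) && is.null(high_cut)) {
    as.numeric(k == 0)
  } else if (is.null(low_cut)) {
    sinc(high_cut)                      # low-pass
  } else if (is.null(high_cut)) {
    as.numeric(k == 0) - sinc(low_cut)  # high-pass = delta - low-pass
  } else {
    sinc(high_cut) - sinc(low_cut)      # band-pass
  }
  w <- if (window == "kaiser") {
    besselI(beta * sqrt(pmax(0, 1 - (2 * k / m)^2)), 0) / besselI(beta, 0)
  } else {
    0.54 + 0.46 * cos(2 * pi * k / m)
  }
  h <- h * w
  ## normalize gain to 1 at a reference passband frequency
  f_ref <- if (is.null(low_cut) && is.null(high_cut)) {
    0
  } else if (is.null(low_cut)) {
    0
  } else if (is.null(high_cut)) {
    nyq
  } else {
    (low_cut + high_cut) / 2
  }
  gain <- abs(sum(h * exp(-2i * pi * f_ref / fs * seq_along(h))))
  h / gain
}

## Apply a symmetric FIR zero-phase: odd-reflection padding at both ends,
## FFT convolution, group-delay compensation. x may be a vector or a
## samples-by-channels matrix.
.fir_apply <- function(x, h) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  d <- (length(h) - 1) / 2
  p <- min(d, n - 1)
  refl_top <- 2 * matrix(xm[1, ], p, ncol(xm), byrow = TRUE) -
    xm[p:1 + 1, , drop = FALSE]
  refl_bot <- 2 * matrix(xm[n, ], p, ncol(xm), byrow = TRUE) -
    xm[n - (1:p), , drop = FALSE]
  xp <- rbind(refl_top, xm, refl_bot)
  np <- nrow(xp)
  nfft <- stats::nextn(np + length(h) - 1, 2)
  hf <- fft(c(h, numeric(nfft - length(h))))
  xf <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  y <- Re(stats::mvfft(xf * hf, inverse = TRUE)) / nfft
  out <- y[p + d + seq_len(n), , drop = FALSE]
  if (vec) drop(out) else {
    dimnames(out) <- dimnames(xm)
    out
  }
}

#' Zero-phase windowed-sinc FIR filtering
#'
#' Filters a signal (vector, or samples-by-channels matrix) with a
#' linear-phase windowed-sinc FIR filter, applied on symmetrically padded
#' data with group-delay compensation so the net response is zero-phase.
#' `low_cut`/`high_cut` both `NULL` returns the input unchanged.
#'
#' @inheritParams fir_design
#' @param x Numeric vector or samples-by-channels matrix.
#' @return Filtered data, same shape as `x`.
#' @export
fir_filter <- function(x, fs, low_cut = NULL, high_cut = NULL,
                       trans_width = NULL, atten_db = 60,
                       window = c("kaiser", "hamming")) {
  if (is.null(low_cut) && is.null(high_cut)) return(x)
  h <- fir_design(fs, low_cut, high_cut, trans_width, atten_db,
                  match.arg(window))
  .fir_apply(x, h)
}

#' Analytic signal via the FFT
#'
#' @param x Real numeric vector.
#' @return Complex vector; `Mod()` of it is the amplitude envelope and
#'   `Arg()` the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) return(as.complex(x))
  xf <- fft(x)
  hmult <- numeric(n)
  if (n %% 2 == 0) {
    hmult[c(1, n / 2 + 1)] <- 1
    hmult[2:(n / 2)] <- 2
  } else {
    hmult[1] <- 1
    hmult[2:((n + 1) / 2)] <- 2
  }
  fft(xf * hmult, inverse = TRUE) / n
}

#' Amplitude envelope (Hilbert magnitude)
#'
#' @inheritParams analytic_signal
#' @return Nonnegative numeric vector, `Mod(analytic_signal(x))`.
#' @export
hilbert_envelope <- function(x) Mod(analytic_signal(x))

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Welch power spectral density
#'
#' Averaged Hamming-windowed periodograms over 50%-overlapping segments.
#' With the default 1-s window the frequency grid has 1 Hz resolution and
#' each segment coincides with one epoch of [epoch_alpha_power()], which is
#' what makes session-mean epoch power and Welch power agree exactly.
#' One-sided density scaling: for white noise of variance s^2 the powers
#' sum (times the bin width) to s^2.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param win_sec Segment length in seconds (default 1).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A tibble with columns `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, win_sec = 1, overlap = 0.5) {
  nwin <- round(win_sec * fs)
  if (length(x) < nwin) stop("signal shorter than one Welch window", call. = FALSE)
  p <- .segment_psd_matrix(x, fs, nwin, overlap)
  tibble::tibble(freq = attr(p, "freq"), power = rowMeans(p))
}

## Periodogram of every segment: matrix (freq x segment) with "freq" attr.
## Shared by welch_psd() and the 1-s epoch grid.
.segment_psd_matrix <- function(x, fs, nwin, overlap = 0.5) {
  step <- round(nwin * (1 - overlap))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- hamming_window(nwin)
  scale <- 1 / (fs * sum(w^2))
  nf <- nwin %/% 2 + 1
  seg <- vapply(starts, function(s) x[s:(s + nwin - 1)] * w, numeric(nwin))
  xf <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
  p <- Mod(xf)^2 * scale
  one_sided <- rep(2, nf)
  one_sided[1] <- 1
  if (nwin %% 2 == 0) one_sided[nf] <- 1
  p <- p * one_sided
  attr(p, "freq") <- (seq_len(nf) - 1) * fs / nwin
  attr(p, "start_sample") <- starts
  p
}
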