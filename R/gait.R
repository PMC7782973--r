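## Stride-cycle extraction from ankle velocity, 9-phase binning of any
## co-registered series, and the electrode-impedance-by-phase control.

#' Elementwise speed magnitude
#'
#' `speed = sqrt(vx^2 + vy^2 + vz^2)`.
#'
#' @param vx,vy,vz Equal-length velocity components (m/s).
#' @return Speed vector (m/s).
#' @export
speed_magnitude <- function(vx, vy, vz) {
  if (length(vx) != length(vy) || length(vx) != length(vz)) {
    stop("velocity component lengths differ", call. = FALSE)
  }
  sqrt(vx^2 + vy^2 + vz^2)
}

## Speed magnitude of one named sensor from a session motion matrix.
.sensor_speed <- function(motion, sensor) {
  speed_magnitude(motion[, paste0(sensor, "_x")],
                  motion[, paste0(sensor, "_y")],
                  motion[, paste0(sensor, "_z")])
}

#' Combined, 2 Hz low-passed ankle speed
#'
#' The speed-magnitude series of both ankles are summed and low-pass
#' filtered at 2 Hz (windowed-sinc, zero-phase).
#'
#' @param motion Samples x 9 motion matrix with `left_*`, `right_*`,
#'   `back_*` columns, or a `session_recording`.
#' @param fs Motion sampling rate.
#' @return Filtered combined speed vector (m/s).
#' @export
combined_ankle_speed <- function(motion, fs = MOTION_FS) {
  if (inherits(motion, "session_recording")) {
    fs <- motion$fs_motion
    motion <- motion$motion
  }
  need <- as.vector(outer(c("left", "right"), c("x", "y", "z"), paste,
                          sep = "_"))
  if (!all(need %in% colnames(motion))) {
    stop("ankle sensor stream missing: ",
         paste(setdiff(need, colnames(motion)), collapse = ", "),
         call. = FALSE)
  }
  combined <- .sensor_speed(motion, "left") + .sensor_speed(motion, "right")
  fir_filter(combined, fs, high_cut = 2)
}

#' Segment stride cycles from the filtered combined speed
#'
#' Local speed minima mark stride starts/ends and the intervening local
#' maximum anchors the speed profile. Extrema are located from the
#' instantaneous phase of the mean-removed analytic signal (wrap crossings
#' give minima, upward zero crossings maxima) and refined to the nearest
#' true local extremum of the filtered series within a quarter stride.
#' First/last incomplete strides are discarded; strides with outlier
#' durations are flagged by the MAD-median rule (`excluded` column) but
#' kept in the table. Left and right strides are not distinguished.
#'
#' @param filtered_speed Output of [combined_ankle_speed()].
#' @param fs Motion sampling rate.
#' @return A `stride_set` tibble: `stride`, `start`, `max_idx`, `end`
#'   (sample indices), `start_s`, `max_s`, `end_s`, `duration_s`,
#'   `excluded`.
#' @export
segment_strides <- function(filtered_speed, fs = MOTION_FS) {
  x <- filtered_speed - mean(filtered_speed)
  if (sd(x) < 1e-12) stop("no gait detected", call. = FALSE)
  ph <- Arg(analytic_signal(x))
  ## -pi wrap crossings = minima candidates; upward 0 crossings = maxima
  dph <- diff(ph)
  minima <- which(dph < -pi) + 1L
  maxima <- which(ph[-length(ph)] < 0 & ph[-1] >= 0 & abs(dph) < pi) + 1L
  if (length(minima) < 3) stop("no gait detected", call. = FALSE)
  period <- stats::median(diff(minima))
  refine <- function(idx, what) {
    w <- max(2L, round(period / 4))
    vapply(idx, function(i) {
      lo <- max(1L, i - w)
      hi <- min(length(x), i + w)
      seg <- x[lo:hi]
      as.integer(lo - 1L + if (what == "min") which.min(seg) else
        which.max(seg))
    }, integer(1))
  }
  minima <- unique(refine(minima, "min"))
  strides <- tibble::tibble(
    start = minima[-length(minima)],
    end = minima[-1]
  )
  strides$max_idx <- vapply(seq_len(nrow(strides)), function(i) {
    seg <- x[strides$start[i]:strides$end[i]]
    strides$start[i] - 1L + which.max(seg)
  }, integer(1))
  strides$duration_s <- (strides$end - strides$start) / fs
  strides <- strides[strides$duration_s > 0, , drop = FALSE]
  verdict <- mad_median_outliers(strides$duration_s)
  tibble::tibble(
    stride = seq_len(nrow(strides)),
    start = strides$start, max_idx = strides$max_idx, end = strides$end,
    start_s = (strides$start - 1) / fs,
    max_s = (strides$max_idx - 1) / fs,
    end_s = (strides$end - 1) / fs,
    duration_s = strides$duration_s,
    excluded = verdict$outlier
  )
}

#' Bin a co-registered series into the nine walking phases
#'
#' Every retained stride's `[start, end)` interval is split into 9
#' equal-duration bins. With `reducer = "mean"` the samples falling in a
#' bin are averaged, then averaged across strides; with
#' `reducer = "event_rate"` the `series` argument is a vector of event
#' onset times (s) and each bin's value is the event count divided by the
#' total time spent in that bin (events/s). Bin edges are converted to the
#' series' own timebase directly (half-open bins; a boundary event goes to
#' the earlier bin).
#'
#' @param series Numeric signal vector, or event onset times for
#'   `reducer = "event_rate"`.
#' @param series_fs Sampling rate of `series` (ignored for event rates).
#' @param strides A `stride_set` from [segment_strides()].
#' @param reducer `"mean"` or `"event_rate"`.
#' @param exclude_outlier_value With `reducer = "mean"`: additionally drop
#'   strides whose stride-mean value is a MAD-median outlier (the rule
#'   applied to e.g. stride-wise alpha power).
#' @return A `phase_profile` tibble: `phase` (1-9), `value`, `n_strides`.
#' @export
phase_bin_series <- function(series, series_fs, strides,
                             reducer = c("mean", "event_rate"),
                             exclude_outlier_value = FALSE) {
  reducer <- match.arg(reducer)
  st <- strides[!strides$excluded, , drop = FALSE]
  if (nrow(st) == 0) stop("no retained strides", call. = FALSE)
  edges <- lapply(seq_len(nrow(st)), function(i) {
    seq(st$start_s[i], st$end_s[i], length.out = 10)
  })
  if (reducer == "event_rate") {
    counts <- numeric(9)
    tot_time <- numeric(9)
    for (e in edges) {
      counts <- counts + vapply(1:9, function(b) {
        sum(series >= e[b] & series < e[b + 1])
      }, 0)
      tot_time <- tot_time + diff(e)
    }
    return(tibble::tibble(phase = 1:9, value = counts / tot_time,
                          n_strides = nrow(st)))
  }
  per_stride <- .stride_bin_matrix(series, series_fs, edges)
  keep <- rep(TRUE, ncol(per_stride))
  if (exclude_outlier_value && ncol(per_stride) >= 3) {
    keep <- !mad_median_outliers(colMeans(per_stride, na.rm = TRUE))$outlier
  }
  tibble::tibble(phase = 1:9,
                 value = rowMeans(per_stride[, keep, drop = FALSE],
                                  na.rm = TRUE),
                 n_strides = sum(keep))
}

## 9 x n_strides matrix of per-stride bin means.
.stride_bin_matrix <- function(series, series_fs, edges) {
  vapply(edges, function(e) {
    vapply(1:9, function(b) {
      i0 <- floor(e[b] * series_fs) + 1
      i1 <- ceiling(e[b + 1] * series_fs)
      i1 <- min(i1, length(series))
      if (i1 < i0) return(NA_real_)
      mean(series[i0:i1], na.rm = TRUE)
    }, 0)
  }, numeric(9))
}

#' Phase profile with one stride per bin (round-robin)
#'
#' Like [phase_bin_series()] with `reducer = "mean"`, but each retained
#' stride contributes to a single phase bin, assigned round-robin. The
#' nine estimates then come from disjoint strides, so for a signal whose
#' estimation window couples neighbouring bins (e.g. the 200-ms
#' impedance window) the bin values are statistically independent and a
#' permutation test over bins is exact under the null.
#'
#' @inheritParams phase_bin_series
#' @return A `phase_profile` tibble (`phase`, `value`, `n_strides`).
#' @export
phase_bin_series_independent <- function(series, series_fs, strides) {
  st <- strides[!strides$excluded, , drop = FALSE]
  if (nrow(st) < 9) stop("need at least 9 retained strides", call. = FALSE)
  edges <- lapply(seq_len(nrow(st)), function(i) {
    seq(st$start_s[i], st$end_s[i], length.out = 10)
  })
  m <- .stride_bin_matrix(series, series_fs, edges)
  grp <- rep_len(1:9, ncol(m))
  vals <- vapply(1:9, function(b) {
    mean(m[b, grp == b], na.rm = TRUE)
  }, 0)
  tibble::tibble(phase = 1:9, value = vals,
                 n_strides = as.integer(table(grp)))
}

#' Continuous electrode impedance from the 125 Hz carrier
#'
#' Complex demodulation at 125 Hz with a sliding 200 ms Hamming window:
#' per sample, the windowed signal power at 125 Hz, mapped to kOhm by a
#' linear calibration constant (the generator's convention `power = kOhm`
#' at `calibration = 1`). Measurement noise can push values slightly
#' below 0.
#'
#' @param x Raw channel vector (uV).
#' @param fs Sampling rate in Hz (must exceed 250 Hz).
#' @param carrier_hz Carrier frequency (default 125).
#' @param window_s Window length in seconds (default 0.2).
#' @param calibration kOhm per unit carrier power.
#' @return Impedance trace in kOhm, same length as `x`.
#' @export
impedance_trace <- function(x, fs = EEG_FS, carrier_hz = 125,
                            window_s = 0.2, calibration = 1) {
  if (fs < 2 * carrier_hz) {
    stop("sampling rate too low for a ", carrier_hz, " Hz carrier",
         call. = FALSE)
  }
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  z <- x * exp(-2i * pi * carrier_hz * t)
  w <- hamming_window(round(window_s * fs))
  w <- w / sum(w)
  zr <- .fir_apply(Re(z), w)
  zi <- .fir_apply(Im(z), w)
  ## tone amplitude a -> |demod| = a/2 -> power a^2/2 = 2*|demod|^2
  out <- 2 * (zr^2 + zi^2) * calibration
  ## the sliding estimate is undefined inside the first/last half window
  half <- ceiling(length(w) / 2)
  out[c(seq_len(half), n - seq_len(half) + 1)] <- NA_real_
  out
}

#' Session-mean impedance over the occipital/parietal control set
#'
#' @param session A `session_recording` carrying the 125 Hz carrier.
#' @param ... Passed to [impedance_trace()].
#' @return Impedance trace (kOhm) averaged over O1, O2, P7, P8.
#' @export
mean_impedance_trace <- function(session, ...) {
  cm <- channel_map()
  tr <- vapply(cm$impedance,
               function(ch) impedance_trace(session$eeg[, ch],
                                            session$fs_eeg, ...),
               numeric(nrow(session$eeg)))
  rowMeans(tr)
}

#' Session-mean walking speed from the back sensor
#'
#' @param motion Motion matrix or `session_recording`.
#' @return Mean speed magnitude of the back sensor (m/s).
#' @export
mean_back_speed <- function(motion) {
  if (inherits(motion, "session_recording")) motion <- motion$motion
  mean(.sensor_speed(motion, "back"))
}
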