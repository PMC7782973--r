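## Occipital alpha extraction: per-subject PCA to 10 dimensions, Infomax
## ICA over the six concatenated sessions, rule-based alpha-component
## selection, per-session spectra and epoch powers, back-projected
## topography, and the 8-12 Hz Hilbert power envelope.

ALPHA_BAND <- c(8, 12)

#' Natural-gradient Infomax ICA
#'
#' Plain (non-extended) Infomax with the logistic nonlinearity and
#' runica-style annealing, on already whitened data. Deterministic given
#' `seed` (which drives the per-sweep sample permutation).
#'
#' @param z Samples-by-components whitened matrix.
#' @param seed Integer seed.
#' @param max_sweeps,tol Stopping rule: stop when the squared weight change
#'   per sweep drops below `tol` or after `max_sweeps`.
#' @param block Mini-batch size.
#' @param lrate Initial learning rate (default `0.00065 / log(k)`).
#' @return Unmixing matrix `W` (k x k) for the whitened data; activations
#'   are `z %*% t(W)`.
#' @export
infomax_ica <- function(z, seed = 1L, max_sweeps = 192, tol = 3e-7,
                        block = 1024, lrate = NULL) {
  k <- ncol(z)
  n <- nrow(z)
  lrate <- lrate %||% (0.00065 / log(k))
  W <- diag(k)
  set.seed(seed)
  old_change <- Inf
  for (sweep in seq_len(max_sweeps)) {
    W0 <- W
    perm <- sample.int(n)
    starts <- seq(1L, n - block + 1L, by = block)
    blowup <- FALSE
    for (s in starts) {
      xb <- z[perm[s:(s + block - 1L)], , drop = FALSE]
      u <- xb %*% t(W)
      y <- 1 / (1 + exp(-u))
      dW <- (block * diag(k) + crossprod(1 - 2 * y, u)) %*% W
      W <- W + lrate * dW
      if (max(abs(W)) > 1e8 || any(!is.finite(W))) { blowup <- TRUE; break }
    }
    if (blowup) {             # restart colder
      W <- diag(k)
      lrate <- lrate / 2
      old_change <- Inf
      next
    }
    change <- sum((W - W0)^2)
    if (change < tol) break
    if (change > old_change) lrate <- lrate * 0.9
    old_change <- change
  }
  W
}

#' PCA reduction followed by Infomax ICA over a subject's sessions
#'
#' Each session's scalp EEG is re-referenced to the 16-channel average and
#' band-pass filtered 1-100 Hz; the six filtered sessions are concatenated,
#' reduced to `n_dims` principal components, whitened, and unmixed with
#' [infomax_ica()]. ICA weights are estimated on every `decimate`-th sample
#' (ICA treats samples as i.i.d., so decimation only subsamples the
#' marginal distribution); activations and spectra always use full-rate
#' data. Components are ordered by decreasing back-projected variance.
#'
#' @param sessions List of `session_recording`s from one subject.
#' @param n_dims Number of retained principal components (default 10; if
#'   the data rank is lower, the available rank is used with a warning).
#' @param seed ICA seed, recorded in the result.
#' @param decimate Sample decimation factor for the ICA fit.
#' @return An `alpha_decomposition`: `unmixing` (16 x k, channels to
#'   activations), `topography` (16 x k scalp patterns), `activations`
#'   (list per session, samples x k), `psd` (freq x k over the
#'   concatenated sessions), `selection` tibble (see
#'   [select_alpha_components()]), `fs`, `seed`.
#' @export
pca_reduce_then_ica <- function(sessions, n_dims = 10, seed = 1L,
                                decimate = 6L) {
  stopifnot(length(sessions) >= 1)
  cm <- channel_map()
  fs <- sessions[[1]]$fs_eeg
  filtered <- lapply(sessions, function(s) {
    x <- rereference_to_average(s$eeg, cm)[, cm$scalp, drop = FALSE]
    fir_filter(x, fs, low_cut = 1, high_cut = 100)
  })
  xall <- do.call(rbind, filtered)
  mu <- colMeans(xall)
  xall <- sweep(xall, 2, mu)
  sv <- svd(xall, nu = 0)
  pos <- sum(sv$d > max(sv$d) * 1e-8)
  if (pos < n_dims) {
    warning("data rank ", pos, " < ", n_dims, "; reducing to available rank")
    n_dims <- pos
  }
  dscale <- sv$d[seq_len(n_dims)] / sqrt(nrow(xall) - 1)
  K <- sv$v[, seq_len(n_dims), drop = FALSE] %*% diag(1 / dscale, n_dims)
  z <- xall %*% K                                   # whitened scores
  zfit <- z[seq(1, nrow(z), by = decimate), , drop = FALSE]
  W <- infomax_ica(zfit, seed = seed)
  M <- K %*% t(W)                                   # channels -> activations
  ## scalp patterns: X ~ U %*% t(A), A = t(solve(t(W)) %*% pinv(K))
  pinvK <- diag(dscale, n_dims) %*% t(sv$v[, seq_len(n_dims), drop = FALSE])
  A <- t(solve(t(W)) %*% pinvK)                     # 16 x k
  ## order by back-projected variance (descending), fix sign so the
  ## largest-|weight| scalp pattern entry is positive
  u_all <- z %*% t(W)
  pvar <- colSums(A^2) * apply(u_all, 2, var)
  ord <- order(pvar, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  M <- M[, ord, drop = FALSE]
  sgn <- apply(A, 2, function(a) sign(a[which.max(abs(a))]))
  sgn[sgn == 0] <- 1
  A <- sweep(A, 2, sgn, "*")
  M <- sweep(M, 2, sgn, "*")
  rownames(A) <- rownames(M) <- cm$scalp
  activations <- lapply(filtered, function(x) {
    sweep(x, 2, mu) %*% M
  })
  names(activations) <- names(sessions)
  uc <- do.call(rbind, activations)
  psd <- vapply(seq_len(ncol(uc)),
                function(j) welch_psd(uc[, j], fs)$power,
                numeric(round(fs / 2) + 1))
  freq <- welch_psd(uc[, 1], fs)$freq
  dec <- structure(list(
    unmixing = M, topography = A, activations = activations,
    psd = psd, freq = freq, fs = fs, seed = seed, center = mu
  ), class = "alpha_decomposition")
  dec$selection <- select_alpha_components(dec)
  dec
}

#' @export
print.alpha_decomposition <- function(x, ...) {
  cat("<alpha_decomposition> ", ncol(x$unmixing), " components over ",
      length(x$activations), " sessions; ",
      sum(x$selection$selected), " selected (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

## Local maxima (strictly greater than both neighbors) of a vector.
.local_peaks <- function(p) {
  n <- length(p)
  if (n < 3) return(integer(0))
  which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] > p[3:n]) + 1L
}

## Peak width between the two flanking local minima on the 1-Hz grid.
.peak_width <- function(p, freq, i) {
  left <- i
  while (left > 1 && p[left - 1] < p[left]) left <- left - 1
  right <- i
  while (right < length(p) && p[right + 1] < p[right]) right <- right + 1
  freq[right] - freq[left]
}

#' Rule-based alpha-component selection
#'
#' Applies the four selection criteria to every component of a
#' decomposition, on its 2-50 Hz, 1-Hz-resolution power spectrum:
#' (1) a local spectral peak between 6 and 14 Hz exists; (2) the peak
#' width, measured between the two flanking local minima, is at least
#' 4 Hz -- with several 6-14 Hz peaks, the widest is taken (ties broken
#' toward lower frequency); (3) peak power is at least 3x the mean power
#' between 20 and 50 Hz; (4) the maximum absolute topography weight over
#' O1/O2/POz exceeds the maximum over all other scalp sensors. An empty
#' selection is a valid outcome (the subject is then excluded upstream).
#'
#' @param dec An `alpha_decomposition` (or a list with `psd`, `freq`,
#'   `topography`).
#' @return A tibble with one row per component: `component`, `peak_freq`,
#'   `peak_width`, `peak_power`, `hf_mean` (20-50 Hz mean power), the four
#'   criterion flags `has_peak`, `wide_enough`, `above_broadband`,
#'   `occipital_max`, and `selected`.
#' @export
select_alpha_components <- function(dec) {
  cm <- channel_map()
  occ <- cm$occipital
  other <- setdiff(cm$scalp, occ)
  band <- dec$freq >= 2 & dec$freq <= 50
  freq <- dec$freq[band]
  rows <- lapply(seq_len(ncol(dec$psd)), function(j) {
    p <- dec$psd[band, j]
    peaks <- .local_peaks(p)
    peaks <- peaks[freq[peaks] >= 6 & freq[peaks] <= 14]
    has_peak <- length(peaks) > 0
    pf <- pw <- pp <- NA_real_
    if (has_peak) {
      widths <- vapply(peaks, function(i) .peak_width(p, freq, i), 0)
      best <- peaks[order(-widths, freq[peaks])][1]  # widest, then lowest f
      pf <- freq[best]
      pw <- max(widths)
      pp <- p[best]
    }
    hf <- mean(p[freq >= 20 & freq <= 50])
    topo <- abs(dec$topography[, j])
    tibble::tibble(
      component = j, peak_freq = pf, peak_width = pw, peak_power = pp,
      hf_mean = hf,
      has_peak = has_peak,
      wide_enough = has_peak && pw >= 4,
      above_broadband = has_peak && pp >= 3 * hf,
      occipital_max = max(topo[occ]) > max(topo[other])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$selected <- out$has_peak & out$wide_enough & out$above_broadband &
    out$occipital_max
  out
}

.selected_idx <- function(dec) {
  which(dec$selection$selected)
}

#' Per-session alpha power from the selected components
#'
#' For each session the Welch spectra of all selected components are
#' averaged (arithmetic mean of power) and alpha power is the mean over the
#' 8-12 Hz bins.
#'
#' @param dec An `alpha_decomposition`.
#' @param sessions Optional character vector of session names.
#' @return A tibble with `session`, `alpha_power`, plus the full averaged
#'   spectrum nested in `psd` (list of tibbles). Errors if no component was
#'   selected (subject-level exclusion).
#' @export
component_session_alpha <- function(dec, sessions = names(dec$activations)) {
  sel <- .selected_idx(dec)
  if (!length(sel)) {
    stop("no alpha component selected; subject excluded", call. = FALSE)
  }
  rows <- lapply(sessions, function(nm) {
    u <- dec$activations[[nm]][, sel, drop = FALSE]
    ps <- vapply(seq_len(ncol(u)), function(j) welch_psd(u[, j], dec$fs)$power,
                 numeric(length(dec$freq)))
    pm <- rowMeans(ps)
    ab <- dec$freq >= ALPHA_BAND[1] & dec$freq <= ALPHA_BAND[2]
    tibble::tibble(session = nm, alpha_power = mean(pm[ab]),
                   psd = list(tibble::tibble(freq = dec$freq, power = pm)))
  })
  dplyr::bind_rows(rows)
}

#' Back-projected per-sensor alpha power map
#'
#' The selected components are jointly projected back into sensor space
#' and alpha power (mean 8-12 Hz Welch power) computed per scalp sensor.
#'
#' @param dec An `alpha_decomposition`.
#' @param session Session name (default: all concatenated).
#' @return A tibble with `channel` and `alpha_power` (16 rows).
#' @export
backproject_alpha_topography <- function(dec, session = NULL) {
  sel <- .selected_idx(dec)
  if (!length(sel)) {
    stop("no alpha component selected; subject excluded", call. = FALSE)
  }
  u <- if (is.null(session)) {
    do.call(rbind, dec$activations)[, sel, drop = FALSE]
  } else {
    dec$activations[[session]][, sel, drop = FALSE]
  }
  xs <- u %*% t(dec$topography[, sel, drop = FALSE])  # samples x 16
  ab <- dec$freq >= ALPHA_BAND[1] & dec$freq <= ALPHA_BAND[2]
  ap <- apply(xs, 2, function(ch) mean(welch_psd(ch, dec$fs)$power[ab]))
  out <- tibble::tibble(channel = rownames(dec$topography),
                        alpha_power = ap)
  class(out) <- c("alpha_topography", class(out))
  out
}

#' Per-epoch alpha power on the 1-s / 0.5-s-step grid
#'
#' Epochs are Hamming-windowed 1-s FFT periodograms on a grid anchored at
#' t = 0 with 0.5 s steps (a 76.5-s session yields 152 epochs; any final
#' partial window is dropped). Per-epoch alpha power is averaged over the
#' selected components; the session mean over epochs equals the session's
#' Welch alpha power by construction. Outliers are flagged with the
#' MAD-median rule within the session.
#'
#' @param dec An `alpha_decomposition`.
#' @param session Session name.
#' @return A tibble with `session`, `epoch`, `t_start`, `t_end`,
#'   `alpha_power`, `outlier`.
#' @export
epoch_alpha_power <- function(dec, session) {
  sel <- .selected_idx(dec)
  if (!length(sel)) {
    stop("no alpha component selected; subject excluded", call. = FALSE)
  }
  u <- dec$activations[[session]][, sel, drop = FALSE]
  nwin <- round(dec$fs)
  ab_idx <- NULL
  pow <- NULL
  for (j in seq_len(ncol(u))) {
    p <- .segment_psd_matrix(u[, j], dec$fs, nwin, overlap = 0.5)
    if (is.null(ab_idx)) {
      fr <- attr(p, "freq")
      ab_idx <- which(fr >= ALPHA_BAND[1] & fr <= ALPHA_BAND[2])
      starts <- attr(p, "start_sample")
    }
    pj <- colMeans(p[ab_idx, , drop = FALSE])
    pow <- if (is.null(pow)) pj else pow + pj
  }
  pow <- pow / ncol(u)
  t0 <- (starts - 1) / dec$fs
  tibble::tibble(
    session = session, epoch = seq_along(pow),
    t_start = t0, t_end = t0 + 1,
    alpha_power = pow,
    outlier = mad_median_outliers(pow)$outlier
  )
}

#' Continuous alpha power envelope (Hilbert)
#'
#' Each selected component's activation is band-pass filtered 8-12 Hz with
#' a Hamming-window FIR filter, Hilbert transformed, and the squared
#' magnitudes averaged over components. Note this envelope power is on a
#' different (larger) scale than Welch band power.
#'
#' @param dec An `alpha_decomposition`.
#' @param session Session name.
#' @param band Pass band in Hz.
#' @return Numeric vector of nonnegative power values, one per sample.
#' @export
alpha_envelope <- function(dec, session, band = ALPHA_BAND) {
  sel <- .selected_idx(dec)
  if (!length(sel)) {
    stop("no alpha component selected; subject excluded", call. = FALSE)
  }
  u <- dec$activations[[session]][, sel, drop = FALSE]
  env2 <- 0
  for (j in seq_len(ncol(u))) {
    xf <- fir_filter(u[, j], dec$fs, band[1], band[2], window = "hamming")
    env2 <- env2 + Mod(analytic_signal(xf))^2
  }
  env2 / ncol(u)
}
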