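## Synthetic walking-EEG sessions with fully known ground truth. The
## generator emulates the statistical structure the downstream analyses
## assume: 1/f scalp noise plus an occipitally weighted, bursty alpha source
## whose amplitude depends on condition and stride phase; EOG with saccadic
## spike transients and slow blink waveforms at condition- and
## phase-dependent rates (renewal processes with a refractory gap);
## quasi-periodic ankle speed; pupil drift with dropout runs.

EEG_FS <- 500
MOTION_FS <- 120

#' Ground-truth configuration for the synthetic generator
#'
#' Every per-condition parameter is a named vector over the six cells
#' `light_still, light_slow, light_normal, dark_still, dark_slow,
#' dark_normal` (scalars are recycled to all cells). Defaults encode the
#' study conditions the pipeline is built for: occipital alpha suppressed by
#' 20% during walking and stronger in darkness, saccade rate increasing
#' with speed in the light only, blink rate increasing with speed in both
#' lighting levels, pupil larger in darkness, stride periods of ~1.13 s
#' (slow) and ~0.64 s (normal), and mean back speeds of ~0.5/1.1 m/s.
#'
#' @param alpha_amp Alpha source amplitude per condition (uV).
#' @param alpha_freq Individual alpha frequency (Hz).
#' @param alpha_burst_sd Log-sd of the slow lognormal burst envelope
#'   (mean 1); 0 gives a constant-amplitude alpha rhythm.
#' @param alpha_phase_mod_depth Fractional amplitude modulation over the
#'   stride cycle, in `[0, 1]`; amplitude is lowest at the stride
#'   boundaries (low speed / double support phase).
#' @param saccade_rate,blink_rate Mean event rates per condition
#'   (events/s); events keep a hard refractory gap (150 ms saccades,
#'   400 ms blinks) with the mean rate preserved.
#' @param phase_concentration Preference of events for the low speed phase
#'   (>= 0); event intensity is proportional to
#'   `1 + phase_concentration * cos(2*pi*stride_fraction)`.
#' @param stride_period Stride period (s) per walking speed, named
#'   `slow`/`normal`.
#' @param back_speed Mean back-sensor speed (m/s) per walking cell.
#' @param pupil_mean Mean pupil radius per condition (a.u.).
#' @param pupil_missing_frac Fraction of pupil samples lost to dropout,
#'   in `[0, 1)`; placed in contiguous geometric runs.
#' @param saccade_amp Peak of the 15-ms biphasic EOG spike (uV).
#' @param blink_amp Peak of the 250-ms raised-cosine blink bump on the
#'   above-eye channels (uV).
#' @param noise_sd Per-channel 1/f noise standard deviation (uV).
#' @param impedance_kohm If non-`NULL`, a 125 Hz carrier whose power equals
#'   this impedance (kOhm) is added to every scalp channel.
#' @param seed Master integer seed; per-session streams are derived from
#'   `(seed, subject, condition)`.
#' @return A `gt_config` list, validated.
#' @export
gt_config <- function(alpha_amp = c(light_still = 12, light_slow = 9.6,
                                    light_normal = 9.6, dark_still = 20,
                                    dark_slow = 16, dark_normal = 16),
                      alpha_freq = 10,
                      alpha_burst_sd = 0.4,
                      alpha_phase_mod_depth = 0.15,
                      saccade_rate = c(light_still = 1.2, light_slow = 1.7,
                                       light_normal = 2.0, dark_still = 1.0,
                                       dark_slow = 1.05, dark_normal = 1.1),
                      blink_rate = c(light_still = 0.30, light_slow = 0.45,
                                     light_normal = 0.60, dark_still = 0.30,
                                     dark_slow = 0.45, dark_normal = 0.60),
                      phase_concentration = 0.5,
                      stride_period = c(slow = 1.13, normal = 0.64),
                      back_speed = c(light_slow = 0.53, light_normal = 1.12,
                                     dark_slow = 0.50, dark_normal = 0.96),
                      pupil_mean = c(light_still = 3.0, light_slow = 3.0,
                                     light_normal = 3.0, dark_still = 4.6,
                                     dark_slow = 5.0, dark_normal = 5.0),
                      pupil_missing_frac = 0.12,
                      saccade_amp = 40,
                      blink_amp = 150,
                      noise_sd = 8,
                      impedance_kohm = NULL,
                      seed = 1L) {
  cells <- .condition_keys()
  expand <- function(x, keys = cells) {
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, length(keys)), keys)
    missing <- setdiff(keys, names(x))
    if (length(missing)) {
      stop("condition cell(s) missing from template: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x[keys]
  }
  cfg <- list(
    alpha_amp = expand(alpha_amp),
    alpha_freq = alpha_freq,
    alpha_burst_sd = alpha_burst_sd,
    alpha_phase_mod_depth = alpha_phase_mod_depth,
    saccade_rate = expand(saccade_rate),
    blink_rate = expand(blink_rate),
    phase_concentration = phase_concentration,
    stride_period = expand(stride_period, WALKING_SPEEDS),
    back_speed = expand(back_speed,
                        paste(rep(LIGHTING_LEVELS, each = 2), WALKING_SPEEDS,
                              sep = "_")),
    pupil_mean = expand(pupil_mean),
    pupil_missing_frac = pupil_missing_frac,
    saccade_amp = saccade_amp,
    blink_amp = blink_amp,
    noise_sd = noise_sd,
    impedance_kohm = impedance_kohm,
    seed = as.integer(seed)
  )
  stopifnot(
    all(cfg$saccade_rate >= 0), all(cfg$blink_rate >= 0),
    cfg$alpha_phase_mod_depth >= 0, cfg$alpha_phase_mod_depth <= 1,
    all(cfg$stride_period > 0),
    cfg$pupil_missing_frac >= 0, cfg$pupil_missing_frac < 1,
    cfg$phase_concentration >= 0, cfg$noise_sd >= 0
  )
  structure(cfg, class = "gt_config")
}

.condition_keys <- function() {
  paste(rep(LIGHTING_LEVELS, each = 3), rep(SPEED_LEVELS, 2), sep = "_")
}

#' Canonical condition-cell key, e.g. `"dark_normal"`
#'
#' @param lighting,speed Condition levels (vectorized).
#' @return Character vector `"<lighting>_<speed>"`.
#' @export
cond_key <- function(lighting, speed) paste(lighting, speed, sep = "_")

## Deterministic per-session stream derived from (master seed, subject,
## condition); kept below 2^31.
session_seed <- function(master, subject, lighting, speed) {
  ci <- match(cond_key(lighting, speed), .condition_keys())
  as.integer((as.numeric(master) * 1009 + subject * 7919 + ci * 104729 + 1) %%
               2147483629)
}

## 1/f ("pink") noise columns, unit variance, via spectral shaping.
.pink_noise <- function(n, ncols, fs) {
  white <- matrix(rnorm(n * ncols), n, ncols)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, 1))            # flat below 1 Hz
  g[1] <- 0                            # no DC
  x <- Re(stats::mvfft(stats::mvfft(white) * g, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, sd), "/")
}

## Smooth unit-variance noise: Gaussian knots at `knot_hz`, spline to t.
.slow_noise <- function(t, knot_hz = 2) {
  nk <- max(4, ceiling(max(t) * knot_hz) + 2)
  kt <- seq(0, max(t), length.out = nk)
  y <- stats::spline(kt, rnorm(nk), xout = t)$y
  (y - mean(y)) / sd(y)
}

## Event times with mean rate `rate`, a hard refractory gap `refractory`
## (candidate gaps are refractory + Exp, so the candidate renewal rate is
## exactly rate*(1+conc)), thinned by stride-phase preference with
## acceptance probability (1 + conc*cos(2*pi*frac(t))) / (1 + conc);
## frac_fun NULL => uniform acceptance 1/(1+conc). Mean output rate: rate.
.phase_event_times <- function(rate, duration, conc, frac_fun,
                               refractory = 0) {
  if (rate <= 0) return(numeric(0))
  lam <- rate * (1 + conc)
  if (lam * refractory >= 0.9) {
    stop("event rate ", rate, "/s too high for a ", refractory,
         " s refractory gap", call. = FALSE)
  }
  exp_mean <- 1 / lam - refractory
  cand <- numeric(0)
  t <- stats::rexp(1, 1 / (1 / lam))      # first event: plain Exp
  while (t < duration) {
    cand <- c(cand, t)
    t <- t + refractory + stats::rexp(1, 1 / exp_mean)
  }
  if (!length(cand)) return(numeric(0))
  accept <- if (is.null(frac_fun)) {
    rep(1 / (1 + conc), length(cand))
  } else {
    (1 + conc * cos(2 * pi * frac_fun(cand))) / (1 + conc)
  }
  cand[runif(length(cand)) < accept]
}

## Add `wave` starting at each time to the named columns of `mat`, scaled
## per channel by `gains`; clipped at the edges, every insertion counted.
.add_waveform <- function(mat, times, fs, wave, gains) {
  if (!length(times)) return(mat)
  n <- nrow(mat)
  cols <- match(names(gains), colnames(mat))
  keep <- !is.na(cols)
  cols <- cols[keep]; g <- gains[keep]
  for (t0 in times) {
    i0 <- round(t0 * fs) + 1
    if (i0 > n) next
    idx <- i0:min(n, i0 + length(wave) - 1)
    wv <- wave[seq_along(idx)]
    mat[idx, cols] <- mat[idx, cols] + outer(wv, g)
  }
  mat
}

.saccade_wave <- function(amp, fs = EEG_FS) {
  tt <- seq(0, 0.015, by = 1 / fs)
  amp * sin(2 * pi * tt / 0.015)       # one biphasic cycle, ~67 Hz lobe
}

.blink_wave <- function(amp, fs = EEG_FS) {
  tt <- seq(0, 0.25, by = 1 / fs)
  amp * 0.5 * (1 - cos(2 * pi * tt / 0.25))
}

## Scalp pattern of the alpha source: occipital-dominant.
.alpha_topography <- function() {
  w <- c(Fp1 = 0.02, Fp2 = 0.02, Fz = 0.05, F7 = 0.04, F8 = 0.04,
         C3 = 0.10, Cz = 0.15, C4 = 0.10, T7 = 0.08, T8 = 0.08,
         P7 = 0.38, P8 = 0.36, Pz = 0.45, POz = 0.75, O1 = 1.00, O2 = 0.92)
  w[channel_map()$scalp]
}

#' Generate one synthetic multi-stream session
#'
#' Produces a 24-channel EEG/EOG stream at 500 Hz, three 3-axis velocity
#' sensors and a pupil trace at 120 Hz, for one condition cell, with a
#' `truth` block recording every injected event time, the stride
#' boundaries, and the generating parameters. Deterministic given
#' `(config$seed, subject, lighting, speed)`.
#'
#' @param config A [gt_config()].
#' @param lighting `"light"` or `"dark"`.
#' @param speed `"still"`, `"slow"` or `"normal"`.
#' @param duration Session length in seconds (default 76.5).
#' @param subject Subject index used in seed derivation.
#' @return A `session_recording` list with elements `eeg` (samples x 24
#'   matrix, uV), `motion` (samples x 9 matrix, m/s), `pupil` (vector,
#'   0 = missing), `fs_eeg`, `fs_motion`, `lighting`, `speed`, `duration`,
#'   `truth`.
#' @export
generate_session <- function(config, lighting, speed, duration = 76.5,
                             subject = 1L) {
  stopifnot(inherits(config, "gt_config"))
  lighting <- match.arg(lighting, LIGHTING_LEVELS)
  speed <- match.arg(speed, SPEED_LEVELS)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  walking <- speed %in% WALKING_SPEEDS
  if (walking && (is.na(config$stride_period[speed]) ||
                  config$stride_period[speed] <= 0)) {
    stop("stride_period undefined for walking speed '", speed, "'",
         call. = FALSE)
  }
  key <- cond_key(lighting, speed)
  cm <- channel_map()

  seed <- session_seed(config$seed, subject, lighting, speed)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  n_e <- round(duration * EEG_FS)
  n_m <- round(duration * MOTION_FS)
  t_e <- (seq_len(n_e) - 1) / EEG_FS
  t_m <- (seq_len(n_m) - 1) / MOTION_FS

  ## --- stride timing -------------------------------------------------
  boundaries <- NULL
  frac_fun <- NULL
  if (walking) {
    period <- config$stride_period[[speed]]
    ## within-session stride-time variability of healthy gait is a few
    ## percent; 4% CV keeps stride counts within +/-1 of duration/period.
    ## Walking is already ongoing at session start, so the first boundary
    ## sits at a random fraction of a stride before t = 0.
    durs <- numeric(0)
    while (sum(durs) < duration + 2 * period) {
      durs <- c(durs, stats::rlnorm(25, log(period) - 0.04^2 / 2, 0.04))
    }
    boundaries <- c(0, cumsum(durs)) - runif(1) * period
    boundaries <- boundaries[seq_len(which(boundaries > duration)[1])]
    frac_fun <- function(tt) {
      i <- findInterval(tt, boundaries, rightmost.closed = FALSE)
      i <- pmin(pmax(i, 1L), length(boundaries) - 1L)
      (tt - boundaries[i]) / (boundaries[i + 1] - boundaries[i])
    }
  }

  ## --- alpha source + scalp EEG --------------------------------------
  amp <- config$alpha_amp[[key]]
  burst <- if (config$alpha_burst_sd > 0) {
    exp(config$alpha_burst_sd * .slow_noise(t_e) - config$alpha_burst_sd^2 / 2)
  } else rep(1, n_e)
  mod <- if (walking && config$alpha_phase_mod_depth > 0) {
    1 - config$alpha_phase_mod_depth * cos(2 * pi * frac_fun(t_e))
  } else rep(1, n_e)
  alpha_src <- amp * burst * mod * sin(2 * pi * config$alpha_freq * t_e +
                                         runif(1, 0, 2 * pi))
  topo <- .alpha_topography()
  scalp <- if (config$noise_sd > 0) {
    .pink_noise(n_e, 16, EEG_FS) * config$noise_sd
  } else matrix(0, n_e, 16)
  colnames(scalp) <- cm$scalp
  scalp <- scalp + outer(alpha_src, topo)

  if (!is.null(config$impedance_kohm)) {
    carrier_amp <- sqrt(2 * config$impedance_kohm)
    ph <- runif(16, 0, 2 * pi)
    scalp <- scalp + carrier_amp *
      cos(outer(t_e, rep(2 * pi * 125, 16)) + matrix(ph, n_e, 16, TRUE))
  }

  eog <- if (config$noise_sd > 0) {
    .pink_noise(n_e, 6, EEG_FS) * config$noise_sd
  } else matrix(0, n_e, 6)
  colnames(eog) <- cm$eog
  ears <- if (config$noise_sd > 0) {
    .pink_noise(n_e, 2, EEG_FS) * config$noise_sd * 0.5
  } else matrix(0, n_e, 2)
  colnames(ears) <- cm$earlobes

  ## --- eye events -----------------------------------------------------
  sacc_times <- .phase_event_times(config$saccade_rate[[key]], duration,
                                   config$phase_concentration, frac_fun,
                                   refractory = 0.15)
  blink_times <- .phase_event_times(config$blink_rate[[key]], duration,
                                    config$phase_concentration, frac_fun,
                                    refractory = 0.40)
  sw <- .saccade_wave(config$saccade_amp)
  eog <- .add_waveform(eog, sacc_times, EEG_FS, sw,
                       setNames(rep(1, 6), cm$eog))
  scalp <- .add_waveform(scalp, sacc_times, EEG_FS, sw,
                         c(Fp1 = 0.08, Fp2 = 0.08, Fz = 0.05, F7 = 0.06,
                           F8 = 0.06, Cz = 0.03))
  bw <- .blink_wave(config$blink_amp)
  eog <- .add_waveform(eog, blink_times, EEG_FS, bw,
                       c(EOGLA = 1, EOGRA = 0.95, EOGLB = -0.6, EOGRB = -0.58,
                         EOGLC = 0.15, EOGRC = 0.15))
  scalp <- .add_waveform(scalp, blink_times, EEG_FS, bw,
                         c(Fp1 = 0.25, Fp2 = 0.25, Fz = 0.10))

  eeg <- cbind(scalp, eog, ears)

  ## --- motion ----------------------------------------------------------
  u_l <- c(0.90, 0.33, 0.28); u_l <- u_l / sqrt(sum(u_l^2))
  u_r <- c(0.88, 0.30, 0.37); u_r <- u_r / sqrt(sum(u_r^2))
  motion <- matrix(rnorm(n_m * 9, sd = 0.02), n_m, 9)
  colnames(motion) <- as.vector(outer(c("x", "y", "z"),
                                      c("left", "right", "back"),
                                      function(a, s) paste(s, a, sep = "_")))
  if (walking) {
    fr <- frac_fun(t_m)
    base <- 0.15
    combined <- base + 3 * config$back_speed[[key]] * sin(pi * fr)^2
    s_l <- combined / 2 * (1 + 0.8 * sin(2 * pi * fr))
    s_r <- combined / 2 * (1 - 0.8 * sin(2 * pi * fr))
    motion[, paste0("left_", c("x", "y", "z"))] <-
      motion[, paste0("left_", c("x", "y", "z"))] + outer(s_l, u_l)
    motion[, paste0("right_", c("x", "y", "z"))] <-
      motion[, paste0("right_", c("x", "y", "z"))] + outer(s_r, u_r)
    motion[, "back_x"] <- motion[, "back_x"] + config$back_speed[[key]]
  }

  ## --- pupil -----------------------------------------------------------
  pupil <- config$pupil_mean[[key]] + 0.25 * .slow_noise(t_m) +
    rnorm(n_m, sd = 0.02)
  miss <- rep(FALSE, n_m)
  if (config$pupil_missing_frac > 0) {
    target <- config$pupil_missing_frac * n_m
    while (sum(miss) < target) {
      run <- 1 + stats::rgeom(1, 1 / 24)   # mean run ~ 0.2 s
      s0 <- sample.int(n_m, 1)
      miss[s0:min(n_m, s0 + run - 1)] <- TRUE
    }
  }
  pupil[miss] <- 0

  structure(list(
    eeg = eeg, fs_eeg = EEG_FS,
    motion = motion, fs_motion = MOTION_FS,
    pupil = pupil,
    lighting = lighting, speed = speed, duration = duration,
    subject = subject,
    truth = list(
      seed = seed,
      alpha_amp = amp,
      alpha_freq = config$alpha_freq,
      alpha_phase_mod_depth = if (walking) config$alpha_phase_mod_depth else 0,
      alpha_topography = topo,
      saccade_times = sacc_times,
      blink_times = blink_times,
      ## only boundaries inside the session window: the edge strides are
      ## partial and not recoverable from the recorded speed
      stride_boundaries = boundaries[boundaries >= 0 &
                                       boundaries <= duration],
      back_speed = if (walking) config$back_speed[[key]] else 0,
      pupil_mean = config$pupil_mean[[key]],
      pupil_missing = which(miss)
    )
  ), class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat("<session_recording> ", x$lighting, "/", x$speed, ", ",
      x$duration, " s; EEG ", nrow(x$eeg), "x", ncol(x$eeg), " @ ",
      x$fs_eeg, " Hz; motion @ ", x$fs_motion, " Hz\n", sep = "")
  if (!is.null(x$truth)) {
    cat("  truth: ", length(x$truth$saccade_times), " saccades, ",
        length(x$truth$blink_times), " blinks, ",
        max(0, length(x$truth$stride_boundaries) - 1), " strides\n", sep = "")
  }
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Each subject receives all six condition cells (in randomized order) with
#' subject-level parameters jittered multiplicatively by
#' `between_subject_sd` (lognormal, mean 1) and an individual alpha
#' frequency.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config Template [gt_config()].
#' @param between_subject_sd Lognormal sd of the per-subject multipliers
#'   applied to alpha amplitude, event rates and pupil mean (0 = identical
#'   subjects).
#' @param duration Session length in seconds.
#' @param subjects Subject indices to generate (default all). Each
#'   subject's streams depend only on `(config$seed, subject index)`, so
#'   generating subjects one at a time gives bit-identical sessions to a
#'   full-cohort call while holding only one subject in memory.
#' @return A `ga_cohort`: list of subjects, each with `subject`, `config`
#'   (the jittered per-subject config), and `sessions` (named list of six
#'   `session_recording`s in randomized order).
#' @export
generate_cohort <- function(n_subjects, config = gt_config(),
                            between_subject_sd = 0.15, duration = 76.5,
                            subjects = seq_len(n_subjects)) {
  stopifnot(n_subjects >= 1, inherits(config, "gt_config"),
            all(subjects >= 1), all(subjects <= n_subjects))
  subjects <- lapply(as.integer(subjects), function(s) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(session_seed(config$seed, s, "light", "still") + 500009L)
    cfg <- config
    if (between_subject_sd > 0) {
      jit <- function() stats::rlnorm(1, -between_subject_sd^2 / 2,
                                      between_subject_sd)
      cfg$alpha_amp <- cfg$alpha_amp * jit()
      cfg$saccade_rate <- cfg$saccade_rate * jit()
      cfg$blink_rate <- cfg$blink_rate * jit()
      cfg$pupil_mean <- cfg$pupil_mean * jit()
      cfg$alpha_freq <- min(12, max(8, cfg$alpha_freq + rnorm(1, 0, 0.6)))
    }
    ord <- sample(.condition_keys())
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    sessions <- lapply(ord, function(k) {
      parts <- strsplit(k, "_")[[1]]
      generate_session(cfg, parts[1], parts[2], duration, subject = s)
    })
    names(sessions) <- ord
    list(subject = s, config = cfg, sessions = sessions, order = ord)
  })
  structure(subjects, class = "ga_cohort",
            seed = config$seed, duration = duration)
}
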