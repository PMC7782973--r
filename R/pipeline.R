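## End-to-end orchestration: cohort -> per-subject processing -> cohort
## randomization statistics -> report tables, with explicit exclusion
## bookkeeping at every rule.

#' Process one subject's six sessions
#'
#' Runs the whole per-subject chain: ICA decomposition and alpha-component
#' selection, per-session alpha power, the 1-s epoch grid with saccade/
#' blink/pupil covariates, eye-event detection with a participant-level
#' blink threshold, pupil cleaning, gait segmentation and phase profiles
#' (alpha envelope + event rates + pupil) for the walking sessions.
#'
#' @param subj One element of a `ga_cohort` (list with `subject`,
#'   `sessions`).
#' @param seed ICA seed.
#' @param phase_profiles Compute walking-phase profiles (slower).
#' @return A list: `subject`, `conditions` (per-session tibble),
#'   `epochs`, `phase` (per-session 9-phase tibble or NULL), `selection`,
#'   `excluded_no_component`, `excluded_pupil`.
#' @export
process_subject <- function(subj, seed = 1L, phase_profiles = TRUE) {
  sessions <- subj$sessions
  dec <- pca_reduce_then_ica(sessions, seed = seed)
  no_comp <- !any(dec$selection$selected)
  cm <- channel_map()
  thr <- estimate_blink_threshold(
    unlist(lapply(sessions, function(s) s$eeg[, "EOGLA"])),
    unlist(lapply(sessions, function(s) s$eeg[, "EOGLB"])))
  pupils <- lapply(sessions, function(s) process_pupil(s$pupil))
  pupil_excluded <- mean(vapply(sessions, function(s) {
    mean(pupil_missing_mask(s$pupil))
  }, 0)) > 0.99
  conditions <- NULL
  epochs <- NULL
  phase <- NULL
  alpha_tbl <- if (!no_comp) component_session_alpha(dec) else NULL
  rows <- lapply(names(sessions), function(nm) {
    s <- sessions[[nm]]
    ev <- detect_eye_events(s, thr)
    walking <- s$speed %in% WALKING_SPEEDS
    tibble::tibble(
      subject = subj$subject, session = nm,
      lighting = s$lighting, speed = s$speed,
      alpha_power = if (!no_comp) {
        alpha_tbl$alpha_power[alpha_tbl$session == nm]
      } else NA_real_,
      saccade_rate = sum(ev$kind == "saccade") / s$duration,
      blink_rate = sum(ev$kind == "blink") / s$duration,
      pupil_mean = pupils[[nm]]$session_mean,
      back_speed = if (walking) mean_back_speed(s) else NA_real_,
      events = list(ev)
    )
  })
  conditions <- dplyr::bind_rows(rows)
  if (!no_comp) {
    epochs <- dplyr::bind_rows(lapply(names(sessions), function(nm) {
      ep <- epoch_alpha_power(dec, nm)
      ep <- epoch_covariates(ep, conditions$events[[
        which(conditions$session == nm)]],
        pupils[[nm]], sessions[[nm]]$fs_motion)
      ep$subject <- subj$subject
      ep
    }))
  }
  if (phase_profiles && !no_comp) {
    walk_names <- names(sessions)[vapply(sessions, function(s) {
      s$speed %in% WALKING_SPEEDS
    }, TRUE)]
    phase <- dplyr::bind_rows(lapply(walk_names, function(nm) {
      s <- sessions[[nm]]
      strides <- tryCatch(
        segment_strides(combined_ankle_speed(s), s$fs_motion),
        error = function(e) NULL)
      if (is.null(strides) || sum(!strides$excluded) < 3) return(NULL)
      env <- alpha_envelope(dec, nm)
      ev <- conditions$events[[which(conditions$session == nm)]]
      pb <- function(x, fs) phase_bin_series(x, fs, strides)$value
      tibble::tibble(
        subject = subj$subject, session = nm,
        lighting = s$lighting, speed = s$speed,
        phase = 1:9,
        alpha_power = phase_bin_series(env, s$fs_eeg, strides,
                                       exclude_outlier_value = TRUE)$value,
        saccade_rate = phase_bin_series(
          ev$onset_s[ev$kind == "saccade"], NA, strides,
          reducer = "event_rate")$value,
        blink_rate = phase_bin_series(
          ev$onset_s[ev$kind == "blink"], NA, strides,
          reducer = "event_rate")$value,
        pupil = if (!pupils[[nm]]$excluded) {
          pb(pupils[[nm]]$clean, s$fs_motion)
        } else NA_real_,
        n_strides = sum(!strides$excluded)
      )
    }))
  }
  list(subject = subj$subject, conditions = conditions, epochs = epochs,
       phase = phase, selection = dec$selection,
       excluded_no_component = no_comp, excluded_pupil = pupil_excluded)
}

#' Run the full cohort analysis
#'
#' Orchestrates per-subject processing and the cohort-level randomization
#' statistics: (a) condition-level 2 (lighting) x 3 (speed) within-subject
#' ANOVAs on alpha power, saccade rate, blink rate and pupil size; (b)
#' epoch-level alpha-by-covariate group tables with one-way ANOVAs; (c)
#' walking-phase profiles with 2 (lighting) x 2 (walking speed) x 9
#' (phase) ANOVAs. Subjects without a selected alpha component are
#' excluded from alpha analyses, subjects with > 99% missing pupil from
#' pupil analyses; both exclusions are logged.
#'
#' @param cohort A `ga_cohort`.
#' @param n_perm Permutations for every randomization test.
#' @param seed Master seed (ICA seeds and permutation seeds derive from
#'   it).
#' @param phase_profiles Include the phase-level analyses.
#' @return A `ga_report` list: `conditions`, `anova_condition` (per DV),
#'   `epoch_groups` + `anova_epoch` (per grouping), `phase` +
#'   `anova_phase` (per DV), `exclusions`, `n_perm`, `seed`.
#' @export
run_full <- function(cohort, n_perm = 1000, seed = 1L,
                     phase_profiles = TRUE) {
  subjects <- lapply(cohort, process_subject, seed = seed,
                     phase_profiles = phase_profiles)
  conditions <- dplyr::bind_rows(lapply(subjects, `[[`, "conditions"))
  exclusions <- tibble::tibble(
    subject = vapply(subjects, `[[`, 0L, "subject"),
    no_alpha_component = vapply(subjects, `[[`, TRUE,
                                "excluded_no_component"),
    pupil_missing = vapply(subjects, `[[`, TRUE, "excluded_pupil")
  )
  ok_alpha <- exclusions$subject[!exclusions$no_alpha_component]
  ok_pupil <- exclusions$subject[!exclusions$pupil_missing]
  cond_dvs <- c(alpha_power = "alpha_power", saccade_rate = "saccade_rate",
                blink_rate = "blink_rate", pupil_mean = "pupil_mean")
  anova_condition <- lapply(seq_along(cond_dvs), function(i) {
    dv <- cond_dvs[i]
    keep <- if (dv == "alpha_power") ok_alpha else if (dv == "pupil_mean") {
      ok_pupil
    } else exclusions$subject
    d <- conditions[conditions$subject %in% keep,
                    c("subject", "lighting", "speed", dv)]
    if (length(unique(d$subject)) < 2) return(NULL)
    perm_anova_within(d, dv, c("lighting", "speed"), n_perm = n_perm,
                      seed = seed + 100 + i)
  })
  names(anova_condition) <- names(cond_dvs)

  epochs <- dplyr::bind_rows(lapply(subjects, `[[`, "epochs"))
  epoch_groups <- list()
  anova_epoch <- list()
  if (nrow(epochs)) {
    groupings <- c("saccade_count", "blink_count", "pupil_quintile")
    for (g in seq_along(groupings)) {
      gr <- tryCatch(group_epochs_by_covariate(epochs, groupings[g]),
                     error = function(e) NULL)
      if (is.null(gr)) next
      epoch_groups[[groupings[g]]] <- gr
      ## keep subjects with every group populated (balanced design)
      full <- names(which(table(gr$subject) == nlevels(gr$group)))
      grb <- gr[gr$subject %in% full, , drop = FALSE]
      if (length(full) >= 2 && nlevels(droplevels(grb$group)) >= 2) {
        anova_epoch[[groupings[g]]] <-
          perm_anova_within(grb, "alpha_power", "group",
                            n_perm = n_perm, seed = seed + 200 + g)
      }
    }
  }

  phase <- dplyr::bind_rows(lapply(subjects, `[[`, "phase"))
  anova_phase <- list()
  if (phase_profiles && nrow(phase)) {
    phase_dvs <- c("alpha_power", "saccade_rate", "blink_rate")
    for (i in seq_along(phase_dvs)) {
      dv <- phase_dvs[i]
      d <- phase[, c("subject", "lighting", "speed", "phase", dv)]
      d <- d[stats::complete.cases(d), , drop = FALSE]
      full <- names(which(table(d$subject) == 2 * 2 * 9))
      d <- d[d$subject %in% full, , drop = FALSE]
      if (length(full) >= 2) {
        anova_phase[[dv]] <-
          perm_anova_within(d, dv, c("lighting", "speed", "phase"),
                            n_perm = n_perm, seed = seed + 300 + i)
      }
    }
  }

  structure(list(
    conditions = dplyr::select(conditions, -"events"),
    events = dplyr::select(
      tidyr::unnest(conditions[, c("subject", "session", "events")],
                    "events"),
      dplyr::all_of(c("subject", "session", "kind", "onset_s", "offset_s",
                      "amplitude"))),
    anova_condition = anova_condition,
    epochs = epochs, epoch_groups = epoch_groups, anova_epoch = anova_epoch,
    phase = phase, anova_phase = anova_phase,
    exclusions = exclusions, n_perm = n_perm, seed = seed
  ), class = "ga_report")
}

#' @export
print.ga_report <- function(x, ...) {
  cat("<ga_report> ", length(unique(x$conditions$subject)), " subjects, ",
      nrow(x$conditions), " sessions (seed ", x$seed, ", ", x$n_perm,
      " permutations)\n", sep = "")
  cat("  excluded: ", sum(x$exclusions$no_alpha_component),
      " without alpha component, ", sum(x$exclusions$pupil_missing),
      " with >99% missing pupil\n", sep = "")
  for (nm in names(x$anova_condition)) {
    a <- x$anova_condition[[nm]]
    if (is.null(a)) next
    cat("  ", nm, ": ",
        paste(sprintf("%s F=%.2f p=%.4f", a$effect, a$statistic,
                      a$p_value), collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Impedance-by-phase control on a dedicated walking cohort
#'
#' Generates (or accepts) walking-only sessions carrying the 125 Hz
#' impedance carrier, extracts the continuous impedance of the four
#' occipital/parietal control electrodes, bins it into the nine walking
#' phases, and tests the phase effect with a one-way randomization ANOVA.
#' With constant true impedance this mirrors the expected null result.
#' Binning uses [phase_bin_series_independent()] (one stride per bin,
#' round-robin): the 200-ms estimation window correlates neighbouring
#' bins of a shared-stride profile, which would make the cell-exchange
#' randomization anti-conservative under the null.
#'
#' @param n_subjects Number of subjects.
#' @param impedance_kohm True (constant) impedance injected.
#' @param config Base [gt_config()]; its seed drives generation.
#' @param n_perm,seed Permutation settings.
#' @return A list: `profiles` (subject x phase tibble), `anova`
#'   (`perm_test`).
#' @export
run_impedance_control <- function(n_subjects = 16, impedance_kohm = 10,
                                  config = gt_config(), n_perm = 1000,
                                  seed = 1L) {
  config$impedance_kohm <- impedance_kohm
  profiles <- dplyr::bind_rows(lapply(seq_len(n_subjects), function(s) {
    sess <- generate_session(config, "light", "normal", subject = s)
    strides <- segment_strides(combined_ankle_speed(sess), sess$fs_motion)
    tr <- mean_impedance_trace(sess)
    tibble::tibble(subject = s, phase = 1:9,
                   impedance = phase_bin_series_independent(
                     tr, sess$fs_eeg, strides)$value)
  }))
  anova <- perm_anova_within(profiles, "impedance", "phase",
                             n_perm = n_perm, seed = seed)
  list(profiles = profiles, anova = anova)
}

#' Write a fixture cohort to disk
#'
#' `tiny` = 4 subjects x 6 sessions x 20 s (fast enough for continuous
#' testing); `standard` = 26 subjects x 6 sessions x 76.5 s (the full
#' study geometry).
#'
#' @param out_dir Output directory.
#' @param scale `"tiny"` or `"standard"`.
#' @param config Template [gt_config()].
#' @return The cohort (invisibly written under `out_dir`).
#' @export
make_fixtures <- function(out_dir, scale = c("tiny", "standard"),
                          config = gt_config()) {
  scale <- match.arg(scale)
  n <- if (scale == "tiny") 4 else 26
  dur <- if (scale == "tiny") 20 else 76.5
  cohort <- generate_cohort(n, config, duration = dur)
  write_cohort(cohort, out_dir)
  invisible(cohort)
}
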