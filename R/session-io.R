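## Session persistence and channel-group bookkeeping. Sessions round-trip
## through plain CSV (readr writes shortest-round-trip doubles, so loading
## is bit-exact) plus a meta.json carrying conditions, rates and the truth
## block.

#' Channel groups of the 24-channel montage
#'
#' @return A list with `scalp` (16 names), `eog` (6 names, left/right x
#'   above/below/canthus), `earlobes` (2), `occipital` (the O1/O2/POz set
#'   used by the component-selection rule) and `impedance` (the
#'   O1/O2/P7/P8 set averaged for the impedance control).
#' @export
channel_map <- function() {
  list(
    scalp = c("Fp1", "Fp2", "Fz", "F7", "F8", "C3", "Cz", "C4",
              "T7", "T8", "P7", "P8", "Pz", "POz", "O1", "O2"),
    eog = c("EOGLA", "EOGLB", "EOGLC", "EOGRA", "EOGRB", "EOGRC"),
    eog_roles = c(EOGLA = "left_above", EOGLB = "left_below",
                  EOGLC = "left_canthus", EOGRA = "right_above",
                  EOGRB = "right_below", EOGRC = "right_canthus"),
    earlobes = c("A1", "A2"),
    occipital = c("O1", "O2", "POz"),
    impedance = c("O1", "O2", "P7", "P8")
  )
}

#' Write one session to a directory
#'
#' Writes `eeg.csv` (column `time` in seconds, then the 24 named channels),
#' `motion.csv` (`time` + 9 sensor-axis columns), `pupil.csv`
#' (`time`, `radius`; 0 marks missing) and `meta.json` (conditions, rates,
#' duration, truth block).
#'
#' @param session A `session_recording`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n_e <- nrow(session$eeg)
  eeg_df <- tibble::as_tibble(session$eeg)
  eeg_df <- dplyr::bind_cols(
    tibble::tibble(time = (seq_len(n_e) - 1) / session$fs_eeg), eeg_df)
  readr::write_csv(eeg_df, file.path(path, "eeg.csv"), progress = FALSE)
  n_m <- nrow(session$motion)
  mot_df <- dplyr::bind_cols(
    tibble::tibble(time = (seq_len(n_m) - 1) / session$fs_motion),
    tibble::as_tibble(session$motion))
  readr::write_csv(mot_df, file.path(path, "motion.csv"), progress = FALSE)
  pup_df <- tibble::tibble(time = (seq_len(length(session$pupil)) - 1) /
                             session$fs_motion,
                           radius = session$pupil)
  readr::write_csv(pup_df, file.path(path, "pupil.csv"), progress = FALSE)
  meta <- list(lighting = session$lighting, speed = session$speed,
               duration = session$duration, fs_eeg = session$fs_eeg,
               fs_motion = session$fs_motion, subject = session$subject,
               truth = session$truth)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load and validate one session directory
#'
#' Validates the schema against [channel_map()]: every scalp, EOG and
#' earlobe channel must be present (the error names the absent channels)
#' and stream lengths must be consistent with the metadata sampling rates.
#'
#' @param path Directory written by [write_session()].
#' @return A `session_recording`.
#' @export
load_session <- function(path) {
  for (f in c("eeg.csv", "motion.csv", "pupil.csv", "meta.json")) {
    if (!file.exists(file.path(path, f))) {
      stop("session file missing: ", file.path(path, f), call. = FALSE)
    }
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  cm <- channel_map()
  ## base read.csv: strtod parsing is correctly rounded, so the CSV
  ## round-trip with readr's shortest-representation writer is bit-exact
  eeg_df <- utils::read.csv(file.path(path, "eeg.csv"), check.names = FALSE)
  wanted <- c(cm$scalp, cm$eog, cm$earlobes)
  absent <- setdiff(wanted, names(eeg_df))
  if (length(absent)) {
    stop("EEG channel(s) missing: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  eeg <- as.matrix(eeg_df[wanted])
  if (abs(nrow(eeg) - meta$duration * meta$fs_eeg) > 1) {
    stop("EEG length ", nrow(eeg), " inconsistent with ", meta$duration,
         " s at ", meta$fs_eeg, " Hz", call. = FALSE)
  }
  mot_df <- utils::read.csv(file.path(path, "motion.csv"), check.names = FALSE)
  motion <- as.matrix(mot_df[setdiff(names(mot_df), "time")])
  if (abs(nrow(motion) - meta$duration * meta$fs_motion) > 1) {
    stop("motion length inconsistent with metadata sampling rate",
         call. = FALSE)
  }
  pup_df <- utils::read.csv(file.path(path, "pupil.csv"), check.names = FALSE)
  truth <- meta$truth
  if (!is.null(truth)) {
    for (f in c("saccade_times", "blink_times", "stride_boundaries",
                "pupil_missing")) {
      truth[[f]] <- as.numeric(truth[[f]] %||% numeric(0))
    }
    if (!is.null(truth$alpha_topography)) {
      truth$alpha_topography <- unlist(truth$alpha_topography)
    }
  }
  structure(list(
    eeg = eeg, fs_eeg = meta$fs_eeg,
    motion = motion, fs_motion = meta$fs_motion,
    pupil = pup_df$radius,
    lighting = meta$lighting, speed = meta$speed, duration = meta$duration,
    subject = meta$subject, truth = truth
  ), class = "session_recording")
}

#' Write a whole cohort (one directory per subject)
#'
#' @param cohort A `ga_cohort` from [generate_cohort()].
#' @param path Root directory; sessions land in
#'   `subject-XX/<lighting>_<speed>/`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ga_cohort"))
  for (subj in cohort) {
    sdir <- file.path(path, sprintf("subject-%02d", subj$subject))
    for (key in names(subj$sessions)) {
      write_session(subj$sessions[[key]], file.path(sdir, key))
    }
  }
  invisible(path)
}

#' Load a cohort written by [write_cohort()]
#'
#' @param path Root directory.
#' @return A `ga_cohort`.
#' @export
load_cohort <- function(path) {
  sdirs <- sort(list.dirs(path, recursive = FALSE))
  subjects <- lapply(sdirs, function(sdir) {
    keys <- sort(list.dirs(sdir, recursive = FALSE, full.names = FALSE))
    sessions <- lapply(keys, function(k) load_session(file.path(sdir, k)))
    names(sessions) <- keys
    list(subject = sessions[[1]]$subject, config = NULL,
         sessions = sessions, order = keys)
  })
  structure(subjects, class = "ga_cohort")
}

#' Missing-sample mask of a raw pupil trace
#'
#' Any non-finite value or exact 0 (the tracker's track-loss sentinel)
#' counts as missing.
#'
#' @param pupil Numeric vector.
#' @return Logical vector.
#' @export
pupil_missing_mask <- function(pupil) !is.finite(pupil) | pupil == 0

#' Re-reference scalp EEG to the grand average of the 16 scalp channels
#'
#' Subtracts, at every sample, the mean of the 16 scalp channels from each
#' scalp channel; EOG and earlobe channels are left untouched. The
#' operation is idempotent and leaves the scalp channel-mean at zero for
#' every sample.
#'
#' @param eeg Samples-by-channels matrix with named columns.
#' @param cm A [channel_map()].
#' @return The re-referenced matrix, same shape.
#' @export
rereference_to_average <- function(eeg, cm = channel_map()) {
  scalp <- intersect(cm$scalp, colnames(eeg))
  if (length(scalp) < 2) {
    stop("need at least 2 scalp channels to re-reference", call. = FALSE)
  }
  ref <- rowMeans(eeg[, scalp, drop = FALSE])
  eeg[, scalp] <- eeg[, scalp, drop = FALSE] - ref
  eeg
}
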