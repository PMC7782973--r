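## Randomization statistics: within-subject permutation ANOVA (cell labels
## exchanged within each participant), sign-flipping paired test, the
## MAD-median outlier rule, Benjamini-Yekutieli FDR, and the epoch-grouping
## analyses linking alpha power to eye metrics.

#' MAD-median outlier rule
#'
#' Flags value `p` of a sample `P` as an outlier iff
#' `|p - median(P)| * 0.6745 > 2.24 * median(|P - median(P)|)`.
#' When the MAD-median is zero (more than half the values identical) the
#' rule degenerates to flagging every value different from the median.
#'
#' @param values Numeric vector (>= 3 finite values).
#' @return A list (`mad_median_verdict`) with `values`, `median`,
#'   `mad_median`, and the logical `outlier` mask.
#' @export
mad_median_outliers <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("need at least 3 finite values", call. = FALSE)
  med <- median(v)
  madm <- median(abs(v - med))
  dev <- abs(values - med) * 0.6745
  outlier <- if (madm == 0) {
    is.finite(values) & values != med
  } else {
    is.finite(values) & dev > 2.24 * madm
  }
  structure(list(values = values, median = med, mad_median = madm,
                 outlier = outlier),
            class = "mad_median_verdict")
}

## ---------------------------------------------------------------------
## Balanced fully-crossed within-subject ANOVA, closed form.
## Data: Y (subjects x cells); `levels` gives the factor level counts, with
## cells varying fastest in the LAST factor (row-major over factor order).
## For effect E (subset of within factors), with subject S:
##   SS_E    = sum_{U subseteq E} (-1)^{|E|-|U|} Q_U
##   F_E     = (SS_E/df_E) / (SS_{E+S}/df_{E+S})
## where Q_U = sum of (marginal totals)^2 / (obs per total).

.cell_factor_index <- function(levels) {
  ## matrix cells x factors of level indices, last factor fastest
  k <- length(levels)
  idx <- expand.grid(rev(lapply(levels, seq_len)))[, k:1, drop = FALSE]
  colnames(idx) <- names(levels)
  as.matrix(idx)
}

## Precompute, per subset of factors, the cell->group indicator matrix.
.anova_plan <- function(levels) {
  k <- length(levels)
  cells <- prod(levels)
  idx <- .cell_factor_index(levels)
  subsets <- list(integer(0))
  for (f in seq_len(k)) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, f)))
  }
  groups <- lapply(subsets, function(s) {
    if (!length(s)) return(NULL)  # grand total
    key <- apply(idx[, s, drop = FALSE], 1, paste, collapse = "\r")
    g <- match(key, unique(key))
    m <- matrix(0, cells, max(g))
    m[cbind(seq_len(cells), g)] <- 1
    m
  })
  effects <- subsets[-1]  # all non-empty subsets are testable effects
  list(levels = levels, cells = cells, subsets = subsets, groups = groups,
       effects = effects)
}

## Q_U for every subset, with and without subject.
.anova_F <- function(Y, plan) {
  n <- nrow(Y)
  cells <- plan$cells
  tot <- sum(Y)
  q0 <- tot^2 / (n * cells)
  q_sub <- sum(rowSums(Y)^2) / cells          # subject-only
  nsub <- length(plan$subsets)
  q_between <- numeric(nsub)   # subject averaged out
  q_with <- numeric(nsub)      # subject retained
  q_between[1] <- q0
  q_with[1] <- q_sub
  for (i in seq_len(nsub)[-1]) {
    m <- plan$groups[[i]]
    per <- cells / ncol(m)                    # cells per group
    gt <- Y %*% m                             # n x groups totals
    q_with[i] <- sum(gt^2) / per
    q_between[i] <- sum(colSums(gt)^2) / (n * per)
  }
  ## inclusion-exclusion over subsets
  out <- lapply(plan$effects, function(e) {
    ss_e <- 0
    ss_es <- 0
    for (i in seq_len(nsub)) {
      s <- plan$subsets[[i]]
      if (all(s %in% e)) {
        sgn <- (-1)^(length(e) - length(s))
        ss_e <- ss_e + sgn * q_between[i]
        ss_es <- ss_es + sgn * (q_with[i] - q_between[i])
      }
    }
    df_e <- prod(plan$levels[e] - 1)
    df_es <- df_e * (n - 1)
    ms_err <- ss_es / df_es
    f <- if (ms_err > 0) {
      (ss_e / df_e) / ms_err
    } else if (ss_e <= 0) 0 else Inf   # no variance anywhere -> null F
    list(ss = ss_e, df1 = df_e, df2 = df_es, F = f)
  })
  names(out) <- vapply(plan$effects, function(e) {
    paste(names(plan$levels)[e], collapse = ":")
  }, "")
  out
}

## Permute cell labels independently within each subject (the quoted
## randomization scheme): returns Y with every row scrambled.
.permute_within_rows <- function(Y) {
  n <- nrow(Y); c <- ncol(Y)
  o <- order(rep(seq_len(n), each = c), runif(n * c))
  matrix(t(Y)[o], n, c, byrow = TRUE)
}

#' Randomization within-subject ANOVA
#'
#' Observed F statistics for every main effect and interaction of a
#' complete balanced within-subject design, with p-values from a null
#' distribution built by randomly exchanging the cell labels within each
#' participant (full reassignment of all cells, the same shuffle serving
#' every effect). `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param data Long-format data frame with one row per subject x cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor column names.
#' @param subject Name of the subject identifier column.
#' @param n_perm Number of permutations (default 5000; < 100 warns).
#' @param seed Integer seed, recorded in the result.
#' @return A `perm_test` tibble with one row per effect: `effect`,
#'   `statistic` (observed F), `df1`, `df2`, `p_value`, `n_perm`, `seed`.
#' @export
perm_anova_within <- function(data, dv, within, subject = "subject",
                              n_perm = 5000, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100: permutation p-values very coarse")
  df <- as.data.frame(data)
  for (w in within) {
    if (!is.factor(df[[w]])) df[[w]] <- factor(df[[w]])
    df[[w]] <- droplevels(df[[w]])
  }
  levels <- vapply(within, function(w) nlevels(df[[w]]), 0L)
  names(levels) <- within
  subj <- factor(df[[subject]])
  cells <- prod(levels)
  ## order rows: subject-major, factors row-major (last fastest)
  key <- do.call(order, c(list(subj), lapply(within, function(w) df[[w]])))
  df <- df[key, , drop = FALSE]
  subj <- subj[key]
  n <- nlevels(subj)
  if (nrow(df) != n * cells) {
    stop("design unbalanced: expected ", n * cells, " rows (", n,
         " subjects x ", cells, " cells), got ", nrow(df), call. = FALSE)
  }
  ## after subject-major ordering rows are factor-crossed per subject, but
  ## the within-subject cell order must match the plan's row-major layout
  idx <- .cell_factor_index(levels)
  lev_codes <- vapply(within, function(w) as.integer(df[[w]]),
                      integer(nrow(df)))
  per_subj <- matrix(seq_len(nrow(df)), ncol = n)  # rows of each subject
  Y <- matrix(NA_real_, n, cells)
  plan_key <- apply(idx, 1, paste, collapse = "\r")
  for (s in seq_len(n)) {
    rows <- per_subj[, s]
    row_key <- apply(lev_codes[rows, , drop = FALSE], 1, paste,
                     collapse = "\r")
    Y[s, ] <- df[[dv]][rows][match(plan_key, row_key)]
  }
  if (anyNA(Y)) stop("design unbalanced: missing subject x cell values",
                     call. = FALSE)
  plan <- .anova_plan(levels)
  obs <- .anova_F(Y, plan)
  set.seed(seed)
  exceed <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    fp <- .anova_F(.permute_within_rows(Y), plan)
    for (j in seq_along(obs)) {
      if (!is.na(fp[[j]]$F) && !is.na(obs[[j]]$F) &&
          fp[[j]]$F >= obs[[j]]$F) {
        exceed[j] <- exceed[j] + 1
      }
    }
  }
  out <- tibble::tibble(
    effect = names(obs),
    statistic = unname(vapply(obs, function(o) o$F, 0)),
    df1 = unname(vapply(obs, function(o) o$df1, 0)),
    df2 = unname(vapply(obs, function(o) o$df2, 0)),
    p_value = (1 + exceed) / (1 + n_perm),
    n_perm = n_perm, seed = seed
  )
  class(out) <- c("perm_test", class(out))
  out
}

#' Randomization paired t-test (sign flipping)
#'
#' Two-tailed test of the mean within-subject difference `x - y`; the null
#' distribution flips the sign of each subject's difference independently.
#'
#' @param x,y Equal-length paired samples (n >= 2).
#' @param n_perm Number of sign-flip draws.
#' @param seed Integer seed.
#' @return A one-row `perm_test` tibble: `effect = "paired"`, `statistic`
#'   (observed mean difference), `p_value`, `n_perm`, `seed`, `n`.
#' @export
perm_paired_t <- function(x, y, n_perm = 5000, seed = 1L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  obs <- mean(d)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  null <- colMeans(signs * d)
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  out <- tibble::tibble(effect = "paired", statistic = obs,
                        df1 = NA_real_, df2 = NA_real_, p_value = p,
                        n_perm = n_perm, seed = seed)
  class(out) <- c("perm_test", class(out))
  out
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up FDR control valid under arbitrary dependency (the step-up rule
#' with the `c(m) = sum(1/i)` correction factor), plus the significance
#' mask at the given q.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q FDR level for the mask (default 0.05).
#' @return A tibble with `p_value`, `p_adjusted`, `significant`.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- p.adjust(p_values, method = "BY")
  tibble::tibble(p_value = p_values, p_adjusted = adj,
                 significant = !is.na(adj) & adj <= q)
}

#' Group 1-s epochs by eye-movement covariates and average alpha power
#'
#' Implements the epoch-level exclusion and grouping rules: MAD-median
#' alpha outliers (the `outlier` column) are dropped first; epochs with 5
#' or more saccades, or more than 1 blink, are excluded from the
#' respective analyses; saccade groups are counts 0-4, blink groups 0-1,
#' and pupil epochs are split per participant into five equal-count groups
#' from smallest to largest mean pupil size (ties broken by epoch order).
#'
#' @param epochs Tibble with one row per epoch: `subject`, `alpha_power`,
#'   `outlier` (logical), and the grouping covariate -- `saccade_count`,
#'   `blink_count` or `pupil` as required.
#' @param grouping `"saccade_count"`, `"blink_count"` or
#'   `"pupil_quintile"`.
#' @return A tibble with `subject`, `group`, `alpha_power` (mean over the
#'   subject's epochs in that group) and `n_epochs`. Empty groups are
#'   dropped with a warning.
#' @export
group_epochs_by_covariate <- function(epochs,
                                      grouping = c("saccade_count",
                                                   "blink_count",
                                                   "pupil_quintile")) {
  grouping <- match.arg(grouping)
  df <- dplyr::filter(epochs, !.data$outlier)
  if (grouping == "saccade_count") {
    df <- dplyr::filter(df, .data$saccade_count <= 4)
    df$group <- factor(df$saccade_count, levels = 0:4)
  } else if (grouping == "blink_count") {
    df <- dplyr::filter(df, .data$blink_count <= 1)
    df$group <- factor(df$blink_count, levels = 0:1)
  } else {
    df <- df[is.finite(df$pupil), , drop = FALSE]
    df <- df |>
      dplyr::group_by(.data$subject) |>
      dplyr::mutate(group = {
        r <- rank(.data$pupil, ties.method = "first")
        factor(ceiling(r / (length(r) / 5)), levels = 1:5)
      }) |>
      dplyr::ungroup()
  }
  out <- df |>
    dplyr::group_by(.data$subject, .data$group, .drop = FALSE) |>
    dplyr::summarise(alpha_power = mean(.data$alpha_power),
                     n_epochs = dplyr::n(), .groups = "drop")
  empty <- out$n_epochs == 0
  if (any(empty)) {
    warning(sum(empty), " empty subject x group cell(s) dropped")
    out <- out[!empty, , drop = FALSE]
  }
  out
}

#' Frequency-wise speed comparison with BY-FDR masking
#'
#' For each 1-Hz frequency bin between 2 and 50 Hz, a one-way
#' within-subject randomization ANOVA compares the per-session power
#' spectra across the three speed levels, separately per lighting level;
#' the per-frequency p-values are BY-FDR masked.
#'
#' @param psd_tbl Tibble with columns `subject`, `lighting`, `speed`,
#'   `freq`, `power` (one row per subject x condition x frequency).
#' @param n_perm,seed Permutation settings passed to
#'   [perm_anova_within()].
#' @return A tibble with `lighting`, `freq`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
frequencywise_speed_scan <- function(psd_tbl, n_perm = 1000, seed = 1L) {
  freqs <- sort(unique(psd_tbl$freq))
  freqs <- freqs[freqs >= 2 & freqs <= 50]
  out <- lapply(unique(psd_tbl$lighting), function(lt) {
    rows <- lapply(seq_along(freqs), function(i) {
      f <- freqs[i]
      d <- dplyr::filter(psd_tbl, .data$lighting == lt, .data$freq == f)
      r <- perm_anova_within(d, "power", "speed", n_perm = n_perm,
                             seed = seed + i)
      tibble::tibble(lighting = lt, freq = f, statistic = r$statistic[1],
                     p_value = r$p_value[1])
    })
    res <- dplyr::bind_rows(rows)
    adj <- fdr_adjust(res$p_value)
    res$p_adjusted <- adj$p_adjusted
    res$significant <- adj$significant
    res
  })
  dplyr::bind_rows(out)
}
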