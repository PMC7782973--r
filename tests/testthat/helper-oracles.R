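# Independent oracles, deliberately brute force.

# MAD-median rule straight off the printed formula
oracle_mad_mask <- function(p) {
  med <- median(p)
  madm <- median(abs(p - med))
  if (madm == 0) return(p != med)
  abs(p - med) * 0.6745 > 2.24 * madm
}

# Benjamini-Yekutieli step-up, literal definition
oracle_by_adjust <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ranked <- p[o]
  adj <- pmin(1, ranked * m * cm / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Benjamini-Hochberg discoveries (for the BY-never-more-than-BH check)
oracle_bh_discoveries <- function(p, q = 0.05) {
  sum(p.adjust(p, "BH") <= q)
}

# event matching: recall of truth times and count of unmatched detections
match_events <- function(truth, detected, tol) {
  if (!length(truth)) {
    return(list(recall = NA_real_, false_events = length(detected)))
  }
  hit <- vapply(truth, function(t) any(abs(detected - t) <= tol), TRUE)
  false_ev <- if (!length(detected)) 0L else {
    sum(!vapply(detected, function(d) any(abs(truth - d) <= tol), TRUE))
  }
  list(recall = mean(hit), false_events = false_ev)
}

# first-harmonic relative modulation depth of a 9-bin phase profile,
# for profiles shaped value ~ a * (1 - m*cos(2*pi*phase_frac))
profile_cosine_depth <- function(values) {
  centers <- ((1:9) - 0.5) / 9
  c_hat <- 2 * mean(values * cos(2 * pi * centers))
  -c_hat / mean(values)
}
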