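# Shared fixtures, generated once per test run and cached.

.ga_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .ga_cache)) assign(key, force(expr), .ga_cache)
  get(key, .ga_cache)
}

# one standard-length subject (6 x 76.5 s) and its decomposition
std_subject_sessions <- function() {
  cached("std_sessions", {
    cfg <- gt_config(seed = 7L)
    keys <- paste(rep(c("light", "dark"), each = 3),
                  rep(c("still", "slow", "normal"), 2), sep = "_")
    sessions <- lapply(keys, function(k) {
      p <- strsplit(k, "_")[[1]]
      generate_session(cfg, p[1], p[2], subject = 1L)
    })
    names(sessions) <- keys
    sessions
  })
}

std_subject_dec <- function() {
  cached("std_dec", pca_reduce_then_ica(std_subject_sessions(), seed = 7L))
}

tiny_cohort <- function() {
  cached("tiny_cohort", generate_cohort(4, gt_config(seed = 21L),
                                        duration = 20))
}

# a walking session with default parameters
walk_session <- function() {
  cached("walk_session",
         generate_session(gt_config(seed = 13L), "dark", "normal"))
}
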