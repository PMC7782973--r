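# A hand-built decomposition object for the operations that only need
# spectra/topography/activations, independent of the ICA fit.
fake_dec <- function(activations, topography, fs = 500,
                     selected = rep(TRUE, ncol(topography))) {
  freq <- welch_psd(activations[[1]][, 1], fs)$freq
  uc <- do.call(rbind, activations)
  psd <- vapply(seq_len(ncol(uc)), function(j) welch_psd(uc[, j], fs)$power,
                numeric(length(freq)))
  dec <- structure(list(unmixing = NULL, topography = topography,
                        activations = activations, psd = psd, freq = freq,
                        fs = fs, seed = 0L),
                   class = "alpha_decomposition")
  dec$selection <- tibble::tibble(component = seq_along(selected),
                                  selected = selected)
  dec
}

test_that("Infomax recovers known super-Gaussian sources through a random
           mixing matrix", {
  set.seed(8)
  n <- 20000
  t <- seq_len(n) / 500
  # alpha-like bursts, sparse spikes, Laplacian noise: all super-Gaussian
  burst <- exp(1.2 * sin(2 * pi * 0.2 * t))
  s1 <- burst * sin(2 * pi * 10 * t)
  s2 <- rbinom(n, 1, 0.01) * rnorm(n, sd = 6)
  s3 <- sign(rnorm(n)) * rexp(n)
  S <- scale(cbind(s1, s2, s3))
  A <- matrix(rnorm(16 * 3), 16, 3)
  X <- S %*% t(A)
  # whiten to 3 dims, then unmix
  sv <- svd(X, nu = 0)
  K <- sv$v[, 1:3] %*% diag(1 / (sv$d[1:3] / sqrt(n - 1)))
  Z <- X %*% K
  W <- infomax_ica(Z, seed = 4L)
  U <- Z %*% t(W)
  cors <- abs(cor(U, S))
  best <- apply(cors, 2, max)
  expect_true(all(best > 0.95))
  # each recovered component matches a distinct source
  expect_setequal(apply(cors, 2, which.max), 1:3)
})

test_that("already-independent whitened sources are recovered near-exactly
           and the fit is seed-deterministic", {
  set.seed(3)
  Z <- scale(matrix(sign(rnorm(30000)) * rexp(30000), ncol = 3))
  W1 <- infomax_ica(Z, seed = 9L)
  W2 <- infomax_ica(Z, seed = 9L)
  expect_identical(W1, W2)
  U <- Z %*% t(W1)
  cors <- abs(cor(U, Z))
  expect_true(all(apply(cors, 2, max) > 0.99))
})

test_that("component selection applies the four criteria exactly", {
  cm <- channel_map()
  freq <- 0:250
  # decomposition with hand-drawn spectra so every rule instance is exact
  psd_dec <- function(psd_col, topo) {
    dec <- structure(list(psd = cbind(psd_col), freq = freq,
                          topography = topo, fs = 500),
                     class = "alpha_decomposition")
    dec
  }
  topo_occ <- matrix(0, 16, 1, dimnames = list(cm$scalp, NULL))
  topo_occ["O1", 1] <- 1
  topo_frontal <- matrix(0, 16, 1, dimnames = list(cm$scalp, NULL))
  topo_frontal["Fz", 1] <- 1

  # broad 10 Hz peak, width 6 Hz (minima at 7 and 13), 5x the 20-50 mean
  broad <- rep(1, length(freq))
  broad[freq >= 8 & freq <= 12] <- c(2, 3.5, 5, 3.5, 2)
  broad[freq %in% c(7, 13)] <- 0.8
  s1 <- select_alpha_components(psd_dec(broad, topo_occ))
  expect_true(s1$selected[1])
  expect_equal(s1$peak_freq, 10)
  expect_equal(s1$peak_width, 6)
  expect_gte(s1$peak_power, 3 * s1$hf_mean)

  # same spectrum, frontal topography -> rejected by criterion 4 alone
  s2 <- select_alpha_components(psd_dec(broad, topo_frontal))
  expect_false(s2$selected[1])
  expect_false(s2$occipital_max[1])
  expect_true(s2$wide_enough[1])

  # narrow 10 Hz line (flanking minima at 9 and 11) -> criterion 2
  narrow <- rep(1, length(freq))
  narrow[freq == 10] <- 5
  narrow[freq %in% c(9, 11)] <- 0.8
  s3 <- select_alpha_components(psd_dec(narrow, topo_occ))
  expect_false(s3$selected[1])
  expect_false(s3$wide_enough[1])
  expect_equal(s3$peak_width[1], 2)

  # broadband-high component -> criterion 3
  broadband <- rep(1, length(freq))
  broadband[freq >= 8 & freq <= 12] <- c(2, 2.4, 2.6, 2.4, 2)
  broadband[freq %in% c(7, 13)] <- 0.9
  broadband[freq >= 20 & freq <= 50] <- 1.2
  s4 <- select_alpha_components(psd_dec(broadband, topo_occ))
  expect_false(s4$selected[1])
  expect_false(s4$above_broadband[1])

  # with several 6-14 Hz peaks the widest wins
  double <- rep(1, length(freq))
  double[freq == 7] <- 4          # narrow: minima at 6 and 8
  double[freq %in% c(6, 8)] <- 0.6
  double[freq >= 10 & freq <= 14] <- c(2, 3, 3.6, 3, 2)  # wide, peak at 12
  double[freq %in% c(9, 15)] <- 0.6
  s5 <- select_alpha_components(psd_dec(double, topo_occ))
  expect_equal(s5$peak_freq[1], 12)
  expect_equal(s5$peak_width[1], 6)
})

test_that("selection is a pure predicate: permuting component order never
           changes the selected set", {
  dec <- std_subject_dec()
  perm <- rev(seq_len(ncol(dec$psd)))
  dec_p <- dec
  dec_p$psd <- dec$psd[, perm]
  dec_p$topography <- dec$topography[, perm]
  sel_p <- select_alpha_components(dec_p)
  expect_identical(sel_p$selected, dec$selection$selected[perm])
})

test_that("session alpha power averages component spectra as specified", {
  fs <- 500
  cm <- channel_map()
  t <- seq(1 / fs, 20, by = 1 / fs)
  act <- cbind(sin(2 * pi * 10 * t))
  topo <- matrix(0, 16, 1, dimnames = list(cm$scalp, NULL))
  topo["O1", ] <- 1
  d1 <- fake_dec(list(a = act), topo)
  a1 <- component_session_alpha(d1)
  ref <- welch_psd(act[, 1], fs)
  expect_equal(a1$alpha_power,
               mean(ref$power[ref$freq >= 8 & ref$freq <= 12]))
  # two identical components average to the same value
  d2 <- fake_dec(list(a = cbind(act, act)),
                 cbind(topo, topo))
  expect_equal(component_session_alpha(d2)$alpha_power, a1$alpha_power)
  # empty selection signals subject-level exclusion
  d3 <- fake_dec(list(a = act), topo, selected = FALSE)
  expect_error(component_session_alpha(d3), "excluded")
})

test_that("back-projection places power on the carrying sensors", {
  fs <- 500
  cm <- channel_map()
  t <- seq(1 / fs, 20, by = 1 / fs)
  act <- cbind(sin(2 * pi * 10 * t))
  topo <- matrix(0, 16, 1, dimnames = list(cm$scalp, NULL))
  topo["O1", ] <- 1
  m1 <- backproject_alpha_topography(fake_dec(list(a = act), topo))
  expect_gt(m1$alpha_power[m1$channel == "O1"], 0)
  expect_true(all(m1$alpha_power[m1$channel != "O1"] < 1e-12))
  # mirrored O1/O2 weights give a symmetric map
  topo2 <- topo; topo2["O1", ] <- 0.7; topo2["O2", ] <- 0.7
  m2 <- backproject_alpha_topography(fake_dec(list(a = act), topo2))
  expect_equal(m2$alpha_power[m2$channel == "O1"],
               m2$alpha_power[m2$channel == "O2"], ignore_attr = TRUE)
})

test_that("epoch grid bookkeeping: 152 epochs per 76.5-s session and the
           epoch mean reproduces Welch session power", {
  dec <- std_subject_dec()
  for (nm in c("light_still", "dark_normal")) {
    ep <- epoch_alpha_power(dec, nm)
    expect_equal(nrow(ep), 152)
    welch <- component_session_alpha(dec, nm)$alpha_power
    expect_lt(abs(mean(ep$alpha_power) - welch) / welch, 1e-6)
  }
})

test_that("a stationary sine yields equal epoch powers", {
  fs <- 500
  cm <- channel_map()
  t <- seq(1 / fs, 20, by = 1 / fs)
  act <- cbind(sin(2 * pi * 10 * t))
  topo <- matrix(0, 16, 1, dimnames = list(cm$scalp, NULL))
  topo["O1", ] <- 1
  ep <- epoch_alpha_power(fake_dec(list(a = act), topo), "a")
  expect_lt(diff(range(ep$alpha_power)) / mean(ep$alpha_power), 0.01)
})

test_that("alpha envelope recovers amplitude and AM modulation depth", {
  fs <- 500
  cm <- channel_map()
  t <- seq(1 / fs, 30, by = 1 / fs)
  topo <- matrix(0, 16, 1, dimnames = list(cm$scalp, NULL))
  topo["O1", ] <- 1
  amp <- 2.5
  d1 <- fake_dec(list(a = cbind(amp * sin(2 * pi * 10 * t))), topo)
  env <- sqrt(alpha_envelope(d1, "a"))
  mid <- 2000:13000
  expect_lt(abs(mean(env[mid]) - amp) / amp, 0.02)
  # DC input -> envelope ~ 0
  d0 <- fake_dec(list(a = cbind(rep(1, length(t)))), topo)
  expect_lt(max(alpha_envelope(d0, "a")), 1e-4)
  # AM at 1 Hz, depth 0.3: recovered within 5%
  m <- 0.3
  am <- (1 + m * cos(2 * pi * 1 * t)) * sin(2 * pi * 10 * t)
  dam <- fake_dec(list(a = cbind(am)), topo)
  enva <- sqrt(alpha_envelope(dam, "a"))[mid]
  tm <- t[mid]
  depth <- 2 * Mod(mean(enva * exp(-2i * pi * 1 * tm))) / mean(enva)
  expect_lt(abs(depth - m) / m, 0.05)
})

test_that("the full decomposition finds occipital alpha components on a
           synthetic subject and orders sessions correctly", {
  dec <- std_subject_dec()
  expect_gte(sum(dec$selection$selected), 1)
  sel <- dec$selection[dec$selection$selected, ]
  expect_true(all(sel$peak_freq >= 6 & sel$peak_freq <= 14))
  expect_true(all(sel$peak_width >= 4))
  alpha <- component_session_alpha(dec)
  a <- setNames(alpha$alpha_power, alpha$session)
  expect_gt(a[["light_still"]], a[["light_normal"]])
  expect_gt(a[["dark_still"]], a[["dark_normal"]])
  topo <- backproject_alpha_topography(dec)
  expect_true(topo$channel[which.max(topo$alpha_power)] %in%
                channel_map()$occipital)
})
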