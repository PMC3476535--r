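fs <- 512

test_that("a pure sinusoid peaks at the nearest grid bin in every column", {
  x <- sin(2 * pi * 10 * (0:(6 * fs - 1)) / fs)
  sp <- morlet_spectrogram(x, fs)
  nearest <- which.min(abs(sp$freqs - 10))
  expect_true(all(apply(sp$values, 1, which.max) == nearest))
})

test_that("amplitude doubling shifts every value by 10*log10(4) dB", {
  set.seed(1)
  x <- stats::rnorm(4 * fs)
  s1 <- morlet_spectrogram(x, fs)
  s2 <- morlet_spectrogram(2 * x, fs)
  expect_equal(s2$values - s1$values,
               matrix(10 * log10(4), nrow(s1$values), ncol(s1$values)),
               tolerance = 1e-9)
})

test_that("L2-normalised wavelets give flat expected power on white noise", {
  set.seed(2)
  ## compare two grid bins an octave apart over repeated draws
  fr <- c(10, 20)
  pw <- replicate(60, {
    s <- morlet_spectrogram(stats::rnorm(3 * fs), fs, freqs = fr)
    colMeans(10^(s$values / 10))
  })
  m <- rowMeans(pw)
  expect_lt(abs(m[1] / m[2] - 1), 0.1)
  expect_lt(abs(m[1] - 1), 0.1)      # unit-variance input -> unit power
})

test_that("signals shorter than the window are rejected", {
  expect_error(morlet_spectrogram(stats::rnorm(100), fs), "shorter")
})

test_that("baseline normalization zeroes the baseline and is shift invariant", {
  set.seed(3)
  ev <- quick_events(1)
  x <- stats::rnorm(attr(ev, "n_samples"))
  sp <- epoch_spectrogram(x, fs, ev$onset_sample[1], ev$offset_sample[1])
  spn <- baseline_normalize(sp)
  bcols <- spn$times >= -1 & spn$times <= -0.5
  expect_equal(max(abs(colMeans(spn$values[bcols, ]))), 0, tolerance = 1e-9)
  ## adding a constant dB offset before normalizing changes nothing
  sp2 <- sp; sp2$values <- sp$values + 7.5
  expect_equal(baseline_normalize(sp2)$values, spn$values,
               tolerance = 1e-9)
})

test_that("time-warping is the identity at the target duration and preserves
          affine time courses", {
  ev <- quick_events(1, dur_s = 3)
  sp <- structure(list(
    values = matrix(rep(seq(-1.5, 4.5, by = 0.025), 2),
                    ncol = 2) , times = seq(-1.5, 4.5, by = 0.025),
    freqs = c(10, 20), kind = "normalized", offset = 3),
    class = "spectrogram")
  w <- timewarp(sp, target_duration = 3)
  keep <- sp$times >= -1 - 1e-9 & sp$times <= 4 + 1e-9
  expect_equal(w$values[, 1], sp$values[keep, 1], tolerance = 1e-9)
  ## affine course stays affine with matched endpoints under stretching
  w2 <- timewarp(sp, target_duration = 4.5)
  mid <- w2$times >= 0 & w2$times <= 4.5
  tv <- w2$times[mid]; vv <- w2$values[mid, 1]
  fitl <- stats::lm(vv ~ tv)
  expect_lt(max(abs(stats::residuals(fitl))), 1e-9)
  expect_equal(vv[1], 0, tolerance = 1e-9)
  expect_equal(vv[length(vv)], 3, tolerance = 1e-9)
})

test_that("warp then inverse-warp recovers a smooth map", {
  tt <- seq(-1.5, 4.5, by = 0.025)
  smooth <- outer(sin(tt), c(1, 0.5)) + outer(cos(0.3 * tt), c(0, 1))
  sp <- structure(list(values = smooth, times = tt, freqs = c(10, 20),
                       kind = "normalized", offset = 3),
                  class = "spectrogram")
  w <- timewarp(sp, target_duration = 3.6)
  back <- timewarp(w, offset = 3.6, target_duration = 3)
  keep <- tt >= -1 - 1e-9 & tt <= 4 + 1e-9
  expect_equal(back$values, sp$values[keep, ], tolerance = 5e-3)
  expect_error(timewarp(sp, offset = 0, target_duration = 3), "offset")
})

test_that("bootstrap mask: alpha = 1 marks everything significant", {
  set.seed(4)
  ev <- quick_events(6)
  x <- stats::rnorm(attr(ev, "n_samples"))
  specs <- quick_norm_specs(x, ev)
  mk <- bootstrap_mask(specs, alpha = 1, n_boot = 60, seed = 1)
  expect_true(all(mk$mask))
  expect_equal(mk$values, mk$grand)
})

test_that("bootstrap mask detects a planted sustained power drop", {
  set.seed(5)
  ev <- quick_events(25, dur_s = 3)
  n <- attr(ev, "n_samples")
  x <- stats::rnorm(n)
  bf <- signal::butter(4, c(8, 12) / (fs / 2), "pass")
  carrier <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  carrier <- carrier / stats::sd(carrier)
  amp <- rep(1, n)
  for (j in seq_len(nrow(ev)))
    amp[(ev$onset_sample[j] + 1):ev$offset_sample[j]] <- 0.5
  x <- 4 * amp * carrier + 0.5 * x
  specs <- quick_norm_specs(x, ev)
  mk <- bootstrap_mask(specs, alpha = 0.05, n_boot = 150, seed = 2)
  asel <- mk$freqs >= 8 & mk$freqs <= 12
  tin <- mk$times > 0.5 & mk$times < 2.5
  expect_gt(mean(mk$mask[tin, asel]), 0.8)
  expect_lt(mean(mk$grand[tin, asel][mk$mask[tin, asel]]), -3)
})

test_that("small bootstrap counts warn", {
  ev <- quick_events(3)
  x <- stats::rnorm(attr(ev, "n_samples"))
  specs <- quick_norm_specs(x, ev)
  expect_warning(bootstrap_mask(specs, n_boot = 20, seed = 1), "unstable")
})

test_that("ERD statistic equals a direct masked-mean oracle", {
  set.seed(6)
  mk <- structure(list(
    values = matrix(0, 40, 24), grand = matrix(stats::rnorm(40 * 24), 40),
    mask = matrix(stats::runif(40 * 24) < 0.3, 40),
    times = seq(-1, 4, length.out = 40),
    freqs = log_freq_grid(8, 40, 24), offset = 3, alpha = 0.05,
    n_trials = 10, kind = "masked"), class = "spectrogram")
  st <- erd_statistic(mk, band = c(8, 12))
  fsel <- mk$freqs >= 8 & mk$freqs <= 12
  tsel <- mk$times >= 0 & mk$times <= 3
  oracle <- mean(mk$grand[tsel, fsel][mk$mask[tsel, fsel]])
  expect_equal(st$mean_db, oracle, tolerance = 1e-12)
  ## uniform -3 dB significant region
  mk$grand[] <- -3; mk$mask[] <- TRUE
  expect_equal(erd_statistic(mk, c(8, 12))$mean_db, -3)
  ## empty mask is flagged undefined
  mk$mask[] <- FALSE
  expect_false(erd_statistic(mk, c(8, 12))$defined)
})

test_that("paired effort t-test matches the textbook formula and limits", {
  set.seed(7)
  a <- stats::rnorm(8); b <- stats::rnorm(8)
  r <- compare_effort_ttest(a, b)
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  ## identical vectors
  r0 <- compare_effort_ttest(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  ## constant nonzero difference: analytic limit
  rc <- compare_effort_ttest(a + 2, a)
  expect_lt(rc$p, 1e-6)
})

test_that("permutation comparison is exact for 4+4 trials and calibrated", {
  set.seed(8)
  mkspec <- function(v) structure(list(
    values = matrix(v, 6, 4), times = seq(-1, 4, length.out = 6),
    freqs = c(8, 10, 12, 14), kind = "normalized", offset = 3,
    baseline = c(-1, -0.5)), class = "spectrogram")
  sa <- lapply(1:4, function(i) mkspec(stats::rnorm(24)))
  sb <- lapply(1:4, function(i) mkspec(stats::rnorm(24)))
  r <- compare_conditions_permutation(sa, sb, alpha = 0.05, n_perm = 100,
                                      seed = 1)
  expect_true(r$exact)
  expect_equal(r$n_perm_used, choose(8, 4))
  ## disjoint constant offsets: everything significant
  sa2 <- lapply(1:4, function(i) mkspec(rep(5, 24)))
  sb2 <- lapply(1:4, function(i) mkspec(rep(-5, 24)))
  r2 <- compare_conditions_permutation(sa2, sb2, alpha = 0.05,
                                       n_perm = 100, seed = 1)
  expect_true(all(r2$mask))
  expect_equal(unname(r2$difference[1, 1]), 10)
})
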