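fs <- 512

test_that("zero-phase high-pass removes DC and passes 10 Hz untouched", {
  n <- 10 * fs
  tt <- (0:(n - 1)) / fs
  x <- rbind(rep(50, n),                        # pure offset
             sin(2 * pi * 10 * tt))
  y <- highpass(x, cutoff = 1, order = 4, fs = fs)
  expect_lt(max(abs(y[1, ])), 50 * 1e-6)
  ## compare amplitude and phase at 10 Hz on the interior (no edge effects)
  core <- (2 * fs):(8 * fs)
  ref <- sin(2 * pi * 10 * tt)
  amp <- sqrt(mean(y[2, core]^2)) / sqrt(mean(ref[core]^2))
  expect_lt(abs(amp - 1), 0.01)
  ## zero phase: cross-correlation peaks at lag 0
  cc <- stats::ccf(y[2, core], ref[core], lag.max = 3, plot = FALSE)
  expect_equal(unname(cc$lag[which.max(cc$acf)]), 0)
  expect_error(highpass(x, cutoff = 300, fs = fs), "Nyquist")
})

test_that("the three rejection rules fire on the constructed channels and
          attribute the correct rule", {
  set.seed(1)
  n <- 64
  ns <- 25 * fs
  ## 64 channels sharing smooth sources so neighbours correlate
  src <- matrix(stats::rnorm(6 * ns), 6)
  mix <- vapply(seq_len(6), function(k)
    scalp_potential(rand_dipole(10, 50), stats::rnorm(3), fix_electrodes,
                    fix_sphere), numeric(64))
  mix <- mix / max(abs(mix))
  x <- mix %*% src * 10 + matrix(stats::rnorm(64 * ns, 0, 0.5), 64)
  ## channel 5: huge variance; channel 20: kurtotic; channel 40: decorrelated
  x[5, ] <- stats::rnorm(ns, 0, 1200)
  spikes <- sample(ns, 200)
  x[20, spikes] <- x[20, spikes] + 80 * sign(stats::rnorm(200))
  x[40, ] <- stats::rnorm(ns, 0, stats::sd(x[40, ]))
  rec <- recording(x, fs_eeg = fs, electrode_positions = fix_electrodes)
  rj <- reject_channels(rec)
  v <- unname(rj$report$verdict)
  expect_equal(v[5], "rejected_std")
  expect_equal(v[20], "rejected_kurtosis")
  expect_equal(v[40], "rejected_correlation")
  expect_equal(sum(v != "kept"), 3)
  expect_equal(rj$report$retained, 61)
  expect_equal(nrow(rj$recording$eeg), 61)
  ## identical clean Gaussian channels: everything kept
  set.seed(2)
  xg <- mix %*% matrix(stats::rnorm(6 * ns), 6) * 10 +
    matrix(stats::rnorm(64 * ns, 0, 0.5), 64)
  rg <- reject_channels(recording(xg, fs_eeg = fs,
                                  electrode_positions = fix_electrodes))
  expect_equal(rg$report$retained, 64)
})

test_that("rejection verdicts are reproducible and the report is coherent", {
  set.seed(3)
  ns <- 20 * fs
  mix <- vapply(seq_len(4), function(k)
    scalp_potential(rand_dipole(10, 50), stats::rnorm(3), fix_electrodes,
                    fix_sphere), numeric(64))
  x <- (mix / max(abs(mix))) %*% matrix(stats::rnorm(4 * ns), 4) * 10 +
    matrix(stats::rnorm(64 * ns, 0, 0.5), 64)
  rec <- recording(x, fs_eeg = fs, electrode_positions = fix_electrodes)
  r1 <- reject_channels(rec); r2 <- reject_channels(rec)
  expect_identical(r1$report$verdict, r2$report$verdict)
  expect_equal(r1$report$retained, sum(r1$report$verdict == "kept"))
  expect_equal(r1$report$retained_fraction,
               r1$report$retained / 64)
})

test_that("average reference zeroes column means, is idempotent, and
          commutes with the high-pass", {
  set.seed(4)
  x <- matrix(stats::rnorm(16 * 4 * fs), 16) + 5
  y <- rereference_average(x)
  expect_lt(max(abs(colMeans(y))), 1e-9)
  expect_equal(rereference_average(y), y, tolerance = 1e-12)
  expect_equal(rereference_average(matrix(stats::rnorm(fs), 1)),
               matrix(0, 1, fs))
  a <- rereference_average(highpass(x, fs = fs))
  b <- highpass(rereference_average(x), fs = fs)
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("trapezoidal force onsets are detected at the analytic crossing", {
  fsa <- 1000
  ev <- quick_events(2, dur_s = 3, pause_s = 5, mode = "isometric",
                     direction = "extension")
  n_aux <- ceiling((attr(ev, "n_samples") / fs) * fsa)
  force <- numeric(n_aux)
  ta <- (0:(n_aux - 1)) / fsa
  for (j in 1:2) {
    on_t <- ev$onset_sample[j] / fs; off_t <- ev$offset_sample[j] / fs
    idx <- which(ta >= on_t & ta <= off_t)
    rel <- ta[idx] - on_t
    force[idx] <- 300 * pmax(0, pmin(1, pmin(rel, (off_t - on_t) - rel) / 0.3))
  }
  rec <- recording(matrix(0, 8, attr(ev, "n_samples")), fs_eeg = fs,
                   aux = list(force = force, angle = numeric(n_aux)),
                   fs_aux = fsa)
  ref <- detect_trial_bounds(rec, ev)
  ## analytic 10% crossing of a 300 ms ramp: 30 ms after nominal onset
  for (j in 1:2) {
    expect_lt(abs(ref$onset_sample[j] / fs -
                    (ev$onset_sample[j] / fs + 0.03)), 2 / fsa + 1 / fs)
    expect_true(attr(ref, "refined")[j])
  }
})

test_that("flat auxiliary falls back to nominal bounds with a warning", {
  ev <- quick_events(1, mode = "isometric")
  n_aux <- ceiling(attr(ev, "n_samples") / fs * 1000)
  rec <- recording(matrix(0, 8, attr(ev, "n_samples")), fs_eeg = fs,
                   aux = list(force = numeric(n_aux),
                              angle = numeric(n_aux)))
  expect_warning(ref <- detect_trial_bounds(rec, ev), "nominal")
  expect_equal(ref$onset_sample, ev$onset_sample)
  expect_equal(ref$offset_sample, ev$offset_sample)
})

test_that("triangular angle excursions give near-full trial duration", {
  fsa <- 1000
  ev <- quick_events(2, dur_s = 3, mode = "isotonic")
  n_aux <- ceiling(attr(ev, "n_samples") / fs * fsa)
  angle <- numeric(n_aux)
  ta <- (0:(n_aux - 1)) / fsa
  for (j in 1:2) {
    on_t <- ev$onset_sample[j] / fs; off_t <- ev$offset_sample[j] / fs
    idx <- which(ta >= on_t & ta <= off_t)
    rel <- (ta[idx] - on_t) / (off_t - on_t)
    angle[idx] <- 30 * (1 - abs(2 * rel - 1))
  }
  rec <- recording(matrix(0, 8, attr(ev, "n_samples")), fs_eeg = fs,
                   aux = list(force = numeric(n_aux), angle = angle),
                   fs_aux = fsa)
  ref <- detect_trial_bounds(rec, ev)
  ## analytic: crossings at 10% and ~8% of the triangle, so the detected
  ## span is (1 - 0.10 - 0.08) x nominal at least, within 5%
  for (j in 1:2) {
    span <- (ref$offset_sample[j] - ref$onset_sample[j]) / fs
    nominal <- (ev$offset_sample[j] - ev$onset_sample[j]) / fs
    analytic <- nominal * (1 - 0.10 / 2 - 0.08 / 2)
    expect_lt(abs(span - analytic) / nominal, 0.05)
  }
})
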