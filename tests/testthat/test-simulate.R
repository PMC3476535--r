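test_that("the default protocol has 280 trials with a 4:3 mode ratio and
          no isotonic knee flexion", {
  ev <- make_protocol(seed = 1)
  expect_equal(nrow(ev), 280)
  expect_equal(sum(ev$mode == "isometric"), 160)
  expect_equal(sum(ev$mode == "isotonic"), 120)
  expect_equal(sum(ev$mode == "isometric") / sum(ev$mode == "isotonic"),
               4 / 3)
  expect_equal(nrow(ev[ev$joint == "knee" & ev$mode == "isotonic" &
                         ev$direction == "flexion", ]), 0)
  ## sorted, non-overlapping, ~3 s trials with 5 s pauses
  expect_false(is.unsorted(ev$onset_sample, strictly = TRUE))
  durs <- (ev$offset_sample - ev$onset_sample) / attr(ev, "fs")
  expect_lt(abs(mean(durs) - 3), 0.15)
  expect_lt(abs(stats::sd(durs) / mean(durs) - 0.1), 0.05)
  gaps <- (ev$onset_sample[-1] - ev$offset_sample[-280]) / attr(ev, "fs")
  expect_true(all(abs(gaps - 5) < 1e-3))
})

test_that("the protocol is seed-deterministic and reps = 0 gives an empty
          table", {
  expect_identical(make_protocol(seed = 5), make_protocol(seed = 5))
  expect_false(identical(make_protocol(seed = 5), make_protocol(seed = 6)))
  e0 <- make_protocol(reps = 0, seed = 1)
  expect_equal(nrow(e0), 0)
})

test_that("trial-event validation catches the documented violations", {
  expect_error(trial_events(10, 5, "knee", "isometric", "flexion", "high"),
               "row\\(s\\) 1")
  expect_error(trial_events(c(0, 100), c(200, 300), rep("knee", 2),
                            rep("isometric", 2), rep("flexion", 2),
                            rep("high", 2)), "overlap")
  expect_error(trial_events(0, 100, "knee", "isotonic", "flexion", "high"),
               "isotonic knee flexion")
  expect_error(trial_events(0, 100, "elbow", "isometric", "flexion",
                            "high"), "joint")
})

test_that("unmodulated sources have equal trial and rest band power", {
  src <- list(s = source_spec("s", c(-5, 5, 70), bands = c(alpha = 4),
                              erd_profile = "none"))
  ev <- quick_events(20)
  sim <- simulate_sources(ev, src, fs = 512,
                          n_samples = attr(ev, "n_samples"), seed = 1)
  x <- sim$activations[1, ]
  inmask <- logical(length(x))
  for (j in seq_len(nrow(ev)))
    inmask[(ev$onset_sample[j] + 1):ev$offset_sample[j]] <- TRUE
  ratio <- mean(x[inmask]^2) / mean(x[!inmask]^2)
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
})

test_that("sustained d = 0.5 suppresses mid-trial alpha power by about
          (1-d)^2, i.e. -6 dB", {
  src <- list(s = source_spec("s", c(-5, 5, 70),
                              bands = c(alpha = 4, beta = 3),
                              erd_profile = "sustained",
                              erd_depth = c(high = 0.5, low = 0.5)))
  ev <- quick_events(40)
  sim <- simulate_sources(ev, src, fs = 512,
                          n_samples = attr(ev, "n_samples"), seed = 2,
                          depth_jitter = 0)
  x <- sim$activations[1, ]
  vals <- vapply(seq_len(nrow(ev)), function(j) {
    spn <- baseline_normalize(epoch_spectrogram(
      x, 512, ev$onset_sample[j], ev$offset_sample[j],
      freqs = log_freq_grid(8, 12, 6)))
    mid <- spn$times > 0.5 & spn$times < spn$offset - 0.5
    mean(spn$values[mid, ])
  }, numeric(1))
  expect_lt(abs(mean(vals) - 20 * log10(0.5)), 1)
})

test_that("transient profiles suppress onset power but not mid-trial", {
  src <- list(s = source_spec("s", c(-5, 5, 70),
                              bands = c(alpha = 4, beta = 3),
                              erd_profile = "transient",
                              erd_depth = c(high = 0.6, low = 0.6)))
  ev <- quick_events(40)
  sim <- simulate_sources(ev, src, fs = 512,
                          n_samples = attr(ev, "n_samples"), seed = 3,
                          depth_jitter = 0)
  x <- sim$activations[1, ]
  vals <- vapply(seq_len(nrow(ev)), function(j) {
    spn <- baseline_normalize(epoch_spectrogram(
      x, 512, ev$onset_sample[j], ev$offset_sample[j],
      freqs = log_freq_grid(8, 12, 6)))
    mid <- spn$times > 0.6 & spn$times < spn$offset - 0.6
    on <- abs(spn$times) < 0.15
    c(mean(spn$values[mid, ]), mean(spn$values[on, ]))
  }, numeric(2))
  expect_lt(abs(mean(vals[1, ])), 1)          # mid-trial back at baseline
  expect_lt(mean(vals[2, ]), -2)              # onset window suppressed
})

test_that("noiseless single-source recordings are rank 1 and equal the
          mixing times the activations", {
  src <- list(s = source_spec("s", c(-5, 5, 70), bands = c(alpha = 4),
                              erd_profile = "none"))
  ev <- quick_events(2)
  sim <- simulate_sources(ev, src, fs = 512,
                          n_samples = attr(ev, "n_samples"), seed = 4)
  out <- simulate_recording(sim, fix_electrodes, fix_sphere,
                            noise_rms = 0, seed = 4)
  sv <- svd(out$recording$eeg[, 1:5000])$d
  expect_lt(sv[2] / sv[1], 1e-10)
  expect_equal(unname(out$recording$eeg),
               unname(out$truth$mixing$knee %*% sim$activations),
               tolerance = 1e-12)
})

test_that("force appears only in isometric trials and angle excursions only
          in isotonic trials", {
  ev <- make_protocol(reps = 2, seed = 3)
  src <- default_sources()
  sim <- simulate_sources(ev, src, fs = 512,
                          n_samples = attr(ev, "n_samples"), seed = 5)
  out <- simulate_recording(sim, fix_electrodes, fix_sphere, seed = 5)
  fsa <- out$recording$fs_aux
  ta <- (seq_along(out$recording$aux$force) - 1) / fsa
  iso_mask <- iso_t <- logical(length(ta))
  for (j in seq_len(nrow(ev))) {
    idx <- ta >= ev$onset_sample[j] / 512 & ta <= ev$offset_sample[j] / 512
    if (ev$mode[j] == "isometric") iso_mask <- iso_mask | idx
    else iso_t <- iso_t | idx
  }
  expect_gt(max(out$recording$aux$force[iso_mask]), 50)
  expect_lt(max(abs(out$recording$aux$force[!iso_mask])), 10)
  expect_gt(max(abs(out$recording$aux$angle[iso_t])), 15)
  expect_lt(max(abs(out$recording$aux$angle[!iso_t])), 5)
})

test_that("limb-specific sources shift posteriorly in the ankle regime and
          the per-sample regime follows the upcoming trial", {
  ev <- make_protocol(reps = 1, seed = 2)
  src <- default_sources()
  sim <- simulate_sources(ev, src, fs = 512,
                          n_samples = attr(ev, "n_samples"), seed = 6)
  out <- simulate_recording(sim, fix_electrodes, fix_sphere, seed = 6)
  locs <- out$truth$locations
  expect_equal(locs$ankle$sma - locs$knee$sma, c(0, -15, 0))
  expect_equal(locs$ankle$visual, locs$knee$visual)
  reg <- out$truth$regime
  j <- 3
  pre <- ev$offset_sample[j - 1] + 5
  expect_equal(unname(reg[pre]), ev$joint[j])
  expect_equal(unname(reg[ev$onset_sample[j] + 5]), ev$joint[j])
})

test_that("depth ordering across effort levels is enforced", {
  expect_error(source_spec("s", c(0, 0, 60),
                           erd_depth = c(high = 0.2, low = 0.5)),
               "high >= low")
})
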