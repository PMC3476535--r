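## shared fixtures: built in code, deterministic

fix_sphere <- sphere_model()
fix_electrodes <- electrode_layout(64, fix_sphere)
## one shared search grid (expensive to build) for all dipole tests
fix_grid <- dipole_grid(fix_electrodes, fix_sphere)

## a random dipole strictly inside the brain sphere
rand_dipole <- function(rmin = 5, rmax = 75) {
  u <- stats::rnorm(3)
  u / sqrt(sum(u^2)) * stats::runif(1, rmin, rmax)
}

## Laplacian iid sources, unit variance
rlaplace_mat <- function(n, m) {
  matrix(stats::rexp(n * m) * sign(stats::rnorm(n * m)), n, m) / sqrt(2)
}

## small trial-event table: nt trials of dur_s seconds, pause_s pauses
quick_events <- function(nt, dur_s = 3, pause_s = 5, fs = 512,
                         joint = "knee", mode = "isotonic",
                         direction = "extension", effort = "high") {
  onset <- (pause_s + (seq_len(nt) - 1) * (dur_s + pause_s)) * fs
  ev <- trial_events(round(onset), round(onset + dur_s * fs),
                     rep(joint, nt), rep(mode, nt),
                     rep(direction, nt), rep(effort, nt))
  attr(ev, "fs") <- fs
  attr(ev, "n_samples") <- as.integer(max(ev$offset_sample) + 2 * fs)
  ev
}

## normalized spectrogram list from a continuous signal and events
quick_norm_specs <- function(x, ev, fs = 512, freqs = log_freq_grid(8, 40, 24)) {
  lapply(seq_len(nrow(ev)), function(j) {
    sp <- epoch_spectrogram(x, fs, ev$onset_sample[j], ev$offset_sample[j],
                            freqs = freqs)
    baseline_normalize(sp)
  })
}
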