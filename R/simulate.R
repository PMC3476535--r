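#' Synthetic exercise protocol
#'
#' Generates a randomized trial-event table emulating a seated lower-limb
#' exercise session: seven exercises (isometric knee flexion/extension,
#' isotonic knee extension, isometric and isotonic ankle plantarflexion and
#' dorsiflexion -- isotonic knee flexion is excluded) at two effort levels,
#' `reps` repetitions each, performed in shuffled blocks of one
#' exercise-effort combination, with ~3 s trials and 5 s pauses.
#'
#' @param reps Repetitions per exercise and effort level.
#' @param trial_mean Mean trial duration (s).
#' @param trial_cv Coefficient of variation of the lognormal duration
#'   jitter.
#' @param pause Pause between repetitions (s).
#' @param fs EEG sampling rate used to convert times to samples.
#' @param margin Quiet time (s) before the first and after the last trial.
#' @param seed Integer seed.
#' @return A `trial_events` table with attributes `fs` and `n_samples`
#'   (total recording length implied by the protocol).
#' @export
make_protocol <- function(reps = 20, trial_mean = 3, trial_cv = 0.1,
                          pause = 5, fs = 512, margin = 2, seed = 1) {
  ex <- data.frame(
    joint = c("knee", "knee", "knee", "ankle", "ankle", "ankle", "ankle"),
    mode = c("isometric", "isometric", "isotonic",
             "isometric", "isometric", "isotonic", "isotonic"),
    direction = c("flexion", "extension", "extension",
                  "flexion", "extension", "flexion", "extension"),
    stringsAsFactors = FALSE)
  blocks <- merge(ex, data.frame(effort = c("high", "low")))
  set.seed(seed)
  blocks <- blocks[sample(nrow(blocks)), , drop = FALSE]
  if (reps == 0) {
    ev <- trial_events(integer(0), integer(0), character(0), character(0),
                       character(0), character(0))
    attr(ev, "fs") <- fs
    attr(ev, "n_samples") <- as.integer(2 * margin * fs)
    return(ev)
  }
  sdlog <- sqrt(log(1 + trial_cv^2))
  meanlog <- log(trial_mean) - sdlog^2 / 2
  rows <- vector("list", nrow(blocks) * reps)
  t_cur <- margin
  k <- 0
  for (b in seq_len(nrow(blocks))) {
    for (r in seq_len(reps)) {
      onset <- t_cur + pause
      dur <- stats::rlnorm(1, meanlog, sdlog)
      k <- k + 1
      rows[[k]] <- data.frame(onset = onset, offset = onset + dur,
                              joint = blocks$joint[b], mode = blocks$mode[b],
                              direction = blocks$direction[b],
                              effort = blocks$effort[b],
                              stringsAsFactors = FALSE)
      t_cur <- onset + dur
    }
  }
  tab <- do.call(rbind, rows)
  ev <- trial_events(round(tab$onset * fs), round(tab$offset * fs),
                     tab$joint, tab$mode, tab$direction, tab$effort)
  attr(ev, "fs") <- fs
  attr(ev, "n_samples") <- as.integer(ceiling((t_cur + margin + pause) * fs))
  ev
}

#' Specification of one synthetic source
#'
#' Describes a simulated signal generator: its dipole location and moment
#' direction (for cortical and artifact mixing columns), per-band baseline
#' scalp amplitudes, and how its oscillatory amplitude is modulated by the
#' task (event-related desynchronization).
#'
#' @param name Identifier.
#' @param location Length-3 dipole location (mm, head frame).
#' @param moment Length-3 moment direction (normalised internally).
#' @param bands Named numeric vector of baseline scalp amplitudes in
#'   microvolts per band; band edges are taken from `band_edges`.
#' @param erd_profile `"by_mode"` (transient modulation for isometric
#'   trials, sustained for isotonic -- the study conditions), `"transient"`,
#'   `"sustained"`, or `"none"`.
#' @param erd_depth Named vector `c(high=, low=)` of fractional amplitude
#'   suppression depths per effort level; `high >= low` required.
#' @param role `"cortical"`, `"ocular"` or `"muscular"`.
#' @param limb_specific If `TRUE` the source location is shifted between
#'   the knee and ankle regimes (somatotopic shift).
#' @param band_edges Named list of band frequency ranges (Hz).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(name, location, moment = c(0, 0, 1),
                        bands = c(alpha = 3, beta = 2),
                        erd_profile = c("by_mode", "transient", "sustained",
                                        "none"),
                        erd_depth = c(high = 0, low = 0),
                        role = c("cortical", "ocular", "muscular"),
                        limb_specific = FALSE,
                        band_edges = list(alpha = c(8, 12),
                                          beta = c(12, 30))) {
  erd_profile <- match.arg(erd_profile)
  role <- match.arg(role)
  stopifnot(length(location) == 3, length(moment) == 3)
  if (!all(names(bands) %in% names(band_edges)))
    stop("unknown band name(s): ",
         paste(setdiff(names(bands), names(band_edges)), collapse = ", "))
  if (erd_depth[["high"]] < erd_depth[["low"]])
    stop("erd_depth must satisfy high >= low")
  structure(list(name = name, location = as.numeric(location),
                 moment = as.numeric(moment) / sqrt(sum(moment^2)),
                 bands = bands, erd_profile = erd_profile,
                 erd_depth = erd_depth, role = role,
                 limb_specific = limb_specific, band_edges = band_edges),
            class = "source_spec")
}

#' Default synthetic source set
#'
#' Nine sources emulating the regions reported for seated lower-limb
#' exercise: seven cortical generators (supplementary motor area -- the
#' limb-specific source whose location shifts posteriorly for ankle tasks
#' -- left and right dorsal premotor, posterior cingulate, posterior
#' parietal, anterior cingulate, visual), one ocular and one neck-muscle
#' artifact generator.  Task-related alpha/beta desynchronization is
#' deepest in the supplementary motor area and present with smaller depths
#' in the premotor and parietal sources; the anterior cingulate and visual
#' sources do not modulate with the task.
#'
#' @param sphere A [sphere_model()].
#' @return Named list of [source_spec()] objects.
#' @export
default_sources <- function(sphere = sphere_model()) {
  list(
    sma = source_spec("sma", c(-5, 5, 70), c(0.2, 0.3, 1),
                      bands = c(alpha = 4, beta = 3),
                      erd_profile = "by_mode",
                      erd_depth = c(high = 0.50, low = 0.30),
                      limb_specific = TRUE),
    premotor_left = source_spec("premotor_left", c(-35, 8, 60),
                                c(-0.5, 0.2, 1),
                                bands = c(alpha = 3.5, beta = 2.5),
                                erd_profile = "by_mode",
                                erd_depth = c(high = 0.45, low = 0.27)),
    premotor_right = source_spec("premotor_right", c(30, 4, 60),
                                 c(0.5, 0.2, 1),
                                 bands = c(alpha = 3.5, beta = 2.5),
                                 erd_profile = "by_mode",
                                 erd_depth = c(high = 0.45, low = 0.27)),
    posterior_cingulate = source_spec("posterior_cingulate", c(5, -35, 45),
                                      c(0, -0.4, 1),
                                      bands = c(alpha = 3, beta = 2),
                                      erd_profile = "by_mode",
                                      erd_depth = c(high = 0.35, low = 0.21)),
    posterior_parietal = source_spec("posterior_parietal", c(-5, -55, 52),
                                     c(0, -0.5, 1),
                                     bands = c(alpha = 4, beta = 2),
                                     erd_profile = "by_mode",
                                     erd_depth = c(high = 0.40, low = 0.24)),
    anterior_cingulate = source_spec("anterior_cingulate", c(3, 25, 45),
                                     c(0, 0.5, 1),
                                     bands = c(alpha = 3, beta = 2),
                                     erd_profile = "none"),
    visual = source_spec("visual", c(0, -65, 20), c(0, -1, 0.3),
                         bands = c(alpha = 5, beta = 1.5),
                         erd_profile = "none"),
    ocular = source_spec("ocular", c(0, 74, -24), c(0, 0.3, 1),
                         bands = c(alpha = 0),
                         erd_profile = "none", role = "ocular"),
    muscular = source_spec("muscular", c(62, -43, -32), c(1, -0.6, -0.5),
                           bands = c(alpha = 0),
                           erd_profile = "none", role = "muscular")
  )
}

## unit-RMS band-limited Gaussian noise (4th-order Butterworth band-pass)
.band_noise <- function(n, fs, band, seed_offset = 0) {
  x <- stats::rnorm(n)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filter(bf, x)
  y <- as.numeric(y)
  y / stats::sd(y)
}

## unit-RMS pink (1/f) noise via spectral shaping, high-passed above 1 Hz
.pink_noise <- function(n, fs) {
  nf <- stats::nextn(n, 2)
  sp <- stats::fft(stats::rnorm(nf))
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1)          # two-sided frequency index
  fhz <- f * fs / nf
  shape <- 1 / sqrt(pmax(fhz, 1))   # flat below 1 Hz, 1/f above
  y <- Re(stats::fft(sp * shape, inverse = TRUE)) / nf
  y <- y[seq_len(n)]
  y / stats::sd(y)
}

## ERD modulation window on a per-sample time axis for one trial
.erd_window <- function(tt, onset, offset, profile, ramp = 0.3,
                        bump = 0.6) {
  m <- numeric(length(tt))
  if (profile == "none") return(m)
  if (profile == "transient") {
    for (t0 in c(onset, offset)) {
      idx <- which(abs(tt - t0) < bump / 2)
      m[idx] <- pmax(m[idx], 0.5 * (1 + cos(2 * pi * (tt[idx] - t0) / bump)))
    }
  } else {                          # sustained
    idx <- which(tt >= onset & tt <= offset)
    m[idx] <- 1
    ru <- which(tt >= onset & tt < onset + ramp)
    m[ru] <- 0.5 * (1 - cos(pi * (tt[ru] - onset) / ramp))
    rd <- which(tt > offset - ramp & tt <= offset)
    m[rd] <- 0.5 * (1 - cos(pi * (offset - tt[rd]) / ramp))
  }
  m
}

#' Simulate source activations for a protocol
#'
#' Generates the per-source signals implied by a trial-event table.  Each
#' cortical source is a sum of band-limited Gaussian noise carriers whose
#' instantaneous amplitude is `a_base * (1 - d * m(t))`, where `d` is the
#' effort-dependent desynchronization depth and `m(t)` the modulation
#' window (raised-cosine bumps of 600 ms at trial onset and offset for the
#' transient profile; a plateau with 300 ms cosine ramps for the sustained
#' profile), plus a pink (1/f) background 10 dB below the alpha baseline.
#' The ocular source emits Poisson blinks (0.2/s, 300 ms biphasic pulses)
#' and the muscular source broadband 20-150 Hz bursts during trials only.
#'
#' @param events A `trial_events` table.
#' @param sources List of [source_spec()] (see [default_sources()]).
#' @param fs Sampling rate (Hz).
#' @param n_samples Total length; defaults to the protocol attribute.
#' @param seed Integer seed.
#' @param depth_jitter SD of the per-trial jitter added to the nominal
#'   depth (truncated to `[0, 0.95]`).
#' @param blink_rate Blink rate (1/s) for the ocular source.
#' @param ocular_amp,muscular_amp Scalp amplitudes (microvolts) of the
#'   artifact sources.
#' @return List with `activations` (sources x samples matrix, microvolt
#'   scalp scale), `truth` (per-trial depths and profiles, per-sample
#'   modulation per source), and the inputs.
#' @export
simulate_sources <- function(events, sources, fs = 512, n_samples = NULL,
                             seed = 1, depth_jitter = 0.05,
                             blink_rate = 0.2, ocular_amp = 25,
                             muscular_amp = 6) {
  validate_trial_events(events)
  if (nrow(events) > 1 &&
      any(events$onset_sample[-1] < events$offset_sample[-nrow(events)]))
    stop("overlapping trials")
  if (is.null(n_samples)) n_samples <- attr(events, "n_samples")
  if (is.null(n_samples))
    n_samples <- max(events$offset_sample) + 2 * fs
  n_samples <- as.integer(n_samples)
  set.seed(seed)
  tt <- (seq_len(n_samples) - 1) / fs
  ns <- length(sources)
  S <- matrix(0, ns, n_samples)
  rownames(S) <- names(sources)
  trial_depth <- matrix(0, nrow(events), ns,
                        dimnames = list(NULL, names(sources)))
  trial_profile <- matrix("none", nrow(events), ns,
                          dimnames = list(NULL, names(sources)))
  modulation <- matrix(0, ns, n_samples)

  for (k in seq_len(ns)) {
    sp <- sources[[k]]
    if (sp$role == "cortical") {
      ## per-trial modulation window
      m <- numeric(n_samples)
      for (j in seq_len(nrow(events))) {
        prof <- switch(sp$erd_profile,
                       by_mode = if (events$mode[j] == "isometric")
                         "transient" else "sustained",
                       sp$erd_profile)
        trial_profile[j, k] <- prof
        if (prof == "none") next
        d <- sp$erd_depth[[events$effort[j]]]
        d <- min(0.95, max(0, d + stats::rnorm(1, 0, depth_jitter)))
        trial_depth[j, k] <- d
        on_t <- events$onset_sample[j] / fs
        off_t <- events$offset_sample[j] / fs
        i0 <- max(1L, events$onset_sample[j] - as.integer(fs))
        i1 <- min(n_samples, events$offset_sample[j] + as.integer(fs))
        idx <- i0:i1
        m[idx] <- pmax(m[idx],
                       d * .erd_window(tt[idx], on_t, off_t, prof))
      }
      modulation[k, ] <- m
      x <- numeric(n_samples)
      for (bn in names(sp$bands)) {
        a <- sp$bands[[bn]]
        if (a <= 0) next
        carrier <- .band_noise(n_samples, fs, sp$band_edges[[bn]])
        x <- x + a * (1 - m) * carrier
      }
      a_alpha <- if ("alpha" %in% names(sp$bands)) sp$bands[["alpha"]] else
        max(sp$bands)
      if (a_alpha > 0)
        x <- x + a_alpha * 10^(-10 / 20) * .pink_noise(n_samples, fs)
      S[k, ] <- x
    } else if (sp$role == "ocular") {
      n_blinks <- stats::rpois(1, blink_rate * n_samples / fs)
      onsets <- sort(stats::runif(n_blinks, 0, n_samples / fs - 0.35))
      pulse_t <- seq(0, 0.3, by = 1 / fs)
      ## biphasic pulse: one full sine cycle under a Hann envelope
      pulse <- sin(2 * pi * pulse_t / 0.3) *
        0.5 * (1 - cos(2 * pi * pulse_t / 0.3))
      x <- numeric(n_samples)
      for (ot in onsets) {
        i0 <- as.integer(ot * fs) + 1L
        ii <- i0:(i0 + length(pulse) - 1L)
        x[ii] <- x[ii] + pulse
      }
      ## continuous low-frequency ocular baseline (eye wander): blinks are
      ## then large but not degenerate outliers of the source density
      S[k, ] <- ocular_amp * x +
        0.1 * ocular_amp * .band_noise(n_samples, fs, c(1, 7))
    } else {                       # muscular
      mask <- numeric(n_samples)
      for (j in seq_len(nrow(events))) {
        idx <- (events$onset_sample[j] + 1L):events$offset_sample[j]
        w <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
        mask[idx] <- w
      }
      ## resting muscle tone plus in-trial bursts
      S[k, ] <- muscular_amp * (0.2 + mask) *
        .band_noise(n_samples, fs, c(20, 150))
    }
  }
  list(activations = S, fs = fs, n_samples = n_samples,
       truth = list(trial_depth = trial_depth,
                    trial_profile = trial_profile,
                    modulation = modulation),
       sources = sources, events = events, seed = seed)
}

#' Regime mixing matrices for a source set
#'
#' Columns are the scalp projections ([scalp_potential()]) of each source,
#' normalised so the strongest electrode of each column is 1 (source
#' activations then carry the microvolt scale).  Limb-specific sources are
#' shifted posteriorly (-Y) by `shift_mm` in the ankle regime.
#'
#' @param sources List of [source_spec()].
#' @param electrodes n x 3 electrode matrix.
#' @param sphere A [sphere_model()].
#' @param shift_mm Somatotopic location shift (mm) of limb-specific sources
#'   between regimes.
#' @return List with `knee` and `ankle` mixing matrices (channels x
#'   sources) and the per-regime source locations.
#' @export
regime_mixing <- function(sources, electrodes, sphere = sphere_model(),
                          shift_mm = 15) {
  mk <- function(regime) {
    loc <- lapply(sources, function(sp) {
      l <- sp$location
      if (isTRUE(sp$limb_specific) && regime == "ankle")
        l <- l + c(0, -shift_mm, 0)
      l
    })
    A <- sapply(seq_along(sources), function(k) {
      v <- scalp_potential(loc[[k]], sources[[k]]$moment, electrodes,
                           sphere)
      v / max(abs(v))
    })
    colnames(A) <- names(sources)
    list(A = A, locations = loc)
  }
  knee <- mk("knee"); ankle <- mk("ankle")
  list(knee = knee$A, ankle = ankle$A,
       locations = list(knee = knee$locations, ankle = ankle$locations))
}

#' Simulate a scalp EEG recording from source activations
#'
#' Mixes the source activations through the regime-dependent mixing
#' matrices (knee-trial stretches through the knee matrix, ankle stretches
#' through the ankle matrix; inter-trial samples use the regime of the
#' upcoming trial), then adds white sensor noise, 60 Hz line interference
#' and a per-channel random-walk drift.  Auxiliary channels are generated
#' on their own clock: a trapezoidal load-cell force per isometric trial
#' and a triangular angle excursion per isotonic trial.
#'
#' @param sim Output of [simulate_sources()].
#' @param electrodes n x 3 electrode matrix (mm).
#' @param sphere A [sphere_model()].
#' @param shift_mm Somatotopic regime shift passed to [regime_mixing()].
#' @param noise_rms White sensor noise RMS (microvolts); 0 disables all
#'   sensor noise terms including the diffuse background.
#' @param line_amp 60 Hz line amplitude (microvolts).
#' @param drift_rms Target RMS of the random-walk drift (microvolts).
#' @param bg_n,bg_amp Number and peak scalp amplitude (microvolts) of
#'   diffuse pink-noise background generators (deep random dipoles)
#'   emulating volume-conducted ongoing cortical activity; they are part
#'   of the noise model, not of the ground-truth mixing.
#' @param fs_aux Auxiliary sampling rate (Hz).
#' @param subject_id Subject identifier.
#' @param seed Integer seed.
#' @return List with the `eeg_recording`, the `trial_events`, and `truth`
#'   (regime mixing matrices, per-sample regime, source ground truth).
#' @export
simulate_recording <- function(sim, electrodes, sphere = sphere_model(),
                               shift_mm = 15, noise_rms = 1,
                               line_amp = 0.5, drift_rms = 10,
                               bg_n = 6, bg_amp = 8,
                               fs_aux = 1000, subject_id = "S01",
                               seed = 1) {
  electrodes <- as.matrix(electrodes)
  events <- sim$events
  fs <- sim$fs
  n <- sim$n_samples
  nch <- nrow(electrodes)
  set.seed(seed)
  mix <- regime_mixing(sim$sources, electrodes, sphere, shift_mm)

  ## per-sample regime: each sample belongs to the upcoming (or current)
  ## trial's joint
  regime <- character(n)
  bounds <- c(0L, events$offset_sample)
  for (j in seq_len(nrow(events))) {
    idx <- (bounds[j] + 1L):events$offset_sample[j]
    regime[idx] <- events$joint[j]
  }
  if (max(events$offset_sample) < n)
    regime[(max(events$offset_sample) + 1L):n] <-
      events$joint[nrow(events)]

  eeg <- matrix(0, nch, n)
  for (rg in c("knee", "ankle")) {
    cols <- which(regime == rg)
    if (length(cols))
      eeg[, cols] <- mix[[rg]] %*% sim$activations[, cols, drop = FALSE]
  }
  if (noise_rms > 0) {
    ## diffuse background: volume-conducted pink activity from deep dipoles
    if (bg_n > 0 && bg_amp > 0) {
      rb <- 0.6 * sphere$brain_fraction * sphere$radius
      for (b in seq_len(bg_n)) {
        loc <- stats::runif(3, -1, 1)
        loc <- loc / sqrt(sum(loc^2)) * stats::runif(1, 0.2, 1) * rb
        mom <- stats::rnorm(3)
        col <- scalp_potential(loc, mom, electrodes, sphere)
        col <- col / max(abs(col))
        eeg <- eeg + outer(col, bg_amp * .pink_noise(n, fs))
      }
    }
    eeg <- eeg + matrix(stats::rnorm(nch * n, 0, noise_rms), nch, n)
    ph <- stats::runif(1, 0, 2 * pi)
    gain <- stats::runif(nch, 0.7, 1.3)
    eeg <- eeg + outer(gain, line_amp * sin(2 * pi * 60 *
                                              (seq_len(n) - 1) / fs + ph))
    for (ch in seq_len(nch)) {
      d <- cumsum(stats::rnorm(n))
      eeg[ch, ] <- eeg[ch, ] + d * (drift_rms / stats::sd(d))
    }
  }

  ## auxiliary mechanical channels
  n_aux <- ceiling(n / fs * fs_aux)
  ta <- (seq_len(n_aux) - 1) / fs_aux
  force <- stats::rnorm(n_aux, 0, 0.5)
  angle <- stats::rnorm(n_aux, 0, 0.2)
  for (j in seq_len(nrow(events))) {
    on_t <- events$onset_sample[j] / fs
    off_t <- events$offset_sample[j] / fs
    idx <- which(ta >= on_t & ta <= off_t)
    if (!length(idx)) next
    rel <- ta[idx] - on_t
    dur <- off_t - on_t
    if (events$mode[j] == "isometric") {
      amp <- switch(events$joint[j], knee = 400, ankle = 200)
      if (events$effort[j] == "low") amp <- amp / 4
      rise <- 0.3
      prof <- pmin(1, pmin(rel, dur - rel) / rise)
      prof <- pmax(prof, 0)
      force[idx] <- force[idx] + amp * prof
    } else {
      amp <- switch(events$joint[j], knee = 45, ankle = 20)
      prof <- 1 - abs(2 * rel / dur - 1)       # triangle peaking mid-trial
      angle[idx] <- angle[idx] + amp * prof
    }
  }

  rec <- recording(eeg, fs_eeg = fs,
                   channel_labels = rownames(electrodes),
                   electrode_positions = electrodes,
                   aux = list(force = force, angle = angle),
                   fs_aux = fs_aux, subject_id = subject_id)
  list(recording = rec, events = events,
       truth = c(sim$truth,
                 list(mixing = mix[c("knee", "ankle")],
                      locations = mix$locations,
                      regime = regime,
                      activations = sim$activations)))
}

#' Simulate one subject of the default study
#'
#' Convenience wrapper: protocol, sources and scalp mixing with the
#' default study conditions (64 channels, 7 cortical + 2 artifact sources,
#' 20 repetitions per exercise and effort unless overridden).
#'
#' @param subject_id Subject identifier.
#' @param seed Integer seed (protocol, sources and sensor noise are derived
#'   from it).
#' @param reps Repetitions per exercise-effort block.
#' @param n_channels Number of scalp electrodes.
#' @param sphere A [sphere_model()].
#' @param sources Source set (default [default_sources()]).
#' @param ... Passed on to [simulate_recording()].
#' @return As [simulate_recording()].
#' @export
simulate_subject <- function(subject_id = "S01", seed = 1, reps = 20,
                             n_channels = 64, sphere = sphere_model(),
                             sources = default_sources(sphere), ...) {
  ev <- make_protocol(reps = reps, seed = seed)
  sim <- simulate_sources(ev, sources, fs = attr(ev, "fs"),
                          n_samples = attr(ev, "n_samples"), seed = seed + 1)
  el <- electrode_layout(n_channels, sphere)
  simulate_recording(sim, el, sphere, subject_id = subject_id,
                     seed = seed + 2, ...)
}
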