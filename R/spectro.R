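#' Logarithmic frequency grid
#'
#' @param fmin,fmax Frequency range (Hz).
#' @param n Number of log-spaced bins.
#' @return Strictly increasing numeric vector with a constant ratio
#'   between consecutive bins.
#' @export
log_freq_grid <- function(fmin = 3, fmax = 150, n = 220) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Morlet spectrogram with a fixed-duration window
#'
#' Convolves the signal with complex Morlet wavelets whose Gaussian
#' envelope has a fixed full width (+-3 sigma) equal to `window` at every
#' frequency (so the number of cycles grows proportionally with
#' frequency).  Wavelets are L2-normalised; power is the squared magnitude
#' sampled every `step` seconds, returned as `10*log10(power)`.
#'
#' @param x Numeric signal, or a matrix of signals (one per row) sharing
#'   the time axis; the multi-signal form computes all spectrograms in one
#'   pass and returns a list.
#' @param fs Sampling rate (Hz).
#' @param freqs Frequency grid (default [log_freq_grid()]).
#' @param window Envelope full width (s).
#' @param step Time step between spectrogram columns (s).
#' @param t0 Time of the first sample of `x` (s); output column times are
#'   expressed on this axis (only columns where the full window fits are
#'   produced).
#' @return Object of class `spectrogram`: `values` (time x frequency, dB),
#'   `times`, `freqs`, `kind = "raw"`; a list of them for matrix input.
#' @export
morlet_spectrogram <- function(x, fs, freqs = log_freq_grid(),
                               window = 0.5, step = 0.025, t0 = 0) {
  multi <- is.matrix(x)
  xm <- if (multi) x else matrix(x, nrow = 1)
  n <- ncol(xm)
  k <- nrow(xm)
  bank <- .wavelet_bank(fs, freqs, window)
  half <- bank$half
  wl <- 2L * half + 1L
  if (n < wl) stop("signal shorter than the analysis window")
  step_n <- max(1L, round(step * fs))
  centers <- seq(half + 1L, n - half, by = step_n)
  nt <- length(centers)
  idx <- outer(centers, (-half):half, "+")         # nt x wl
  seg <- matrix(0, k * nt, wl)
  for (i in seq_len(k)) seg[(i - 1) * nt + seq_len(nt), ] <-
    matrix(xm[i, idx], nrow = nt)
  pw <- (seg %*% bank$Wr)^2 + (seg %*% bank$Wi)^2
  times <- t0 + (centers - 1) / fs
  mk <- function(i) structure(
    list(values = 10 * log10(pmax(pw[(i - 1) * nt + seq_len(nt), ,
                                     drop = FALSE], 1e-300)),
         times = times, freqs = freqs, kind = "raw"),
    class = "spectrogram")
  if (multi) lapply(seq_len(k), mk) else mk(1)
}

## wavelet bank cache: complex Morlet filters with a fixed-duration
## Gaussian envelope, L2-normalised; rebuilt only when fs, grid or window
## change
.bank_env <- new.env(parent = emptyenv())
.wavelet_bank <- function(fs, freqs, window) {
  key <- paste0(fs, "_", window, "_", length(freqs), "_",
                format(freqs[1], digits = 12), "_",
                format(freqs[length(freqs)], digits = 12))
  b <- .bank_env[[key]]
  if (!is.null(b)) return(b)
  half <- round(window * fs / 2)
  wl <- 2L * half + 1L
  wt <- (seq_len(wl) - half - 1) / fs
  sigma <- window / 6                     # +-3 sigma spans the window
  env <- exp(-wt^2 / (2 * sigma^2))
  ph <- 2 * pi * outer(wt, freqs)
  Wr <- env * cos(ph)
  Wi <- env * sin(ph)
  nrm <- sqrt(colSums(Wr^2 + Wi^2))
  Wr <- Wr / rep(nrm, each = wl)
  Wi <- Wi / rep(nrm, each = wl)
  b <- list(Wr = Wr, Wi = Wi, half = half)
  .bank_env[[key]] <- b
  b
}

#' Epoch spectrogram time-locked to a trial
#'
#' Extracts `[onset - pre, offset + post]` (plus the half window needed at
#' the edges) from a continuous signal and computes its Morlet spectrogram
#' with times relative to trial onset.
#'
#' @param x Continuous signal (or matrix of signals, one per row, for
#'   which a list of spectrograms is returned).
#' @param fs Sampling rate (Hz).
#' @param onset_sample,offset_sample Trial bounds (0-based samples).
#' @param pre,post Seconds of context before onset and after offset.
#' @param ... Passed to [morlet_spectrogram()].
#' @return A raw `spectrogram` with `onset = 0` and attribute `offset`
#'   (trial duration, s).
#' @export
epoch_spectrogram <- function(x, fs, onset_sample, offset_sample,
                              pre = 1.5, post = 1.5, window = 0.5,
                              step = 0.025, ...) {
  half <- round(window * fs / 2)
  step_n <- max(1L, round(step * fs))
  ## snap the epoch start to the column grid so that every trial's column
  ## times are exact multiples of the step relative to onset
  pre_n <- as.integer(ceiling(pre * fs / step_n) * step_n)
  i0 <- as.integer(onset_sample) + 1L - pre_n - half
  nlen <- if (is.matrix(x)) ncol(x) else length(x)
  i1 <- min(nlen, as.integer(offset_sample + post * fs + half))
  if (i0 < 1L)
    stop("insufficient pre-trial context for the requested epoch")
  seg <- if (is.matrix(x)) x[, i0:i1, drop = FALSE] else x[i0:i1]
  sp <- morlet_spectrogram(seg, fs, window = window, step = step,
                           t0 = (i0 - 1 - onset_sample) / fs, ...)
  off <- (offset_sample - onset_sample) / fs
  if (is.matrix(x)) {
    for (i in seq_along(sp)) sp[[i]]$offset <- off
  } else sp$offset <- off
  sp
}

#' Baseline-normalise a spectrogram
#'
#' Subtracts, per frequency, the mean log power over the pre-trial
#' baseline window from every column, storing the baseline spectrum.
#'
#' @param spec A raw `spectrogram` with times relative to trial onset.
#' @param baseline Two-element window (s) relative to onset.
#' @return A `spectrogram` with `kind = "normalized"` and
#'   `baseline_spectrum`.
#' @export
baseline_normalize <- function(spec, baseline = c(-1, -0.5)) {
  cols <- which(spec$times >= baseline[1] & spec$times <= baseline[2])
  if (!length(cols)) stop("no spectrogram columns in the baseline window")
  bs <- colMeans(spec$values[cols, , drop = FALSE])
  spec$values <- sweep(spec$values, 2, bs)
  spec$baseline_spectrum <- bs
  spec$baseline <- baseline
  spec$kind <- "normalized"
  spec
}

#' Linearly time-warp a spectrogram to a common trial duration
#'
#' Columns before onset are kept; columns between onset and offset are
#' linearly resampled (linear interpolation per frequency) onto a grid of
#' the same column spacing spanning `target_duration`; columns after
#' offset are appended unstretched with times shifted so the trial ends at
#' `target_duration`.
#'
#' @param spec A `spectrogram` (times relative to onset, onset at 0).
#' @param offset Trial offset time (s); defaults to `spec$offset`.
#' @param target_duration Common duration (s).
#' @return The warped `spectrogram` (`offset` set to `target_duration`).
#' @export
timewarp <- function(spec, offset = spec$offset, target_duration,
                     pre_keep = 1, post_keep = 1) {
  if (is.null(offset)) stop("trial offset unknown")
  if (offset <= 0) stop("offset must exceed onset")
  tt <- spec$times
  dt <- stats::median(diff(tt))
  eps <- dt / 2
  pre <- which(tt >= -pre_keep - eps & tt < -eps)
  new_mid_t <- seq(0, target_duration + eps, by = dt)
  new_mid_t <- new_mid_t[new_mid_t <= target_duration + eps]
  ## linear latency map [0, target] -> [0, offset]
  src_mid <- new_mid_t / max(target_duration, eps) * offset
  post_t <- target_duration + seq(dt, post_keep + eps, by = dt)
  src_post <- offset + (post_t - target_duration)
  src <- c(src_mid, src_post)
  keepable <- which(tt >= -eps)
  tk <- tt[keepable]
  vk <- spec$values[keepable, , drop = FALSE]
  ## vectorised two-point linear interpolation of every frequency column
  pos <- findInterval(src, tk, all.inside = TRUE)
  t0c <- tk[pos]; t1c <- tk[pos + 1]
  w1 <- (src - t0c) / (t1c - t0c)
  w1 <- pmin(1, pmax(0, w1))                       # rule-2 clamping
  vals_new <- (1 - w1) * vk[pos, , drop = FALSE] +
    w1 * vk[pos + 1, , drop = FALSE]
  spec$values <- rbind(spec$values[pre, , drop = FALSE], vals_new)
  spec$times <- c(tt[pre], new_mid_t, post_t)
  spec$offset <- target_duration
  spec$warped <- TRUE
  spec
}

## extract per-trial value arrays on a common grid, failing loudly when
## grids differ
.spec_stack <- function(specs) {
  t1 <- specs[[1]]$times; f1 <- specs[[1]]$freqs
  for (s in specs[-1])
    if (length(s$times) != length(t1) ||
        max(abs(s$times - t1)) > 1e-9 ||
        max(abs(s$freqs - f1)) > 1e-9)
      stop("spectrograms are not on a common time-frequency grid")
  array(unlist(lapply(specs, function(s) s$values)),
        dim = c(length(t1), length(f1), length(specs)))
}

#' Bootstrap significance mask for a set of trial spectrograms
#'
#' Builds, per frequency, a surrogate null distribution of the trial-mean
#' normalized dB value: each resample draws one random baseline column
#' per trial from the pool of all trials' raw (un-normalized) baseline
#' columns and one baseline level per trial from the pool of per-trial
#' baseline spectra, and averages their difference across trials.  The
#' observed grand average is thresholded at the two-tailed empirical
#' `alpha/2` and `1 - alpha/2` percentiles; non-significant values are
#' set to 0 dB.  Drawing columns across trials (rather than from each
#' trial's own baseline) matters for calibration: within one trial the
#' normalized baseline columns are centred by construction, so their
#' spread understates the null variability of in-trial points.
#'
#' @param specs List of baseline-normalised `spectrogram`s on a common
#'   grid (time-warped if durations differ).
#' @param alpha Two-tailed significance level.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param baseline Baseline window (s) from which null columns are drawn;
#'   defaults to the window stored in the first spectrogram.
#' @return A `spectrogram` whose `values` are the thresholded grand
#'   average, with `mask` (logical time x frequency), `grand` (unmasked
#'   grand average) and the per-frequency `lower`/`upper` thresholds.
#' @export
bootstrap_mask <- function(specs, alpha = 0.05, n_boot = 200, seed = 1,
                           baseline = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (n_boot < 50)
    warning("fewer than 50 bootstrap resamples; percentile thresholds ",
            "will be unstable")
  if (is.null(baseline)) baseline <- specs[[1]]$baseline
  if (is.null(baseline)) baseline <- c(-1, -0.5)
  arr <- .spec_stack(specs)
  tt <- specs[[1]]$times
  nt <- dim(arr)[1]; nf <- dim(arr)[2]; ntr <- dim(arr)[3]
  bcols <- which(tt >= baseline[1] & tt <= baseline[2])
  if (!length(bcols)) stop("no baseline columns available")
  ## per-trial baseline spectra (to restore raw columns); absent when the
  ## inputs were never normalized, in which case levels are zero
  B <- t(vapply(specs, function(s)
    if (is.null(s$baseline_spectrum)) numeric(nf) else s$baseline_spectrum,
    numeric(nf)))
  grand <- apply(arr, c(1, 2), mean)
  set.seed(seed)
  lower <- upper <- numeric(nf)
  nb <- length(bcols)
  for (f in seq_len(nf)) {
    ## pooled raw baseline columns across trials
    pool <- as.vector(matrix(arr[bcols, f, ], nb, ntr) +
                        rep(B[, f], each = nb))
    draw <- matrix(sample(pool, n_boot * ntr, replace = TRUE),
                   n_boot, ntr)
    lev <- matrix(sample(B[, f], n_boot * ntr, replace = TRUE),
                  n_boot, ntr)
    null <- rowMeans(draw) - rowMeans(lev)
    qs <- stats::quantile(null, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                          type = 7)
    lower[f] <- qs[1]; upper[f] <- qs[2]
  }
  mask <- sweep(grand, 2, lower, "<") | sweep(grand, 2, upper, ">")
  out <- specs[[1]]
  out$grand <- grand
  out$values <- ifelse(mask, grand, 0)
  out$mask <- mask
  out$lower <- lower
  out$upper <- upper
  out$alpha <- alpha
  out$n_trials <- ntr
  out$kind <- "masked"
  out
}

#' Mean significant desynchronization in a frequency band
#'
#' Mean of the masked grand-average dB values over the significant
#' time-frequency points with frequency in `band` and time inside the
#' trial (`[0, offset]`).
#'
#' @param masked A masked `spectrogram` from [bootstrap_mask()].
#' @param band Two-element frequency range (Hz), e.g. `c(8, 12)` for
#'   alpha or `c(12, 30)` for beta.
#' @param interval Time interval (s); defaults to the trial span.
#' @return List with `mean_db`, `n_points`, and `defined` (`FALSE` when no
#'   point is significant in the band).
#' @export
erd_statistic <- function(masked, band, interval = c(0, masked$offset)) {
  if (is.null(masked$mask)) stop("not a masked spectrogram")
  fsel <- masked$freqs >= band[1] & masked$freqs <= band[2]
  tsel <- masked$times >= interval[1] & masked$times <= interval[2]
  m <- masked$mask[tsel, fsel, drop = FALSE]
  v <- masked$grand[tsel, fsel, drop = FALSE]
  if (!any(m))
    return(list(mean_db = NA_real_, n_points = 0L, defined = FALSE))
  list(mean_db = mean(v[m]), n_points = sum(m), defined = TRUE)
}

#' Paired t-test of high- versus low-effort desynchronization
#'
#' Two-sided paired t-test across subjects.  A zero-variance nonzero
#' difference is treated as the analytic limit (`t = Inf`, `p = 0`).
#'
#' @param erd_high,erd_low Per-subject mean dB values (same order).
#' @return List with `t`, `p`, `df`, `mean_difference`.
#' @export
compare_effort_ttest <- function(erd_high, erd_low) {
  stopifnot(length(erd_high) == length(erd_low))
  d <- erd_high - erd_low
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd < 1e-12 * max(abs(md), 1e-300)) {
    if (abs(md) < 1e-300)
      return(list(t = 0, p = 1, df = n - 1, mean_difference = md))
    return(list(t = sign(md) * Inf, p = 0, df = n - 1,
                mean_difference = md))
  }
  tt <- md / (sdd / sqrt(n))
  list(t = tt, p = 2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE),
       df = n - 1, mean_difference = md)
}

#' Pointwise permutation comparison of two spectrogram sets
#'
#' Permutes condition labels across trials and thresholds the observed
#' mean difference map at two-tailed pointwise percentiles of the
#' permutation distribution.  When the number of distinct label
#' assignments is no larger than `n_perm`, all assignments are enumerated
#' exactly.
#'
#' @param specs_a,specs_b Lists of normalised `spectrogram`s on a common
#'   grid.
#' @param alpha Two-tailed level.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @return List with `difference` (mean A - mean B), `mask`, `lower`,
#'   `upper`, `n_perm_used`, `exact`.
#' @export
compare_conditions_permutation <- function(specs_a, specs_b, alpha = 0.05,
                                           n_perm = 500, seed = 1) {
  arr <- .spec_stack(c(specs_a, specs_b))
  na <- length(specs_a); nb <- length(specs_b)
  ntot <- na + nb
  nt <- dim(arr)[1]; nf <- dim(arr)[2]
  flat <- matrix(arr, nt * nf, ntot)      # points x trials
  obs <- rowMeans(flat[, seq_len(na), drop = FALSE]) -
    rowMeans(flat[, na + seq_len(nb), drop = FALSE])
  exact <- choose(ntot, na) <= n_perm
  if (exact) {
    combs <- utils::combn(ntot, na)
    perms <- lapply(seq_len(ncol(combs)), function(i) combs[, i])
  } else {
    set.seed(seed)
    perms <- lapply(seq_len(n_perm), function(i) sample(ntot, na))
  }
  nP <- length(perms)
  dist <- matrix(0, nt * nf, nP)
  tot <- rowSums(flat)
  for (i in seq_len(nP)) {
    sa <- rowSums(flat[, perms[[i]], drop = FALSE])
    dist[, i] <- sa / na - (tot - sa) / nb
  }
  qs <- t(apply(dist, 1, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), names = FALSE))
  mask <- obs < qs[, 1] | obs > qs[, 2]
  list(difference = matrix(obs, nt, nf),
       mask = matrix(mask, nt, nf),
       lower = matrix(qs[, 1], nt, nf),
       upper = matrix(qs[, 2], nt, nf),
       times = specs_a[[1]]$times, freqs = specs_a[[1]]$freqs,
       n_perm_used = nP, exact = exact)
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "%s spectrogram: %d times [%.2f, %.2f] s x %d freqs [%.3g, %.3g] Hz\n",
    x$kind, length(x$times), min(x$times), max(x$times),
    length(x$freqs), min(x$freqs), max(x$freqs)))
  if (!is.null(x$mask))
    cat(sprintf("  significant points: %.1f%% (alpha = %g, %d trials)\n",
                100 * mean(x$mask), x$alpha, x$n_trials))
  invisible(x)
}

#' Plot a spectrogram
#'
#' Time-frequency image on a log frequency axis with onset/offset markers;
#' masked (0 dB) points appear at mid-scale as in the usual
#' event-related spectral perturbation display.
#'
#' @param x A `spectrogram`.
#' @param zlim Colour limits (dB); default symmetric about 0.
#' @param ... Passed to [graphics::image()].
#' @export
plot.spectrogram <- function(x, zlim = NULL, ...) {
  v <- x$values
  if (is.null(zlim)) {
    m <- max(abs(v), na.rm = TRUE)
    zlim <- c(-m, m)
  }
  pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  graphics::image(x$times, log10(x$freqs), v, zlim = zlim, col = pal,
                  xlab = "time (s)", ylab = "log10 frequency (Hz)", ...)
  graphics::abline(v = 0, lwd = 2)
  if (!is.null(x$offset)) graphics::abline(v = x$offset, lwd = 2)
  invisible(x)
}
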