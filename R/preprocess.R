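#' Zero-phase high-pass filter
#'
#' Forward-backward (zero phase lag) Butterworth high-pass; the effective
#' magnitude response is the squared filter response and the DC component
#' is removed.
#'
#' @param rec An `eeg_recording` or channels x samples matrix.
#' @param cutoff Cutoff frequency (Hz).
#' @param order Butterworth order of the one-pass filter (the
#'   forward-backward application doubles the effective order).
#' @param fs Sampling rate; taken from the recording when available.
#' @return Filtered object of the same type.
#' @export
highpass <- function(rec, cutoff = 1, order = 4, fs = NULL) {
  is_rec <- inherits(rec, "eeg_recording")
  x <- if (is_rec) rec$eeg else as.matrix(rec)
  if (is.null(fs)) fs <- if (is_rec) rec$fs_eeg else
    stop("fs required for a plain matrix")
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  ## remove the mean first: filtfilt start-up transients on a large DC
  ## offset would otherwise bleed into the record edges
  x <- x - rowMeans(x)
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- signal::filtfilt(bf, x[ch, ])
  if (is_rec) {
    rec$eeg <- x
    rec
  } else x
}

#' Reject noisy channels
#'
#' Applies, in order, the three channel-quality rules: (1) remove channels
#' with sample standard deviation at or above `std_limit`; (2) remove
#' channels whose kurtosis exceeds the across-channel mean kurtosis by
#' more than `kurt_z` standard deviations (statistics computed once on the
#' rule-1 survivors); (3) split the record into windows of `window_s`
#' seconds and remove channels whose maximum absolute Pearson correlation
#' against their `n_neighbors` nearest neighbours (3-D electrode distance)
#' is at or below `r_limit` in more than `max_uncorrelated` of the
#' windows.
#'
#' @param rec An `eeg_recording` with electrode positions.
#' @param std_limit Rule-1 standard deviation limit (microvolts).
#' @param kurt_z Rule-2 z-score threshold.
#' @param r_limit Rule-3 correlation threshold.
#' @param max_uncorrelated Rule-3 maximum tolerated fraction of
#'   uncorrelated windows.
#' @param window_s Rule-3 window length (s).
#' @param n_neighbors Number of nearest neighbours for rule 3.
#' @return List with the reduced `recording` and a `rejection_report`
#'   (per-channel verdicts, thresholds, retained count and fraction).
#' @export
reject_channels <- function(rec, std_limit = 1000, kurt_z = 3,
                            r_limit = 0.4, max_uncorrelated = 0.001,
                            window_s = 1, n_neighbors = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$electrode_positions))
    stop("channel rejection requires electrode positions")
  x <- rec$eeg
  nch <- nrow(x)
  if (nch < 8) stop("channel rejection requires at least 8 channels")
  verdict <- rep("kept", nch)
  names(verdict) <- rec$channel_labels

  ## rule 1: amplitude
  sds <- apply(x, 1, stats::sd)
  verdict[sds >= std_limit] <- "rejected_std"

  ## rule 2: kurtosis of rule-1 survivors, single pass
  surv1 <- which(verdict == "kept")
  kur <- apply(x[surv1, , drop = FALSE], 1, function(v) {
    v <- v - mean(v)
    mean(v^4) / mean(v^2)^2
  })
  kz <- (kur - mean(kur)) / stats::sd(kur)
  verdict[surv1[kz > kurt_z]] <- "rejected_kurtosis"

  ## rule 3: windowed neighbour correlation on rule-1/2 survivors
  surv2 <- which(verdict == "kept")
  pos <- rec$electrode_positions
  dmat <- as.matrix(stats::dist(pos[surv2, , drop = FALSE]))
  diag(dmat) <- Inf
  nn <- t(apply(dmat, 1, function(d)
    order(d)[seq_len(min(n_neighbors, length(d) - 1))]))
  wlen <- max(2L, round(window_s * rec$fs_eeg))
  nwin <- floor(ncol(x) / wlen)
  if (nwin >= 1) {
    ns <- length(surv2)
    nnb <- ncol(nn)
    unc <- matrix(FALSE, ns, nwin)
    for (w in seq_len(nwin)) {
      seg <- x[surv2, ((w - 1) * wlen + 1):(w * wlen), drop = FALSE]
      seg <- seg - rowMeans(seg)
      sdv <- sqrt(rowSums(seg^2))
      sdv[sdv < .Machine$double.eps] <- Inf
      cc <- abs(tcrossprod(seg / sdv))
      cc[!is.finite(cc)] <- 0
      rmax <- cc[cbind(seq_len(ns), nn[, 1])]
      for (j in seq_len(nnb)[-1])
        rmax <- pmax(rmax, cc[cbind(seq_len(ns), nn[, j])])
      unc[, w] <- rmax <= r_limit
    }
    frac <- rowMeans(unc)
    verdict[surv2[frac > max_uncorrelated]] <- "rejected_correlation"
  }

  keep <- which(verdict == "kept")
  if (length(keep) < 8)
    stop("fewer than 8 channels survive rejection; downstream ICA is ",
         "unsupported")
  out <- rec
  out$eeg <- x[keep, , drop = FALSE]
  out$channel_labels <- rec$channel_labels[keep]
  out$electrode_positions <- rec$electrode_positions[keep, , drop = FALSE]
  report <- structure(
    list(verdict = verdict,
         thresholds = list(std_limit = std_limit, kurt_z = kurt_z,
                           r_limit = r_limit,
                           max_uncorrelated = max_uncorrelated,
                           window_s = window_s, n_neighbors = n_neighbors),
         retained = length(keep),
         n_channels = nch,
         retained_fraction = length(keep) / nch),
    class = "rejection_report")
  list(recording = out, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  tab <- table(factor(x$verdict,
                      levels = c("kept", "rejected_std",
                                 "rejected_kurtosis",
                                 "rejected_correlation")))
  cat(sprintf("Channel rejection: %d of %d retained (%.1f%%)\n",
              x$retained, x$n_channels, 100 * x$retained_fraction))
  for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across retained channels.
#' Idempotent; column means of the result are numerically zero.
#'
#' @param rec An `eeg_recording` or channels x samples matrix.
#' @return Same type, average-referenced.
#' @export
rereference_average <- function(rec) {
  is_rec <- inherits(rec, "eeg_recording")
  x <- if (is_rec) rec$eeg else as.matrix(rec)
  x <- sweep(x, 2, colMeans(x))
  if (is_rec) {
    rec$eeg <- x
    rec
  } else x
}

#' Refine trial bounds from a mechanical channel
#'
#' For each nominal trial, estimates the onset and offset of the actual
#' effort from the auxiliary channel: force for isometric trials, absolute
#' angular deviation for isotonic trials.  The baseline is the median of
#' the second preceding the nominal onset; the detection threshold is
#' baseline + `threshold` of the peak-to-baseline range (with a small
#' hysteresis band for the offset); onset is the first crossing and offset
#' the last.  When no crossing is found the nominal bounds are kept and a
#' warning logged.
#'
#' @param rec An `eeg_recording` with `force` and `angle` aux channels.
#' @param events A `trial_events` table (EEG samples).
#' @param threshold Fraction of the peak-to-baseline range.
#' @param hysteresis Offset threshold is `threshold - hysteresis`.
#' @param search_s Search window (s) around the nominal bounds.
#' @return The events table with refined `onset_sample`/`offset_sample`
#'   (EEG sample units) and a logical attribute `refined` per row.
#' @export
detect_trial_bounds <- function(rec, events, threshold = 0.10,
                                hysteresis = 0.02, search_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_eeg
  fsa <- rec$fs_aux
  refined <- logical(nrow(events))
  out <- events
  for (j in seq_len(nrow(events))) {
    sig <- if (events$mode[j] == "isometric") rec$aux$force else
      rec$aux$angle
    if (is.null(sig)) next
    on_a <- events$onset_sample[j] / fs * fsa
    off_a <- events$offset_sample[j] / fs * fsa
    i0 <- max(1L, as.integer(on_a - search_s * fsa))
    i1 <- min(length(sig), as.integer(off_a + search_s * fsa))
    b0 <- max(1L, as.integer(on_a - fsa))
    base <- stats::median(sig[b0:max(b0, as.integer(on_a))])
    seg <- sig[i0:i1]
    dev <- if (events$mode[j] == "isometric") seg - base else
      abs(seg - base)
    pk <- max(dev)
    if (pk <= 0) {
      warning(sprintf("trial %d: flat auxiliary signal; keeping nominal bounds", j))
      next
    }
    thr_on <- threshold * pk
    thr_off <- max(0, threshold - hysteresis) * pk
    above_on <- which(dev > thr_on)
    if (!length(above_on)) {
      warning(sprintf("trial %d: no threshold crossing; keeping nominal bounds", j))
      next
    }
    onset_a <- i0 - 1L + above_on[1]
    above_off <- which(dev > thr_off)
    offset_a <- i0 - 1L + above_off[length(above_off)]
    out$onset_sample[j] <- as.integer(round((onset_a - 1) / fsa * fs))
    out$offset_sample[j] <- as.integer(round((offset_a - 1) / fsa * fs))
    refined[j] <- TRUE
  }
  attr(out, "refined") <- refined
  out
}
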