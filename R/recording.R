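#' EEG recording container
#'
#' Bundles a multichannel EEG matrix with its sampling rate, channel labels,
#' 3-D electrode positions and auxiliary mechanical channels (load-cell
#' force, joint angle) sampled on their own clock.  The head frame has its
#' origin at the scalp-sphere centre, +X right, +Y anterior, +Z superior.
#'
#' @param eeg Channels x samples numeric matrix (microvolts).
#' @param fs_eeg EEG sampling rate in Hz.
#' @param channel_labels Character vector, one label per EEG row.
#' @param electrode_positions Channels x 3 matrix (mm).
#' @param aux Named list of auxiliary numeric signals (e.g. `force` in N,
#'   `angle` in degrees).
#' @param fs_aux Auxiliary sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param position_tolerance Allowed relative radial deviation of electrodes
#'   from the scalp sphere.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(eeg, fs_eeg = 512, channel_labels = NULL,
                      electrode_positions = NULL, aux = list(),
                      fs_aux = 1000, subject_id = "S01",
                      position_tolerance = 0.01) {
  eeg <- as.matrix(eeg)
  if (is.null(channel_labels))
    channel_labels <- sprintf("E%03d", seq_len(nrow(eeg)))
  stopifnot(fs_eeg > 0, fs_aux > 0)
  if (nrow(eeg) != length(channel_labels))
    stop("eeg row count does not match the number of channel labels")
  if (!is.null(electrode_positions)) {
    electrode_positions <- as.matrix(electrode_positions)
    if (nrow(electrode_positions) != nrow(eeg))
      stop("eeg row count does not match the electrode position table")
    r <- sqrt(rowSums(electrode_positions^2))
    if (diff(range(r)) > 2 * position_tolerance * stats::median(r))
      stop("electrode positions do not lie on a common scalp sphere ",
           "within the radial tolerance")
  }
  structure(list(eeg = eeg, fs_eeg = fs_eeg,
                 channel_labels = as.character(channel_labels),
                 electrode_positions = electrode_positions,
                 aux = aux, fs_aux = fs_aux,
                 subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording '%s': %d channels x %d samples at %g Hz (%.1f s)\n",
    x$subject_id, nrow(x$eeg), ncol(x$eeg), x$fs_eeg,
    ncol(x$eeg) / x$fs_eeg))
  if (length(x$aux))
    cat(sprintf("  aux channels (%g Hz): %s\n", x$fs_aux,
                paste(names(x$aux), collapse = ", ")))
  invisible(x)
}

#' Trial event table
#'
#' Validated table of per-repetition trial bounds and factor labels.
#' Sample indices are 0-based and intervals half-open `[onset, offset)`.
#'
#' @param onset_sample,offset_sample Integer EEG sample indices.
#' @param joint `"knee"` or `"ankle"`.
#' @param mode `"isometric"` or `"isotonic"`.
#' @param direction `"flexion"` or `"extension"` (for the ankle,
#'   plantarflexion is coded as flexion and dorsiflexion as extension).
#' @param effort `"high"` or `"low"`.
#' @return A `data.frame` of class `trial_events`.
#' @export
trial_events <- function(onset_sample, offset_sample, joint, mode,
                         direction, effort) {
  ev <- data.frame(onset_sample = as.integer(onset_sample),
                   offset_sample = as.integer(offset_sample),
                   joint = as.character(joint),
                   mode = as.character(mode),
                   direction = as.character(direction),
                   effort = as.character(effort),
                   stringsAsFactors = FALSE)
  validate_trial_events(ev)
  class(ev) <- c("trial_events", "data.frame")
  ev
}

#' Validate a trial event table
#'
#' Checks factor levels, `onset < offset` per row, sorted non-overlapping
#' trials, and the protocol constraint that isotonic knee flexion does not
#' occur.
#' @param ev A data frame with the six trial-event columns.
#' @return Invisibly, `ev`.
#' @export
validate_trial_events <- function(ev) {
  need <- c("onset_sample", "offset_sample", "joint", "mode", "direction",
            "effort")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events table lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(ev$offset_sample <= ev$onset_sample)
  if (length(bad))
    stop("offset_sample <= onset_sample in event row(s) ",
         paste(bad, collapse = ", "))
  chk <- function(col, lv) {
    b <- which(!ev[[col]] %in% lv)
    if (length(b)) stop("invalid ", col, " in event row(s) ",
                        paste(b, collapse = ", "))
  }
  chk("joint", c("knee", "ankle"))
  chk("mode", c("isometric", "isotonic"))
  chk("direction", c("flexion", "extension"))
  chk("effort", c("high", "low"))
  if (nrow(ev) > 1) {
    if (is.unsorted(ev$onset_sample, strictly = TRUE))
      stop("events are not sorted by onset")
    ov <- which(ev$onset_sample[-1] < ev$offset_sample[-nrow(ev)])
    if (length(ov))
      stop("overlapping trials at event row(s) ",
           paste(ov + 1, collapse = ", "))
  }
  ikf <- which(ev$joint == "knee" & ev$mode == "isotonic" &
                 ev$direction == "flexion")
  if (length(ikf))
    stop("isotonic knee flexion is not part of the protocol (row(s) ",
         paste(ikf, collapse = ", "), ")")
  invisible(ev)
}

## four-way condition label (mode x effort) used by the decoder
condition_label <- function(ev) {
  paste(ev$effort, ev$mode, sep = "_")
}
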