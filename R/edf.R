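## Minimal EDF (European Data Format) support: 16-bit integer samples,
## one-second data records, per-signal sampling rates.  Only the features
## needed to round-trip this package's recordings are implemented.

.edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

.edf_num <- function(x, width) {
  for (d in 8:2) {
    s <- formatC(x, format = "g", digits = d, width = -1)
    if (nchar(s) <= width) return(.edf_pad(s, width))
  }
  .edf_pad(formatC(x, format = "e", digits = 1), width)
}

#' Write an EEG recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a per-channel symmetric
#' physical range.  EEG channels keep their labels; auxiliary channels are
#' written with an `AUX `-prefixed label and their own sampling rate.
#' Signals are zero-padded to a whole number of one-second data records.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param aux_prefix Label prefix marking auxiliary channels.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path, aux_prefix = "AUX") {
  stopifnot(inherits(rec, "eeg_recording"))
  sigs <- c(lapply(seq_len(nrow(rec$eeg)), function(i)
    list(label = rec$channel_labels[i], fs = rec$fs_eeg,
         x = rec$eeg[i, ], dim = "uV")),
    lapply(names(rec$aux), function(nm)
      list(label = paste(aux_prefix, nm), fs = rec$fs_aux,
           x = as.numeric(rec$aux[[nm]]),
           dim = if (nm == "force") "N" else "deg")))
  ns <- length(sigs)
  for (s in sigs) if (any(!is.finite(s$x)))
    stop("non-finite sample value in signal '", s$label, "'")
  n_rec <- max(vapply(sigs, function(s) ceiling(length(s$x) / s$fs),
                      numeric(1)))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec$subject_id, 80),
    .edf_pad("eegmix synthetic recording", 80),
    .edf_pad("01.01.20", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  qparam <- lapply(sigs, function(s) {
    pm <- max(abs(s$x), 1e-6)
    ## quantize against the value the 8-character header field can hold,
    ## so writer and reader use the identical physical range
    pm <- as.numeric(trimws(.edf_num(pm, 8)))
    if (pm < max(abs(s$x))) pm <- pm * (1 + 1e-3)
    pm <- as.numeric(trimws(.edf_num(pm, 8)))
    list(pmin = -pm, pmax = pm, dmin = -32768L, dmax = 32767L)
  })
  field <- function(f, width)
    writeChar(paste0(vapply(seq_len(ns), f, character(1)), collapse = ""),
              con, eos = NULL)
  field(function(i) .edf_pad(sigs[[i]]$label, 16), 16)
  field(function(i) .edf_pad("", 80), 80)
  field(function(i) .edf_pad(sigs[[i]]$dim, 8), 8)
  field(function(i) .edf_num(qparam[[i]]$pmin, 8), 8)
  field(function(i) .edf_num(qparam[[i]]$pmax, 8), 8)
  field(function(i) .edf_pad(qparam[[i]]$dmin, 8), 8)
  field(function(i) .edf_pad(qparam[[i]]$dmax, 8), 8)
  field(function(i) .edf_pad("", 80), 80)
  field(function(i) .edf_pad(sigs[[i]]$fs, 8), 8)
  field(function(i) .edf_pad("", 32), 32)
  ## digitize
  dig <- lapply(seq_len(ns), function(i) {
    s <- sigs[[i]]; q <- qparam[[i]]
    x <- c(s$x, numeric(n_rec * s$fs - length(s$x)))
    d <- round((x - q$pmin) / (q$pmax - q$pmin) * (q$dmax - q$dmin) +
                 q$dmin)
    as.integer(pmin(pmax(d, q$dmin), q$dmax))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      fsr <- sigs[[i]]$fs
      writeBin(dig[[i]][((r - 1) * fsr + 1):(r * fsr)], con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param aux_prefix Label prefix marking auxiliary channels.
#' @return List with `eeg` (channels x samples), `channel_labels`,
#'   `fs_eeg`, `aux` (named list), `fs_aux`, `subject_id`.
#' @export
read_edf <- function(path, aux_prefix = "AUX") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  subject_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- per(16)
  per(80)
  dims <- per(8)
  pmin <- as.numeric(per(8)); pmax <- as.numeric(per(8))
  dmin <- as.numeric(per(8)); dmax <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8))
  per(32)
  sig <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                   endian = "little")
      sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  is_aux <- startsWith(labels, aux_prefix)
  eeg_idx <- which(!is_aux)
  aux_idx <- which(is_aux)
  eeg <- do.call(rbind, sig[eeg_idx])
  aux <- sig[aux_idx]
  names(aux) <- trimws(sub(paste0("^", aux_prefix, "\\s*"), "",
                           labels[aux_idx]))
  list(eeg = eeg, channel_labels = labels[eeg_idx],
       fs_eeg = spr[eeg_idx[1]] / rec_dur,
       aux = aux,
       fs_aux = if (length(aux_idx)) spr[aux_idx[1]] / rec_dur else 1000,
       subject_id = subject_id)
}

#' Write a recording, events and electrode positions to disk
#'
#' Writes `<prefix>.edf` (signals), `<prefix>_events.tsv` (the six-column
#' trial table) and `<prefix>_positions.tsv` (label, x, y, z in mm).
#'
#' @param rec An `eeg_recording`.
#' @param events A `trial_events` table.
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths.
#' @export
write_recording <- function(rec, events, prefix) {
  validate_trial_events(events)
  paths <- c(edf = paste0(prefix, ".edf"),
             events = paste0(prefix, "_events.tsv"),
             positions = paste0(prefix, "_positions.tsv"))
  write_edf(rec, paths[["edf"]])
  utils::write.table(as.data.frame(events)[, c(
    "onset_sample", "offset_sample", "joint", "mode", "direction",
    "effort")], paths[["events"]], sep = "\t", quote = FALSE,
    row.names = FALSE)
  pos <- data.frame(label = rec$channel_labels,
                    rec$electrode_positions)
  colnames(pos) <- c("label", "x", "y", "z")
  utils::write.table(pos, paths[["positions"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a recording, events and electrode positions
#'
#' @param signal_path EDF file written by [write_recording()] (or any EDF
#'   whose auxiliary channels are labelled with `aux_prefix`).
#' @param events_path Tab-separated trial table with the six event
#'   columns.
#' @param positions_path Tab-separated electrode table (label, x, y, z);
#'   default derived from `signal_path`.
#' @param aux_prefix Auxiliary channel label prefix.
#' @return List with the `eeg_recording` and the `trial_events`.
#' @export
read_recording <- function(signal_path, events_path,
                           positions_path = NULL, aux_prefix = "AUX") {
  if (is.null(positions_path))
    positions_path <- sub("\\.edf$", "_positions.tsv", signal_path)
  e <- read_edf(signal_path, aux_prefix)
  pos <- utils::read.table(positions_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing_ch <- setdiff(pos$label, e$channel_labels)
  if (length(missing_ch))
    stop("channels named in the position table are absent from the EDF: ",
         paste(missing_ch, collapse = ", "))
  m <- match(e$channel_labels, pos$label)
  if (any(is.na(m)))
    stop("no electrode position for channel(s): ",
         paste(e$channel_labels[is.na(m)], collapse = ", "))
  ev <- utils::read.table(events_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ev <- trial_events(ev$onset_sample, ev$offset_sample, ev$joint, ev$mode,
                     ev$direction, ev$effort)
  rec <- recording(e$eeg, fs_eeg = e$fs_eeg,
                   channel_labels = e$channel_labels,
                   electrode_positions = as.matrix(pos[m, c("x", "y", "z")]),
                   aux = e$aux, fs_aux = e$fs_aux,
                   subject_id = e$subject_id)
  list(recording = rec, events = ev)
}
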