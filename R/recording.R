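#' Multichannel bipolar electrogram recording
#'
#' Container for a block of bipolar voltage electrograms (BVE) from a
#' circular mapping catheter. Channels are stored in catheter-adjacency
#' order around the loop; the loop is circularly closed, so the neighbours
#' of bipole `i` are `i - 1` and `i + 1` modulo the channel count. All
#' amplitudes are in millivolts.
#'
#' @param samples numeric matrix, one column per bipole, one row per sample
#'   (millivolts).
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param channels character vector of bipole names in adjacency order;
#'   defaults to `"b1"`, `"b2"`, ...
#' @param record_id opaque identifier string.
#'
#' @return An object of class `pv_recording` with fields `record_id`, `fs`,
#'   `channels`, `samples` (matrix) and `n_samples`.
#' @export
pv_recording <- function(samples, fs, channels = NULL, record_id = "rec") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (is.null(channels)) channels <- paste0("b", seq_len(ncol(samples)))
  channels <- as.character(channels)
  if (length(channels) != ncol(samples))
    stop("channel name count does not match sample columns")
  if (ncol(samples) < 2) stop("a recording needs at least 2 channels")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  bad <- !is.finite(samples)
  if (any(bad)) {
    ch <- channels[unique(((which(bad) - 1) %/% nrow(samples)) + 1)]
    stop("non-finite amplitudes in channel(s): ", paste(ch, collapse = ", "))
  }
  colnames(samples) <- channels
  structure(
    list(record_id = as.character(record_id), fs = as.numeric(fs),
         channels = channels, samples = samples, n_samples = nrow(samples)),
    class = "pv_recording")
}

#' @export
print.pv_recording <- function(x, ...) {
  cat(sprintf("<pv_recording '%s': %d channels x %d samples @ %g Hz (%.1f ms)>\n",
              x$record_id, length(x$channels), x$n_samples, x$fs,
              1000 * x$n_samples / x$fs))
  invisible(x)
}

#' Recording duration in milliseconds
#' @param rec a [pv_recording()].
#' @return duration in ms.
#' @export
recording_duration_ms <- function(rec) 1000 * rec$n_samples / rec$fs

#' Circular neighbours of a bipole
#'
#' Loop-catheter geometry: the bipoles form a closed ring, so channel 1 and
#' channel K are adjacent.
#'
#' @param i channel index (1-based).
#' @param k number of channels on the ring.
#' @return integer vector of length 2: left and right neighbour indices.
#' @export
ring_neighbors <- function(i, k) {
  c(((i - 2) %% k) + 1, (i %% k) + 1)
}

pv_veins  <- c("LSPV", "LIPV", "RSPV", "RIPV")
pv_phases <- c("before", "during", "after")
pv_labels <- c("PV-NF", "atrial-FF", "combined")

#' Beat annotation
#'
#' One manually (or synthetically) delimited electrogram on one recording.
#' The window is expressed in milliseconds from the first sample of the
#' recording; the sample mapping is half-open:
#' `floor(onset_ms * fs / 1000)` inclusive to `ceil(offset_ms * fs / 1000)`
#' exclusive, so adjacent windows never double-count a sample.
#'
#' Labels follow the three classes seen during a cryoballoon freeze:
#' `"PV-NF"` (local pulmonary-vein nearfield only), `"atrial-FF"` (atrial
#' farfield only) and `"combined"` (superimposed FF and NF). After complete
#' isolation the vein can no longer produce a nearfield, so `"PV-NF"` is
#' invalid in phase `"after"`.
#'
#' @param record_id,patient_id identifier strings.
#' @param vein one of `"LSPV"`, `"LIPV"`, `"RSPV"`, `"RIPV"`.
#' @param phase one of `"before"`, `"during"`, `"after"` (relative to the
#'   freeze cycle).
#' @param onset_ms,offset_ms beat window bounds in ms (0 <= onset < offset).
#' @param label one of `"PV-NF"`, `"atrial-FF"`, `"combined"`.
#' @param laa_lspv_distance_mm optional non-negative distance between the
#'   left atrial appendage and the LSPV (anatomical metadata).
#' @return An object of class `pv_beat`.
#' @export
pv_beat <- function(record_id, patient_id, vein, phase, onset_ms, offset_ms,
                    label, laa_lspv_distance_mm = NA_real_) {
  vein  <- match.arg(vein, pv_veins)
  phase <- match.arg(phase, pv_phases)
  label <- match.arg(label, pv_labels)
  onset_ms <- as.numeric(onset_ms); offset_ms <- as.numeric(offset_ms)
  if (!is.finite(onset_ms) || !is.finite(offset_ms))
    stop("onset_ms/offset_ms must be finite")
  if (onset_ms < 0) stop("onset_ms must be >= 0")
  if (onset_ms >= offset_ms)
    stop("onset_ms must be strictly before offset_ms")
  if (phase == "after" && label == "PV-NF")
    stop("label 'PV-NF' is impossible in phase 'after': ",
         "the isolated vein has no nearfield")
  d <- as.numeric(laa_lspv_distance_mm)
  if (!is.na(d) && d < 0) stop("laa_lspv_distance_mm must be non-negative")
  structure(
    list(record_id = as.character(record_id),
         patient_id = as.character(patient_id),
         vein = vein, phase = phase,
         onset_ms = onset_ms, offset_ms = offset_ms, label = label,
         laa_lspv_distance_mm = d),
    class = "pv_beat")
}

#' @export
print.pv_beat <- function(x, ...) {
  cat(sprintf("<pv_beat %s/%s %s/%s [%g, %g) ms: %s>\n",
              x$patient_id, x$record_id, x$vein, x$phase,
              x$onset_ms, x$offset_ms, x$label))
  invisible(x)
}

#' Beat window as sample indices
#'
#' Half-open mapping from milliseconds to 1-based sample indices.
#'
#' @param beat a [pv_beat()].
#' @param rec the [pv_recording()] it annotates.
#' @return integer vector of row indices into `rec$samples`.
#' @export
beat_sample_index <- function(beat, rec) {
  lo <- floor(beat$onset_ms * rec$fs / 1000)        # 0-based inclusive
  hi <- ceiling(beat$offset_ms * rec$fs / 1000)     # 0-based exclusive
  if (hi > rec$n_samples)
    stop("beat window [", beat$onset_ms, ", ", beat$offset_ms,
         ") ms exceeds the recording (", recording_duration_ms(rec), " ms)")
  seq.int(lo + 1, hi)
}

#' Extract the beat segment from one channel
#' @param rec a [pv_recording()].
#' @param beat a [pv_beat()].
#' @param channel channel index (1-based).
#' @return numeric vector of samples in mV.
#' @export
beat_segment <- function(rec, beat, channel) {
  rec$samples[beat_sample_index(beat, rec), channel]
}

#' Is a label nearfield-positive?
#'
#' The binary clinical question is the presence of a pulmonary-vein
#' nearfield component: `"PV-NF"` and `"combined"` count as nearfield,
#' `"atrial-FF"` as farfield.
#'
#' @param label character vector of beat labels.
#' @return logical vector.
#' @export
is_nearfield_label <- function(label) label %in% c("PV-NF", "combined")
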