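#' Acquisition-chain filter configuration
#'
#' The clinical recording chain applies a 30--300 Hz band-pass and a 50 Hz
#' mains notch to every intracardiac bipolar channel. The band-pass is
#' realized as a 4th-order Butterworth and the notch as a 2nd-order IIR
#' biquad; both are run forward-backward (zero phase) so that onset timing
#' and slew-rate morphology are not distorted.
#'
#' @param hp_hz high-pass cut-off in Hz (default 30).
#' @param lp_hz low-pass cut-off in Hz (default 300).
#' @param notch_hz mains notch centre frequency in Hz (default 50).
#' @param notch_q notch quality factor (default 30; bandwidth = notch_hz/Q).
#' @param enabled if `FALSE`, [apply_standard_filters()] passes the signal
#'   through untouched — for synthetic inputs that are band-limited by
#'   construction.
#' @return a `filter_config` list.
#' @export
filter_config <- function(hp_hz = 30, lp_hz = 300, notch_hz = 50,
                          notch_q = 30, enabled = TRUE) {
  if (!(hp_hz > 0 && hp_hz < lp_hz))
    stop("need 0 < hp_hz < lp_hz")
  if (notch_q <= 0) stop("notch_q must be positive")
  structure(list(hp_hz = hp_hz, lp_hz = lp_hz, notch_hz = notch_hz,
                 notch_q = notch_q, enabled = isTRUE(enabled)),
            class = "filter_config")
}

# RBJ audio-cookbook notch biquad; r-signal offers no notch designer.
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply the standard acquisition filters to a recording
#'
#' Zero-phase band-pass plus mains notch, per channel. Output length equals
#' input length; filtering is linear, so superpositions of inputs map to
#' superpositions of outputs.
#'
#' @param rec a [pv_recording()].
#' @param cfg a [filter_config()].
#' @return filtered [pv_recording()].
#' @export
apply_standard_filters <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!cfg$enabled) return(rec)
  nyq <- rec$fs / 2
  if (cfg$hp_hz >= nyq)
    stop("hp_hz ", cfg$hp_hz, " Hz is at or above Nyquist (", nyq, " Hz)")
  if (!(cfg$notch_hz > 0 && cfg$notch_hz < nyq))
    stop("notch_hz must lie in (0, fs/2)")
  out <- rec$samples
  if (cfg$lp_hz < nyq) {
    bp <- signal::butter(2, c(cfg$hp_hz, cfg$lp_hz) / nyq, type = "pass")
  } else {
    # low-pass edge at/above Nyquist: the band-pass degenerates to high-pass
    bp <- signal::butter(4, cfg$hp_hz / nyq, type = "high")
  }
  nf <- design_notch(cfg$notch_hz, rec$fs, cfg$notch_q)
  for (j in seq_len(ncol(out))) {
    x <- signal::filtfilt(bp, out[, j])
    out[, j] <- signal::filtfilt(signal::Arma(b = nf$b, a = nf$a), x)
  }
  pv_recording(out, fs = rec$fs, channels = rec$channels,
               record_id = rec$record_id)
}

#' Noise-gate configuration
#'
#' Noisy electrograms are discarded by comparing the RMS of a quiet
#' reference period immediately before the beat (before the P-wave) with
#' the RMS of the beat itself. A beat whose baseline is too large relative
#' to its own content carries no usable signal.
#'
#' @param reference_window_ms length of the pre-beat baseline window in ms
#'   (default 50).
#' @param ratio_threshold maximum allowed baseline-RMS / beat-RMS in (0, 1]
#'   (default 0.2); the comparison is strict, so a ratio exactly at the
#'   threshold is accepted.
#' @param all_channels_must_fail if `TRUE` (default) a beat is rejected only
#'   when every channel fails the ratio test, since feature extraction later
#'   keeps a single best channel; set `FALSE` to reject when any channel
#'   fails.
#' @return a `noise_gate_config` list.
#' @export
noise_gate_config <- function(reference_window_ms = 50, ratio_threshold = 0.2,
                              all_channels_must_fail = TRUE) {
  if (reference_window_ms <= 0) stop("reference_window_ms must be > 0")
  if (!(ratio_threshold > 0 && ratio_threshold <= 1))
    stop("ratio_threshold must lie in (0, 1]")
  structure(list(reference_window_ms = reference_window_ms,
                 ratio_threshold = ratio_threshold,
                 all_channels_must_fail = isTRUE(all_channels_must_fail)),
            class = "noise_gate_config")
}

rms <- function(x) sqrt(mean(x^2))

#' Assess a beat against the baseline noise gate
#'
#' The decision is scale-invariant: rescaling the whole recording leaves
#' every baseline/beat RMS ratio, and hence the decision, unchanged.
#'
#' @param rec a [pv_recording()] (typically already filtered).
#' @param beat a [pv_beat()] whose reference window
#'   `[onset - reference_window_ms, onset)` must lie inside the recording.
#' @param cfg a [noise_gate_config()].
#' @return list with `decision` (`"accept"`/`"reject"`), `baseline_ratio`
#'   (the smallest per-channel ratio: the ratio on the most favourable
#'   channel) and `channel_ratios`.
#' @export
assess_noise <- function(rec, beat, cfg = noise_gate_config()) {
  stopifnot(inherits(cfg, "noise_gate_config"))
  ref_onset <- beat$onset_ms - cfg$reference_window_ms
  if (ref_onset < 0)
    stop("reference window [", ref_onset, ", ", beat$onset_ms,
         ") ms starts before the recording")
  lo <- floor(ref_onset * rec$fs / 1000) + 1
  hi <- ceiling(beat$onset_ms * rec$fs / 1000)
  idx_beat <- beat_sample_index(beat, rec)
  ratios <- vapply(seq_along(rec$channels), function(j) {
    base_rms <- rms(rec$samples[lo:hi, j])
    beat_rms <- rms(rec$samples[idx_beat, j])
    if (beat_rms == 0) Inf else base_rms / beat_rms
  }, numeric(1))
  fails <- ratios > cfg$ratio_threshold          # strict: equality accepts
  rejected <- if (cfg$all_channels_must_fail) all(fails) else any(fails)
  list(decision = if (rejected) "reject" else "accept",
       baseline_ratio = min(ratios), channel_ratios = ratios)
}
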