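#' Spectral analysis configuration
#'
#' The power spectrum of a beat is computed with a short-time FFT: a 35 ms
#' window slid across the annotated beat, each window zero-padded to
#' `fs / freq_resolution_hz` samples so the frequency grid has exactly the
#' requested resolution (200 samples and a 10 Hz grid at 2000 Hz). The
#' spectrum is split at 150 Hz into a low band (atrial farfield energy) and
#' a high band (pulmonary-vein nearfield energy) up to 300 Hz, the upper
#' edge of the acquisition band-pass.
#'
#' Band-edge convention: the bin at exactly `band_split_hz` belongs to the
#' HIGH band, and the bin at `band_max_hz` is included in the high band, so
#' LF covers [0, 150) and HF [150, 300].
#'
#' @param window_ms sliding window width in ms (default 35).
#' @param freq_resolution_hz frequency grid spacing in Hz (default 10).
#' @param band_split_hz low/high band split in Hz (default 150).
#' @param band_max_hz upper band edge in Hz (default 300).
#' @param window_step_ms slide step in ms (default 5).
#' @param taper `"rectangular"` (default) or `"hann"`.
#' @return a `spectral_config` list.
#' @export
spectral_config <- function(window_ms = 35, freq_resolution_hz = 10,
                            band_split_hz = 150, band_max_hz = 300,
                            window_step_ms = 5,
                            taper = c("rectangular", "hann")) {
  taper <- match.arg(taper)
  if (!(band_split_hz > 0 && band_split_hz < band_max_hz))
    stop("need 0 < band_split_hz < band_max_hz")
  if (band_split_hz %% freq_resolution_hz != 0 ||
      band_max_hz %% freq_resolution_hz != 0)
    stop("freq_resolution_hz must divide band_split_hz and band_max_hz")
  if (window_step_ms > window_ms)
    stop("window_step_ms must not exceed window_ms")
  if (window_ms <= 0 || window_step_ms <= 0 || freq_resolution_hz <= 0)
    stop("window_ms, window_step_ms, freq_resolution_hz must be positive")
  structure(list(window_ms = window_ms,
                 freq_resolution_hz = freq_resolution_hz,
                 band_split_hz = band_split_hz, band_max_hz = band_max_hz,
                 window_step_ms = window_step_ms, taper = taper),
            class = "spectral_config")
}

band_power_from_fft <- function(X, freqs, lo, hi, n_unpadded,
                                include_hi = FALSE) {
  sel <- if (include_hi) freqs >= lo & freqs <= hi else freqs >= lo & freqs < hi
  sum(Mod(X[sel])^2) / n_unpadded
}

#' Sliding-window band powers of one beat segment
#'
#' For each window position (windows fully inside the beat; if the beat is
#' shorter than the window, one window equal to the zero-padded beat), the
#' window is zero-padded to `fs / freq_resolution_hz` samples and its DFT
#' power summed over the low band `[0, band_split_hz)` and the high band
#' `[band_split_hz, band_max_hz]`, each divided by the number of un-padded
#' samples. Only non-negative-frequency bins enter a band, so
#' `p_lf + p_hf` equals the total 0--`band_max_hz` power.
#'
#' @param segment numeric vector, single-channel beat samples in mV.
#' @param fs sampling rate in Hz.
#' @param cfg a [spectral_config()].
#' @return data.frame with columns `window_start_ms`, `p_lf`, `p_hf`.
#' @export
sliding_band_powers <- function(segment, fs, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  n <- length(segment)
  if (n < 1) stop("empty segment")
  if (cfg$band_max_hz > fs / 2)
    stop("band_max_hz ", cfg$band_max_hz, " Hz exceeds Nyquist (", fs / 2, " Hz)")
  win_n <- round(cfg$window_ms * fs / 1000)
  step_n <- max(1, round(cfg$window_step_ms * fs / 1000))
  n_pad <- round(fs / cfg$freq_resolution_hz)
  if (win_n > n_pad)
    stop("window of ", win_n, " samples exceeds the zero-padded length ",
         n_pad, "; coarser freq_resolution_hz needed")
  starts <- if (n < win_n) 1L else seq.int(1L, n - win_n + 1L, by = step_n)
  freqs <- (seq_len(n_pad) - 1) * fs / n_pad
  out <- matrix(0, nrow = length(starts), ncol = 3)
  for (i in seq_along(starts)) {
    s <- starts[i]
    w <- segment[s:min(n, s + win_n - 1L)]
    n_un <- length(w)
    if (cfg$taper == "hann" && n_un > 1)
      w <- w * (0.5 - 0.5 * cos(2 * pi * (seq_len(n_un) - 1) / (n_un - 1)))
    X <- stats::fft(c(w, rep(0, n_pad - n_un)))
    out[i, ] <- c(
      (s - 1) * 1000 / fs,
      band_power_from_fft(X, freqs, 0, cfg$band_split_hz, n_un),
      band_power_from_fft(X, freqs, cfg$band_split_hz, cfg$band_max_hz, n_un,
                          include_hi = TRUE))
  }
  data.frame(window_start_ms = out[, 1], p_lf = out[, 2], p_hf = out[, 3])
}

#' Spectral features of one annotated beat
#'
#' Per channel, the channel-level high-band power is the maximum of `p_hf`
#' over the sliding windows; the retained bipole is the one with the
#' highest channel-level high-band power (the pair closest to the
#' nearfield source; ties break to the lowest index). `p_lf` and
#' `p_hf_rel` are reported from the retained channel at its maximizing
#' window. The neighbour ratio compares the retained channel's high-band
#' power with its two ring neighbours and keeps the larger ratio: a local
#' source decays steeply around the loop, a distant one does not.
#'
#' @param rec a [pv_recording()] with at least 3 channels.
#' @param beat a [pv_beat()].
#' @param cfg a [spectral_config()].
#' @return list with `p_hf`, `p_lf`, `p_hf_rel`, `p_hf_neighbor_ratio`,
#'   `selected_channel` (1-based), `neighbor_floored` (TRUE when a
#'   zero neighbour power was floored to keep the ratio finite).
#' @export
extract_spectral_features <- function(rec, beat, cfg = spectral_config()) {
  k <- length(rec$channels)
  if (k < 3) stop("neighbor ratio undefined with fewer than 3 channels")
  per_ch <- lapply(seq_len(k), function(j)
    sliding_band_powers(beat_segment(rec, beat, j), rec$fs, cfg))
  ch_phf <- vapply(per_ch, function(bp) max(bp$p_hf), numeric(1))
  sel <- which.max(ch_phf)                      # ties -> lowest index
  best_win <- which.max(per_ch[[sel]]$p_hf)
  p_hf <- per_ch[[sel]]$p_hf[best_win]
  p_lf <- per_ch[[sel]]$p_lf[best_win]
  tot <- p_lf + p_hf
  p_hf_rel <- if (tot > 0) p_hf / tot else 0
  nb <- ring_neighbors(sel, k)
  floor_mv2 <- 1e-12
  nb_p <- pmax(ch_phf[nb], floor_mv2)
  list(p_hf = p_hf, p_lf = p_lf, p_hf_rel = p_hf_rel,
       p_hf_neighbor_ratio = max(p_hf / nb_p),
       selected_channel = sel,
       neighbor_floored = any(ch_phf[nb] < floor_mv2))
}

#' Temporal features of one annotated beat
#'
#' `v_max` is the peak-to-peak amplitude (max minus min) within the beat
#' window on the retained bipole — the EP-lab convention for bipolar
#' amplitude. The slew rate is the first derivative of the electrogram
#' (central differences, one-sided at the endpoints; the signal in mV is
#' converted to V), and the feature is the proportion of beat samples
#' whose |dV/dt| exceeds the threshold.
#'
#' @param rec a [pv_recording()].
#' @param beat a [pv_beat()].
#' @param selected_channel 1-based bipole index (from
#'   [extract_spectral_features()]).
#' @param slew_threshold threshold in V/s (default 0.15).
#' @return list with `v_max` (mV), `slew_rate_prop`, `slew_threshold`,
#'   `duration_ms`.
#' @export
extract_temporal_features <- function(rec, beat, selected_channel,
                                      slew_threshold = 0.15) {
  if (slew_threshold <= 0) stop("slew_threshold must be positive")
  x <- beat_segment(rec, beat, selected_channel)
  n <- length(x)
  if (n < 3) stop("segment of ", n, " samples too short for a derivative")
  v <- x / 1000                                  # mV -> V
  dvdt <- numeric(n)
  dvdt[1] <- (v[2] - v[1]) * rec$fs
  dvdt[n] <- (v[n] - v[n - 1]) * rec$fs
  dvdt[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * rec$fs / 2
  list(v_max = max(x) - min(x),
       slew_rate_prop = mean(abs(dvdt) > slew_threshold),
       slew_threshold = slew_threshold,
       duration_ms = beat$offset_ms - beat$onset_ms)
}

feature_names <- c("p_hf", "p_lf", "p_hf_rel", "p_hf_neighbor_ratio",
                   "v_max", "slew_rate_prop")

#' Full six-feature vector of one beat
#'
#' Combines the four spectral and two temporal features with the beat's
#' clinical metadata. Inputs are never mutated.
#'
#' @param rec a [pv_recording()].
#' @param beat a [pv_beat()].
#' @param cfg a [spectral_config()].
#' @param slew_threshold slew-rate threshold in V/s (default 0.15).
#' @return one-row data.frame: the six features, `selected_channel`,
#'   `duration_ms`, and metadata columns (`record_id`, `patient_id`,
#'   `vein`, `phase`, `label`, `laa_lspv_distance_mm`).
#' @export
extract_feature_vector <- function(rec, beat, cfg = spectral_config(),
                                   slew_threshold = 0.15) {
  sp <- extract_spectral_features(rec, beat, cfg)
  tm <- extract_temporal_features(rec, beat, sp$selected_channel,
                                  slew_threshold)
  data.frame(
    p_hf = sp$p_hf, p_lf = sp$p_lf, p_hf_rel = sp$p_hf_rel,
    p_hf_neighbor_ratio = sp$p_hf_neighbor_ratio,
    v_max = tm$v_max, slew_rate_prop = tm$slew_rate_prop,
    selected_channel = sp$selected_channel, duration_ms = tm$duration_ms,
    record_id = beat$record_id, patient_id = beat$patient_id,
    vein = beat$vein, phase = beat$phase, label = beat$label,
    laa_lspv_distance_mm = beat$laa_lspv_distance_mm,
    stringsAsFactors = FALSE)
}

#' Feature table for a set of recordings and annotations
#'
#' Applies the standard filters, runs the noise gate, and extracts the
#' six-feature vector for every accepted beat.
#'
#' @param recordings named list of [pv_recording()] (names = record_id) or a
#'   single recording.
#' @param beats list of [pv_beat()].
#' @param filter_cfg a [filter_config()]; `enabled = FALSE` skips filtering.
#' @param gate_cfg a [noise_gate_config()], or `NULL` to accept everything.
#' @param spectral_cfg a [spectral_config()].
#' @param slew_threshold slew-rate threshold in V/s.
#' @return data.frame, one row per accepted beat (see
#'   [extract_feature_vector()] for columns); attribute `n_rejected` counts
#'   beats discarded by the noise gate.
#' @export
extract_feature_table <- function(recordings, beats,
                                  filter_cfg = filter_config(),
                                  gate_cfg = noise_gate_config(),
                                  spectral_cfg = spectral_config(),
                                  slew_threshold = 0.15) {
  if (inherits(recordings, "pv_recording"))
    recordings <- stats::setNames(list(recordings), recordings$record_id)
  filtered <- lapply(recordings, apply_standard_filters, cfg = filter_cfg)
  rows <- list()
  n_rejected <- 0L
  for (b in beats) {
    rec <- filtered[[b$record_id]]
    if (is.null(rec)) stop("no recording with record_id '", b$record_id, "'")
    if (!is.null(gate_cfg)) {
      g <- assess_noise(rec, b, gate_cfg)
      if (g$decision == "reject") { n_rejected <- n_rejected + 1L; next }
    }
    rows[[length(rows) + 1L]] <-
      extract_feature_vector(rec, b, spectral_cfg, slew_threshold)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(p_hf = numeric(0), p_lf = numeric(0), p_hf_rel = numeric(0),
               p_hf_neighbor_ratio = numeric(0), v_max = numeric(0),
               slew_rate_prop = numeric(0), selected_channel = integer(0),
               duration_ms = numeric(0), record_id = character(0),
               patient_id = character(0), vein = character(0),
               phase = character(0), label = character(0),
               laa_lspv_distance_mm = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a feature table as CSV
#'
#' Column order is fixed (six features, then `selected_channel`,
#' `duration_ms`, then metadata) and numbers are printed with full double
#' precision, so identical inputs yield byte-identical files.
#'
#' @param table data.frame from [extract_feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- c(feature_names, "selected_channel", "duration_ms", "record_id",
            "patient_id", "vein", "phase", "label", "laa_lspv_distance_mm")
  tab <- table[, intersect(cols, names(table)), drop = FALSE]
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 17, format = "g"))
  con <- file(path, "wb")
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
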