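#' Parameters of the synthetic beat model
#'
#' Each electrogram component is a Gabor atom (Gaussian-envelope sinusoid):
#' the atrial farfield is a broad, low-frequency deflection present on all
#' eight bipoles with mild decay around the ring from a reference bipole,
#' while the pulmonary-vein nearfield is a short, high-frequency deflection
#' centred on one active bipole with steep decay to its ring neighbours.
#' A combined beat is the sum of the two with the nearfield delayed
#' relative to the farfield onset. White measurement noise and a small
#' 50 Hz mains component are added on every channel.
#'
#' Defaults reflect typical clinical morphology: farfield 80 Hz / 70 ms /
#' 0.3 mV, nearfield 220 Hz / 58 ms / 0.5 mV, combined annotated duration
#' about 94 ms (nearfield delayed 36 ms).
#'
#' @param ff list: `center_freq_hz` (80), `duration_ms` (70),
#'   `amplitude_mv` (0.3), `spatial_decay_per_channel` (0.95),
#'   `freq_jitter_hz` (0), `hf_contamination_prob` (0),
#'   `hf_contamination_mv` (0) — the last three model farfield sources
#'   (e.g. a close left atrial appendage) whose spectrum reaches into the
#'   high band.
#' @param nf list: `center_freq_hz` (220), `duration_ms` (58),
#'   `amplitude_mv` (0.5), `spatial_decay_per_channel` (0.4),
#'   `active_channel` (`NA` = drawn at random per beat).
#' @param combined list: `nf_delay_ms` (36), `delay_jitter_ms` (6).
#' @param noise list: `white_rms_mv` (0.02), `mains_50hz_mv` (0.01).
#' @param amplitude_jitter_sdlog lognormal sd of a per-beat gain that
#'   multiplies every component of the beat at once (0 disables) — the
#'   effect of variable catheter contact and wall distance, which scales
#'   the whole electrogram rather than its components independently.
#' @param n_channels number of bipoles on the ring (default 8).
#' @return a `beat_model_params` list.
#' @export
beat_model_params <- function(ff = list(), nf = list(), combined = list(),
                              noise = list(), amplitude_jitter_sdlog = 0,
                              n_channels = 8) {
  ffd <- utils::modifyList(list(center_freq_hz = 80, duration_ms = 70,
                                amplitude_mv = 0.3,
                                spatial_decay_per_channel = 0.95,
                                freq_jitter_hz = 0,
                                hf_contamination_prob = 0,
                                hf_contamination_mv = 0), ff)
  nfd <- utils::modifyList(list(center_freq_hz = 220, duration_ms = 58,
                                amplitude_mv = 0.5,
                                spatial_decay_per_channel = 0.4,
                                active_channel = NA), nf)
  cbd <- utils::modifyList(list(nf_delay_ms = 36, delay_jitter_ms = 6),
                           combined)
  nsd <- utils::modifyList(list(white_rms_mv = 0.02, mains_50hz_mv = 0.01),
                           noise)
  stopifnot(ffd$duration_ms > 0, nfd$duration_ms > 0,
            ffd$spatial_decay_per_channel > 0,
            ffd$spatial_decay_per_channel <= 1,
            nfd$spatial_decay_per_channel > 0,
            nfd$spatial_decay_per_channel <= 1,
            n_channels >= 3)
  structure(list(ff = ffd, nf = nfd, combined = cbd, noise = nsd,
                 amplitude_jitter_sdlog = amplitude_jitter_sdlog,
                 n_channels = n_channels),
            class = "beat_model_params")
}

# Gabor atom sampled at fs: Gaussian envelope (sd = duration/6, so the
# support is ~ +-3 sd) times a sinusoid at f0. t0/duration in ms.
gabor_atom <- function(t_ms, t0_ms, duration_ms, f0_hz, amplitude_mv,
                       phase = 0) {
  s <- duration_ms / 6
  amplitude_mv * exp(-((t_ms - t0_ms)^2) / (2 * s^2)) *
    sin(2 * pi * f0_hz * (t_ms - t0_ms) / 1000 + phase)
}

ring_distance <- function(i, j, k) {
  d <- abs(i - j)
  pmin(d, k - d)
}

#' Generate one synthetic annotated beat
#'
#' The returned recording has a quiet pre-roll of 100 ms (room for the
#' noise-gate reference window) followed by the beat and a 20 ms tail.
#' The annotation window covers the component support plus a small margin;
#' a combined beat's annotated duration is the farfield-to-nearfield span
#' (about 94 ms at defaults).
#'
#' All random quantities (component placement, phases, amplitude jitter,
#' noise) are drawn in a fixed order that does not depend on the class, so
#' the model is exactly additive under a shared seed: a combined beat with
#' farfield amplitude 0 has the same samples as the PV-NF beat generated
#' from the same RNG state.
#'
#' @param class_label `"PV-NF"`, `"atrial-FF"` or `"combined"`.
#' @param params a [beat_model_params()].
#' @param fs sampling rate in Hz (default 2000).
#' @param patient_id,record_id,vein,phase annotation metadata.
#' @return list with `recording` (a [pv_recording()]), `beat`
#'   (a [pv_beat()]) and `active_channel`.
#' @export
generate_beat <- function(class_label = c("PV-NF", "atrial-FF", "combined"),
                          params = beat_model_params(), fs = 2000,
                          patient_id = "p1", record_id = "r1",
                          vein = "LSPV", phase = "during") {
  class_label <- match.arg(class_label)
  if (class_label != "atrial-FF" && params$nf$amplitude_mv <= 0)
    stop("class '", class_label, "' requires a positive nearfield amplitude")
  k <- params$n_channels
  pre_ms <- 100

  has_ff <- class_label %in% c("atrial-FF", "combined")
  has_nf <- class_label %in% c("PV-NF", "combined")
  # draw ALL randomness up front, in class-independent order
  nf_delay <- max(0, params$combined$nf_delay_ms +
                    stats::rnorm(1, 0, max(params$combined$delay_jitter_ms,
                                           1e-12)))
  active <- params$nf$active_channel
  if (is.na(active)) active <- sample.int(k, 1)
  ff_ref <- sample.int(k, 1)
  ff_phase <- stats::runif(1, 0, 2 * pi)
  nf_phase <- stats::runif(1, 0, 2 * pi)
  gain <- stats::rlnorm(1, 0, max(params$amplitude_jitter_sdlog, 1e-12))
  if (params$amplitude_jitter_sdlog == 0) gain <- 1
  ff_amp <- gain * params$ff$amplitude_mv
  nf_amp <- gain * params$nf$amplitude_mv
  ff_f0 <- max(40, params$ff$center_freq_hz +
                 stats::rnorm(1, 0, max(params$ff$freq_jitter_hz, 1e-12)))
  contam_amp <- gain * params$ff$hf_contamination_mv
  contam <- stats::runif(1) < params$ff$hf_contamination_prob && has_ff

  ff_dur <- params$ff$duration_ms
  nf_dur <- params$nf$duration_ms
  # component centres relative to the quiet pre-roll; the nearfield always
  # sits nf_delay after the farfield onset, whichever components are active
  ff_t0 <- ff_dur / 2
  nf_t0 <- nf_delay + nf_dur / 2
  support_end <- max(if (has_ff) ff_dur else 0,
                     if (has_nf) nf_delay + nf_dur else 0)
  onset_ms <- pre_ms + if (class_label == "PV-NF") nf_delay else 0
  offset_ms <- pre_ms + support_end
  total_ms <- pre_ms + support_end + 20
  n <- ceiling(total_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  sig <- matrix(0, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    if (has_ff) {
      decay <- params$ff$spatial_decay_per_channel ^ ring_distance(j, ff_ref, k)
      sig[, j] <- sig[, j] +
        gabor_atom(t_ms, pre_ms + ff_t0, ff_dur, ff_f0, ff_amp * decay,
                   ff_phase)
      if (contam)
        sig[, j] <- sig[, j] +
          gabor_atom(t_ms, pre_ms + ff_t0, ff_dur / 2, 210,
                     contam_amp * decay, nf_phase)
    }
    if (has_nf) {
      decay <- params$nf$spatial_decay_per_channel ^
        ring_distance(j, active, k)
      sig[, j] <- sig[, j] +
        gabor_atom(t_ms, pre_ms + nf_t0, nf_dur, params$nf$center_freq_hz,
                   nf_amp * decay, nf_phase)
    }
    if (params$noise$white_rms_mv > 0)
      sig[, j] <- sig[, j] + stats::rnorm(n, 0, params$noise$white_rms_mv)
    if (params$noise$mains_50hz_mv > 0)
      sig[, j] <- sig[, j] +
        params$noise$mains_50hz_mv * sin(2 * pi * 50 * t_ms / 1000 +
                                         stats::runif(1, 0, 2 * pi))
  }
  rec <- pv_recording(sig, fs = fs, record_id = record_id)
  beat <- pv_beat(record_id, patient_id, vein, phase,
                  onset_ms = onset_ms, offset_ms = offset_ms,
                  label = class_label)
  list(recording = rec, beat = beat, active_channel = active)
}

#' Parameters of a cryoballoon freeze cycle
#'
#' During an effective freeze the pulmonary-vein nearfield delays
#' progressively beat by beat and disappears at isolation; after isolation
#' only the atrial farfield remains.
#'
#' @param n_beats number of beats in the cycle.
#' @param beat_interval_ms spacing between beat onsets (default 800, sinus
#'   rhythm ~75 bpm).
#' @param initial_nf_delay_ms nearfield delay at the first beat (default 20).
#' @param delay_increment_per_beat_ms added delay per beat (default 8).
#' @param isolation_beat_index 0-based index of the first beat without a
#'   nearfield (beats before it are combined); must be `<= n_beats`.
#' @param vein,patient_id annotation metadata.
#' @return a `freeze_cycle_params` list.
#' @export
freeze_cycle_params <- function(n_beats = 10, beat_interval_ms = 800,
                                initial_nf_delay_ms = 20,
                                delay_increment_per_beat_ms = 8,
                                isolation_beat_index = 6,
                                vein = "LSPV", patient_id = "p1") {
  stopifnot(n_beats >= 1, isolation_beat_index >= 0,
            isolation_beat_index <= n_beats,
            delay_increment_per_beat_ms >= 0)
  structure(list(n_beats = n_beats, beat_interval_ms = beat_interval_ms,
                 initial_nf_delay_ms = initial_nf_delay_ms,
                 delay_increment_per_beat_ms = delay_increment_per_beat_ms,
                 isolation_beat_index = isolation_beat_index,
                 vein = vein, patient_id = patient_id),
            class = "freeze_cycle_params")
}

#' Generate a synthetic freeze-cycle recording
#'
#' Beats before `isolation_beat_index` are combined FF-NF with a nearfield
#' delay growing by `delay_increment_per_beat_ms` per beat (phase
#' `"during"`); from the isolation index on, beats are atrial farfield
#' only (phase `"after"`).
#'
#' @param fp a [freeze_cycle_params()].
#' @param bp a [beat_model_params()].
#' @param fs sampling rate in Hz.
#' @param record_id identifier for the produced recording.
#' @return list with `recording` and `beats` (list of [pv_beat()]).
#' @export
generate_freeze_cycle <- function(fp = freeze_cycle_params(),
                                  bp = beat_model_params(), fs = 2000,
                                  record_id = "freeze1") {
  support <- max(bp$ff$duration_ms,
                 fp$initial_nf_delay_ms +
                   fp$n_beats * fp$delay_increment_per_beat_ms +
                   bp$nf$duration_ms) + 120
  if (fp$beat_interval_ms < support)
    stop("beat_interval_ms ", fp$beat_interval_ms,
         " ms is shorter than the beat support (", support, " ms)")
  # fixed active channel for the whole cycle: the catheter does not move
  active <- bp$nf$active_channel
  if (is.na(active)) active <- sample.int(bp$n_channels, 1)
  bp$nf$active_channel <- active
  n_total <- ceiling(fp$n_beats * fp$beat_interval_ms * fs / 1000)
  sig <- matrix(0, nrow = n_total, ncol = bp$n_channels)
  beats <- vector("list", fp$n_beats)
  for (i in seq_len(fp$n_beats)) {
    idx0 <- i - 1L                              # 0-based beat index
    isolated <- idx0 >= fp$isolation_beat_index
    bpi <- bp
    bpi$combined$nf_delay_ms <- fp$initial_nf_delay_ms +
      idx0 * fp$delay_increment_per_beat_ms
    bpi$combined$delay_jitter_ms <- 0           # delays strictly increase
    g <- generate_beat(if (isolated) "atrial-FF" else "combined",
                       bpi, fs = fs, patient_id = fp$patient_id,
                       record_id = record_id, vein = fp$vein,
                       phase = if (isolated) "after" else "during")
    off <- round(idx0 * fp$beat_interval_ms * fs / 1000)
    span <- seq_len(g$recording$n_samples) + off
    span <- span[span <= n_total]
    sig[span, ] <- sig[span, ] + g$recording$samples[seq_along(span), ]
    shift_ms <- off * 1000 / fs
    beats[[i]] <- pv_beat(record_id, fp$patient_id, fp$vein, g$beat$phase,
                          g$beat$onset_ms + shift_ms,
                          g$beat$offset_ms + shift_ms, g$beat$label)
  }
  list(recording = pv_recording(sig, fs = fs, record_id = record_id),
       beats = beats, active_channel = active)
}

difficulty_params <- function(difficulty = c("separated", "overlap_heavy")) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "separated") {
    beat_model_params()
  } else {
    # overlap-heavy regime: a weaker nearfield superimposed on the farfield
    # with no delay, a broad per-beat contact gain, and a fraction of
    # farfield beats carrying a sharp high-frequency component — the
    # close-LAA situation in which farfield spectra reach into the high
    # band
    beat_model_params(
      ff = list(freq_jitter_hz = 15, hf_contamination_prob = 0.55,
                hf_contamination_mv = 0.15),
      nf = list(amplitude_mv = 0.2),
      combined = list(nf_delay_ms = 0, delay_jitter_ms = 4),
      noise = list(white_rms_mv = 0.025, mains_50hz_mv = 0.01),
      amplitude_jitter_sdlog = 0.7)
  }
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes one CSV+JSON recording per beat plus a single annotation CSV,
#' using per-patient RNG substreams derived from the master seed so that
#' patients are exchangeable units and datasets are reproducible.
#'
#' Class proportions may be given over the three beat classes, or as
#' `c(nearfield = ..., farfield = ...)`, in which case the nearfield share
#' is split between `PV-NF` and `combined` (the farfield share maps to
#' `atrial-FF`). Counts are apportioned by largest remainder so they sum
#' exactly to the number of beats.
#'
#' @param out_dir output directory (created if needed).
#' @param n_patients number of patients.
#' @param beats_per_patient beats per patient.
#' @param class_mix named proportions summing to 1 (default: the clinical
#'   balance, 48.7% farfield / 51.3% nearfield-positive).
#' @param difficulty `"separated"` (default parameters) or
#'   `"overlap_heavy"` (weaker, undelayed nearfield plus farfield
#'   high-frequency contamination).
#' @param seed master seed.
#' @param fs sampling rate in Hz.
#' @param params optional [beat_model_params()] overriding the difficulty
#'   preset.
#' @return invisibly, a list with `annotations` (the CSV path),
#'   `class_counts`, and `dir`.
#' @export
generate_dataset <- function(out_dir, n_patients = 20, beats_per_patient = 12,
                             class_mix = c(nearfield = 0.513,
                                           farfield = 0.487),
                             difficulty = c("separated", "overlap_heavy"),
                             seed = 1L, fs = 2000, params = NULL) {
  difficulty <- match.arg(difficulty)
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1 (got ", sum(class_mix), ")")
  if (is.null(params)) params <- difficulty_params(difficulty)
  mix <- normalize_class_mix(class_mix)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_beats <- n_patients * beats_per_patient
  counts <- largest_remainder(mix * n_beats)
  # shuffle so every patient receives a mix of classes
  class_seq <- withr::with_seed(seed, sample(rep(names(mix), counts)))
  pat_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1,
                                                 n_patients))
  beats <- list()
  bi <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("p%03d", p)
    withr::local_seed(pat_seeds[p])
    vein <- sample(pv_veins, 1)
    for (b in seq_len(beats_per_patient)) {
      bi <- bi + 1L
      lab <- class_seq[bi]
      rid <- sprintf("%s_b%03d", pid, b)
      phase <- if (lab == "atrial-FF") sample(c("before", "during", "after"), 1)
      else sample(c("before", "during"), 1)
      g <- generate_beat(lab, params, fs = fs, patient_id = pid,
                         record_id = rid, vein = vein, phase = phase)
      write_recording_csv(g$recording, file.path(out_dir,
                                                 paste0(rid, ".csv")))
      beats[[bi]] <- g$beat
    }
  }
  ann_path <- file.path(out_dir, "annotations.csv")
  write_annotations(beats, ann_path)
  invisible(list(annotations = ann_path,
                 class_counts = table(vapply(beats, `[[`, "", "label")),
                 dir = out_dir))
}

normalize_class_mix <- function(class_mix) {
  nm <- names(class_mix)
  if (is.null(nm)) stop("class_mix must be named")
  if (setequal(nm, c("nearfield", "farfield"))) {
    nfp <- class_mix[["nearfield"]]
    c("PV-NF" = nfp / 2, "combined" = nfp / 2,
      "atrial-FF" = class_mix[["farfield"]])
  } else if (all(nm %in% pv_labels)) {
    out <- stats::setNames(rep(0, 3), pv_labels)
    out[nm] <- class_mix
    out
  } else stop("class_mix names must be the three beat classes or ",
              "nearfield/farfield")
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    add <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  stats::setNames(as.integer(fl), names(x))
}

#' Load a dataset directory written by [generate_dataset()]
#' @param dir dataset directory.
#' @return list with `recordings` (named list of [pv_recording()]) and
#'   `beats` (list of [pv_beat()]).
#' @export
load_dataset <- function(dir) {
  beats <- read_annotations(file.path(dir, "annotations.csv"))
  ids <- unique(vapply(beats, `[[`, "", "record_id"))
  recs <- lapply(ids, function(rid)
    read_recording(file.path(dir, paste0(rid, ".csv")), "csv"))
  names(recs) <- ids
  list(recordings = recs, beats = beats)
}
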