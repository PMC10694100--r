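# Independent oracles used across tests.

# Direct O(N^2) discrete Fourier transform (no FFT), summing |X_k|^2 bin by
# bin over a frequency band. Mirrors the documented band-power definition:
# zero-pad to n_pad, band power = sum over selected bins / n unpadded.
oracle_band_power <- function(segment, fs, n_pad, lo, hi, include_hi) {
  n <- length(segment)
  x <- c(segment, rep(0, n_pad - n))
  idx <- 0:(n_pad - 1)
  W <- exp(-2i * pi * outer(idx, idx) / n_pad)
  X <- as.vector(W %*% x)
  f <- idx * fs / n_pad
  sel <- if (include_hi) f >= lo & f <= hi else f >= lo & f < hi
  sum(Mod(X[sel])^2) / n
}

oracle_band_pair <- function(segment, fs, n_pad = 200, split = 150, top = 300) {
  c(p_lf = oracle_band_power(segment, fs, n_pad, 0, split, FALSE),
    p_hf = oracle_band_power(segment, fs, n_pad, split, top, TRUE))
}

# A recording whose channels are pure sinusoids with given amplitudes.
sine_recording <- function(freq_hz, amplitudes, fs = 2000, dur_ms = 200,
                           phase = 0) {
  if (length(amplitudes) == 1) amplitudes <- rep(amplitudes, 2)
  n <- round(dur_ms * fs / 1000)
  t <- (seq_len(n) - 1) / fs
  sig <- sapply(amplitudes, function(a) a * sin(2 * pi * freq_hz * t + phase))
  pv_recording(sig, fs = fs, record_id = "sine")
}

whole_beat <- function(rec, label = "atrial-FF", phase = "during") {
  pv_beat(rec$record_id, "p1", "LSPV", phase, 0,
          recording_duration_ms(rec), label)
}
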