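# Minimal EDF (European Data Format) I/O.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian 16-bit integers, mapped linearly between the
# digital and physical ranges declared per signal. We emit a single data
# record holding the whole recording, which keeps the writer simple and is
# valid EDF. Amplitudes are quantized to the 16-bit grid on write, so the
# EDF round trip is exact only to the quantization step (the CSV dialect is
# the lossless fixture format).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Signals are scaled to the full 16-bit digital range using a symmetric
#' physical range covering the data; physical dimension is millivolts.
#'
#' @param rec a [pv_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  k <- length(rec$channels)
  n <- rec$n_samples
  # symmetric physical range per signal, padded so zero maps to digital 0
  pmax <- apply(abs(rec$samples), 2, max)
  pmax[pmax == 0] <- 1
  pmax <- pmax * 1.001
  header_bytes <- 256L * (1L + k)
  rec_dur <- n / rec$fs
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL)
  put(edf_pad("0", 8))
  put(edf_pad("X X X X", 80))                      # local patient id
  put(edf_pad(paste("Startdate X X X X", rec$record_id), 80))
  put(edf_pad("01.01.00", 8))
  put(edf_pad("00.00.00", 8))
  put(edf_pad(header_bytes, 8))
  put(edf_pad("", 44))
  put(edf_pad(1, 8))                               # one data record
  put(edf_num(rec_dur, 8))
  put(edf_pad(k, 4))
  for (j in seq_len(k)) put(edf_pad(rec$channels[j], 16))
  for (j in seq_len(k)) put(edf_pad("", 80))       # transducer
  for (j in seq_len(k)) put(edf_pad("mV", 8))
  for (j in seq_len(k)) put(edf_num(-pmax[j], 8))
  for (j in seq_len(k)) put(edf_num(pmax[j], 8))
  for (j in seq_len(k)) put(edf_pad(-32768, 8))
  for (j in seq_len(k)) put(edf_pad(32767, 8))
  for (j in seq_len(k)) put(edf_pad("", 80))       # prefiltering
  for (j in seq_len(k)) put(edf_pad(n, 8))
  for (j in seq_len(k)) put(edf_pad("", 32))
  for (j in seq_len(k)) {
    dig <- round(rec$samples[, j] / pmax[j] * 32767)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  grab <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  h <- list(version = grab(8), patient = grab(80), recording = grab(80),
            startdate = grab(8), starttime = grab(8),
            header_bytes = as.integer(grab(8)), reserved = grab(44),
            n_records = as.integer(grab(8)),
            record_duration = as.numeric(grab(8)),
            ns = as.integer(grab(4)))
  ns <- h$ns
  field <- function(nc) vapply(seq_len(ns), function(i) grab(nc), character(1))
  h$label        <- field(16)
  h$transducer   <- field(80)
  h$dim          <- field(8)
  h$phys_min     <- as.numeric(field(8))
  h$phys_max     <- as.numeric(field(8))
  h$dig_min      <- as.numeric(field(8))
  h$dig_max      <- as.numeric(field(8))
  h$prefiltering <- field(80)
  h$n_per_record <- as.integer(field(8))
  h$sig_reserved <- field(32)
  h
}

#' Read a recording from an EDF file
#'
#' All signals must share one sampling rate (bipoles of one catheter do).
#' Physical dimensions of V or uV are converted to millivolts; anything
#' else is taken as already being mV.
#'
#' @param path EDF file path.
#' @param record_id optional identifier; defaults to the EDF recording field
#'   or the file name.
#' @return a [pv_recording()].
#' @export
read_recording_edf <- function(path, record_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (is.na(h$record_duration) || h$record_duration <= 0)
    stop("missing sampling rate: EDF record duration is absent or zero")
  fs <- h$n_per_record / h$record_duration
  if (length(unique(fs)) != 1)
    stop("channels have differing sampling rates; channel '",
         h$label[which(fs != fs[1])[1]], "' differs")
  n_total <- h$n_records * h$n_per_record
  sig <- matrix(0, nrow = n_total[1], ncol = h$ns)
  fill <- rep(0L, h$ns)
  for (r in seq_len(h$n_records)) {
    for (j in seq_len(h$ns)) {
      dig <- readBin(con, integer(), n = h$n_per_record[j], size = 2,
                     signed = TRUE, endian = "little")
      if (length(dig) < h$n_per_record[j])
        stop("truncated EDF data in channel '", h$label[j], "'")
      g <- (h$phys_max[j] - h$phys_min[j]) / (h$dig_max[j] - h$dig_min[j])
      phys <- h$phys_min[j] + (dig - h$dig_min[j]) * g
      sig[fill[j] + seq_along(phys), j] <- phys
      fill[j] <- fill[j] + length(phys)
    }
  }
  scale <- ifelse(tolower(h$dim) == "v", 1000,
                  ifelse(tolower(h$dim) %in% c("uv", "µv"), 0.001, 1))
  sig <- sweep(sig, 2, scale, `*`)
  if (is.null(record_id)) {
    record_id <- sub("^Startdate X X X X ?", "", h$recording)
    if (!nzchar(record_id)) record_id <- basename(path)
  }
  pv_recording(sig, fs = fs[1], channels = h$label, record_id = record_id)
}
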