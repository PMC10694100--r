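#' Read a recording from disk
#'
#' Two formats are supported: standard EDF, and a plain-text CSV dialect
#' intended for diff-able fixtures. The CSV dialect is one `sample` index
#' column plus one column per bipole (millivolts, "." decimal, UTF-8), with
#' a sidecar JSON file `<path>.json` carrying `fs`, `channel_names` and
#' `record_id`. Channel order in the file defines catheter adjacency and is
#' preserved exactly.
#'
#' @param path file path (`.csv` expects the sidecar `<path>.json`).
#' @param format `"edf"` or `"csv"`.
#' @return a [pv_recording()].
#' @export
read_recording <- function(path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") return(read_recording_edf(path))
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sidecar metadata file: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("missing sampling rate in sidecar: ", meta_path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(tab)[1], "sample"))
    stop("CSV signal dialect requires a leading 'sample' column")
  sig <- as.matrix(tab[, -1, drop = FALSE])
  channels <- names(tab)[-1]
  if (!is.null(meta$channel_names)) {
    if (!identical(as.character(meta$channel_names), channels))
      stop("sidecar channel_names disagree with CSV columns")
  }
  rid <- if (is.null(meta$record_id)) basename(path) else meta$record_id
  pv_recording(sig, fs = meta$fs, channels = channels, record_id = rid)
}

#' Write a recording in the CSV+JSON fixture dialect
#'
#' The round trip through [read_recording()] reproduces the samples exactly
#' for all finite inputs (values are printed with full double precision).
#'
#' @param rec a [pv_recording()].
#' @param path output `.csv` path; `<path>.json` is written alongside.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  tab <- data.frame(sample = seq_len(rec$n_samples) - 1L)
  sig <- as.data.frame(rec$samples)
  names(sig) <- rec$channels
  tab <- cbind(tab, sig)
  # format() with digits=17 keeps doubles bit-stable through the round trip
  txt <- vapply(tab, function(col) {
    if (is.double(col)) formatC(col, digits = 17, format = "g") else format(col)
  }, character(nrow(tab)))
  con <- file(path, "wb")  # binary mode: fixed "\n", bit-stable across OS
  writeLines(paste(names(tab), collapse = ","), con)
  writeLines(apply(txt, 1, paste, collapse = ","), con)
  close(con)
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$channels, record_id = rec$record_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a beat-annotation table
#'
#' Expects a CSV with header columns `record_id, patient_id, vein, phase,
#' onset_ms, offset_ms, label` and optionally `laa_lspv_distance_mm`. The
#' whole file is validated before anything is returned: any row violating
#' the beat invariants (unknown vein/phase/label token, `onset >= offset`,
#' a `PV-NF` label in phase `after`) fails the read with the offending row
#' numbers, so a partially-valid table is never silently truncated.
#'
#' @param path annotation CSV path.
#' @return list of [pv_beat()] objects (possibly empty).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "patient_id", "vein", "phase",
            "onset_ms", "offset_ms", "label")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("annotation CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) return(list())
  if (!"laa_lspv_distance_mm" %in% names(tab))
    tab$laa_lspv_distance_mm <- NA_real_
  beats <- vector("list", nrow(tab))
  errs <- character(0)
  for (i in seq_len(nrow(tab))) {
    b <- tryCatch(
      pv_beat(tab$record_id[i], tab$patient_id[i], tab$vein[i], tab$phase[i],
              tab$onset_ms[i], tab$offset_ms[i], tab$label[i],
              tab$laa_lspv_distance_mm[i]),
      error = function(e) e)
    if (inherits(b, "error")) {
      errs <- c(errs, sprintf("row %d: %s", i, conditionMessage(b)))
    } else beats[[i]] <- b
  }
  if (length(errs))
    stop("invalid annotation rows:\n", paste(errs, collapse = "\n"))
  beats
}

#' Write a beat-annotation table
#' @param beats list of [pv_beat()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(beats, path) {
  tab <- annotations_to_df(beats)
  con <- file(path, "wb")
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  invisible(path)
}

#' Annotation list as a data frame
#' @param beats list of [pv_beat()] objects.
#' @return data.frame, one row per beat.
#' @export
annotations_to_df <- function(beats) {
  do.call(rbind, c(list(data.frame(
    record_id = character(0), patient_id = character(0), vein = character(0),
    phase = character(0), onset_ms = numeric(0), offset_ms = numeric(0),
    label = character(0), laa_lspv_distance_mm = numeric(0))),
    lapply(beats, function(b)
      data.frame(record_id = b$record_id, patient_id = b$patient_id,
                 vein = b$vein, phase = b$phase, onset_ms = b$onset_ms,
                 offset_ms = b$offset_ms, label = b$label,
                 laa_lspv_distance_mm = b$laa_lspv_distance_mm))))
}
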