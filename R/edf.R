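# Minimal reader for European Data Format (EDF, 16-bit) and BioSemi Data
# Format (BDF, 24-bit) files. Covers the fixed-layout header and contiguous
# signal records; returns the physically-scaled signal matrix. Annotation
# channels are not interpreted.

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF or BDF recording
#'
#' Parses the file header and all data records, applies the per-signal
#' digital-to-physical scaling, and returns a channels x samples matrix. All
#' signals must share one sampling rate (the usual case for EEG exports);
#' mixed-rate files are rejected.
#'
#' @param path an `.edf` (16-bit) or `.bdf` (24-bit) file.
#' @return List with `data` (channels x samples, physical units), `labels`,
#'   `srate` (Hz), `n_records`, `record_duration` (s) and `format`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (magic[1] == as.raw(255)) {
    format <- "bdf"
    if (rawToChar(magic[2:8]) != "BIOSEMI")
      stopf("'%s': unrecognized BDF identifier", path)
  } else if (trimws(rawToChar(magic)) == "0") {
    format <- "edf"
  } else stopf("'%s': not an EDF/BDF file (bad version field)", path)
  invisible(read_ascii(con, 80L))  # patient id
  invisible(read_ascii(con, 80L))  # recording id
  invisible(read_ascii(con, 16L))  # start date + time
  header_bytes <- as.integer(read_ascii(con, 8L))
  invisible(read_ascii(con, 44L))  # reserved
  n_rec <- as.integer(read_ascii(con, 8L))
  dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1) stopf("'%s': bad signal count in header", path)
  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- fld(16L)
  invisible(fld(80L))  # transducer
  invisible(fld(8L))   # physical dimension
  phys_min <- as.numeric(fld(8L)); phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L)); dig_max <- as.numeric(fld(8L))
  invisible(fld(80L))  # prefiltering
  nsamp <- as.integer(fld(8L))
  invisible(fld(32L))  # reserved
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, nsamp)))
    stopf("'%s': malformed numeric signal-header field", path)
  if (length(unique(nsamp)) != 1L)
    stopf("'%s': mixed per-signal sampling rates are not supported", path)
  nsamp <- nsamp[1]
  expected_header <- 256L + ns * 256L
  if (!is.na(header_bytes) && header_bytes != expected_header)
    stopf("'%s': header declares %d bytes, expected %d", path, header_bytes,
          expected_header)
  bps <- if (format == "edf") 2L else 3L
  total <- n_rec * ns * nsamp
  if (format == "edf") {
    dig <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                   endian = "little")
  } else {
    bytes <- as.integer(readBin(con, "raw", total * bps))
    b1 <- bytes[seq(1, length(bytes), 3)]
    b2 <- bytes[seq(2, length(bytes), 3)]
    b3 <- bytes[seq(3, length(bytes), 3)]
    dig <- b1 + 256 * b2 + 65536 * b3
    dig <- ifelse(dig >= 8388608, dig - 16777216, dig)
  }
  if (length(dig) != total)
    stopf("'%s': truncated data section (%d of %d samples)", path,
          length(dig), total)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  # records x (signal-major blocks of nsamp)
  out <- matrix(0, nrow = ns, ncol = n_rec * nsamp)
  arr <- array(dig, dim = c(nsamp, ns, n_rec))
  for (s in seq_len(ns))
    out[s, ] <- as.vector(arr[, s, ]) * gain[s] + offset[s]
  list(data = out, labels = labels, srate = nsamp / dur, n_records = n_rec,
       record_duration = dur, format = format)
}
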