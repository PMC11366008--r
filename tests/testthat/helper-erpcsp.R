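# shared fixtures: reduced montages, fast generator configs, and an EDF/BDF
# writer so the reader can be tested against files with known content

tiny_montage <- function() subset_montage()  # 8 midline-ish channels, has FCz

mid_montage <- function() subset_montage(c(
  "AFz", "Fz", "F3", "F4", "FC1", "FC2", "FCz", "Cz", "C3", "C4",
  "CPz", "Pz", "P3", "P4", "POz", "Oz"))

# short-epoch config: spans baseline and analysis window, fast to generate
quick_config <- function(n_per_group = 6, trials_per_valence = 6,
                         montage = tiny_montage(), effects = list(),
                         noise_sd = 5, seed = 1, ...) {
  generator_config(n_per_group = n_per_group,
                   trials_per_valence = trials_per_valence,
                   montage = montage, t0 = -400, t1 = 700,
                   noise_sd = noise_sd, effects = effects, seed = seed, ...)
}

flat_erp <- function(values, srate = 256, t0 = -400, labels = NULL) {
  # channels x samples ERP from a matrix (or a single channel vector)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  labels <- labels %||% paste0("ch", seq_len(nrow(values)))
  subject_erp("toy", "positive", "broadband", values, srate, t0,
              montage(labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- EDF/BDF writer (test fixture only) ------------------------------------

ascii_field <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  substr(s, 1, width)
}

# digital: list of integer vectors (one per signal, same length);
# phys/dig: per-signal c(min, max) lists
write_edf_fixture <- function(path, labels, digital, phys_min, phys_max,
                              dig_min, dig_max, record_duration = 1,
                              format = c("edf", "bdf")) {
  format <- match.arg(format)
  ns <- length(labels)
  nsamp <- length(digital[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "edf") {
    writeChar(ascii_field("0", 8), con, eos = NULL)
  } else {
    writeBin(as.raw(255), con)
    writeChar("BIOSEMI", con, eos = NULL)
  }
  writeChar(ascii_field("test patient", 80), con, eos = NULL)
  writeChar(ascii_field("test recording", 80), con, eos = NULL)
  writeChar(ascii_field("01.01.24", 8), con, eos = NULL)
  writeChar(ascii_field("00.00.00", 8), con, eos = NULL)
  writeChar(ascii_field(256 + ns * 256, 8), con, eos = NULL)
  writeChar(ascii_field("", 44), con, eos = NULL)
  writeChar(ascii_field(1, 8), con, eos = NULL)     # one data record
  writeChar(ascii_field(record_duration, 8), con, eos = NULL)
  writeChar(ascii_field(ns, 4), con, eos = NULL)
  fld <- function(vals, width)
    for (v in vals) writeChar(ascii_field(v, width), con, eos = NULL)
  fld(labels, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(phys_min, 8); fld(phys_max, 8)
  fld(dig_min, 8); fld(dig_max, 8)
  fld(rep("", ns), 80)
  fld(rep(nsamp, ns), 8)
  fld(rep("", ns), 32)
  for (sig in digital) {
    if (format == "edf") {
      writeBin(as.integer(sig), con, size = 2L, endian = "little")
    } else {
      v <- ifelse(sig < 0, sig + 16777216, sig)
      b <- rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)
      writeBin(as.raw(b), con)
    }
  }
  path
}
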