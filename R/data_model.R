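#' Feedback-locked epoch set for one subject
#'
#' Container for a subject's single-trial EEG epochs time-locked to feedback
#' onset, with per-trial feedback valence labels.
#'
#' @param subject_id character scalar.
#' @param data numeric array, trials x channels x samples, in microvolts.
#' @param valence character vector, one of `"positive"`/`"negative"` per trial.
#' @param srate sampling rate in Hz.
#' @param t0 time of the first sample relative to feedback onset, in ms
#'   (negative = pre-feedback).
#' @param montage an [montage()] whose size matches the channel dimension.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(subject_id, data, valence, srate, t0, montage) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("subject %s: 'data' must be a trials x channels x samples array",
          subject_id)
  if (!inherits(montage, "eeg_montage")) stopf("'montage' must be an eeg_montage")
  d <- dim(data)
  if (d[2] != length(montage))
    stopf("subject %s: %d channels in data but %d in montage",
          subject_id, d[2], length(montage))
  if (length(valence) != d[1])
    stopf("subject %s: %d valence labels for %d trials",
          subject_id, length(valence), d[1])
  valence <- as.character(valence)
  bad <- setdiff(unique(valence), c("positive", "negative"))
  if (length(bad))
    stopf("subject %s: invalid valence label(s): %s", subject_id,
          paste(bad, collapse = ", "))
  if (!is.numeric(srate) || srate <= 0) stopf("'srate' must be > 0")
  structure(list(subject_id = subject_id, data = data, valence = valence,
                 srate = as.numeric(srate), t0 = as.numeric(t0),
                 montage = montage),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s: %d trials (%d positive / %d negative), %d ch, %d samples @ %g Hz, t0 = %g ms\n",
              x$subject_id, d[1], sum(x$valence == "positive"),
              sum(x$valence == "negative"), d[2], d[3], x$srate, x$t0))
  invisible(x)
}

#' Subject-level condition-averaged ERP
#'
#' A channels x samples matrix holding one subject's feedback-locked ERP for
#' one valence, tagged with the frequency band it currently represents so
#' that band filters and analysis windows are never applied twice.
#'
#' @inheritParams epoch_set
#' @param valence `"positive"` or `"negative"`.
#' @param band `"broadband"`, `"delta"` or `"theta"`.
#' @param data numeric matrix, channels x samples (microvolts).
#' @return An object of class `subject_erp`.
#' @export
subject_erp <- function(subject_id, valence, band = "broadband", data,
                        srate, t0, montage) {
  valence <- match.arg(valence, c("positive", "negative"))
  band <- match.arg(band, c("broadband", "delta", "theta"))
  if (!is.matrix(data)) stopf("'data' must be a channels x samples matrix")
  if (!all(is.finite(data)))
    stopf("subject %s: non-finite values in ERP data", subject_id)
  if (nrow(data) != length(montage))
    stopf("subject %s: %d channels in ERP but %d in montage",
          subject_id, nrow(data), length(montage))
  structure(list(subject_id = subject_id, valence = valence, band = band,
                 data = data, srate = as.numeric(srate), t0 = as.numeric(t0),
                 montage = montage),
            class = "subject_erp")
}

#' @export
print.subject_erp <- function(x, ...) {
  cat(sprintf("<subject_erp> %s / %s / %s: %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$valence, x$band, nrow(x$data), ncol(x$data),
              x$srate))
  invisible(x)
}

erp_times <- function(erp) erp$t0 + (seq_len(ncol(erp$data)) - 1L) * 1000 / erp$srate

#' Subject metadata table
#'
#' Builds/validates the questionnaire metadata table with one row per subject:
#' BDI-II total score (0-63) and STAI-T total score (20-80), plus optional
#' descriptive fields.
#'
#' @param subject_id character vector.
#' @param bdi,stai integer questionnaire scores (NA allowed).
#' @param age,gender optional descriptive vectors.
#' @return A data frame of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, bdi, stai, age = NA, gender = NA) {
  df <- data.frame(subject_id = as.character(subject_id),
                   bdi = as.numeric(bdi), stai = as.numeric(stai),
                   age = age, gender = gender,
                   stringsAsFactors = FALSE)
  bad_bdi <- !is.na(df$bdi) & (df$bdi < 0 | df$bdi > 63)
  bad_stai <- !is.na(df$stai) & (df$stai < 20 | df$stai > 80)
  if (any(bad_bdi))
    stopf("BDI-II scores out of range 0-63 for: %s",
          paste(df$subject_id[bad_bdi], collapse = ", "))
  if (any(bad_stai))
    stopf("STAI-T scores out of range 20-80 for: %s",
          paste(df$subject_id[bad_stai], collapse = ", "))
  class(df) <- c("subject_meta", "data.frame")
  df
}

#' Questionnaire-based group assignment
#'
#' Assigns every subject to exactly one of five labels from the BDI-II and
#' STAI-T scores. With the default cutoffs: `DEP` (bdi > 13 and stai > 41),
#' `ANX` (bdi <= 13 and stai > 42), `CTR_DEP` (bdi <= 13 and stai > 41 but
#' not ANX), `CTR_ANX` (bdi <= 13 and stai < 41), otherwise `UNASSIGNED`.
#' Cutoff comparisons are strict on both sides, so scores sitting exactly on
#' a cutoff are `UNASSIGNED`.
#'
#' The low-BDI/high-STAI cell serves double duty: in the depression contrast
#' its members (both `CTR_DEP` and `ANX`) are the anxiety-matched controls;
#' in the anxiety contrast only its higher-STAI `ANX` members form the
#' symptomatic class. [select_contrast()] implements both readings.
#'
#' @param meta a [subject_meta()] table.
#' @param bdi_cut BDI-II cutoff (default 13).
#' @param stai_high STAI-T cutoff for the high-anxiety cell (default 41).
#' @param stai_anx STAI-T cutoff for the anxiety symptomatic group
#'   (default 42).
#' @param stai_low STAI-T cutoff below which subjects are low-anxiety
#'   controls (default 41).
#' @return Data frame with columns `subject_id`, `group` (factor) and the
#'   cutoffs used (as attributes).
#' @examples
#' m <- subject_meta(c("a", "b", "c"), bdi = c(24, 4, 13),
#'                   stai = c(54, 35, 41))
#' assign_groups(m)$group
#' @export
assign_groups <- function(meta, bdi_cut = 13, stai_high = 41, stai_anx = 42,
                          stai_low = 41) {
  stopifnot(is.data.frame(meta))
  bdi <- meta$bdi; stai <- meta$stai
  grp <- rep("UNASSIGNED", nrow(meta))
  missing <- is.na(bdi) | is.na(stai)
  if (any(missing))
    warnf("missing questionnaire score(s) for %d subject(s); left UNASSIGNED",
          sum(missing))
  ok <- !missing
  grp[ok & bdi > bdi_cut & stai > stai_high] <- "DEP"
  low <- ok & bdi <= bdi_cut
  grp[low & stai > stai_anx] <- "ANX"
  grp[low & stai > stai_high & stai <= stai_anx] <- "CTR_DEP"
  grp[low & stai < stai_low] <- "CTR_ANX"
  out <- data.frame(subject_id = meta$subject_id,
                    group = factor(grp, levels = c("DEP", "CTR_DEP", "ANX",
                                                   "CTR_ANX", "UNASSIGNED")),
                    stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- list(bdi_cut = bdi_cut, stai_high = stai_high,
                               stai_anx = stai_anx, stai_low = stai_low)
  out
}

#' Select the subjects for a binary symptom contrast
#'
#' `depression`: symptomatic = `DEP`; controls = the full low-BDI/high-STAI
#' cell (`CTR_DEP` and `ANX`), keeping anxiety high in both classes.
#' `anxiety`: symptomatic = `ANX`; controls = `CTR_ANX`.
#'
#' @param groups output of [assign_groups()].
#' @param contrast `"depression"` or `"anxiety"`.
#' @return Data frame with `subject_id` and `label`, a factor with levels
#'   `control` / `symptomatic` (the symptomatic group is the positive class).
#' @export
select_contrast <- function(groups, contrast = c("depression", "anxiety")) {
  contrast <- match.arg(contrast)
  g <- as.character(groups$group)
  if (contrast == "depression") {
    pos <- g == "DEP"; neg <- g %in% c("CTR_DEP", "ANX")
  } else {
    pos <- g == "ANX"; neg <- g == "CTR_ANX"
  }
  if (sum(pos) < 2 || sum(neg) < 2)
    stopf("contrast '%s' needs at least 2 subjects per class (got %d vs %d)",
          contrast, sum(pos), sum(neg))
  keep <- pos | neg
  data.frame(subject_id = groups$subject_id[keep],
             label = factor(ifelse(pos[keep], "symptomatic", "control"),
                            levels = c("control", "symptomatic")),
             stringsAsFactors = FALSE)
}
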