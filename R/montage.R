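#' Channel montage
#'
#' A montage is an ordered set of channel labels (10-20/10-10 style) with
#' optional 2-D head-plane coordinates used for topographic export of CSP
#' spatial patterns. Coordinates are unitless; the head is mapped to the unit
#' disc with the nose pointing towards positive y.
#'
#' @param labels character vector of unique channel names, e.g. `"FCz"`.
#' @param positions optional data frame with columns `x` and `y`, one row per
#'   label, in head-plane coordinates.
#' @return An object of class `eeg_montage`.
#' @examples
#' m <- montage(c("FCz", "Cz", "Pz"))
#' length(m$labels)
#' @export
montage <- function(labels, positions = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stopf("montage labels must be unique (duplicated: %s)",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!is.null(positions)) {
    positions <- as.data.frame(positions)
    if (!all(c("x", "y") %in% names(positions)))
      stopf("montage positions need columns 'x' and 'y'")
    if (nrow(positions) != length(labels))
      stopf("montage has %d labels but %d positions",
            length(labels), nrow(positions))
    positions <- positions[, c("x", "y")]
    rownames(positions) <- labels
  }
  structure(list(labels = labels, positions = positions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels%s\n", length(x$labels),
              if (is.null(x$positions)) "" else " (with 2-D positions)"))
  cat("  ", paste(utils::head(x$labels, 10), collapse = " "),
      if (length(x$labels) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
length.eeg_montage <- function(x) length(x$labels)

# 64-channel 10-10 cap layout (BioSemi ordering) with approximate head-plane
# coordinates; y > 0 is anterior.
.biosemi64 <- local({
  labels <- c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5",
    "FC3", "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz",
    "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8",
    "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8",
    "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
  x <- c(-0.3090, -0.5878, -0.4065, -0.2871, -0.5453, -0.7294, -0.8090,
    -0.9511, -0.8884, -0.6768, -0.3749, -0.3910, -0.7198, -0.9341, -1.0000,
    -0.9511, -0.8884, -0.6768, -0.3749, -0.2871, -0.5453, -0.7294, -0.8090,
    -0.7337, -0.5878, -0.4065, -0.3090, 0.0000, 0.0000, 0.0000, 0.0000,
    0.0000, 0.0000, 0.3090, 0.5878, 0.4065, 0.0000, 0.0000, 0.2871, 0.5453,
    0.7294, 0.8090, 0.9511, 0.8884, 0.6768, 0.3749, 0.0000, 0.0000, 0.3910,
    0.7198, 0.9341, 1.0000, 0.9511, 0.8884, 0.6768, 0.3749, 0.2871, 0.5453,
    0.7294, 0.8090, 0.7337, 0.5878, 0.4065, 0.3090)
  y <- c(0.9511, 0.8090, 0.8717, 0.7107, 0.6734, 0.6341, 0.5878, 0.3090,
    0.3410, 0.3599, 0.3749, 0.0000, 0.0000, 0.0000, 0.0000, -0.3090,
    -0.3410, -0.3599, -0.3749, -0.7107, -0.6734, -0.6341, -0.5878, -0.5330,
    -0.8090, -0.8717, -0.9511, -0.9069, -1.0000, -0.9341, -0.7198, -0.3910,
    1.0000, 0.9511, 0.8090, 0.8717, 0.9341, 0.7198, 0.7107, 0.6734, 0.6341,
    0.5878, 0.3090, 0.3410, 0.3599, 0.3749, 0.3910, 0.0000, 0.0000, 0.0000,
    0.0000, 0.0000, -0.3090, -0.3410, -0.3599, -0.3749, -0.7107, -0.6734,
    -0.6341, -0.5878, -0.5330, -0.8090, -0.8717, -0.9511)
  list(labels = labels, x = x, y = y)
})

#' Standard 64-channel montage
#'
#' The 64-channel 10-10 active-electrode cap layout (BioSemi channel order),
#' including the fronto-central midline electrode FCz used for the RewP/FRN
#' amplitude feature. Positions are approximate head-plane projections.
#'
#' @param n optional number of leading channels to keep (the subset always
#'   retains the full cap ordering). Useful for reduced test problems; note
#'   that `FCz` is channel 47, so `n < 47` drops it.
#' @return An `eeg_montage` with up to 64 channels.
#' @examples
#' m <- biosemi64_montage()
#' which(m$labels == "FCz")
#' @export
biosemi64_montage <- function(n = 64L) {
  stopifnot(is_count(n), n <= 64)
  idx <- seq_len(n)
  montage(.biosemi64$labels[idx],
          data.frame(x = .biosemi64$x[idx], y = .biosemi64$y[idx]))
}

#' Small midline-heavy montage for reduced problems
#'
#' Selects a named subset of the 64-channel cap (default: eight channels along
#' and around the midline, including FCz) keeping their positions. Intended
#' for simulation studies where the full cap is unnecessarily large.
#'
#' @param labels channel names to keep (must exist on the 64-channel cap).
#' @return An `eeg_montage`.
#' @export
subset_montage <- function(labels = c("Fz", "FCz", "Cz", "CPz", "Pz",
                                      "F3", "F4", "Oz")) {
  idx <- match(labels, .biosemi64$labels)
  if (anyNA(idx))
    stopf("unknown channel(s): %s", paste(labels[is.na(idx)], collapse = ", "))
  montage(.biosemi64$labels[idx],
          data.frame(x = .biosemi64$x[idx], y = .biosemi64$y[idx]))
}

channel_index <- function(montage, channel) {
  i <- match(channel, montage$labels)
  if (is.na(i)) stopf("channel '%s' not in montage", channel)
  i
}
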