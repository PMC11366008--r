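#' FIR filter specification
#'
#' Describes a zero-phase windowed-sinc (Hamming) FIR design by its passband
#' edges and transition bandwidths. The -6 dB (half-amplitude) cutoff of each
#' edge sits half a transition bandwidth outside the passband edge, the
#' convention of windowed time-domain designs.
#'
#' @param kind `"lowpass"` or `"bandpass"`.
#' @param cutoffs_hz passband edge(s): one value for lowpass, two for
#'   bandpass.
#' @param transition_bw_hz transition bandwidth per edge in Hz (default 2).
#' @param window taper name; only `"hamming"` is implemented.
#' @param zero_phase logical; the kernel is symmetric (linear phase) and is
#'   applied non-causally so the net group delay is zero.
#' @param srate sampling rate in Hz.
#' @return An object of class `fir_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "bandpass"), cutoffs_hz,
                        transition_bw_hz = 2, window = "hamming",
                        zero_phase = TRUE, srate) {
  kind <- match.arg(kind)
  window <- match.arg(window, "hamming")
  nc <- if (kind == "lowpass") 1L else 2L
  if (length(cutoffs_hz) != nc)
    stopf("%s spec needs %d cutoff(s)", kind, nc)
  if (any(cutoffs_hz <= 0) || any(cutoffs_hz >= srate / 2))
    stopf("cutoffs must lie strictly inside (0, srate/2)")
  if (transition_bw_hz <= 0) stopf("transition bandwidth must be > 0")
  lo6 <- cutoffs_hz - transition_bw_hz / 2
  hi6 <- cutoffs_hz + transition_bw_hz / 2
  if (kind == "lowpass") {
    if (hi6 + transition_bw_hz / 2 >= srate / 2)
      stopf("transition band crosses the Nyquist frequency")
  } else {
    if (lo6[1] - transition_bw_hz / 2 < 0)
      stopf("lower transition band crosses 0 Hz")
    if (hi6[2] + transition_bw_hz / 2 >= srate / 2)
      stopf("upper transition band crosses the Nyquist frequency")
    if (hi6[1] >= lo6[2]) stopf("bandpass edges overlap")
  }
  structure(list(kind = kind, cutoffs_hz = cutoffs_hz,
                 transition_bw_hz = transition_bw_hz, window = window,
                 zero_phase = zero_phase, srate = as.numeric(srate)),
            class = "fir_spec")
}

#' @rdname filter_spec
#' @param srate sampling rate in Hz.
#' @details `delta_filter_spec()` is the delta-isolation design (lowpass,
#'   3 Hz passband edge, -6 dB at 4.00 Hz); `theta_filter_spec()` the
#'   theta-isolation design (bandpass 4-7.5 Hz, -6 dB at 3.00 and 8.50 Hz).
#' @export
delta_filter_spec <- function(srate = 256) {
  filter_spec("lowpass", 3, transition_bw_hz = 2, srate = srate)
}

#' @rdname filter_spec
#' @export
theta_filter_spec <- function(srate = 256) {
  filter_spec("bandpass", c(4, 7.5), transition_bw_hz = 2, srate = srate)
}

spec_band <- function(spec) {
  if (spec$kind == "lowpass") "delta" else "theta"
}

# -6 dB cutoff frequencies of a spec (edge +- transition/2)
spec_f6 <- function(spec) {
  if (spec$kind == "lowpass") spec$cutoffs_hz + spec$transition_bw_hz / 2
  else c(spec$cutoffs_hz[1] - spec$transition_bw_hz / 2,
         spec$cutoffs_hz[2] + spec$transition_bw_hz / 2)
}

windowed_sinc_lowpass <- function(fc, n, srate) {
  m <- (n - 1L) / 2L
  t <- (-m):m
  x <- 2 * fc * t / srate
  h <- 2 * fc / srate * ifelse(t == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.54 + 0.46 * cos(pi * t / m)  # symmetric Hamming taper
  h * w
}

build_kernel <- function(spec, n) {
  f6 <- spec_f6(spec)
  if (spec$kind == "lowpass") {
    h <- windowed_sinc_lowpass(f6, n, spec$srate)
    h / sum(h)  # unit DC gain
  } else {
    h <- windowed_sinc_lowpass(f6[2], n, spec$srate) -
      windowed_sinc_lowpass(f6[1], n, spec$srate)
    fmid <- mean(f6)
    k <- seq_len(n) - 1L
    g <- abs(sum(h * exp(-2i * pi * fmid * k / spec$srate)))
    h / g  # unit gain at passband centre
  }
}

#' Magnitude response of an FIR kernel
#'
#' @param h coefficient vector.
#' @param freqs_hz frequencies at which to evaluate.
#' @param srate sampling rate in Hz.
#' @return Magnitude (linear gain) at each frequency.
#' @export
filter_response <- function(h, freqs_hz, srate) {
  k <- seq_along(h) - 1L
  vapply(freqs_hz,
         function(f) abs(sum(h * exp(-2i * pi * f * k / srate))), 0)
}

measure_kernel <- function(h, spec) {
  srate <- spec$srate
  f6 <- spec_f6(spec)
  tb2 <- spec$transition_bw_hz / 2
  grid <- seq(0.01, srate / 2 - 0.01, by = 0.01)
  mag <- filter_response(h, grid, srate)
  crossing <- function(lo, hi) {
    idx <- which(grid >= lo & grid <= hi)
    m <- mag[idx]
    j <- which(diff(m >= 0.5) != 0)
    if (!length(j)) return(NA_real_)
    j <- j[1]
    f1 <- grid[idx[j]]; f2 <- grid[idx[j + 1]]
    m1 <- m[j]; m2 <- m[j + 1]
    f1 + (0.5 - m1) / (m2 - m1) * (f2 - f1)
  }
  if (spec$kind == "lowpass") {
    f6_meas <- crossing(f6 - tb2, f6 + tb2)
    pass <- grid <= spec$cutoffs_hz
    stop_mask <- grid >= f6 + tb2
  } else {
    f6_meas <- c(crossing(f6[1] - tb2, f6[1] + tb2),
                 crossing(f6[2] - tb2, f6[2] + tb2))
    pass <- grid >= spec$cutoffs_hz[1] & grid <= spec$cutoffs_hz[2]
    stop_mask <- grid <= f6[1] - tb2 | grid >= f6[2] + tb2
  }
  list(f6_db = f6_meas,
       passband_ripple = max(abs(mag[pass] - 1)),
       stopband_attenuation_db = -20 * log10(max(mag[stop_mask])))
}

#' Design a windowed-sinc FIR filter
#'
#' Builds the symmetric (linear-phase, odd-length) Hamming windowed-sinc
#' kernel for a [filter_spec()]. The kernel length starts at the classical
#' Hamming heuristic of 3.3 / transition-bandwidth seconds (rounded up to an
#' odd sample count) and is then grown, two taps at a time, until the
#' measured response meets the design's rated characteristics: passband
#' ripple at most `ripple` and stopband attenuation at least
#' `stopband_db` beyond every transition band. The -6 dB points are fixed at
#' passband edge +- half the transition bandwidth by construction.
#'
#' @param spec a [filter_spec()].
#' @param stopband_db rated minimum stopband attenuation in dB (default 53,
#'   the Hamming design rating).
#' @param ripple rated maximum passband ripple (default 0.0194).
#' @param max_extra_taps safety cap on the length search.
#' @return An object of class `fir_design` with elements `h` (coefficients),
#'   `spec`, `n_taps` and `measured` (the audit of -6 dB points, ripple and
#'   stopband attenuation).
#' @examples
#' d <- design_fir(delta_filter_spec())
#' d$measured$f6_db  # 4.00 Hz
#' @export
design_fir <- function(spec, stopband_db = 53, ripple = 0.0194,
                       max_extra_taps = 400L) {
  stopifnot(inherits(spec, "fir_spec"))
  n <- ceiling(3.3 / spec$transition_bw_hz * spec$srate)
  if (n %% 2L == 0L) n <- n + 1L
  n0 <- n
  repeat {
    h <- build_kernel(spec, n)
    meas <- measure_kernel(h, spec)
    if ((meas$stopband_attenuation_db >= stopband_db &&
         meas$passband_ripple <= ripple) || n - n0 >= max_extra_taps)
      break
    n <- n + 2L
  }
  structure(list(h = h, spec = spec, n_taps = n, measured = meas),
            class = "fir_design")
}

#' @export
print.fir_design <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<fir_design> %s %s Hz (srate %g Hz), %d taps\n", s$kind,
              paste(s$cutoffs_hz, collapse = "-"), s$srate, x$n_taps))
  cat(sprintf("  -6 dB point(s): %s Hz\n",
              paste(sprintf("%.3f", x$measured$f6_db), collapse = ", ")))
  cat(sprintf("  passband ripple: %.4f; stopband attenuation: %.1f dB\n",
              x$measured$passband_ripple,
              x$measured$stopband_attenuation_db))
  invisible(x)
}

# Zero-phase application: reflect-pad each channel by half the kernel length,
# convolve with the symmetric kernel, trim. Requires the padded length to be
# available, i.e. epochs longer than half the kernel.
fir_apply_matrix <- function(x, h) {
  p <- (length(h) - 1L) %/% 2L
  n <- ncol(x)
  if (p >= n)
    stopf("signal too short (%d samples) for a %d-tap zero-phase filter",
          n, length(h))
  left <- x[, (p + 1L):2L, drop = FALSE]
  right <- x[, (n - 1L):(n - p), drop = FALSE]
  xp <- cbind(left, x, right)
  y <- conv_same_rows(xp, h)
  y[, (p + 1L):(p + n), drop = FALSE]
}

#' Apply a band-separation filter to a broadband ERP
#'
#' Zero-phase application of a [design_fir()] kernel to a full-length
#' broadband [subject_erp()]; the result is tagged with the corresponding
#' band (`delta` for lowpass, `theta` for bandpass) so that a second
#' filtering pass is refused. Filtering always precedes analysis-window
#' extraction so edge transients never reach the window.
#'
#' @param erp a broadband [subject_erp()].
#' @param design a [fir_design()] (a bare [filter_spec()] is accepted and
#'   designed on the fly).
#' @return The filtered [subject_erp()] with `band` set.
#' @export
apply_filter <- function(erp, design) {
  stopifnot(inherits(erp, "subject_erp"))
  if (inherits(design, "fir_spec")) design <- design_fir(design)
  stopifnot(inherits(design, "fir_design"))
  if (erp$band != "broadband")
    stopf("subject %s: ERP is already band-limited ('%s'); refusing to re-filter",
          erp$subject_id, erp$band)
  if (abs(design$spec$srate - erp$srate) > 1e-9)
    stopf("filter designed for %g Hz but ERP sampled at %g Hz",
          design$spec$srate, erp$srate)
  out <- erp
  out$data <- fir_apply_matrix(erp$data, design$h)
  out$band <- spec_band(design$spec)
  out
}

sample_index <- function(t_ms, t0, srate) round((t_ms - t0) * srate / 1000)

#' Baseline-correct epochs or an ERP
#'
#' Subtracts, per channel (and per trial for epochs), the mean over the
#' pre-feedback baseline interval. Idempotent.
#'
#' @param x an [epoch_set()] or [subject_erp()].
#' @param interval baseline interval in ms relative to feedback onset
#'   (default `c(-250, 0)`).
#' @return `x` with the baseline removed.
#' @export
baseline_correct <- function(x, interval = c(-250, 0)) UseMethod("baseline_correct")

baseline_cols <- function(interval, t0, srate, nsamp) {
  if (interval[1] >= interval[2]) stopf("baseline interval must have start < end")
  i0 <- sample_index(interval[1], t0, srate)
  i1 <- sample_index(interval[2], t0, srate)
  if (i0 < 0 || i1 > nsamp)
    stopf("baseline interval [%g, %g] ms outside the epoch span",
          interval[1], interval[2])
  (i0 + 1L):i1
}

#' @export
baseline_correct.subject_erp <- function(x, interval = c(-250, 0)) {
  cols <- baseline_cols(interval, x$t0, x$srate, ncol(x$data))
  x$data <- x$data - rowMeans(x$data[, cols, drop = FALSE])
  x
}

#' @export
baseline_correct.epoch_set <- function(x, interval = c(-250, 0)) {
  d <- dim(x$data)
  cols <- baseline_cols(interval, x$t0, x$srate, d[3])
  bl <- rowMeans(x$data[, , cols, drop = FALSE], dims = 2)
  x$data <- x$data - array(bl, dim = d)  # column-major recycling over samples
  x
}

#' Average epochs by feedback valence
#'
#' Arithmetic mean across trials of each valence, yielding the subject's
#' positive- and negative-feedback broadband ERPs. Subjects with fewer than
#' `min_trials` artifact-free trials in either valence are excluded (error of
#' class `erpcsp_excluded`), mirroring the usual trial-count exclusion rule.
#'
#' @param epochs an [epoch_set()].
#' @param min_trials minimum trials per valence (default 5).
#' @return Named list with `positive` and `negative` [subject_erp()]s.
#' @export
average_by_condition <- function(epochs, min_trials = 5L) {
  stopifnot(inherits(epochs, "epoch_set"))
  out <- list()
  for (v in c("positive", "negative")) {
    idx <- which(epochs$valence == v)
    if (length(idx) < min_trials)
      stopf("subject %s excluded: only %d %s-feedback trial(s) (minimum %d)",
            epochs$subject_id, length(idx), v, min_trials,
            class = "erpcsp_excluded")
    m <- colMeans(epochs$data[idx, , , drop = FALSE], dims = 1)
    out[[v]] <- subject_erp(epochs$subject_id, v, "broadband", m,
                            epochs$srate, epochs$t0, epochs$montage)
  }
  out
}

#' Extract the analysis window from an ERP
#'
#' Returns the channels x samples matrix covering the half-open interval
#' `[start, end)` in ms, mapped to samples by
#' `round((t_ms - t0) * srate / 1000)`. At 256 Hz the default 200-300 ms
#' window spans 26 samples.
#'
#' @param erp a [subject_erp()].
#' @param window `c(start_ms, end_ms)` relative to feedback onset.
#' @return Numeric matrix, channels x window samples.
#' @export
extract_window <- function(erp, window = c(200, 300)) {
  stopifnot(inherits(erp, "subject_erp"))
  if (window[1] >= window[2]) stopf("analysis window must have start < end")
  i0 <- sample_index(window[1], erp$t0, erp$srate)
  i1 <- sample_index(window[2], erp$t0, erp$srate)
  if (i0 < 0 || i1 > ncol(erp$data) || i0 >= i1)
    stopf("window [%g, %g] ms outside the epoch span", window[1], window[2])
  erp$data[, (i0 + 1L):i1, drop = FALSE]
}

#' Mean-amplitude ERP feature (RewP / FRN)
#'
#' Mean amplitude over the analysis window at a single electrode, the
#' classical quantification of the reward positivity (positive-feedback ERP)
#' and feedback-related negativity (negative-feedback ERP): mean 200-300 ms
#' activity at FCz.
#'
#' @param erp a [subject_erp()].
#' @param channel electrode label (default `"FCz"`).
#' @param window analysis window in ms (default `c(200, 300)`).
#' @return Scalar mean amplitude in microvolts.
#' @export
erp_amplitude <- function(erp, channel = "FCz", window = c(200, 300)) {
  i <- channel_index(erp$montage, channel)
  mean(extract_window(erp, window)[i, ])
}

#' Describe the band-separation filters
#'
#' Designs the delta and theta filters at the given sampling rate and returns
#' the measured audit table (-6 dB points, passband ripple, stopband
#' attenuation, tap count).
#'
#' @param srate sampling rate in Hz.
#' @return Data frame, one row per filter edge measurement.
#' @export
describe_filters <- function(srate = 256) {
  dd <- design_fir(delta_filter_spec(srate))
  dt <- design_fir(theta_filter_spec(srate))
  data.frame(
    filter = c("delta_lowpass", "theta_bandpass", "theta_bandpass"),
    edge = c("upper", "lower", "upper"),
    f6_db_hz = c(dd$measured$f6_db, dt$measured$f6_db),
    passband_ripple = c(dd$measured$passband_ripple,
                        rep(dt$measured$passband_ripple, 2)),
    stopband_attenuation_db = c(dd$measured$stopband_attenuation_db,
                                rep(dt$measured$stopband_attenuation_db, 2)),
    n_taps = c(dd$n_taps, rep(dt$n_taps, 2)))
}
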