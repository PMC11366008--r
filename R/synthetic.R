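#' Gaussian topography templates
#'
#' Unit-norm channel-weight vectors concentrated over a scalp region, used
#' both to plant group effects in the generator and to check that CSP
#' recovers their location. Weights follow a Gaussian of the head-plane
#' distance to a center electrode.
#'
#' @param montage an [montage()] with positions.
#' @param center center electrode label.
#' @param sigma Gaussian width in head-plane units (head radius = 1).
#' @return Unit-norm numeric vector, one weight per channel.
#' @export
topography_at <- function(montage, center, sigma = 0.35) {
  if (is.null(montage$positions))
    stopf("montage has no positions; cannot build a topography")
  i <- channel_index(montage, center)
  dx <- montage$positions$x - montage$positions$x[i]
  dy <- montage$positions$y - montage$positions$y[i]
  w <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
  w / sqrt(sum(w^2))
}

#' @rdname topography_at
#' @details `frontal_topography()` peaks at FCz (falling back to the most
#'   anterior midline channel), `centroparietal_topography()` at Pz.
#' @export
frontal_topography <- function(montage, sigma = 0.35) {
  center <- if ("FCz" %in% montage$labels) "FCz" else
    montage$labels[which.max(montage$positions$y)]
  topography_at(montage, center, sigma)
}

#' @rdname topography_at
#' @export
centroparietal_topography <- function(montage, sigma = 0.35) {
  center <- if ("Pz" %in% montage$labels) "Pz" else
    montage$labels[which.min(montage$positions$y)]
  topography_at(montage, center, sigma)
}

#' Planted group-effect specification
#'
#' Describes one band-limited, spatially localized amplitude effect added to
#' the generated epochs: a Hann-enveloped sinusoid at the band's center
#' frequency (1.5 Hz for delta, 5.75 Hz for theta), weighted by a unit-norm
#' topography, whose source amplitude has a group-mean difference of
#' `amplitude_shift` (symptomatic minus control).
#'
#' @param band `"delta"` or `"theta"`.
#' @param valence `"positive"` or `"negative"`: the feedback condition that
#'   carries the effect.
#' @param topography unit-norm numeric weight vector over channels, or one of
#'   `"frontal"` / `"centroparietal"` (resolved against the montage at
#'   generation time).
#' @param amplitude_shift group-mean source-amplitude difference in
#'   microvolts.
#' @param base_amplitude source amplitude common to both groups (microvolts).
#' @param window `c(start_ms, end_ms)` on which the effect pulse is centered
#'   (default the 200-300 ms analysis window).
#' @param pulse_dur_ms duration of the Hann envelope. The default 1400 ms
#'   keeps the pulse's spectral main lobe about +-1.4 Hz around the carrier,
#'   so a delta effect (1.5 Hz) stays below the theta passband edge (3 Hz at
#'   -6 dB) and a theta effect (5.75 Hz) stays inside 4-7.5 Hz, essentially
#'   out of the delta lowpass.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(band = c("delta", "theta"),
                        valence = c("positive", "negative"),
                        topography = "frontal",
                        amplitude_shift = 1,
                        base_amplitude = 1,
                        window = c(200, 300),
                        pulse_dur_ms = 1400) {
  band <- match.arg(band)
  valence <- match.arg(valence)
  if (is.numeric(topography)) {
    if (!all(is.finite(topography))) stopf("topography must be finite")
    nrm <- sqrt(sum(topography^2))
    if (nrm <= 0) stopf("topography must be non-zero")
    topography <- topography / nrm
  } else topography <- match.arg(topography, c("frontal", "centroparietal"))
  if (window[1] >= window[2]) stopf("effect window must have start < end")
  structure(list(band = band, valence = valence, topography = topography,
                 amplitude_shift = amplitude_shift,
                 base_amplitude = base_amplitude,
                 window = as.numeric(window),
                 pulse_dur_ms = as.numeric(pulse_dur_ms)),
            class = "effect_spec")
}

band_center_hz <- c(delta = 1.5, theta = 5.75)

# Hann-enveloped cosine pulse evaluated at epoch times (ms)
effect_pulse <- function(effect, times_ms) {
  center <- mean(effect$window)
  half <- effect$pulse_dur_ms / 2
  env <- ifelse(abs(times_ms - center) <= half,
                0.5 * (1 + cos(pi * (times_ms - center) / half)), 0)
  fc <- band_center_hz[[effect$band]]
  env * cos(2 * pi * fc * (times_ms - center) / 1000)
}

#' Generator configuration
#'
#' Defaults emulate a typical feedback-task recording: 64 channels at
#' 256 Hz, epochs spanning -1000 to
#' 2400 ms around feedback onset, and per-valence trial counts matching the
#' average artifact-free epoch counts of the feedback task (83 positive, 121
#' negative). Background activity is spatially correlated 1/f noise plus a
#' deterministic per-valence ERP template; group structure enters only
#' through the `effects` list and the questionnaire scores.
#'
#' @param n_per_group subjects per class (symptomatic, control).
#' @param trials_per_valence trials per feedback valence; either one number
#'   or a named vector `c(positive = , negative = )`.
#' @param montage an [montage()] with positions; defaults to the 64-channel
#'   cap. Its size sets the channel count.
#' @param srate sampling rate (Hz).
#' @param t0,t1 epoch span in ms around feedback onset.
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha background.
#' @param noise_sd per-channel noise standard deviation (microvolts).
#' @param erp_scale multiplier on the deterministic ERP template (0 disables
#'   it).
#' @param effects list of [effect_spec()]s.
#' @param subject_sd,trial_sd standard deviations of the subject- and
#'   trial-level Gaussian variability of each effect's source amplitude.
#' @param contrast `"depression"` or `"anxiety"`: which pair of groups the
#'   questionnaire scores emulate.
#' @param seed integer; fully determines the output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 70,
                             trials_per_valence = c(positive = 83,
                                                    negative = 121),
                             montage = biosemi64_montage(),
                             srate = 256, t0 = -1000, t1 = 2400,
                             noise_exponent = 1, noise_sd = 10,
                             erp_scale = 1,
                             effects = list(),
                             subject_sd = 0.5, trial_sd = 0.5,
                             contrast = c("depression", "anxiety"),
                             seed = 1L) {
  contrast <- match.arg(contrast)
  if (length(trials_per_valence) == 1L)
    trials_per_valence <- c(positive = trials_per_valence,
                            negative = trials_per_valence)
  stopifnot(is_count(n_per_group),
            all(vapply(trials_per_valence, is_count, TRUE)),
            inherits(montage, "eeg_montage"),
            srate > 0, t0 < t1, noise_sd >= 0,
            subject_sd >= 0, trial_sd >= 0)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (e$window[1] < t0 || e$window[2] > t1)
      stopf("effect window [%g, %g] ms outside the epoch span [%g, %g]",
            e$window[1], e$window[2], t0, t1)
  }
  structure(list(n_per_group = n_per_group,
                 trials_per_valence = trials_per_valence,
                 montage = montage, srate = srate, t0 = t0, t1 = t1,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 erp_scale = erp_scale, effects = effects,
                 subject_sd = subject_sd, trial_sd = trial_sd,
                 contrast = contrast, seed = as.integer(seed)),
            class = "generator_config")
}

# Group score parameters (means/SDs of the questionnaire instruments by
# group) with truncation ranges that respect the assignment cutoffs.
.score_params <- list(
  DEP     = list(bdi = c(23.47, 8.86), stai = c(54.11, 6.24),
                 bdi_rng = c(14, 63), stai_rng = c(42, 80)),
  CTR_DEP = list(bdi = c(7.07, 3.68), stai = c(47.19, 3.55),
                 bdi_rng = c(0, 13), stai_rng = c(42, 80)),
  ANX     = list(bdi = c(7.02, 3.68), stai = c(47.75, 3.27),
                 bdi_rng = c(0, 13), stai_rng = c(43, 80)),
  CTR_ANX = list(bdi = c(4.44, 3.31), stai = c(34.89, 4.21),
                 bdi_rng = c(0, 13), stai_rng = c(20, 40)))

rtrunc_int <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(2 * n, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(out[seq_len(n)])
}

# spatially correlated noise mixing matrix: each channel mixes the
# independent 1/f sources with spatially smooth random loadings
noise_mixing <- function(montage, seed_draws = TRUE) {
  d <- length(montage)
  A <- matrix(stats::rnorm(d * d), d, d)
  if (!is.null(montage$positions)) {
    px <- montage$positions$x; py <- montage$positions$y
    D2 <- outer(px, px, `-`)^2 + outer(py, py, `-`)^2
    S <- exp(-D2 / (2 * 0.3^2))
    S <- S / rowSums(S)
    A <- S %*% A
  }
  A / sqrt(rowSums(A^2))
}

# n_samples x d matrix of independent 1/f^alpha series, each unit variance.
# Synthesized by spectral shaping on a power-of-two FFT grid (fast) and
# cropped to n samples.
one_over_f <- function(n, d, alpha) {
  nfft <- 2^ceiling(log2(n))
  freqs <- c(0, seq_len(nfft - 1))
  freqs <- pmin(freqs, nfft - freqs)  # two-sided FFT bin frequencies
  amp <- c(0, freqs[-1]^(-alpha / 2))
  re <- matrix(stats::rnorm(nfft * d), nfft, d)
  im <- matrix(stats::rnorm(nfft * d), nfft, d)
  spec <- (re + 1i * im) * amp
  x <- Re(stats::mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE]
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

# deterministic per-valence ERP template: a fronto-central theta-range
# deflection around 250 ms and a slower centro-parietal positivity (P3-like)
erp_template <- function(valence, times_ms, montage, scale = 1) {
  if (scale == 0 || is.null(montage$positions))
    return(matrix(0, length(montage), length(times_ms)))
  topoF <- frontal_topography(montage); topoF <- topoF / max(topoF)
  topoP <- centroparietal_topography(montage); topoP <- topoP / max(topoP)
  hann <- function(c0, dur) ifelse(abs(times_ms - c0) <= dur / 2,
                                   0.5 * (1 + cos(pi * (times_ms - c0) / (dur / 2))), 0)
  amps <- if (valence == "positive") c(theta = 3, delta = 6) else
    c(theta = 4.5, delta = 5)
  wf_theta <- amps[["theta"]] * hann(250, 400) * cos(2 * pi * 5.5 * (times_ms - 250) / 1000)
  wf_delta <- amps[["delta"]] * hann(400, 800)
  scale * (outer(topoF, wf_theta) + outer(topoP, wf_delta))
}

resolve_topography <- function(effect, montage) {
  if (is.character(effect$topography)) {
    switch(effect$topography,
           frontal = frontal_topography(montage),
           centroparietal = centroparietal_topography(montage))
  } else {
    if (length(effect$topography) != length(montage))
      stopf("effect topography has %d weights but montage has %d channels",
            length(effect$topography), length(montage))
    effect$topography
  }
}

#' Generate a synthetic feedback-locked EEG dataset
#'
#' Each trial is the sum of the valence's deterministic ERP template, every
#' planted [effect_spec()] whose valence matches (topography times
#' band-limited pulse, with group-dependent mean source amplitude plus
#' subject- and trial-level Gaussian variability), and spatially correlated
#' 1/f background noise. Questionnaire scores are drawn from group-specific
#' truncated normals that respect the assignment cutoffs, so
#' [assign_groups()] recovers the planted groups.
#'
#' @param config a [generator_config()].
#' @param return `"epochs"` for full [epoch_set()]s, or `"erps"` to reduce
#'   each subject to baseline-corrected condition ERPs on the fly (identical
#'   arithmetic, far smaller memory footprint).
#' @return List with `meta` (a [subject_meta()] table, with the true group in
#'   `attr(,"group")`) and either `epochs` (list of [epoch_set()]) or `erps`
#'   (per subject: list with `positive` / `negative` [subject_erp()]s).
#' @export
generate_dataset <- function(config, return = c("epochs", "erps")) {
  stopifnot(inherits(config, "generator_config"))
  return <- match.arg(return)
  with_seed(config$seed, function() {
    mont <- config$montage
    d <- length(mont)
    n_samp <- round((config$t1 - config$t0) * config$srate / 1000) + 1L
    times <- config$t0 + (seq_len(n_samp) - 1L) * 1000 / config$srate
    n_tot <- 2L * config$n_per_group
    groups <- if (config$contrast == "depression")
      c("DEP", "CTR_DEP") else c("ANX", "CTR_ANX")
    group_of <- rep(groups, each = config$n_per_group)
    ids <- sprintf("S%03d", seq_len(n_tot))

    bdi <- stai <- integer(n_tot)
    for (g in groups) {
      i <- which(group_of == g); p <- .score_params[[g]]
      bdi[i] <- rtrunc_int(length(i), p$bdi[1], p$bdi[2],
                           p$bdi_rng[1], p$bdi_rng[2])
      stai[i] <- rtrunc_int(length(i), p$stai[1], p$stai[2],
                            p$stai_rng[1], p$stai_rng[2])
    }
    meta <- subject_meta(ids, bdi, stai)
    attr(meta, "group") <- group_of

    M <- noise_mixing(mont)
    templates <- list(
      positive = erp_template("positive", times, mont, config$erp_scale),
      negative = erp_template("negative", times, mont, config$erp_scale))
    eff_topo <- lapply(config$effects, resolve_topography, montage = mont)
    eff_pulse <- lapply(config$effects, effect_pulse, times_ms = times)
    symptomatic <- group_of %in% c("DEP", "ANX")

    n_trials <- sum(config$trials_per_valence)
    valence <- rep(c("positive", "negative"), config$trials_per_valence)

    out_ep <- vector("list", n_tot)
    out_erp <- vector("list", n_tot)
    for (s in seq_len(n_tot)) {
      a_subj <- vapply(config$effects, function(ef) {
        ef$base_amplitude + (if (symptomatic[s]) ef$amplitude_shift else 0)
      }, 0) + stats::rnorm(length(config$effects), 0, config$subject_sd)
      # all trials' noise sources in one FFT batch, one mixing product
      src <- one_over_f(n_samp, d * n_trials, config$noise_exponent)
      dim(src) <- c(n_samp, d, n_trials)
      mixed <- config$noise_sd *
        (M %*% matrix(aperm(src, c(2, 1, 3)), nrow = d))
      dim(mixed) <- c(d, n_samp, n_trials)
      dat <- array(0, dim = c(n_trials, d, n_samp))
      for (tr in seq_len(n_trials)) {
        v <- valence[tr]
        trial <- templates[[v]] + mixed[, , tr]
        for (e in seq_along(config$effects)) {
          if (config$effects[[e]]$valence != v) next
          a_tr <- a_subj[e] + stats::rnorm(1, 0, config$trial_sd)
          trial <- trial + outer(eff_topo[[e]], a_tr * eff_pulse[[e]])
        }
        dat[tr, , ] <- trial
      }
      ep <- epoch_set(ids[s], dat, valence, config$srate, config$t0, mont)
      if (return == "epochs") out_ep[[s]] <- ep
      else out_erp[[s]] <- average_by_condition(baseline_correct(ep))
    }
    if (return == "epochs") {
      names(out_ep) <- ids
      list(epochs = out_ep, meta = meta)
    } else {
      names(out_erp) <- ids
      list(erps = out_erp, meta = meta)
    }
  })
}

#' Theoretical planted group differences per band and valence
#'
#' Pure function of the configuration: one row per configured effect with the
#' group-mean source-amplitude difference it plants. Used to decide, ahead of
#' any model fit, which band/valence combination should carry discriminative
#' signal.
#'
#' @param config a [generator_config()].
#' @return Data frame: band, valence, amplitude_shift, base_amplitude,
#'   window_start_ms, window_end_ms.
#' @export
planted_effect_report <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!length(config$effects))
    return(data.frame(band = character(), valence = character(),
                      amplitude_shift = numeric(), base_amplitude = numeric(),
                      window_start_ms = numeric(), window_end_ms = numeric()))
  do.call(rbind, lapply(config$effects, function(e)
    data.frame(band = e$band, valence = e$valence,
               amplitude_shift = e$amplitude_shift,
               base_amplitude = e$base_amplitude,
               window_start_ms = e$window[1], window_end_ms = e$window[2])))
}
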