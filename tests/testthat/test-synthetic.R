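test_that("the same seed reproduces the dataset exactly", {
  cfg <- quick_config(n_per_group = 3, trials_per_valence = 5, seed = 42)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$epochs$S001$data, b$epochs$S001$data)
  expect_identical(a$meta, b$meta)
  cfg2 <- quick_config(n_per_group = 3, trials_per_valence = 5, seed = 43)
  c <- generate_dataset(cfg2)
  expect_false(identical(a$epochs$S001$data, c$epochs$S001$data))
})

test_that("the ERP return mode equals averaging the full epochs", {
  cfg <- quick_config(n_per_group = 2, trials_per_valence = 5, seed = 7)
  full <- generate_dataset(cfg, return = "epochs")
  erps <- generate_dataset(cfg, return = "erps")
  manual <- average_by_condition(baseline_correct(full$epochs$S002))
  expect_equal(erps$erps$S002$positive$data, manual$positive$data)
  expect_equal(erps$erps$S002$negative$data, manual$negative$data)
})

test_that("generated questionnaire scores recover the planted groups", {
  cfg <- quick_config(n_per_group = 15, trials_per_valence = 5, seed = 5)
  ds <- generate_dataset(cfg, return = "erps")
  g <- assign_groups(ds$meta)
  truth <- attr(ds$meta, "group")
  expect_equal(as.character(g$group[truth == "DEP"]), rep("DEP", 15))
  expect_true(all(g$group[truth == "CTR_DEP"] %in% c("CTR_DEP", "ANX")))
  cfg2 <- quick_config(n_per_group = 10, trials_per_valence = 5, seed = 6,
                       contrast = "anxiety")
  ds2 <- generate_dataset(cfg2, return = "erps")
  g2 <- assign_groups(ds2$meta)
  sel <- select_contrast(g2, "anxiety")
  expect_equal(sum(sel$label == "symptomatic"), 10)
  expect_equal(sum(sel$label == "control"), 10)
})

test_that("the planted-effect report is a pure function of the configuration", {
  cfg0 <- quick_config()
  expect_equal(nrow(planted_effect_report(cfg0)), 0)
  eff <- list(effect_spec("theta", "positive", amplitude_shift = 0),
              effect_spec("delta", "negative", "centroparietal",
                          amplitude_shift = 2))
  cfg <- quick_config(effects = eff)
  rep_ <- planted_effect_report(cfg)
  expect_equal(rep_$band, c("theta", "delta"))
  expect_equal(rep_$valence, c("positive", "negative"))
  expect_equal(rep_$amplitude_shift, c(0, 2))
})

test_that("an effect window outside the epoch span is refused", {
  expect_error(quick_config(effects = effect_spec("theta", "positive",
                                                  window = c(600, 800))),
               "outside the epoch span")
})

test_that("zero-effect data carries no label information", {
  cfg <- quick_config(n_per_group = 10, trials_per_valence = 5, seed = 31)
  ds <- generate_dataset(cfg, return = "erps")
  grp <- attr(ds$meta, "group")
  # group difference of raw windowed power at FCz is noise-level
  pow <- vapply(ds$meta$subject_id, function(id)
    mean(extract_window(ds$erps[[id]]$positive)^2), 0)
  d <- mean(pow[grp == "DEP"]) - mean(pow[grp != "DEP"])
  expect_lt(abs(d) / mean(pow), 0.5)
})

test_that("planted theta power matches a band-power oracle at the peak channel", {
  mont <- mid_montage()
  shift <- 6; base <- 1
  cfg <- generator_config(n_per_group = 25, trials_per_valence = 12,
                          montage = mont, t0 = -400, t1 = 700,
                          noise_sd = 2, erp_scale = 0, seed = 77,
                          effects = effect_spec("theta", "positive",
                                                "frontal",
                                                amplitude_shift = shift,
                                                base_amplitude = base))
  ds <- generate_dataset(cfg, return = "erps")
  grp <- attr(ds$meta, "group")
  topo <- frontal_topography(mont)
  peak <- which.max(topo)

  # independent band-power route: 4th-order Butterworth, not the package FIR
  bw <- signal::butter(4, c(4, 7.5) / 128, type = "pass")
  # 200-300 ms window columns under the documented ms->sample rule
  cols <- (round((200 + 400) * 256 / 1000) + 1):round((300 + 400) * 256 / 1000)
  band_power <- function(erp) {
    y <- signal::filtfilt(bw, erp$data[peak, ])
    mean(y[cols]^2)
  }
  pow <- vapply(ds$meta$subject_id, function(id) band_power(ds$erps[[id]]$positive), 0)
  measured <- mean(pow[grp == "DEP"]) - mean(pow[grp != "DEP"])

  # same oracle applied to the deterministic unit pulse
  times <- -400 + (0:281) * 1000 / 256
  eff <- cfg$effects[[1]]
  pulse <- erpcsp:::effect_pulse(eff, times)
  pf <- signal::filtfilt(bw, pulse)
  w2 <- mean(pf[cols]^2)
  expected <- ((base + shift)^2 - base^2) * topo[peak]^2 * w2
  expect_equal(measured, expected, tolerance = 0.2)
})

test_that("background noise follows the configured 1/f spectral slope", {
  cfg <- quick_config(n_per_group = 2, trials_per_valence = 20,
                      noise_sd = 10, seed = 13, erp_scale = 0)
  ds <- generate_dataset(cfg)
  x <- ds$epochs$S001$data
  n <- dim(x)[3]
  freq <- (0:(n - 1)) * 256 / n
  keep <- freq >= 2 & freq <= 40
  pows <- 0
  for (tr in 1:dim(x)[1]) for (ch in 1:4)
    pows <- pows + Mod(fft(x[tr, ch, ]))^2
  fit <- lm(log(pows[keep]) ~ log(freq[keep]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.3)
})

test_that("a delta-only effect barely leaks into the theta band", {
  mont <- mid_montage()
  cfg <- generator_config(n_per_group = 12, trials_per_valence = 8,
                          montage = mont, noise_sd = 1, erp_scale = 0,
                          seed = 19,
                          effects = effect_spec("delta", "positive",
                                                "centroparietal",
                                                amplitude_shift = 8,
                                                base_amplitude = 1))
  ds <- generate_dataset(cfg, return = "erps")
  grp <- attr(ds$meta, "group")
  topo <- centroparietal_topography(mont)
  peak <- which.max(topo)
  dd <- design_fir(delta_filter_spec(256))
  dt <- design_fir(theta_filter_spec(256))
  wpow <- function(id, design) {
    b <- apply_filter(ds$erps[[id]]$positive, design)
    mean(extract_window(b)[peak, ]^2)
  }
  p_delta <- vapply(ds$meta$subject_id, wpow, 0, design = dd)
  p_theta <- vapply(ds$meta$subject_id, wpow, 0, design = dt)
  d_delta <- mean(p_delta[grp == "DEP"]) - mean(p_delta[grp != "DEP"])
  d_theta <- mean(p_theta[grp == "DEP"]) - mean(p_theta[grp != "DEP"])
  expect_lt(abs(d_theta), 0.10 * abs(d_delta))
})
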