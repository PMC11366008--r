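delta_d <- design_fir(delta_filter_spec(256))
theta_d <- design_fir(theta_filter_spec(256))

test_that("the delta and theta designs hit the printed -6 dB points", {
  expect_equal(delta_d$measured$f6_db, 4.00, tolerance = 0.05 / 4)
  expect_equal(theta_d$measured$f6_db[1], 3.00, tolerance = 0.05 / 3)
  expect_equal(theta_d$measured$f6_db[2], 8.50, tolerance = 0.05 / 8.5)
})

test_that("both designs meet the rated ripple and stopband attenuation", {
  expect_lte(delta_d$measured$passband_ripple, 0.0194)
  expect_lte(theta_d$measured$passband_ripple, 0.0194)
  expect_gte(delta_d$measured$stopband_attenuation_db, 53 - 1)
  expect_gte(theta_d$measured$stopband_attenuation_db, 53 - 1)
})

test_that("kernels are odd-length, symmetric, with the correct DC gain", {
  for (d in list(delta_d, theta_d)) {
    expect_equal(d$n_taps %% 2, 1)
    expect_equal(d$h, rev(d$h))
  }
  expect_equal(sum(delta_d$h), 1, tolerance = 1e-12)   # unit DC gain
  # DC null of the bandpass sits at/below the stopband attenuation level
  expect_lt(abs(sum(theta_d$h)), 10^(-52 / 20))
})

test_that("crossover magnitudes at the shared band edges are -6 dB", {
  # delta upper edge 4 Hz and theta lower edge 3 Hz define the crossover
  g_delta <- filter_response(delta_d$h, 4.00, 256)
  g_theta <- filter_response(theta_d$h, c(3.00, 8.50), 256)
  expect_equal(20 * log10(g_delta), -6.02, tolerance = 0.2 / 6)
  expect_equal(20 * log10(g_theta), c(-6.02, -6.02), tolerance = 0.2 / 6)
})

test_that("invalid filter specifications are refused", {
  expect_error(filter_spec("lowpass", 130, srate = 256), "inside")
  expect_error(filter_spec("lowpass", 127.5, transition_bw_hz = 2,
                           srate = 256), "Nyquist")
  expect_error(filter_spec("bandpass", c(1, 2), transition_bw_hz = 3,
                           srate = 256), "0 Hz|overlap")
})

sinusoid_erp <- function(freq, srate = 256, dur_s = 6) {
  n <- dur_s * srate
  t <- (seq_len(n) - 1) / srate
  flat_erp(sin(2 * pi * freq * t), srate = srate, t0 = 0)
}

test_that("in-band sinusoids pass with unit gain, out-of-band at stopband level", {
  central <- 513:1024  # away from edges
  g <- function(design, freq) {
    x <- sinusoid_erp(freq)
    y <- apply_filter(x, design)
    sqrt(mean(y$data[1, central]^2) / mean(x$data[1, central]^2))
  }
  expect_equal(g(delta_d, 1.5), 1, tolerance = 0.02)
  expect_lt(g(theta_d, 1.5), 0.01)
  expect_equal(g(theta_d, 5.75), 1, tolerance = 0.02)
  expect_lt(g(delta_d, 5.75), 0.01)
})

test_that("filtering is zero-phase and linear", {
  x <- sinusoid_erp(5.75)
  y <- apply_filter(x, theta_d)
  central <- 513:1024
  lags <- -3:3
  cors <- sapply(lags, function(l)
    cor(x$data[1, central], y$data[1, central + l]))
  expect_lte(abs(lags[which.max(cors)]), 1)

  a <- sinusoid_erp(5)
  b <- sinusoid_erp(6.5)
  mix <- a; mix$data <- 2 * a$data - 3 * b$data
  lhs <- apply_filter(mix, theta_d)$data
  rhs <- 2 * apply_filter(a, theta_d)$data - 3 * apply_filter(b, theta_d)$data
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("zero input gives zero output and re-filtering is refused", {
  z <- flat_erp(rep(0, 1200))
  zf <- apply_filter(z, delta_d)
  expect_true(all(zf$data == 0))
  expect_equal(zf$band, "delta")
  expect_error(apply_filter(zf, theta_d), "re-filter")
})

test_that("baseline correction matches manual arithmetic and is idempotent", {
  # srate 1000 Hz puts one sample per ms; baseline [-2, 0) covers samples
  # at -2 and -1 ms
  e <- flat_erp(matrix(c(4, 6, 10, 20, 30), nrow = 1), srate = 1000, t0 = -2)
  b <- baseline_correct(e, c(-2, 0))
  expect_equal(b$data[1, ], c(4, 6, 10, 20, 30) - 5)
  expect_equal(baseline_correct(b, c(-2, 0))$data, b$data)

  const <- flat_erp(rep(7, 200), srate = 256, t0 = -400)
  expect_true(all(abs(baseline_correct(const)$data) < 1e-12))
})

test_that("baseline correction of epochs removes each trial's own offset", {
  mont <- montage(c("a", "b"))
  dat <- array(rnorm(3 * 2 * 50), dim = c(3, 2, 50))
  dat[2, , ] <- dat[2, , ] + 100
  ep <- epoch_set("s", dat, rep("positive", 3), 100, -250, mont)
  bc <- baseline_correct(ep, c(-250, 0))
  for (tr in 1:3) for (ch in 1:2)
    expect_equal(mean(bc$data[tr, ch, 1:25]), 0, tolerance = 1e-12)
})

test_that("condition averaging recovers the trial mean and enforces the trial minimum", {
  mont <- montage("only")
  dat <- array(0, dim = c(10, 1, 30))
  for (i in 1:10) dat[i, 1, ] <- i
  ep <- epoch_set("s", dat, rep(c("positive", "negative"), each = 5),
                  100, 0, mont)
  avg <- average_by_condition(ep)
  expect_equal(avg$positive$data[1, ], rep(3, 30))   # mean of 1..5
  expect_equal(avg$negative$data[1, ], rep(8, 30))   # mean of 6..10
  expect_equal(avg$positive$band, "broadband")

  ep4 <- epoch_set("s", dat[1:9, , , drop = FALSE],
                   rep(c("positive", "negative"), c(4, 5)), 100, 0, mont)
  expect_error(average_by_condition(ep4), class = "erpcsp_excluded")
})

test_that("window extraction follows the documented sample-index rule", {
  # 256 Hz, t0 = -1000 ms: [200, 300) ms -> zero-based samples 307..332
  e <- flat_erp(seq_len(871), srate = 256, t0 = -1000)
  w <- extract_window(e, c(200, 300))
  expect_equal(ncol(w), 26)
  expect_equal(w[1, ], as.numeric(308:333))  # R's one-based columns
  full <- extract_window(e, c(-1000, 1000 * 871 / 256 - 1000))
  expect_equal(ncol(full), 871)
  expect_error(extract_window(e, c(300, 300)), "start < end")
  expect_error(extract_window(e, c(2300, 2500)), "outside")
})

test_that("the FCz mean-amplitude feature matches closed forms", {
  mont <- subset_montage(c("Fz", "FCz", "Cz"))
  n <- 282
  const <- subject_erp("s", "positive", "broadband",
                       matrix(2, 3, n), 256, -400, mont)
  expect_equal(erp_amplitude(const), 2)
  # linear ramp: mean over the window equals the ramp at the window midpoint
  ramp <- matrix(rep(seq_len(n), each = 3), 3, n)
  re <- subject_erp("s", "positive", "broadband", ramp, 256, -400, mont)
  w <- extract_window(re, c(200, 300))
  expect_equal(erp_amplitude(re), (w[2, 1] + w[2, ncol(w)]) / 2)
  # 3-sample toy at 1000 Hz against hand arithmetic
  toy <- subject_erp("s", "positive", "broadband",
                     matrix(c(1, 2, 4, 8, 16), 1, 5,
                            dimnames = NULL), 1000, 0, montage("FCz"))
  expect_equal(erp_amplitude(toy, window = c(1, 4)), (2 + 4 + 8) / 3)
  expect_error(erp_amplitude(const, channel = "Oz"), "not in montage")
})

test_that("the filter audit table reports both designs", {
  tab <- describe_filters(256)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$f6_db_hz, c(4, 3, 8.5), tolerance = 0.02)
  expect_true(all(tab$stopband_attenuation_db >= 52))
})
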