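test_that("Welch PSD satisfies Parseval and locates sinusoid peaks", {
  fs <- 100
  set.seed(31)
  x <- rnorm(1000)
  spec <- welch_psd(x, fs)
  expect_equal(sum(spec$psd) * spec$df, var(x), tolerance = 0.05)
  # white noise: one-sided density ~ 2 sigma^2 / fs in the tremor band
  ib <- spec$freqs >= 2 & spec$freqs <= 10
  expect_equal(mean(spec$psd[ib]), 2 / fs, tolerance = 0.2)

  s5 <- welch_psd(make_sine(5, fs, 3), fs)
  expect_equal(s5$freqs[which.max(s5$psd)], 5, tolerance = s5$df)

  z <- welch_psd(numeric(300), fs)
  expect_true(all(z$psd == 0))

  expect_error(welch_psd(rnorm(100), fs), "below minimum window")
})

test_that("tremor peak search is restricted to 2-10 Hz and ties go low", {
  fs <- 100
  # larger 1 Hz component plus weaker 6 Hz: the in-band 6 Hz peak wins
  x <- make_sine(1, fs, 5, amp = 2) + make_sine(6, fs, 5, amp = 1)
  spec <- welch_psd(x, fs)
  expect_equal(locate_tremor_peak(spec), 6, tolerance = 2 * spec$df)

  tie <- manual_spectrum(seq(0, 12, 0.25), rep(0, 49))
  tie$psd[tie$freqs %in% c(4, 7)] <- 1
  expect_equal(locate_tremor_peak(tie), 4)

  zero <- manual_spectrum(seq(0, 12, 0.25), rep(0, 49))
  expect_error(locate_tremor_peak(zero), "no peak")
})

test_that("ATA band clamps to the analysed 2-10 Hz range", {
  expect_equal(ata_band(5), c(4, 6))
  expect_equal(ata_band(2.3), c(2, 3.3))
  expect_equal(ata_band(9.6), c(8.6, 10))
})

test_that("ATA returns peak-to-peak amplitude of a sinusoid and 0 for silence", {
  spec <- tremor_spectrum(make_sine(5, 100, 3), 100)
  expect_equal(ata(spec), 2, tolerance = 0.1)

  spec7 <- tremor_spectrum(make_sine(7, 100, 3, amp = 0.5), 100)
  expect_equal(ata(spec7), 1, tolerance = 0.1)

  silent <- manual_spectrum(seq(0, 12, 0.05), rep(0, 241), f_t = 5)
  expect_equal(ata(silent), 0)
})

test_that("rejection heuristics behave as the rules dictate on crafted spectra", {
  # rule 1: short window
  spec <- tremor_spectrum(make_sine(5, 100, 3), 100)
  r1 <- reject_estimate(spec, duration_s = 1.0)
  expect_false(r1$accepted)
  expect_true("short_window" %in% r1$reasons)
  expect_false(r1$duration_ok)

  # strong single peak over a gently rippling floor: accepted
  f <- seq(0, 12, 0.05)
  floorp <- 1 + 0.05 * sin(2 * pi * f / 0.8)
  peak <- 9 * exp(-((f - 6) / 0.25)^2)
  rs <- reject_estimate(manual_spectrum(f, floorp + peak, f_t = 6), 3)
  expect_true(rs$accepted)
  expect_length(rs$reasons, 0)

  # rule 2: tremor band mean below the comparison-band median
  # a narrow spike flanked by deep minima, comparison band oscillating ~1
  fg <- seq(0, 12, 0.1)
  ps2 <- ifelse(seq_along(fg) %% 2 == 0, 1.05, 0.95)
  i6 <- which(abs(fg - 6) < 1e-9)
  ps2[i6] <- 1.2; ps2[i6 + c(-1, 1)] <- 0.05
  dip <- manual_spectrum(fg, ps2)
  dip$f_t <- locate_tremor_peak(dip)
  r2 <- reject_estimate(dip, 3)
  expect_false(r2$accepted)
  expect_true("low_band_power" %in% r2$reasons)
  expect_lt(mean(dip$psd[r2$f_tb]), r2$p50_cb)

  # rule 3: peak range indistinct from comparison-band fluctuation
  # sawtooth floor with swings of 0.5; the 1.9 peak only rises 0.9 above its
  # neighbouring minima, less than twice the 70th-percentile swing
  ps3 <- ifelse(seq_along(fg) %% 2 == 0, 1.5, 1)
  i8 <- which(abs(fg - 8) < 1e-9)
  ps3[i8] <- 1.9; ps3[i8 + c(-1, 1)] <- 1
  wob <- manual_spectrum(fg, ps3)
  wob$f_t <- locate_tremor_peak(wob)
  r3 <- reject_estimate(wob, 3)
  expect_false(r3$accepted)
  expect_true("flat_peak_p70" %in% r3$reasons)
})

test_that("rejection report partitions the 2-10 Hz band", {
  spec <- tremor_spectrum(make_sine(5, 100, 3) + 0.1 * rnorm(300), 100)
  r <- reject_estimate(spec, 3)
  ib <- which(spec$freqs >= 2 - 1e-9 & spec$freqs <= 10 + 1e-9)
  expect_setequal(c(r$f_tb, r$f_cb), ib)
  expect_length(intersect(r$f_tb, r$f_cb), 0)
  expect_gte(r$delta_tb, 0)
  expect_true(all(r$delta_cb >= 0))
})

test_that("instance amplitude averages log-ATA over accepted repetitions", {
  fs <- 100
  # three identical repetitions: log_ata = log(ATA of one)
  seg <- make_sine(5, fs, 3)
  est <- instance_amplitude(list(seg, seg, seg), fs, parameter_id = "wrist")
  expect_equal(est$n_reps_used, 3)
  expect_equal(est$log_ata, log(2), tolerance = 0.05)
  expect_equal(est$f_t_mean, 5, tolerance = 0.1)
  expect_equal(est$parameter_id, "wrist")

  # amplitudes e/2 and e^3/2 -> ATA = e and e^3 -> mean log = 2
  segs <- list(make_sine(5, fs, 3, amp = exp(1) / 2),
               make_sine(5, fs, 3, amp = exp(3) / 2))
  est2 <- instance_amplitude(segs, fs)
  expect_equal(est2$log_ata, 2, tolerance = 0.05)

  # a short repetition is excluded but does not void the instance
  est3 <- instance_amplitude(list(seg, make_sine(5, fs, 1)), fs)
  expect_equal(est3$n_reps_used, 1)
  expect_false(est3$rejection_reports[[2]]$accepted)

  # all repetitions rejected -> null
  est4 <- instance_amplitude(list(make_sine(5, fs, 1), make_sine(5, fs, 0.5)), fs)
  expect_true(is.na(est4$log_ata))
  expect_equal(est4$n_reps_used, 0)
})

test_that("ATA is linear in amplitude and stable across duration and rate", {
  base <- ata(tremor_spectrum(make_sine(5, 100, 3), 100))
  for (k in c(0.1, 10)) {
    a <- ata(tremor_spectrum(make_sine(5, 100, 3, amp = k), 100))
    expect_equal(a / base, k, tolerance = 0.02)
  }
  for (fs in c(50, 200)) for (dur in c(1.5, 10)) {
    a <- ata(tremor_spectrum(make_sine(5, fs, dur), fs))
    expect_equal(a, 2, tolerance = 0.1)
  }
})
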