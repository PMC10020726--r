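test_that("synthesized pulses are deterministic, one cycle long, validated", {
  w1 <- synthesize_pulse(8, 70, seed = 5)
  w2 <- synthesize_pulse(8, 70, seed = 5)
  expect_identical(w1$samples, w2$samples)
  expect_false(identical(w1$samples, synthesize_pulse(8, 70, seed = 6)$samples))

  w66 <- synthesize_pulse(8, 66)
  expect_length(w66$samples, round(500 * 60 / 66))  # 455
  for (hr in c(66, 74, 86))
    expect_length(synthesize_pulse(10, hr)$samples, round(500 * 60 / hr))

  bp <- synthesize_pulse(8, 70, modality = "BP")
  expect_true(all(bp$samples > 0))
  expect_true(all(is.finite(bp$samples)))

  expect_error(synthesize_pulse(2, 70), "cf_pwv")
  expect_error(synthesize_pulse(25, 70), "cf_pwv")
  expect_error(synthesize_pulse(8, 30), "heart_rate")
  expect_error(synthesize_pulse(8, 130), "heart_rate")
})

test_that("reflected-wave arrival moves earlier as cf-PWV rises", {
  # brute-force peak search over the physiological cf-PWV range
  for (mod in c("PPG", "BP")) for (seed in c(3, 9)) {
    idx <- vapply(seq(5, 14, by = 1), function(cf)
      secondary_peak_index(
        synthesize_pulse(cf, 70, modality = mod, seed = seed)$samples),
      integer(1))
    expect_false(anyNA(idx))
    expect_true(all(diff(idx) < 0),
                info = sprintf("%s seed %d: %s", mod, seed,
                               paste(idx, collapse = " ")))
  }
  # stiff vs compliant contrast: cf 12 arrives strictly before cf 6
  p6 <- secondary_peak_index(synthesize_pulse(6, 70, seed = 1)$samples)
  p12 <- secondary_peak_index(synthesize_pulse(12, 70, seed = 1)$samples)
  expect_lt(p12, p6)
})

test_that("cohorts have equal groups, age-increasing cf-PWV, seeded draws", {
  cg <- generate_cohort(n_groups = 4, n_per_group = 25, seed = 2)
  expect_equal(nrow(cg$cohort), 100)
  expect_equal(as.vector(table(cg$cohort$age_group)), rep(25, 4))
  gm <- tapply(cg$cohort$cf_pwv_true, cg$cohort$age_group, mean)
  expect_true(all(diff(gm) > 0))
  expect_true(all(cg$cohort$cf_pwv_true >= 4 & cg$cohort$cf_pwv_true <= 16))

  one <- generate_cohort(n_groups = 1, n_per_group = 1, seed = 2)
  expect_equal(nrow(one$cohort), 1)

  cg2 <- generate_cohort(n_groups = 4, n_per_group = 25, seed = 3)
  expect_false(identical(cg$cohort$cf_pwv_true, cg2$cohort$cf_pwv_true))
  expect_identical(cg$cohort$age_group, cg2$cohort$age_group)
  # same seed reproduces waveforms exactly
  cg1b <- generate_cohort(n_groups = 4, n_per_group = 25, seed = 2)
  expect_identical(cg$waves[[7]]$samples, cg1b$waves[[7]]$samples)
})

test_that("noise injection hits the requested SNR on the mean-removed signal", {
  long <- pulse_wave(80 + 40 * sin(2 * pi * 1.2 * (0:9999) / 500),
                     fs = 500, modality = "BP")
  for (snr in c(20, 10, 5)) {
    noisy <- add_noise_snr(long, snr, seed = 4)
    ps <- mean((long$samples - mean(long$samples))^2)
    pn <- mean((noisy$samples - long$samples)^2)
    expect_lt(abs(10 * log10(ps / pn) - snr), 0.5)
    expect_equal(noisy$meta$snr_db, snr)
  }
  clean <- add_noise_snr(long, Inf)
  expect_identical(clean$samples, long$samples)
  expect_equal(default_noise_levels("BP"), c(20, 10, 5))
  expect_equal(default_noise_levels("PPG"), c(65, 45, 30))
})

test_that("cohort CSV export round-trips and bad files are reported", {
  cg <- tiny_cohort(n_per_group = 3, n_groups = 2, seed = 8)
  man <- tempfile(fileext = ".csv"); wav <- tempfile(fileext = ".csv")
  write_database_csv(cg, man, wav)
  back <- read_database_csv(man, wav)
  expect_equal(nrow(back$cohort), nrow(cg$cohort))
  expect_equal(back$cohort$cf_pwv_true, cg$cohort$cf_pwv_true)
  for (i in seq_along(cg$waves))
    expect_equal(back$waves[[i]]$samples, cg$waves[[i]]$samples)

  m2 <- read.csv(man)
  m2$cf_pwv <- NULL
  man2 <- tempfile(fileext = ".csv")
  write.csv(m2, man2, row.names = FALSE)
  expect_error(read_database_csv(man2, wav), "missing column")

  w2 <- read.csv(wav, check.names = FALSE)
  w2[2, 3] <- "oops"
  w2[2, -(1:2)] <- NA
  wav2 <- tempfile(fileext = ".csv")
  write.csv(w2, wav2, row.names = FALSE)
  expect_error(read_database_csv(man, wav2), "subject")
})
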