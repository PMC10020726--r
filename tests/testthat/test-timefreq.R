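test_that("spectrograms are square, bounded, finite, and deterministic", {
  w <- synthesize_pulse(9, 72, seed = 2)
  for (sz in c(20, 50)) {
    s <- compute_spectrogram(w, spectrogram_config(out_size = sz))
    expect_equal(dim(s$pixels), c(sz, sz))
    expect_true(all(is.finite(s$pixels)))
    expect_gte(min(s$pixels), 0)
    expect_lte(max(s$pixels), 1)
  }
  s1 <- compute_spectrogram(w, spectrogram_config(out_size = 30))
  s2 <- compute_spectrogram(w, spectrogram_config(out_size = 30))
  expect_identical(s1$pixels, s2$pixels)

  # kaiser window path
  kc <- spectrogram_config(window_type = "kaiser", kaiser_alpha = 3,
                           overlap_pct = 61, out_size = 20)
  sk <- compute_spectrogram(w, kc)
  expect_true(all(is.finite(sk$pixels)))

  # zero signal degenerates to an all-zero image
  z <- pulse_wave(rep(0, 400), fs = 500)
  expect_true(all(compute_spectrogram(z, spectrogram_config(out_size = 20))$pixels == 0))

  # a window longer than half the signal is refused
  short <- pulse_wave(rnorm(40) + 10, fs = 500)
  expect_error(compute_spectrogram(short, spectrogram_config(window_frac = 0.9)),
               "window")
})

test_that("a pure sinusoid concentrates every time bin at its frequency", {
  f0 <- 40
  w <- pulse_wave(sin(2 * pi * f0 * (0:999) / 500), fs = 500)
  s <- compute_spectrogram(w, spectrogram_config(out_size = 20))
  expected_bin <- which.min(abs(s$freq_axis_hz - f0))
  expect_true(all(apply(s$stft, 2, which.max) == expected_bin))
})

test_that("quality coefficients follow the coefficient-of-variation definition", {
  const <- matrix(5, 10, 10)
  q <- quality_coefficients(const)
  expect_equal(q$Qf, 0)
  expect_equal(q$Qt, 0)
  expect_equal(q$Qtf, 0)

  for (seed in 1:3) {
    m <- rand_image(9, seed, lo = 0.1, hi = 2)
    q <- quality_coefficients(m)
    expect_equal(q$Qtf, q$Qf * q$Qt)
    # scale invariance of a std/mean ratio
    q3 <- quality_coefficients(3.7 * m)
    expect_equal(q3$Qf, q$Qf, tolerance = 1e-12)
    expect_equal(q3$Qt, q$Qt, tolerance = 1e-12)
  }

  # hand computation with population std: row (1,3) has sd 1, mean 2;
  # row (2,2) contributes 0
  m2 <- rbind(c(1, 3), c(2, 2))
  q2 <- quality_coefficients(m2)
  expect_equal(q2$Qf, mean(c(1 / 2, 0)))
  # column cvs: (1,2) -> 0.5/1.5, (3,2) -> 0.5/2.5
  expect_equal(q2$Qt, mean(c(0.5 / 1.5, 0.5 / 2.5)))

  # an all-zero row contributes 0, not NaN
  withzero <- rbind(c(0, 0), c(1, 3))
  expect_equal(quality_coefficients(withzero)$Qf, mean(c(0, 1 / 2)))
})

test_that("parameter tuning ranks by mean Qtf with an independent recount", {
  cg <- tiny_cohort(n_per_group = 2, n_groups = 2, seed = 4)
  waves <- cg$waves
  cfgs <- list(spectrogram_config(out_size = 20),
               spectrogram_config(out_size = 50),
               spectrogram_config(window_type = "kaiser", kaiser_alpha = 0.5,
                                  out_size = 20))
  rk <- tune_spectrogram_params(waves, cfgs)
  expect_equal(rk$rank, 1:3)

  # brute-force recomputation of the mean Qtf ordering
  mean_qtf <- vapply(cfgs, function(cfg)
    mean(vapply(waves, function(w)
      quality_coefficients(compute_spectrogram(w, cfg))$Qtf, numeric(1))),
    numeric(1))
  expect_equal(rk$cfg_index, order(-mean_qtf))
  expect_equal(rk$mean_Qtf, sort(mean_qtf, decreasing = TRUE))

  one <- tune_spectrogram_params(waves[1], cfgs[1])
  expect_equal(one$rank, 1)
  expect_equal(one$cfg_index, 1)
})
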