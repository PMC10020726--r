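test_that("standardization uses train-only population statistics", {
  z <- standardize_fit_apply(cbind(x = c(1, 2, 3)))
  expect_equal(as.numeric(z$train),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(round(as.numeric(z$train), 4), c(-1.2247, 0, 1.2247))

  tr <- matrix(rnorm(60), 20, 3)
  te <- matrix(rnorm(30), 10, 3)
  z <- standardize_fit_apply(tr, te)
  expect_lt(max(abs(colMeans(z$train))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(z$train^2)) - 1)), 1e-10)
  # test rows transformed with train statistics, not their own
  expect_equal(z$other, sweep(sweep(te, 2, z$mu), 2, z$sigma, "/"))

  zc <- standardize_fit_apply(cbind(c(5, 5, 5)))
  expect_true(all(zc$train == 0))
})

test_that("cohort splits are exact, stratified, exhaustive, reproducible", {
  strata <- rep(1:6, each = 729)
  sp <- split_cohort(4374, train_frac = 0.7, seed = 3, strata = strata)
  expect_length(sp$train, 3061)  # floor(0.7 * 4374)
  expect_length(sp$test, 1313)
  expect_setequal(c(sp$train, sp$test), 1:4374)
  per_group <- table(strata[sp$train])
  expect_true(all(per_group %in% c(510, 511)))

  sp2 <- split_cohort(4374, train_frac = 0.7, seed = 3, strata = strata)
  expect_identical(sp, sp2)
  sp3 <- split_cohort(4374, train_frac = 0.7, seed = 4, strata = strata)
  expect_false(identical(sp$train, sp3$train))

  spu <- split_cohort(100, train_frac = 0.7, seed = 1)
  expect_length(spu$train, 70)
  expect_error(split_cohort(10, train_frac = 1.2), "train_frac")
})

test_that("R-squared and RMSE satisfy their defining identities", {
  y <- c(1, 2, 5)
  expect_equal(r_squared(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(rmse(y, c(1, 2, 3)), sqrt(4 / 3))
  expect_equal(r_squared(y, c(1, 2, 3)), 1 - 4 / sum((y - mean(y))^2))
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero-variance")
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("MLR recovers an exact linear target perfectly", {
  withr::with_seed(5, {
    x <- matrix(rnorm(200 * 4), 200, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- as.numeric(x %*% c(2, -1, 0.5, 3)) + 7
  })
  sp <- split_cohort(200, 0.7, seed = 1)
  z <- standardize_fit_apply(x[sp$train, ], x[sp$test, ])
  res <- train_eval(z$train, y[sp$train], z$other, y[sp$test],
                    model_spec("MLR", seed = 1))
  expect_gt(res$test_r2, 1 - 1e-6)
  expect_lt(res$test_rmse, 1e-5)
})

test_that("random search draws nest, so more budget never hurts CV score", {
  withr::with_seed(6, {
    x <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, paste0("f", 1:3)))
    y <- sin(x[, 1]) + 0.5 * x[, 2] + rnorm(80, 0, 0.2)
  })
  sp <- split_cohort(80, 0.7, seed = 2)
  z <- standardize_fit_apply(x[sp$train, ], x[sp$test, ])
  res <- lapply(c(1, 3, 6), function(b)
    train_eval(z$train, y[sp$train], z$other, y[sp$test],
               model_spec("SVR", budget = b, seed = 9)))
  best <- vapply(res, `[[`, numeric(1), "best_cv_r2")
  expect_true(all(diff(best) >= 0))
  # the smaller searches are prefixes of the larger one
  expect_equal(res[[1]]$search_report$cv_r2,
               res[[3]]$search_report$cv_r2[1])
  expect_equal(res[[2]]$search_report$cv_r2,
               res[[3]]$search_report$cv_r2[1:3])
})

test_that("nothing from the test rows leaks into the fitted models", {
  cg <- tiny_cohort(n_per_group = 10, n_groups = 3, seed = 12)
  tab <- featurize_cohort(cg$waves, "statistic",
                          spectrogram_config(out_size = 20))
  fit1 <- pwv_fit(tab, models = "RF", seed = 4)
  tab2 <- tab
  perm <- rev(fit1$split$test)
  tab2$cf_pwv[fit1$split$test] <- tab$cf_pwv[perm]  # permute test targets
  fit2 <- pwv_fit(tab2, models = "RF", seed = 4)
  expect_identical(fit1$test_pred$RF, fit2$test_pred$RF)
  expect_identical(fit1$selected_features, fit2$selected_features)
})
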