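make_table <- function(n = 30, p = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.3)
    list(x = x, y = y)
  })
}

test_that("the F-statistic agrees with R's linear-model F test", {
  for (seed in 1:4) {
    tb <- make_table(seed = seed)
    for (j in 1:3)
      expect_equal(f_statistic(tb$y, tb$x[, j]),
                   oracle_f_stat(tb$y, tb$x[, j]), tolerance = 1e-10)
  }
  expect_equal(f_statistic(rnorm(20), rep(1, 20)), 0)
})

test_that("FCQ scores reduce to relevance over mean absolute redundancy", {
  tb <- make_table(seed = 3)
  f <- tb$x[, 3]
  expect_equal(fcq_score(f, tb$y, NULL), f_statistic(tb$y, f))
  # sole selected feature identical to the candidate: denominator is 1
  expect_equal(fcq_score(f, tb$y, cbind(f)), f_statistic(tb$y, f))
  # |S| = 2 against a fully independent formula evaluation
  s <- tb$x[, 1:2]
  expected <- oracle_f_stat(tb$y, f) /
    mean(c(abs(cor(f, s[, 1])), abs(cor(f, s[, 2]))))
  expect_equal(fcq_score(f, tb$y, s), expected, tolerance = 1e-10)
  # correlation with a constant counts as zero redundancy
  expect_equal(fcq_score(f, tb$y, cbind(rep(2, length(f)))),
               f_statistic(tb$y, f) / 1e-12)
})

test_that("greedy ranking matches the exhaustive oracle and is scale-free", {
  for (seed in c(2, 5, 9)) {
    tb <- make_table(n = 40, p = 8, seed = seed)
    rk <- mrmr_rank(tb$x, tb$y)
    expect_setequal(rk$feature, colnames(tb$x))
    expect_identical(rk$feature, oracle_mrmr(tb$x, tb$y))
    # positive rescaling of features leaves the order unchanged
    scales <- withr::with_seed(seed, runif(ncol(tb$x), 0.1, 10))
    rk2 <- mrmr_rank(sweep(tb$x, 2, scales, "*"), tb$y)
    expect_identical(rk2$feature, rk$feature)
  }
})

test_that("an exact duplicate of the top feature is pushed behind novel ones", {
  withr::with_seed(4, {
    n <- 60
    f1 <- rnorm(n)
    f_indep <- rnorm(n)
    y <- f1 + 0.8 * f_indep + rnorm(n, 0, 0.5)
  })
  x <- cbind(a_top = f1, b_dup = f1, c_novel = f_indep)
  rk <- mrmr_rank(x, y)
  expect_equal(rk$feature[1], "a_top")
  expect_lt(which(rk$feature == "c_novel"), which(rk$feature == "b_dup"))
})

test_that("the feature-count sweep recovers a small informative subset", {
  tb <- withr::with_seed(8, {
    n <- 80
    sig <- matrix(rnorm(n * 3), n, 3)
    noise <- matrix(rnorm(n * 9), n, 9)
    x <- cbind(sig, noise)
    colnames(x) <- c(paste0("sig", 1:3), paste0("noise", 1:9))
    y <- sig %*% c(1, 0.8, 0.6) + rnorm(n, 0, 0.2)
    list(x = x, y = as.numeric(y))
  })
  ck <- choose_k(tb$x, tb$y, models = "MLR", k_grid = c(1, 2, 3, 5, 8, 12),
                 seed = 2)
  expect_lte(ck$k, 5)
  expect_true(all(paste0("sig", 1:3) %in%
                    ck$ranking$feature[seq_len(ck$k)]))
  one <- choose_k(tb$x, tb$y, models = "MLR", k_grid = 4, seed = 2)
  expect_equal(one$k, 4)
})
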