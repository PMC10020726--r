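#' Regression model specification
#'
#' One of five model kinds: random forest (`RF`), gradient boosting
#' (`GBR`), multilayer perceptron (`MLP`), multiple linear regression
#' (`MLR`) and support vector regression (`SVR`, radial kernel). `budget`
#' random-search draws from `search` are scored by cross-validated
#' R-squared; `budget = 1` with the default search space is equivalent to
#' fitting the library-default configuration.
#'
#' @param kind one of `"RF"`, `"GBR"`, `"MLP"`, `"MLR"`, `"SVR"`.
#' @param search named list of sampling functions `function(n)` returning
#'   `n` draws per hyperparameter; `NULL` uses [default_search_space()].
#' @param budget number of random-search draws (>= 1).
#' @param seed integer seed for the search draws and model initialisation.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(kind = c("RF", "GBR", "MLP", "MLR", "SVR"),
                       search = NULL, budget = 1L, seed = 1L) {
  kind <- match.arg(kind)
  if (budget < 1L) stopf("budget must be >= 1")
  if (is.null(search)) search <- default_search_space(kind)
  bad <- setdiff(names(search), names(default_search_space(kind, full = TRUE)))
  if (length(bad) > 0L)
    stopf("invalid hyperparameter(s) for %s: %s", kind,
          paste(bad, collapse = ", "))
  structure(list(kind = kind, search = search, budget = as.integer(budget),
                 seed = seed), class = "model_spec")
}

#' Default random-search spaces per model kind
#'
#' @param kind model kind; @param full internal, return the superset of
#'   valid hyperparameter names.
#' @return named list of sampler functions.
#' @export
default_search_space <- function(kind, full = FALSE) {
  runif_log <- function(lo, hi) function(n) exp(runif(n, log(lo), log(hi)))
  spaces <- list(
    RF = list(ntree = function(n) sample(seq(100L, 800L, by = 50L), n, TRUE),
              mtry_frac = function(n) runif(n, 0.2, 1),
              nodesize = function(n) sample(1:10, n, TRUE)),
    GBR = list(nrounds = function(n) sample(seq(50L, 400L, by = 25L), n, TRUE),
               eta = runif_log(0.01, 0.3),
               max_depth = function(n) sample(2:8, n, TRUE),
               subsample = function(n) runif(n, 0.5, 1)),
    MLP = list(size = function(n) sample(c(4L, 8L, 16L, 32L, 64L), n, TRUE),
               decay = runif_log(1e-5, 1e-1),
               maxit = function(n) sample(seq(200L, 800L, by = 100L), n, TRUE)),
    MLR = list(),
    SVR = list(cost = runif_log(0.1, 100),
               svr_gamma = runif_log(1e-4, 1),
               epsilon = function(n) runif(n, 0.01, 0.5))
  )
  if (full) return(spaces[[kind]])
  spaces[[kind]]
}

# library-default hyperparameters used when no draw overrides them
default_hyper <- function(kind, p) {
  switch(kind,
         RF = list(ntree = 500L, mtry_frac = 1 / 3, nodesize = 5L),
         GBR = list(nrounds = 100L, eta = 0.3, max_depth = 6L, subsample = 1),
         MLP = list(size = 16L, decay = 1e-3, maxit = 300L),
         MLR = list(),
         SVR = list(cost = 1, svr_gamma = 1 / max(p, 1L), epsilon = 0.1))
}

# Fit one model of the given kind on a standardized feature matrix.
fit_model <- function(kind, x, y, hyper, seed = 1L) {
  p <- ncol(x)
  hp <- utils::modifyList(default_hyper(kind, p), as.list(hyper))
  with_seed(seed, switch(
    kind,
    RF = randomForest::randomForest(
      x = x, y = y, ntree = as.integer(hp$ntree),
      mtry = max(1L, floor(hp$mtry_frac * p)),
      nodesize = as.integer(hp$nodesize)),
    GBR = xgboost::xgboost(
      x = x, y = y, nrounds = as.integer(hp$nrounds),
      learning_rate = hp$eta, max_depth = as.integer(hp$max_depth),
      subsample = hp$subsample, objective = "reg:squarederror",
      verbosity = 0L, nthreads = 1L),
    MLP = nnet::nnet(x = x, y = y, size = as.integer(hp$size), linout = TRUE,
                     decay = hp$decay, maxit = as.integer(hp$maxit),
                     trace = FALSE, MaxNWts = 50000L),
    MLR = lm(y ~ ., data = data.frame(y = y, x, check.names = FALSE)),
    SVR = e1071::svm(x = x, y = y, type = "eps-regression",
                     kernel = "radial", cost = hp$cost,
                     gamma = hp$svr_gamma, epsilon = hp$epsilon)
  ))
}

predict_model <- function(kind, fit, x) {
  as.numeric(switch(kind,
                    MLR = predict(fit, newdata = data.frame(x, check.names = FALSE)),
                    MLP = predict(fit, x),
                    predict(fit, x)))
}

#' Standardize features with train-only statistics
#'
#' z-scores every column using the mean and population standard deviation
#' of the training rows only; the same transform is applied unchanged to
#' any other table. Constant features get their sigma floored at `eps`
#' (so they transform to all zeros).
#'
#' @param train numeric matrix of training features.
#' @param other optional matrix to transform with the train statistics.
#' @param eps floor for sigma (default 1e-12).
#' @return list with `train`, `other` (or `NULL`), `mu`, `sigma`.
#' @export
standardize_fit_apply <- function(train, other = NULL, eps = 1e-12) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stopf("train must be nonempty")
  mu <- colMeans(train)
  sigma <- sqrt(colMeans(sweep(train, 2L, mu)^2))
  sigma <- pmax(sigma, eps)
  tr <- sweep(sweep(train, 2L, mu), 2L, sigma, "/")
  ot <- if (!is.null(other))
    sweep(sweep(as.matrix(other), 2L, mu), 2L, sigma, "/") else NULL
  list(train = tr, other = ot, mu = mu, sigma = sigma)
}

#' Split a cohort into train and test sets
#'
#' Reproducible 70/30-style split, by default stratified so every stratum
#' (age group) contributes proportionally. The training size is exactly
#' `floor(train_frac * n)`, apportioned across strata by largest
#' remainder (ties to earlier strata).
#'
#' @param n number of rows, or a data.frame whose rows are split.
#' @param train_frac fraction of rows for training, in (0, 1).
#' @param seed integer seed.
#' @param strata optional factor/vector of stratum labels (e.g. age
#'   group); `NULL` for an unstratified split.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(n, train_frac = 0.7, seed = 1L, strata = NULL) {
  if (is.data.frame(n)) {
    if (is.null(strata) && "age_group" %in% names(n)) strata <- n$age_group
    n <- nrow(n)
  }
  if (train_frac <= 0 || train_frac >= 1) stopf("train_frac must be in (0, 1)")
  target <- floor(train_frac * n)
  idx <- with_seed(substream_seed(seed, "split"), {
    if (is.null(strata)) {
      sample(n, target)
    } else {
      stopifnot(length(strata) == n)
      groups <- split(seq_len(n), strata)
      quota <- vapply(groups, length, integer(1L)) * train_frac
      base <- floor(quota)
      extra <- target - sum(base)
      if (extra > 0L) {
        give <- order(-(quota - base), seq_along(groups))[seq_len(extra)]
        base[give] <- base[give] + 1L
      }
      unlist(mapply(function(g, b) if (b > 0L) sample(g, b) else integer(0),
                    groups, base, SIMPLIFY = FALSE), use.names = FALSE)
    }
  })
  list(train = sort(idx), test = setdiff(seq_len(n), idx))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return scalar R-squared (can be negative for a bad model).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stopf("y_true and y_pred must have equal length >= 2")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stopf("R-squared is undefined for a zero-variance target")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return scalar RMSE in the units of the target (m/s for cf-PWV).
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stopf("y_true and y_pred must have equal length >= 2")
  sqrt(mean((y_true - y_pred)^2))
}

cv_fold_ids <- function(n, folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

# mean CV R-squared of one model kind / hyperparameter draw
cv_r2 <- function(x, y, kind, hyper, folds, seed) {
  r2 <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- fit_model(kind, x[tr, , drop = FALSE], y[tr], hyper, seed = seed)
    r_squared(y[!tr], predict_model(kind, fit, x[!tr, , drop = FALSE]))
  }, numeric(1L))
  mean(r2)
}

#' Train and evaluate one model with random-search tuning
#'
#' Draws `spec$budget` hyperparameter configurations (draw 1 is always
#' the library-default configuration; draws are a nested sequence, so a
#' larger budget can only improve the best cross-validated score), scores
#' each by mean `cv_folds`-fold cross-validated R-squared on the training
#' table, refits the best configuration on the full training table and
#' reports held-out R-squared and RMSE. Inputs are expected to be
#' standardized (see [standardize_fit_apply()]); nothing from the test
#' rows influences tuning or fitting.
#'
#' @param train_x,train_y standardized training features and target.
#' @param test_x,test_y standardized test features and target.
#' @param spec a [model_spec()].
#' @param cv_folds number of CV folds (default 5).
#' @return list with `fit`, `kind`, `best_hyper`, `best_cv_r2`,
#'   `test_r2`, `test_rmse`, `search_report`.
#' @export
train_eval <- function(train_x, train_y, test_x, test_y, spec,
                       cv_folds = 5L) {
  stopifnot(inherits(spec, "model_spec"))
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  draws <- draw_hyper(spec)
  folds <- cv_fold_ids(length(train_y), cv_folds,
                       substream_seed(spec$seed, "cv"))
  cv <- vapply(seq_along(draws), function(i) {
    tryCatch(cv_r2(train_x, train_y, spec$kind, draws[[i]], folds,
                   seed = substream_seed(spec$seed, "model") + i),
             error = function(e) -Inf)
  }, numeric(1L))
  best <- which.max(cv)
  fit <- fit_model(spec$kind, train_x, train_y, draws[[best]],
                   seed = substream_seed(spec$seed, "model") + best)
  pred <- predict_model(spec$kind, fit, test_x)
  list(fit = fit, kind = spec$kind, best_hyper = draws[[best]],
       best_cv_r2 = cv[best], test_r2 = r_squared(test_y, pred),
       test_rmse = rmse(test_y, pred),
       search_report = data.frame(draw = seq_along(draws), cv_r2 = cv))
}

# Nested sequence of hyperparameter draws: draw 1 = library defaults,
# draws 2..budget sampled from the search space under the model seed.
draw_hyper <- function(spec) {
  draws <- vector("list", spec$budget)
  draws[[1L]] <- list()  # defaults
  if (spec$budget > 1L) {
    # one full configuration per draw, so draw i is identical for every
    # budget >= i (the running-best CV score is then non-decreasing)
    rest <- with_seed(substream_seed(spec$seed, "search"),
                      lapply(2:spec$budget, function(i)
                        lapply(spec$search, function(fn) fn(1L))))
    draws[2:spec$budget] <- rest
  }
  draws
}
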