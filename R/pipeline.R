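meta_cols <- c("subject_id", "site", "modality", "age_group",
               "heart_rate_bpm", "snr_db", "cf_pwv")

#' Feature columns of a feature table
#'
#' @param table data.frame from [featurize_cohort()].
#' @return character vector of feature column names (metadata and target
#'   excluded).
#' @export
feature_columns <- function(table) setdiff(names(table), meta_cols)

#' Extract one feature family from a cohort of pulse waves
#'
#' Computes the square spectrogram of every wave and extracts the chosen
#' feature family: `"scsa"` (36 Schrodinger-spectrum features), `"energy"`
#' (102 Laws texture-energy features) or `"statistic"` (6 central-moment
#' features). Optional Gaussian noise at a fixed SNR is injected into the
#' time-domain signal before the spectrogram.
#'
#' @param waves list of [pulse_wave()] objects.
#' @param family one of `"scsa"`, `"energy"`, `"statistic"`.
#' @param cfg a [spectrogram_config()].
#' @param snr_db per-wave SNR in dB (`Inf` = no noise).
#' @param gamma gamma for the SCSA family; `NULL` selects it once by
#'   reconstruction SSIM on the first spectrogram of the cohort.
#' @param seed seed for the noise draws.
#' @return data.frame with metadata columns (`subject_id`, `site`,
#'   `modality`, `age_group`, `heart_rate_bpm`, `snr_db`), the feature
#'   columns, and the target column `cf_pwv`.
#' @export
featurize_cohort <- function(waves, family = c("scsa", "energy", "statistic"),
                             cfg = spectrogram_config(out_size = 50),
                             snr_db = Inf, gamma = NULL, seed = 1L) {
  family <- match.arg(family)
  if (length(waves) < 1L) stopf("no waves supplied")
  specs <- vector("list", length(waves))
  for (i in seq_along(waves)) {
    w <- waves[[i]]
    if (is.finite(snr_db)) w <- add_noise_snr(w, snr_db, seed = seed + i)
    specs[[i]] <- compute_spectrogram(w, cfg)
  }
  if (family == "scsa" && is.null(gamma))
    gamma <- select_gamma(specs[[1L]]$pixels)$gamma
  feats <- lapply(specs, function(s) {
    switch(family,
           scsa = scsa_features(s$pixels, gamma = gamma),
           energy = texture_features(s$pixels),
           statistic = moment_features(s$pixels))
  })
  fm <- do.call(rbind, feats)
  meta <- data.frame(
    subject_id = vapply(waves, function(w)
      if (is.null(w$meta$subject_id)) NA_character_ else w$meta$subject_id,
      character(1L)),
    site = vapply(waves, function(w) w$site, character(1L)),
    modality = vapply(waves, function(w) w$modality, character(1L)),
    age_group = vapply(waves, function(w)
      if (is.null(w$meta$age_group)) NA_integer_ else
        as.integer(w$meta$age_group), integer(1L)),
    heart_rate_bpm = vapply(waves, function(w)
      if (is.null(w$meta$heart_rate_bpm)) NA_real_ else
        w$meta$heart_rate_bpm, numeric(1L)),
    snr_db = snr_db)
  out <- cbind(meta, as.data.frame(fm),
               cf_pwv = vapply(waves, function(w)
                 if (is.null(w$meta$cf_pwv_true)) NA_real_ else
                   w$meta$cf_pwv_true, numeric(1L)))
  if (!is.null(gamma)) attr(out, "gamma") <- gamma
  rownames(out) <- NULL
  out
}

#' Fit cf-PWV regression models on a feature table
#'
#' The package's central fitting function. Splits the table into train
#' and test (stratified by age group when available), optionally ranks
#' features with MRMR-FCQ on the training rows only and keeps the top
#' `n_features`, standardizes with train-only statistics, trains every
#' requested model with seeded random-search tuning under 5-fold
#' cross-validation, and evaluates held-out R-squared and RMSE. No
#' information from the test rows influences selection, standardization
#' or tuning.
#'
#' @param table feature table from [featurize_cohort()], or any
#'   data.frame with feature columns and a `cf_pwv` target.
#' @param models character vector of model kinds (see [model_spec()]).
#' @param n_features keep this many MRMR-ranked features; `NULL` keeps
#'   all; `"auto"` chooses the count by [choose_k()] on the training rows.
#' @param budget random-search draws per model (1 = library defaults).
#' @param train_frac training fraction (default 0.7).
#' @param cv_folds CV folds for tuning (default 5).
#' @param seed root seed; the split, search, folds and model
#'   initialisations all derive named substreams from it.
#' @return object of class `pwv_fit`.
#' @examples
#' \donttest{
#' cg <- generate_cohort(n_groups = 2, n_per_group = 30, seed = 1)
#' tab <- featurize_cohort(cg$waves, "statistic",
#'                         spectrogram_config(out_size = 20))
#' fit <- pwv_fit(tab, models = "MLR", seed = 1)
#' print(fit)
#' }
#' @export
pwv_fit <- function(table, models = c("RF", "GBR", "MLP", "MLR", "SVR"),
                    n_features = NULL, budget = 1L, train_frac = 0.7,
                    cv_folds = 5L, seed = 1L) {
  models <- match.arg(models, c("RF", "GBR", "MLP", "MLR", "SVR"),
                      several.ok = TRUE)
  if (!"cf_pwv" %in% names(table)) stopf("table lacks a cf_pwv target column")
  fcols <- feature_columns(table)
  if (length(fcols) == 0L) stopf("table has no feature columns")
  y <- table$cf_pwv
  if (any(!is.finite(y))) stopf("cf_pwv target must be finite")
  x <- as.matrix(table[, fcols, drop = FALSE])
  strata <- if ("age_group" %in% names(table) &&
                !anyNA(table$age_group)) table$age_group else NULL
  sp <- split_cohort(nrow(x), train_frac, seed = seed, strata = strata)

  ranking <- NULL
  keep <- fcols
  if (identical(n_features, "auto")) {
    ck <- choose_k(x[sp$train, , drop = FALSE], y[sp$train],
                   models = models, seed = seed)
    ranking <- ck$ranking
    keep <- ranking$feature[seq_len(ck$k)]
  } else if (!is.null(n_features)) {
    ranking <- mrmr_rank(x[sp$train, , drop = FALSE], y[sp$train])
    keep <- ranking$feature[seq_len(min(n_features, length(fcols)))]
  }
  z <- standardize_fit_apply(x[sp$train, keep, drop = FALSE],
                             x[sp$test, keep, drop = FALSE])
  fits <- lapply(models, function(kind) {
    train_eval(z$train, y[sp$train], z$other, y[sp$test],
               model_spec(kind, budget = budget, seed = seed),
               cv_folds = cv_folds)
  })
  names(fits) <- models
  report <- data.frame(
    model = models,
    cv_r2 = vapply(fits, `[[`, numeric(1L), "best_cv_r2"),
    test_r2 = vapply(fits, `[[`, numeric(1L), "test_r2"),
    test_rmse = vapply(fits, `[[`, numeric(1L), "test_rmse"),
    k_features = length(keep), seed = seed, row.names = NULL)
  best <- models[which.max(report$cv_r2)]
  structure(list(fits = fits, report = report, best_model = best,
                 selected_features = keep, ranking = ranking,
                 mu = z$mu, sigma = z$sigma, split = sp,
                 y = y, seed = seed,
                 test_pred = stats::setNames(
                   lapply(fits, function(f)
                     predict_model(f$kind, f$fit, z$other)), models)),
            class = "pwv_fit")
}

#' @export
print.pwv_fit <- function(x, ...) {
  cat(sprintf("<pwv_fit> %d features, %d train / %d test rows\n",
              length(x$selected_features), length(x$split$train),
              length(x$split$test)))
  df <- x$report
  df$cv_r2 <- round(df$cv_r2, 3)
  df$test_r2 <- round(df$test_r2, 3)
  df$test_rmse <- round(df$test_rmse, 3)
  print(df[, c("model", "cv_r2", "test_r2", "test_rmse")], row.names = FALSE)
  cat(sprintf("best model (by CV R2): %s\n", x$best_model))
  invisible(x)
}

#' @export
summary.pwv_fit <- function(object, ...) {
  best <- object$fits[[object$best_model]]
  cat(sprintf("cf-PWV regression on %d features (seed %d)\n",
              length(object$selected_features), object$seed))
  print.pwv_fit(object)
  cat(sprintf("held-out best: R2 = %.3f, RMSE = %.3f m/s (%s)\n",
              best$test_r2, best$test_rmse, object$best_model))
  if (!is.null(object$ranking))
    cat("top features:",
        paste(head(object$selected_features, 8L), collapse = ", "), "\n")
  invisible(object)
}

#' Predict cf-PWV for new feature rows
#'
#' @param object a [pwv_fit()].
#' @param newdata feature table or matrix containing the selected feature
#'   columns (raw scale; the stored train standardization is applied).
#' @param model model kind to predict with (default: the best by CV
#'   R-squared).
#' @param ... unused.
#' @return numeric vector of cf-PWV predictions in m/s.
#' @export
predict.pwv_fit <- function(object, newdata, model = NULL, ...) {
  kind <- if (is.null(model)) object$best_model else
    match.arg(model, names(object$fits))
  xm <- as.matrix(as.data.frame(newdata)[, object$selected_features,
                                         drop = FALSE])
  z <- sweep(sweep(xm, 2L, object$mu), 2L, object$sigma, "/")
  predict_model(kind, object$fits[[kind]]$fit, z)
}

#' @export
plot.pwv_fit <- function(x, model = NULL, ...) {
  kind <- if (is.null(model)) x$best_model else match.arg(model, names(x$fits))
  yt <- x$y[x$split$test]
  yp <- x$test_pred[[kind]]
  plot(yt, yp, xlab = "true cf-PWV (m/s)", ylab = "predicted cf-PWV (m/s)",
       main = sprintf("%s: R2 = %.3f", kind, r_squared(yt, yp)), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
coef.pwv_fit <- function(object, ...) {
  if (!"MLR" %in% names(object$fits))
    stopf("coefficients are only defined for the MLR model")
  coef(object$fits$MLR$fit)
}

#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Defaults mirror the
#' study conditions: 6 equal age groups, one cycle per subject at 500 Hz,
#' Hamming window with 0% overlap, and modality-specific noise levels.
#'
#' @param cohort `"synthetic"` or `"csv"`.
#' @param n_groups,n_per_group synthetic cohort shape.
#' @param manifest_path,waves_path CSV paths when `cohort = "csv"`.
#' @param modality,site one modality and site per run.
#' @param family feature family: `"scsa"`, `"energy"` or `"statistic"`.
#' @param noise_db vector of SNR levels in dB (`Inf` = noise-free run);
#'   `NULL` means noise-free only.
#' @param out_size spectrogram side in pixels.
#' @param models model kinds to train.
#' @param n_features `NULL`, a count, or `"auto"` (see [pwv_fit()]).
#' @param budget random-search draws.
#' @param seed root seed.
#' @param out_dir optional directory for CSV artifacts (`NULL` = no
#'   files written).
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = c("synthetic", "csv"), n_groups = 6L,
                       n_per_group = 729L, manifest_path = NULL,
                       waves_path = NULL, modality = "PPG", site = "radial",
                       family = c("scsa", "energy", "statistic"),
                       noise_db = NULL, out_size = 50L,
                       models = c("RF", "GBR", "MLP", "MLR", "SVR"),
                       n_features = NULL, budget = 1L, seed = 1L,
                       out_dir = NULL) {
  cohort <- match.arg(cohort)
  family <- match.arg(family)
  modality <- match.arg(modality, c("PPG", "BP"))
  site <- match.arg(site, c("radial", "digital", "brachial"))
  if (cohort == "csv" && (is.null(manifest_path) || is.null(waves_path)))
    stopf("csv cohort needs manifest_path and waves_path")
  if (is.null(noise_db)) noise_db <- Inf
  structure(list(cohort = cohort, n_groups = n_groups,
                 n_per_group = n_per_group, manifest_path = manifest_path,
                 waves_path = waves_path, modality = modality, site = site,
                 family = family, noise_db = noise_db, out_size = out_size,
                 models = models, n_features = n_features, budget = budget,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Load a [run_config()] from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()]
#'   arguments.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$noise_db))
    vals$noise_db <- vapply(vals$noise_db,
                            function(v) if (identical(v, "none")) Inf
                            else as.numeric(v), numeric(1L))
  do.call(run_config, vals)
}

#' Run the full cf-PWV estimation pipeline
#'
#' Cohort generation (or CSV loading), per-noise-level time-domain noise
#' injection, spectrogram computation, feature extraction for one family,
#' optional MRMR selection, model training and evaluation. One
#' [pwv_fit()] is produced per noise level; results are collected into a
#' single evaluation report and, when `out_dir` is set, written as CSV
#' (`features_<snr>.csv`, `selection_report.csv`, `eval_report.csv`).
#' Re-running with the same configuration and seed reproduces the same
#' outputs.
#'
#' @param cfg a [run_config()].
#' @return object of class `pwv_run`: list with `report` (data.frame of
#'   modality, site, family, noise_db, model, r2, rmse, k_features,
#'   seed), `fits` (one `pwv_fit` per noise level), `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    out
  }
  cg <- stage("cohort", {
    if (cfg$cohort == "synthetic")
      generate_cohort(cfg$n_groups, cfg$n_per_group,
                      modalities = cfg$modality, sites = cfg$site,
                      seed = cfg$seed)
    else read_database_csv(cfg$manifest_path, cfg$waves_path)
  })
  scfg <- spectrogram_config(out_size = cfg$out_size)
  fits <- list()
  rows <- list()
  tables <- list()
  for (snr in cfg$noise_db) {
    lab <- if (is.finite(snr)) sprintf("snr%g", snr) else "clean"
    tab <- stage(paste0("featurize-", lab),
                 featurize_cohort(cg$waves, cfg$family, scfg, snr_db = snr,
                                  seed = cfg$seed))
    fit <- stage(paste0("fit-", lab),
                 pwv_fit(tab, models = cfg$models,
                         n_features = cfg$n_features, budget = cfg$budget,
                         seed = cfg$seed))
    tables[[lab]] <- tab
    fits[[lab]] <- fit
    rep <- fit$report
    rows[[lab]] <- data.frame(modality = cfg$modality, site = cfg$site,
                              family = cfg$family, noise_db = snr,
                              model = rep$model, r2 = rep$test_r2,
                              rmse = rep$test_rmse,
                              k_features = rep$k_features, seed = cfg$seed)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (lab in names(tables))
      write.csv(tables[[lab]],
                file.path(cfg$out_dir, sprintf("features_%s.csv", lab)),
                row.names = FALSE)
    write.csv(report, file.path(cfg$out_dir, "eval_report.csv"),
              row.names = FALSE)
    rk <- fits[[1L]]$ranking
    if (!is.null(rk))
      write.csv(rk, file.path(cfg$out_dir, "selection_report.csv"),
                row.names = FALSE)
  }
  structure(list(report = report, fits = fits, config = cfg),
            class = "pwv_run")
}

#' @export
print.pwv_run <- function(x, ...) {
  cat(sprintf("<pwv_run> %s %s, family=%s, %d noise level(s)\n",
              x$config$modality, x$config$site, x$config$family,
              length(x$fits)))
  df <- x$report
  df$r2 <- round(df$r2, 3); df$rmse <- round(df$rmse, 3)
  print(df[, c("noise_db", "model", "r2", "rmse")], row.names = FALSE)
  invisible(x)
}
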