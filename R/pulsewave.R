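#' Single-cycle pulse wave object
#'
#' Container for one cardiac cycle of a peripheral pulse wave together with
#' its sampling rate and subject metadata. `samples` covers exactly one
#' cycle, i.e. `length(samples) == round(fs * 60 / heart_rate_bpm)`.
#'
#' @param samples numeric vector, one cardiac cycle (finite; strictly
#'   positive for BP, which is on an mmHg-like scale).
#' @param fs sampling rate in Hz (default 500).
#' @param site measurement site, one of `"radial"`, `"digital"`, `"brachial"`.
#' @param modality `"PPG"` or `"BP"`.
#' @param meta named list of metadata (`age_group`, `heart_rate_bpm`,
#'   `cf_pwv_true`, `subject_id`, optionally `snr_db`).
#' @return An object of class `pulse_wave`.
#' @export
pulse_wave <- function(samples, fs = 500, site = "radial", modality = "PPG",
                       meta = list()) {
  site <- match.arg(site, c("radial", "digital", "brachial"))
  modality <- match.arg(modality, c("PPG", "BP"))
  if (!is.numeric(samples) || length(samples) < 2L)
    stopf("samples must be a numeric vector with at least 2 points")
  if (!all(is.finite(samples))) stopf("samples must all be finite")
  if (modality == "BP" && any(samples <= 0))
    stopf("BP samples must be strictly positive")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("fs must be > 0")
  structure(list(samples = as.numeric(samples), fs = fs, site = site,
                 modality = modality, meta = meta),
            class = "pulse_wave")
}

#' @export
print.pulse_wave <- function(x, ...) {
  cat(sprintf("<pulse_wave> %s @ %s, %d samples @ %g Hz", x$modality,
              x$site, length(x$samples), x$fs))
  if (!is.null(x$meta$cf_pwv_true))
    cat(sprintf(", cf-PWV %.2f m/s", x$meta$cf_pwv_true))
  if (!is.null(x$meta$snr_db) && is.finite(x$meta$snr_db))
    cat(sprintf(", SNR %g dB", x$meta$snr_db))
  cat("\n")
  invisible(x)
}

#' Synthesize one cardiac cycle of a peripheral pulse wave
#'
#' Generates a single-cycle waveform whose morphology is monotonically
#' shaped by a latent carotid-to-femoral pulse wave velocity. The pulse is
#' modelled as a sum of Gaussian lobes: a systolic lobe, a reflected lobe
#' whose delay after the systolic peak is `2 * d_eff / cf_pwv` seconds
#' (round-trip travel over an effective reflection path of length `d_eff`)
#' and whose relative amplitude grows with `cf_pwv` (stiffer arteries
#' reflect earlier and stronger), and a broad low-amplitude diastolic lobe.
#' PPG waves are zero-baseline and unit-normalized; BP waves sit on an
#' 80 mmHg-like diastolic offset with ~40 units of pulse pressure.
#'
#' @param cf_pwv latent cf-PWV in m/s, in `[3, 20]`.
#' @param heart_rate heart rate in bpm, in `[40, 120]`.
#' @param modality `"PPG"` or `"BP"`.
#' @param site `"radial"`, `"digital"` or `"brachial"` (adds a small
#'   site-specific extra transit delay to the reflected lobe).
#' @param seed integer seed; the waveform is a deterministic function of
#'   (arguments, seed). The seed drives small subject-specific jitter of
#'   lobe timings and widths.
#' @param fs sampling rate in Hz.
#' @param d_eff effective reflection path length in metres (default 0.5).
#' @return A [pulse_wave()].
#' @examples
#' w <- synthesize_pulse(cf_pwv = 8, heart_rate = 70, seed = 1)
#' length(w$samples) == round(500 * 60 / 70)
#' @export
synthesize_pulse <- function(cf_pwv, heart_rate, modality = "PPG",
                             site = "radial", seed = 1L, fs = 500,
                             d_eff = 0.5) {
  if (!is.numeric(cf_pwv) || length(cf_pwv) != 1L || !is.finite(cf_pwv) ||
      cf_pwv < 3 || cf_pwv > 20)
    stopf("cf_pwv must be a single value in [3, 20] m/s, got %s",
          format(cf_pwv))
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L ||
      !is.finite(heart_rate) || heart_rate < 40 || heart_rate > 120)
    stopf("heart_rate must be a single value in [40, 120] bpm, got %s",
          format(heart_rate))
  site <- match.arg(site, c("radial", "digital", "brachial"))
  modality <- match.arg(modality, c("PPG", "BP"))

  period <- 60 / heart_rate
  n <- round(fs * period)
  t <- (seq_len(n) - 1) / fs

  jit <- with_seed(seed, rnorm(4L, 0, 0.02))  # per-subject morphology jitter

  # systolic upstroke peak; fixed fraction of the cycle plus jitter
  t_sys <- 0.13 * period * (1 + jit[1L])
  # widths narrow enough that the reflected lobe stays a distinct local
  # maximum up to cf_pwv = 20 m/s (delay 2*d_eff/cf_pwv >= 0.05 s)
  sd_sys <- if (modality == "PPG") 0.022 * (1 + jit[2L]) else
    0.025 * (1 + jit[2L])

  # reflected wave: delay shrinks and amplitude grows monotonically in cf_pwv
  extra <- c(radial = 0.010, digital = 0.018, brachial = 0.0)[[site]]
  delay <- 2 * d_eff / cf_pwv + extra
  t_ref <- t_sys + delay
  a_ref <- 0.35 + 0.30 * (cf_pwv - 3) / 17
  sd_ref <- 0.035 * (1 + jit[3L])

  # broad diastolic lobe
  t_dia <- 0.72 * period
  sd_dia <- 0.16 * period * (1 + jit[4L])

  shape <- exp(-0.5 * ((t - t_sys) / sd_sys)^2) +
    a_ref * exp(-0.5 * ((t - t_ref) / sd_ref)^2) +
    0.10 * exp(-0.5 * ((t - t_dia) / sd_dia)^2)

  if (modality == "PPG") {
    samples <- shape / max(shape)
  } else {
    samples <- 80 + 40 * shape / max(shape)
  }
  pulse_wave(samples, fs = fs, site = site, modality = modality,
             meta = list(heart_rate_bpm = heart_rate, cf_pwv_true = cf_pwv,
                         seed = seed))
}

#' Generate a synthetic in-silico cohort of single-cycle pulse waves
#'
#' Emulates the structure of an in-silico haemodynamic database: `n_groups`
#' age groups of equal size (`n_per_group` virtual subjects each), heart
#' rates drawn uniformly from 66-86 bpm, and a latent cf-PWV drawn per
#' subject from a truncated normal whose mean increases linearly with age
#' group (means spaced over `pwv_means`, sd `pwv_sd`), reflecting arterial
#' stiffening with age. One waveform is produced per subject for every
#' requested (site, modality) combination.
#'
#' @param n_groups number of age groups (default 6).
#' @param n_per_group subjects per group (default 729).
#' @param modalities character vector from `c("PPG","BP")`.
#' @param sites character vector from `c("radial","digital","brachial")`.
#' @param seed integer root seed; the cohort is fully reproducible.
#' @param fs sampling rate in Hz.
#' @param pwv_means length-2 range of per-group cf-PWV means in m/s.
#' @param pwv_sd within-group cf-PWV standard deviation in m/s.
#' @param pwv_limits truncation limits for cf-PWV in m/s.
#' @param hr_range heart-rate range in bpm.
#' @return A list with `waves` (list of [pulse_wave()], one per
#'   subject x site x modality) and `cohort` (data.frame with columns
#'   subject_id, site, modality, cf_pwv_true, age_group, heart_rate_bpm).
#' @examples
#' cg <- generate_cohort(n_groups = 2, n_per_group = 3, seed = 1)
#' nrow(cg$cohort)
#' @export
generate_cohort <- function(n_groups = 6L, n_per_group = 729L,
                            modalities = "PPG", sites = "radial",
                            seed = 1L, fs = 500,
                            pwv_means = c(6.5, 12.5), pwv_sd = 0.8,
                            pwv_limits = c(4, 16), hr_range = c(66, 86)) {
  if (n_groups < 1L || n_per_group < 1L)
    stopf("n_groups and n_per_group must both be >= 1")
  modalities <- match.arg(modalities, c("PPG", "BP"), several.ok = TRUE)
  sites <- match.arg(sites, c("radial", "digital", "brachial"),
                     several.ok = TRUE)
  n <- n_groups * n_per_group
  mu <- if (n_groups == 1L) mean(pwv_means) else
    seq(pwv_means[1L], pwv_means[2L], length.out = n_groups)

  subj <- with_seed(substream_seed(seed, "cohort"), {
    age_group <- rep(seq_len(n_groups), each = n_per_group)
    cf <- rtruncnorm(n, mu[age_group], pwv_sd, pwv_limits[1L], pwv_limits[2L])
    hr <- runif(n, hr_range[1L], hr_range[2L])
    data.frame(subject_id = sprintf("S%05d", seq_len(n)),
               age_group = age_group, cf_pwv_true = cf, heart_rate_bpm = hr)
  })

  combos <- expand.grid(site = sites, modality = modalities,
                        stringsAsFactors = FALSE)
  waves <- vector("list", n * nrow(combos))
  rows <- vector("list", nrow(combos))
  idx <- 0L
  for (ci in seq_len(nrow(combos))) {
    for (i in seq_len(n)) {
      idx <- idx + 1L
      w <- synthesize_pulse(subj$cf_pwv_true[i], subj$heart_rate_bpm[i],
                            modality = combos$modality[ci],
                            site = combos$site[ci],
                            seed = substream_seed(seed, "wave") + i,
                            fs = fs)
      w$meta$subject_id <- subj$subject_id[i]
      w$meta$age_group <- subj$age_group[i]
      waves[[idx]] <- w
    }
    rows[[ci]] <- data.frame(subject_id = subj$subject_id,
                             site = combos$site[ci],
                             modality = combos$modality[ci],
                             cf_pwv_true = subj$cf_pwv_true,
                             age_group = subj$age_group,
                             heart_rate_bpm = subj$heart_rate_bpm)
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  list(waves = waves, cohort = cohort)
}

# truncated-normal draws by rejection (physiological truncation is mild,
# so acceptance is high; loop guards pathological configs)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean[bad], sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
    guard <- guard + 1L
  }
  pmin(pmax(out, lo), hi)
}

#' Add Gaussian white noise at a target signal-to-noise ratio
#'
#' Adds zero-mean Gaussian white noise with power
#' `P_n = P_s / 10^(snr_db / 10)`, where the signal power `P_s` is the mean
#' square of the mean-removed signal (so that the large DC offset of BP
#' waves does not make the stated SNR vacuous). `snr_db = Inf` is the
#' "no noise" sentinel and returns the input unchanged.
#'
#' @param wave a [pulse_wave()].
#' @param snr_db target SNR in dB (`Inf` for none).
#' @param seed integer seed for the noise draw.
#' @return A [pulse_wave()] with `meta$snr_db` recorded.
#' @export
add_noise_snr <- function(wave, snr_db, seed = 1L) {
  stopifnot(inherits(wave, "pulse_wave"))
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stopf("snr_db must be a single finite value or Inf")
  if (is.infinite(snr_db) && snr_db > 0) {
    wave$meta$snr_db <- Inf
    return(wave)
  }
  x <- wave$samples
  ps <- mean((x - mean(x))^2)
  pn <- ps / 10^(snr_db / 10)
  noise <- with_seed(substream_seed(seed, "noise"),
                     rnorm(length(x), 0, sqrt(pn)))
  out <- wave
  out$samples <- x + noise
  out$meta$snr_db <- snr_db
  out
}

#' Default noise levels per modality
#'
#' The robustness experiments use 20, 10 and 5 dB for BP signals and
#' 65, 45 and 30 dB for PPG signals.
#'
#' @param modality `"PPG"` or `"BP"`.
#' @return numeric vector of SNR values in dB.
#' @export
default_noise_levels <- function(modality = c("PPG", "BP")) {
  modality <- match.arg(modality)
  if (modality == "BP") c(20, 10, 5) else c(65, 45, 30)
}

#' Read a cohort from CSV exports
#'
#' Loads a cohort manifest plus a wide waveform table. The manifest must
#' have columns `subject_id, site, modality, cf_pwv, age_group, hr`; the
#' waveform CSV has one row per subject: a `subject_id` column followed by
#' sample columns (`s1, s2, ...`, trailing `NA`s allowed for ragged cycle
#' lengths).
#'
#' @param manifest_path path to the manifest CSV.
#' @param waves_path path to the wide waveform CSV.
#' @param fs sampling rate of the stored waveforms in Hz.
#' @return list with `waves` and `cohort` as in [generate_cohort()].
#' @export
read_database_csv <- function(manifest_path, waves_path, fs = 500) {
  if (!file.exists(manifest_path)) stopf("manifest not found: %s", manifest_path)
  if (!file.exists(waves_path)) stopf("waveform CSV not found: %s", waves_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "site", "modality", "cf_pwv", "age_group", "hr")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0L)
    stopf("manifest is missing column(s): %s", paste(miss, collapse = ", "))
  wv <- read.csv(waves_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(wv))
    stopf("waveform CSV is missing a subject_id column")
  waves <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    ri <- which(wv$subject_id == man$subject_id[i])
    if (length(ri) != 1L)
      stopf("waveform row for subject %s (manifest row %d) not found or duplicated",
            man$subject_id[i], i)
    samp <- suppressWarnings(as.numeric(wv[ri, -match("subject_id", names(wv))]))
    samp <- samp[!is.na(samp)]
    if (length(samp) < 2L || !all(is.finite(samp)))
      stopf("non-numeric or empty waveform for subject %s (waveform row %d)",
            man$subject_id[i], ri)
    waves[[i]] <- pulse_wave(samp, fs = fs, site = man$site[i],
                             modality = man$modality[i],
                             meta = list(subject_id = man$subject_id[i],
                                         age_group = man$age_group[i],
                                         heart_rate_bpm = man$hr[i],
                                         cf_pwv_true = man$cf_pwv[i]))
  }
  cohort <- data.frame(subject_id = man$subject_id, site = man$site,
                       modality = man$modality, cf_pwv_true = man$cf_pwv,
                       age_group = man$age_group, heart_rate_bpm = man$hr)
  list(waves = waves, cohort = cohort)
}

#' Write a cohort to CSV exports readable by [read_database_csv()]
#'
#' @param cg list with `waves` and `cohort` (as from [generate_cohort()]).
#' @param manifest_path,waves_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_database_csv <- function(cg, manifest_path, waves_path) {
  man <- data.frame(subject_id = cg$cohort$subject_id, site = cg$cohort$site,
                    modality = cg$cohort$modality,
                    cf_pwv = cg$cohort$cf_pwv_true,
                    age_group = cg$cohort$age_group,
                    hr = cg$cohort$heart_rate_bpm)
  write.csv(man, manifest_path, row.names = FALSE)
  maxn <- max(vapply(cg$waves, function(w) length(w$samples), integer(1L)))
  mat <- t(vapply(cg$waves, function(w)
    c(w$samples, rep(NA_real_, maxn - length(w$samples))), numeric(maxn)))
  df <- data.frame(subject_id = vapply(cg$waves, function(w)
    w$meta$subject_id, character(1L)), mat)
  names(df) <- c("subject_id", paste0("s", seq_len(maxn)))
  write.csv(df, waves_path, row.names = FALSE)
  invisible(c(manifest_path, waves_path))
}
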