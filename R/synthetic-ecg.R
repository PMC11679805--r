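#' Default rhythm-generation parameters for a merged class
#'
#' The generator reduces each rhythm class to the features a clinician would
#' name first: heart-rate range, RR-interval regularity, P-wave presence,
#' and (for AFIB) a fibrillatory baseline wave.
#'
#' * SR: 60-100 bpm, regular (RR CV 0.05), P waves present.
#' * SB: 40-55 bpm, regular, P waves present.
#' * GSVT: 110-180 bpm, regular, P waves attenuated (buried in the
#'   preceding T at high rates).
#' * AFIB: 60-160 bpm ventricular response, irregularly irregular
#'   (RR CV 0.30), no P waves, 5-8 Hz fibrillatory wave.
#'
#' @param cls merged class label ("AFIB", "GSVT", "SB", "SR").
#' @return list with fields `hr_range` (bpm), `rr_cv`, `p_wave_amp`
#'   (relative to R), `fib_wave` (list: on, freq_range Hz, amp), `noise_sd`
#'   (relative to R amplitude).
#' @export
#' @examples
#' rhythm_params("AFIB")$p_wave_amp  # 0
rhythm_params <- function(cls) {
  cls <- match.arg(cls, names(rhythm_classes()))
  base <- list(
    hr_range = c(60, 100), rr_cv = 0.05, p_wave_amp = 0.15,
    fib_wave = list(on = FALSE, freq_range = c(5, 8), amp = 0.08),
    noise_sd = 0.03
  )
  switch(cls,
    SR = base,
    SB = modifyList(base, list(hr_range = c(40, 55))),
    GSVT = modifyList(base, list(hr_range = c(110, 180), p_wave_amp = 0.04)),
    AFIB = modifyList(base, list(
      hr_range = c(60, 160), rr_cv = 0.30, p_wave_amp = 0,
      fib_wave = list(on = TRUE, freq_range = c(5, 8), amp = 0.08)))
  )
}

# Gaussian PQRST beat template: amplitude (relative to R = 1), centre offset
# from the R peak (s), width (s) for each wave.
beat_template <- function(p_wave_amp = 0.15) {
  tibble::tibble(
    wave = c("P", "Q", "R", "S", "T"),
    amp = c(p_wave_amp, -0.12, 1.0, -0.25, 0.35),
    center = c(-0.17, -0.035, 0.0, 0.035, 0.26),
    width = c(0.022, 0.010, 0.012, 0.011, 0.060)
  )
}

# Fixed per-lead projection coefficients; lead II is the source trace
# (coefficient exactly 1) so the student view equals the rendered signal.
lead_projection <- function() {
  c(I = 0.55, II = 1.0, III = 0.45, aVR = -0.75, aVL = 0.1, aVF = 0.7,
    V1 = -0.3, V2 = 0.2, V3 = 0.6, V4 = 0.9, V5 = 0.8, V6 = 0.65)
}

# Draw RR intervals covering `duration` seconds: Gamma-distributed with the
# requested mean and coefficient of variation (positive support, so heavy
# irregularity never yields negative intervals).
draw_rr_intervals <- function(mean_rr, rr_cv, duration) {
  if (rr_cv < 0) abort_param("`rr_cv` must be nonnegative")
  n_max <- ceiling(duration / mean_rr * 3) + 8
  if (rr_cv == 0) {
    rr <- rep(mean_rr, n_max)
  } else {
    shape <- 1 / rr_cv^2
    rr <- stats::rgamma(n_max, shape = shape, rate = shape / mean_rr)
  }
  beats <- cumsum(rr)
  beats[beats < duration + mean_rr]
}

#' Generate one labelled synthetic 12-lead ECG record
#'
#' Renders Gaussian PQRST beats on lead II at RR intervals drawn from the
#' class process (record-level heart rate uniform in the class range), adds
#' a fibrillatory sine for AFIB, projects to 12 leads by fixed per-lead
#' coefficients, and adds independent Gaussian noise per lead. Deterministic
#' given `(cls, seed)`.
#'
#' @param cls merged class label.
#' @param seed integer seed.
#' @param fs sampling rate in Hz (default 500, the deposit's rate).
#' @param duration record length in seconds (default 10).
#' @param params rhythm parameters, default [rhythm_params]`(cls)`.
#' @return a 12-lead [ecg_record()] labelled with `cls`; attributes
#'   `beat_times` (R-peak times, s) and `heart_rate` (bpm) carry the
#'   generator's ground truth.
#' @export
#' @examples
#' r <- simulate_ecg("SB", seed = 7)
#' attr(r, "heart_rate")
simulate_ecg <- function(cls, seed, fs = 500, duration = 10,
                         params = rhythm_params(cls)) {
  cls <- match.arg(cls, names(rhythm_classes()))
  if (any(params$hr_range < 20) || any(params$hr_range > 250)) {
    abort_param("hr_range must lie within [20, 250] bpm")
  }
  if (duration * params$hr_range[1] / 60 < 2) {
    abort_param("duration too short for at least 2 beats at the minimum rate")
  }
  withr::with_seed(seed, {
    hr <- stats::runif(1, params$hr_range[1], params$hr_range[2])
    beats <- draw_rr_intervals(60 / hr, params$rr_cv, duration)
    tgrid <- seq(0, by = 1 / fs, length.out = round(duration * fs))
    template <- beat_template(params$p_wave_amp)
    x <- numeric(length(tgrid))
    for (b in beats) {
      for (w in seq_len(nrow(template))) {
        ctr <- b + template$center[w]
        wd <- template$width[w]
        lo <- max(1L, ceiling((ctr - 5 * wd) * fs) + 1L)
        hi <- min(length(tgrid), floor((ctr + 5 * wd) * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        x[idx] <- x[idx] +
          template$amp[w] * exp(-((tgrid[idx] - ctr)^2) / (2 * wd^2))
      }
    }
    if (isTRUE(params$fib_wave$on)) {
      f <- stats::runif(1, params$fib_wave$freq_range[1],
                        params$fib_wave$freq_range[2])
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + params$fib_wave$amp * sin(2 * pi * f * tgrid + phase)
    }
    coefs <- lead_projection()
    sig <- outer(coefs, x)
    if (params$noise_sd > 0) {
      sig <- sig + matrix(stats::rnorm(length(sig), sd = params$noise_sd),
                          nrow = nrow(sig))
    }
    rownames(sig) <- names(coefs)
    # label with one of the class's raw annotation codes so the record is a
    # drop-in for the deposit's manifest (e.g. a GSVT record may carry SVT,
    # AT, SAAWR, ST, AVNRT or AVRT)
    map <- rhythm_merge_map()
    raw_codes <- map$raw_rhythm[map$merged_class == cls]
    raw <- raw_codes[sample.int(length(raw_codes), 1)]
    rec <- ecg_record(sig, fs = fs,
                      record_id = sprintf("SYN_%s_%d", cls, seed),
                      raw_rhythm = raw, merged_class = cls)
    attr(rec, "beat_times") <- beats[beats <= duration]
    attr(rec, "heart_rate") <- hr
    rec
  })
}

#' Generate a balanced labelled synthetic dataset
#'
#' `n_per_class` records for each of the four merged classes, with
#' per-record seeds derived reproducibly from `seed`.
#'
#' @param n_per_class records per class (>= 1).
#' @param seed master seed.
#' @param fs,duration forwarded to [simulate_ecg()].
#' @param noise_sd additive noise level overriding each class default, or
#'   `NULL` to keep the defaults.
#' @return list with `records` (list of `ecg_record`) and `manifest`
#'   (tibble: record_id, raw_rhythm, merged_class).
#' @export
simulate_dataset <- function(n_per_class, seed = 1L, fs = 500, duration = 10,
                             noise_sd = NULL) {
  if (n_per_class < 1) abort_param("`n_per_class` must be >= 1")
  classes <- names(rhythm_classes())
  records <- list()
  k <- 0L
  for (cls in classes) {
    params <- rhythm_params(cls)
    if (!is.null(noise_sd)) params$noise_sd <- noise_sd
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      rec <- simulate_ecg(cls, seed = derive_seed(seed, k), fs = fs,
                          duration = duration, params = params)
      rec$record_id <- sprintf("SYN%05d_%s", k, cls)
      records[[k]] <- rec
    }
  }
  manifest <- tibble::tibble(
    record_id = vapply(records, function(r) r$record_id, character(1)),
    raw_rhythm = vapply(records, function(r) r$raw_rhythm, character(1)),
    merged_class = vapply(records, function(r) r$merged_class, character(1))
  )
  list(records = records, manifest = manifest)
}

#' Write a synthetic dataset as a Chapman-style deposit
#'
#' One CSV per record in the dialect [read_ecg_csv()] reads, plus a
#' `manifest.csv` (record_id, raw_rhythm), so the synthetic set is a drop-in
#' replacement for the real deposit.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset$records) {
    write_ecg_csv(rec, file.path(dir, paste0(rec$record_id, ".csv")))
  }
  readr::write_csv(dataset$manifest[, c("record_id", "raw_rhythm")],
                   file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(dir)
}

#' Rate/regularity rule-based classifier
#'
#' A deliberately simple reference rule used to verify that the synthetic
#' classes are separable from lead II alone: detect R peaks by thresholding,
#' then classify by RR coefficient of variation (> `cv_afib` means AFIB) and
#' mean heart rate (< `hr_low` SB, > `hr_high` GSVT, else SR).
#'
#' @param record an `ecg_record` (12-lead or lead II).
#' @param hr_low,hr_high,cv_afib decision thresholds (bpm, bpm, unitless).
#' @return predicted merged class label.
#' @export
classify_by_rate <- function(record, hr_low = 60, hr_high = 100,
                             cv_afib = 0.15) {
  x <- if ("II" %in% rownames(record$signal)) {
    record$signal["II", ]
  } else {
    record$signal[1, ]
  }
  peaks <- detect_r_peaks(x, record$fs)
  if (length(peaks) < 3) return("SB")
  rr <- diff(peaks) / record$fs
  hr <- 60 / mean(rr)
  cv <- stats::sd(rr) / mean(rr)
  if (cv > cv_afib) "AFIB"
  else if (hr < hr_low) "SB"
  else if (hr > hr_high) "GSVT"
  else "SR"
}

# Threshold R-peak picker: local maxima above 60% of the robust max, with a
# 250 ms refractory period.
detect_r_peaks <- function(x, fs) {
  thr <- 0.6 * stats::quantile(x, 0.999, names = FALSE)
  n <- length(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  if (length(cand) == 0) return(integer(0))
  refractory <- round(0.25 * fs)
  peaks <- cand[1]
  for (i in cand[-1]) {
    if (i - peaks[length(peaks)] > refractory) {
      peaks <- c(peaks, i)
    } else if (x[i] > x[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
    }
  }
  peaks
}
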