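#' Resample an ECG record
#'
#' Rate conversion with zero-phase FIR anti-alias filtering: for a rational
#' ratio p/q the signal is zero-stuffed by p, low-pass filtered at the
#' narrower of the two Nyquist limits with a linear-phase FIR applied
#' forwards and backwards ([signal::filtfilt()], so no group delay), and
#' subsampled by q. The common 500 -> 250 Hz case reduces to plain FIR
#' anti-alias + decimation by 2.
#'
#' @param record an [ecg_record()].
#' @param fs_out target sampling rate in Hz.
#' @param order FIR order (default 64).
#' @return the resampled record; `n_samples_out = round(n_in * fs_out / fs_in)`
#'   per lead, `fs` updated.
#' @export
resample_record <- function(record, fs_out, order = 64) {
  if (!is.numeric(fs_out) || length(fs_out) != 1 || fs_out <= 0) {
    abort_param("`fs_out` must be a single positive rate in Hz")
  }
  if (record$fs <= 0) abort_param("record has non-positive sampling rate")
  if (isTRUE(all.equal(fs_out, record$fs))) return(record)

  fr <- attr(MASS::fractions(fs_out / record$fs, max.denominator = 1000), "fracs")
  pq <- as.numeric(strsplit(fr, "/")[[1]])
  p <- pq[1]
  q <- if (length(pq) == 2) pq[2] else 1
  n_in <- ncol(record$signal)
  n_out <- round(n_in * fs_out / record$fs)

  resample_one <- function(x) {
    if (p > 1) {
      up <- numeric(length(x) * p)
      up[seq(1, length(up), by = p)] <- x * p
      x <- up
    }
    if (q > 1 || p > 1) {
      b <- signal::fir1(order, 1 / max(p, q))
      x <- signal::filtfilt(filt = b, a = 1, x = x)
    }
    x[seq(1, by = q, length.out = min(n_out, floor((length(x) - 1) / q) + 1))]
  }
  out <- t(apply(record$signal, 1, resample_one))
  rownames(out) <- rownames(record$signal)
  record$signal <- out
  record$fs <- fs_out
  record
}

#' Per-lead z-score normalisation
#'
#' Standardises each lead independently to zero mean and unit spread:
#' `Z = (X - mu) / sigma`, with `mu` the lead mean and `sigma` the population
#' (divide-by-n) standard deviation. A zero-variance lead maps to all zeros
#' with a warning rather than an error, so batch pipelines survive
#' pathological inputs.
#'
#' @param record an [ecg_record()].
#' @return the normalised record, with attribute `norm_stats`: a tibble
#'   (`lead`, `mu`, `sigma`) of the statistics used.
#' @export
#' @examples
#' r <- ecg_record(matrix(1:3, nrow = 1, dimnames = list("II", NULL)), fs = 1)
#' zscore_record(r)$signal  # -1.2247, 0, 1.2247
zscore_record <- function(record) {
  sig <- record$signal
  n <- ncol(sig)
  mu <- rowMeans(sig)
  sigma <- sqrt(rowMeans((sig - mu)^2))  # population sd
  zero_sd <- sigma <= 0
  if (any(zero_sd)) {
    rlang::warn(sprintf("constant lead(s) %s mapped to zeros (sigma = 0)",
                        paste(rownames(sig)[zero_sd], collapse = ", ")))
  }
  denom <- ifelse(zero_sd, 1, sigma)
  record$signal <- (sig - mu) / denom
  record$signal[zero_sd, ] <- 0
  attr(record, "norm_stats") <- tibble::tibble(
    lead = rownames(sig), mu = unname(mu), sigma = unname(sigma))
  record
}

#' Extract the lead II view of a 12-lead record
#'
#' Projects a 12-lead record to the single bipolar limb lead the student
#' model consumes; all metadata is preserved. A record that is already
#' single-lead is rejected — the identity of its lead cannot be verified.
#'
#' @param record a 12-lead [ecg_record()].
#' @return a 1-lead `ecg_record` containing lead II.
#' @export
extract_lead_ii <- function(record) {
  if (nrow(record$signal) < 2) {
    abort_param("record is already single-lead; cannot verify it is lead II")
  }
  if (!"II" %in% rownames(record$signal)) {
    abort_param("record has no lead II (leads: %s)",
                paste(rownames(record$signal), collapse = ", "))
  }
  record$signal <- record$signal["II", , drop = FALSE]
  record
}

#' Standard preprocessing pipeline
#'
#' Resample to `fs_out` (default 250 Hz, the wearable acquisition rate) then
#' z-score each lead.
#'
#' @param records list of [ecg_record()] objects (or a single record).
#' @param fs_out target rate in Hz.
#' @return list of preprocessed records (or a single record if one given).
#' @export
preprocess_records <- function(records, fs_out = 250) {
  single <- inherits(records, "ecg_record")
  if (single) records <- list(records)
  out <- lapply(records, function(r) zscore_record(resample_record(r, fs_out)))
  if (single) out[[1]] else out
}
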