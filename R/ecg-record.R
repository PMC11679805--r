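#' Canonical 12-lead order
#'
#' The clinical lead montage in the fixed column order used by every reader
#' and writer in the package.
#'
#' @return character vector of the 12 lead names.
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' The four merged rhythm classes
#'
#' Class labels with their fixed integer codes: AFIB = 0, GSVT = 1, SB = 2,
#' SR = 3. The codes are stable across the whole package (splits, one-hot
#' labels, confusion matrices).
#'
#' @return named integer vector (names are class labels, values the codes).
#' @export
#' @examples
#' rhythm_classes()
rhythm_classes <- function() {
  c(AFIB = 0L, GSVT = 1L, SB = 2L, SR = 3L)
}

#' Construct an ECG record
#'
#' A single multi-lead ECG segment: a leads-by-samples signal matrix with its
#' sampling rate, raw rhythm annotation and (once assigned) merged class.
#'
#' @param signal numeric matrix, leads in rows, samples in columns. Row names
#'   give the lead names; unnamed 12-row matrices get the canonical order
#'   from [ecg_leads()].
#' @param fs sampling rate in Hz.
#' @param record_id opaque record identifier.
#' @param raw_rhythm raw rhythm code string (e.g. "AFIB", "SB"), or `NA`.
#' @param merged_class merged class label ("AFIB", "GSVT", "SB", "SR") or `NA`.
#' @param age subject age in years, or `NA`.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, record_id = NA_character_,
                       raw_rhythm = NA_character_, merged_class = NA_character_,
                       age = NA_real_) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort_param("`signal` must be a numeric matrix (leads x samples)")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort_param("`fs` must be a single positive sampling rate in Hz")
  }
  if (is.null(rownames(signal))) {
    if (nrow(signal) == 12L) {
      rownames(signal) <- ecg_leads()
    } else if (nrow(signal) == 1L) {
      rownames(signal) <- "II"
    } else {
      abort_param("`signal` must have lead names unless it has 12 or 1 rows")
    }
  }
  if (!is.na(merged_class) && !merged_class %in% names(rhythm_classes())) {
    abort_param("`merged_class` must be one of %s",
                paste(names(rhythm_classes()), collapse = ", "))
  }
  structure(
    list(record_id = as.character(record_id),
         signal = signal,
         fs = as.numeric(fs),
         raw_rhythm = as.character(raw_rhythm),
         merged_class = as.character(merged_class),
         age = as.numeric(age)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d lead(s) x %d samples @ %g Hz",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs))
  if (!is.na(x$raw_rhythm)) cat(sprintf(", rhythm %s", x$raw_rhythm))
  if (!is.na(x$merged_class)) cat(sprintf(" (class %s)", x$merged_class))
  cat("\n")
  invisible(x)
}

#' @export
dim.ecg_record <- function(x) dim(x$signal)

#' Tidy an ECG record into a long tibble
#'
#' One row per (lead, sample): columns `record_id`, `lead`, `time` (seconds),
#' `value`. Convenient for ggplot2.
#'
#' @param x an `ecg_record`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy ecg_record
#' @export
tidy.ecg_record <- function(x, ...) {
  n <- ncol(x$signal)
  tibble::tibble(
    record_id = x$record_id,
    lead = rep(rownames(x$signal), each = n),
    time = rep(seq(0, by = 1 / x$fs, length.out = n), nrow(x$signal)),
    value = as.vector(t(x$signal))
  )
}

#' Plot an ECG record
#'
#' Faceted trace of each lead against time.
#'
#' @param object an `ecg_record`.
#' @param leads optional character vector restricting which leads are drawn.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ecg_record
#' @export
autoplot.ecg_record <- function(object, leads = NULL, ...) {
  df <- tidy.ecg_record(object)
  if (!is.null(leads)) df <- dplyr::filter(df, .data$lead %in% leads)
  df$lead <- factor(df$lead, levels = rownames(object$signal))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = sprintf("%s (%s)", object$record_id,
                                  ifelse(is.na(object$merged_class), "?",
                                         object$merged_class))) +
    ggplot2::theme_minimal()
}
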