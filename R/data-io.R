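#' Raw-to-merged rhythm code map
#'
#' The total mapping from the 11 raw rhythm annotations to the four study
#' classes: AFIB and AF merge into AFIB; the six supraventricular
#' tachycardia-related codes (SVT, AT, SAAWR, ST, AVNRT, AVRT) merge into
#' GSVT; SB stays SB; SR and SI (sinus arrhythmia) merge into SR.
#'
#' @return tibble with columns `raw_rhythm`, `merged_class`, `class_code`.
#' @export
#' @examples
#' rhythm_merge_map()
rhythm_merge_map <- function() {
  map <- c(
    AFIB = "AFIB", AF = "AFIB",
    SVT = "GSVT", AT = "GSVT", SAAWR = "GSVT", ST = "GSVT",
    AVNRT = "GSVT", AVRT = "GSVT",
    SB = "SB",
    SR = "SR", SI = "SR"
  )
  tibble::tibble(
    raw_rhythm = names(map),
    merged_class = unname(map),
    class_code = unname(rhythm_classes()[map])
  )
}

#' Merge a raw rhythm code into its study class
#'
#' @param raw_rhythm character vector of raw rhythm codes.
#' @return character vector of merged class labels ("AFIB", "GSVT", "SB",
#'   "SR").
#' @export
#' @examples
#' merge_rhythm_label(c("AF", "SAAWR", "SI"))
merge_rhythm_label <- function(raw_rhythm) {
  map <- rhythm_merge_map()
  idx <- match(raw_rhythm, map$raw_rhythm)
  if (anyNA(idx)) {
    bad <- unique(raw_rhythm[is.na(idx)])
    abort_param(
      "unknown rhythm code(s) %s; accepted codes are: %s",
      paste(sprintf("'%s'", bad), collapse = ", "),
      paste(map$raw_rhythm, collapse = ", ")
    )
  }
  map$merged_class[idx]
}

#' Check whether a record is usable
#'
#' A record is rejected when any lead is entirely zero (a disconnected or
#' dropped electrode), when any value is missing/non-finite, or when an
#' expected lead row is absent. An isolated zero sample is fine —
#' physiological traces cross zero constantly.
#'
#' @param record an [ecg_record()].
#' @param expected_leads leads the record must contain (default: the 12-lead
#'   montage for 12-row signals, otherwise the record's own leads).
#' @return logical scalar with attribute `reason` (character, `""` when
#'   usable) describing the offending lead.
#' @export
check_usability <- function(record, expected_leads = NULL) {
  sig <- record$signal
  if (is.null(expected_leads)) {
    # multi-lead records must carry the full montage; a single-lead record
    # is checked against itself
    expected_leads <- if (nrow(sig) == 1) rownames(sig) else ecg_leads()
  }
  missing_leads <- setdiff(expected_leads, rownames(sig))
  if (length(missing_leads) > 0) {
    return(structure(FALSE, reason = sprintf(
      "missing lead(s): %s", paste(missing_leads, collapse = ", "))))
  }
  if (!all(is.finite(sig))) {
    bad <- rownames(sig)[rowSums(!is.finite(sig)) > 0]
    return(structure(FALSE, reason = sprintf(
      "missing/non-finite values in lead(s): %s", paste(bad, collapse = ", "))))
  }
  all_zero <- rowSums(sig != 0) == 0
  if (any(all_zero)) {
    return(structure(FALSE, reason = sprintf(
      "all-zero lead(s): %s", paste(rownames(sig)[all_zero], collapse = ", "))))
  }
  structure(TRUE, reason = "")
}

#' Read a Chapman-style per-record CSV
#'
#' Each record is a CSV of `n_samples` rows by 12 lead columns sampled at
#' 500 Hz (10 s = 5000 rows). The manifest supplies the raw rhythm label and
#' optional age for the record id (taken from the file name).
#'
#' @param path path to the record CSV.
#' @param manifest data frame with columns `record_id`, `raw_rhythm` and
#'   optionally `age`, or `NULL` to read the signal without a label.
#' @param fs sampling rate of the stored trace in Hz.
#' @return an [ecg_record()] with leads in rows.
#' @export
read_ecg_csv <- function(path, manifest = NULL, fs = 500) {
  if (!file.exists(path)) abort_param("no such file: %s", path)
  record_id <- sub("\\.[cC][sS][vV]$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != 12L) {
    abort_param("malformed record CSV %s: expected 12 lead columns, found %d",
                basename(path), ncol(df))
  }
  if (!identical(colnames(df), ecg_leads())) {
    if (!setequal(colnames(df), ecg_leads())) {
      abort_param("malformed record CSV %s: lead columns must be %s",
                  basename(path), paste(ecg_leads(), collapse = ", "))
    }
    df <- df[, ecg_leads()]
  }
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0) {
    abort_param("malformed record CSV %s: non-numeric values in column '%s'",
                basename(path), colnames(df)[bad[1]])
  }
  sig <- t(as.matrix(df))
  rownames(sig) <- ecg_leads()
  raw_rhythm <- NA_character_
  age <- NA_real_
  if (!is.null(manifest)) {
    i <- match(record_id, manifest$record_id)
    if (is.na(i)) {
      abort_param("record id '%s' not found in manifest", record_id)
    }
    raw_rhythm <- manifest$raw_rhythm[i]
    if ("age" %in% names(manifest)) age <- as.numeric(manifest$age[i])
  }
  ecg_record(sig, fs = fs, record_id = record_id, raw_rhythm = raw_rhythm,
             age = age)
}

#' Write an ECG record as a Chapman-style CSV
#'
#' The exact dialect [read_ecg_csv()] reads: samples in rows, the 12 leads in
#' columns with a header row.
#'
#' @param record an [ecg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  df <- as.data.frame(t(record$signal), check.names = FALSE)
  # readr writes shortest round-trip representations, so a write/read cycle
  # reproduces the signal bit for bit
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a label manifest
#'
#' Two-or-more-column CSV with at least `record_id` and `raw_rhythm`.
#'
#' @param path manifest CSV path.
#' @return tibble.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("record_id", "raw_rhythm")
  if (!all(need %in% names(df))) {
    abort_param("manifest must have columns %s", paste(need, collapse = ", "))
  }
  df$record_id <- as.character(df$record_id)
  df
}

#' Stratified train/validation/test split
#'
#' Per class, ids are shuffled with a class-specific generator derived from
#' `seed`, then assigned floor(f_train * n) to train, floor(f_val * n) to
#' validation, and the remainder to test. Deterministic for a fixed seed.
#'
#' @param manifest data frame with columns `record_id` and `merged_class`
#'   (labels or integer codes).
#' @param fractions length-3 numeric (train, validation, test) summing to 1.
#' @param seed integer seed.
#' @return tibble `record_id`, `merged_class`, `split` (factor
#'   train/validation/test).
#' @export
#' @examples
#' man <- tibble::tibble(record_id = sprintf("R%03d", 1:40),
#'                       merged_class = rep(c("AFIB", "GSVT", "SB", "SR"), 10))
#' table(split_records(man, seed = 1)$split)
split_records <- function(manifest, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    abort_param("`fractions` must be three proportions summing to 1")
  }
  if (any(fractions < 0)) abort_param("`fractions` must be nonnegative")
  cls <- as.character(manifest$merged_class)
  counts <- table(cls)
  if (any(counts < 3)) {
    abort_param("class '%s' has fewer than 3 records; cannot populate three splits",
                names(counts)[which(counts < 3)[1]])
  }
  pieces <- lapply(seq_along(sort(unique(cls))), function(k) {
    cl <- sort(unique(cls))[k]
    ids <- manifest$record_id[cls == cl]
    rng <- derive_seed(seed, k)
    ord <- withr::with_seed(rng, sample.int(length(ids)))
    ids <- ids[ord]
    n <- length(ids)
    n_tr <- floor(fractions[1] * n)
    n_va <- floor(fractions[2] * n)
    tibble::tibble(
      record_id = ids,
      merged_class = cl,
      split = c(rep("train", n_tr), rep("validation", n_va),
                rep("test", n - n_tr - n_va))
    )
  })
  out <- dplyr::bind_rows(pieces)
  out$split <- factor(out$split, levels = c("train", "validation", "test"))
  out[order(match(out$record_id, manifest$record_id)), ]
}

#' Summarise a deposit: usability filter plus merged-class totals
#'
#' Applies [check_usability()] to every record CSV under `data_dir`, merges
#' the raw rhythm labels, and tabulates retained records per merged class —
#' the bookkeeping behind the study's cohort table.
#'
#' @param data_dir directory of per-record CSVs.
#' @param manifest label manifest (data frame or path).
#' @return list with `summary` (tibble: merged_class, n_retained),
#'   `retained_ids`, and `dropped` (tibble: record_id, reason).
#' @export
summarise_deposit <- function(data_dir, manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  files <- list.files(data_dir, pattern = "\\.[cC][sS][vV]$", full.names = TRUE)
  files <- files[sub("\\.[cC][sS][vV]$", "", basename(files)) %in% manifest$record_id]
  keep <- character(0)
  drop_id <- character(0)
  drop_reason <- character(0)
  cls <- character(0)
  for (f in files) {
    rec <- read_ecg_csv(f, manifest)
    ok <- check_usability(rec)
    if (isTRUE(as.logical(ok))) {
      keep <- c(keep, rec$record_id)
      cls <- c(cls, merge_rhythm_label(rec$raw_rhythm))
    } else {
      drop_id <- c(drop_id, rec$record_id)
      drop_reason <- c(drop_reason, attr(ok, "reason"))
    }
  }
  summary <- tibble::tibble(merged_class = names(rhythm_classes())) |>
    dplyr::left_join(
      tibble::tibble(merged_class = cls) |> dplyr::count(.data$merged_class,
                                                         name = "n_retained"),
      by = "merged_class"
    ) |>
    dplyr::mutate(n_retained = dplyr::coalesce(.data$n_retained, 0L))
  list(summary = summary,
       retained_ids = keep,
       dropped = tibble::tibble(record_id = drop_id, reason = drop_reason))
}
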