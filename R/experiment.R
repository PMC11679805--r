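#' Reduced-width teacher profile for CPU-scale experiments
#'
#' Same topology as [teacher_spec()] (stem convolution, four residual SE
#' blocks, two LSTM layers, dense softmax head) with narrower channels
#' (8 / 8-16-16-32 / LSTM 16), sized so a full distillation experiment runs
#' on a single CPU in minutes. The full-width default spec is used for
#' complexity accounting; this profile is used for training studies.
#'
#' @param ... overrides forwarded to [teacher_spec()].
#' @return a `teacher_spec`.
#' @export
desk_teacher_spec <- function(...) {
  teacher_spec(stem_ch = 8, block_channels = c(8, 16, 16, 32),
               lstm_hidden = 16, ...)
}

#' Run the knowledge-distillation comparison experiment
#'
#' End-to-end desk-scale protocol on synthetic data: simulate a balanced
#' four-class 12-lead dataset, resample 500 -> 250 Hz and z-score, split
#' 70/20/10 per class, train the teacher on the 12-lead view, then train
#' paired students on the lead II view — one arm with knowledge
#' distillation (`alpha`, `temperature`) and one without (`alpha = 1`) —
#' across several seeds, and score all models on the held-out test split.
#'
#' @param n_per_class synthetic records per class.
#' @param seeds how many paired student seeds to run.
#' @param epochs epoch budget for teacher and students.
#' @param seed master seed controlling simulation, split, and training.
#' @param temperature,alpha distillation hyperparameters of the KD arm.
#' @param teacher_spec teacher architecture (default [desk_teacher_spec()]).
#' @param student_spec student architecture (default [student_spec()]).
#' @param noise_sd generator noise override (`NULL` keeps class defaults).
#' @param fs_out preprocessing target rate in Hz.
#' @param verbose print progress.
#' @return a `kd_experiment` list: `runs` (tibble: seed, arm,
#'   test_accuracy %, best_val_acc), `summary` (tibble with the median
#'   accuracy per arm and their difference), `teacher` (tibble row),
#'   `teacher_fit`, `student_fits`, `data` (test split kept for reports).
#' @export
run_kd_experiment <- function(n_per_class = 250, seeds = 5, epochs = 12,
                              seed = 1L, temperature = 4, alpha = 0.5,
                              teacher_spec = desk_teacher_spec(),
                              student_spec = distillecg::student_spec(),
                              noise_sd = NULL, fs_out = 250,
                              verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating %d records/class ...", n_per_class)
  ds <- simulate_dataset(n_per_class, seed = derive_seed(seed, 1L),
                         noise_sd = noise_sd)
  say("preprocessing (resample -> %g Hz, z-score) ...", fs_out)
  recs <- preprocess_records(ds$records, fs_out = fs_out)
  split <- split_records(ds$manifest, seed = derive_seed(seed, 2L))
  data <- kd_data(recs, split)

  say("training teacher (%d epochs) ...", epochs)
  t_cfg <- distill_config(temperature = temperature, alpha = 1,
                          epochs = epochs, seed = derive_seed(seed, 3L))
  teacher_fit <- train_teacher(data, spec = teacher_spec, config = t_cfg)
  t_eval <- evaluate_model(teacher_fit, data$test$x12, data$test$y)
  say("teacher test accuracy: %.1f%%", t_eval$accuracy)

  runs <- list()
  student_fits <- list()
  for (s in seq_len(seeds)) {
    for (arm in c("kd", "no_kd")) {
      cfg <- distill_config(
        temperature = temperature,
        alpha = if (arm == "kd") alpha else 1,
        epochs = epochs, seed = derive_seed(seed, 100L + s))
      fit <- distill_student(teacher_fit, data, spec = student_spec,
                             config = cfg)
      ev <- evaluate_model(fit, data$test$x1, data$test$y)
      say("seed %d %-5s: test accuracy %.1f%%", s, arm, ev$accuracy)
      runs[[length(runs) + 1L]] <- tibble::tibble(
        seed = s, arm = arm, test_accuracy = ev$accuracy,
        best_val_acc = 100 * max(fit$log$val_acc))
      student_fits[[sprintf("seed%d_%s", s, arm)]] <- fit
    }
  }
  runs <- dplyr::bind_rows(runs)
  med <- runs |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(median_test_accuracy = stats::median(.data$test_accuracy),
                     .groups = "drop")
  kd_med <- med$median_test_accuracy[med$arm == "kd"]
  nk_med <- med$median_test_accuracy[med$arm == "no_kd"]
  summary <- tibble::tibble(
    kd_median_accuracy = kd_med,
    no_kd_median_accuracy = nk_med,
    kd_delta = kd_med - nk_med)
  structure(list(
    runs = runs, summary = summary,
    teacher = tibble::tibble(test_accuracy = t_eval$accuracy),
    teacher_fit = teacher_fit, student_fits = student_fits,
    data = data
  ), class = "kd_experiment")
}

#' @export
print.kd_experiment <- function(x, ...) {
  cat("<kd_experiment>\n")
  cat(sprintf("  teacher test accuracy: %.2f%%\n", x$teacher$test_accuracy))
  cat(sprintf("  student median test accuracy: KD %.2f%% vs no-KD %.2f%% (delta %+.2f)\n",
              x$summary$kd_median_accuracy, x$summary$no_kd_median_accuracy,
              x$summary$kd_delta))
  invisible(x)
}
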