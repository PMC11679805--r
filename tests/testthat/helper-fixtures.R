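# shared fixtures: all built in code at test time

# a clean 12-lead record with distinct values per lead
make_flat_record <- function(n = 100, fs = 500) {
  sig <- outer(seq_len(12), sin(2 * pi * 5 * seq_len(n) / fs))
  sig <- sig + 0.01 * matrix(seq_len(12 * n), 12, n)
  ecg_record(sig, fs = fs, record_id = "FIX1", raw_rhythm = "SR")
}

# write a record + manifest into a temp deposit dir, return paths
write_tmp_deposit <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  for (r in records) write_ecg_csv(r, file.path(dir, paste0(r$record_id, ".csv")))
  man <- data.frame(record_id = vapply(records, `[[`, "", "record_id"),
                    raw_rhythm = vapply(records, `[[`, "", "raw_rhythm"))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  dir
}

# central-difference gradient of scalar f at x (vector/array)
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(as.array(x)))
  xv <- as.vector(x)
  for (i in seq_along(xv)) {
    xp <- xv; xp[i] <- xp[i] + eps
    xm <- xv; xm[i] <- xm[i] - eps
    dim(xp) <- dim(g); dim(xm) <- dim(g)
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# a quick paired dataset of short synthetic records for training tests
make_tiny_kd_data <- function(n_per_class = 8, duration = 4, seed = 404) {
  ds <- simulate_dataset(n_per_class, seed = seed, duration = duration)
  recs <- preprocess_records(ds$records)
  split <- split_records(ds$manifest, c(0.5, 0.25, 0.25), seed = seed)
  kd_data(recs, split)
}

tiny_teacher_spec <- function(...) {
  teacher_spec(stem_ch = 4, stem_kernel = 7, block_channels = c(4, 6, 6, 8),
               block_kernel = 3, lstm_hidden = 5, ...)
}

tiny_student_spec <- function() {
  student_spec(conv1 = list(ch = 4, kernel = 5, stride = 4, pool = 2),
               conv2 = list(ch = 6, kernel = 3, stride = 4, pool = 2))
}
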