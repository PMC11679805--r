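test_that("merge map is total over the 11 raw codes with the right fan-in", {
  map <- rhythm_merge_map()
  expect_equal(nrow(map), 11)
  expect_setequal(unique(map$merged_class), names(rhythm_classes()))
  expect_equal(sum(map$merged_class == "AFIB"), 2)
  expect_equal(sum(map$merged_class == "GSVT"), 6)
  expect_equal(sum(map$merged_class == "SB"), 1)
  expect_equal(sum(map$merged_class == "SR"), 2)
})

test_that("raw rhythm codes merge into the documented classes", {
  expect_equal(merge_rhythm_label("AF"), "AFIB")
  expect_equal(merge_rhythm_label("AFIB"), "AFIB")
  expect_equal(merge_rhythm_label("SAAWR"), "GSVT")
  expect_equal(merge_rhythm_label("ST"), "GSVT")
  expect_equal(merge_rhythm_label("SB"), "SB")
  expect_equal(merge_rhythm_label("SI"), "SR")
  # vectorised over the full domain: exactly the 4 targets appear
  all_codes <- rhythm_merge_map()$raw_rhythm
  expect_setequal(unique(merge_rhythm_label(all_codes)),
                  c("AFIB", "GSVT", "SB", "SR"))
  expect_error(merge_rhythm_label("VT"), "accepted codes")
})

test_that("usability filter flags all-zero leads, missing values, absent leads", {
  rec <- make_flat_record()
  expect_true(as.logical(check_usability(rec)))
  expect_equal(attr(check_usability(rec), "reason"), "")

  r2 <- rec
  r2$signal["V3", ] <- 0
  ok <- check_usability(r2)
  expect_false(as.logical(ok))
  expect_match(attr(ok, "reason"), "V3")

  r3 <- rec
  r3$signal["aVL", 17] <- NA
  ok3 <- check_usability(r3)
  expect_false(as.logical(ok3))
  expect_match(attr(ok3, "reason"), "aVL")

  r4 <- rec
  r4$signal <- r4$signal[-5, ]
  expect_false(as.logical(check_usability(r4)))
  expect_match(attr(check_usability(r4), "reason"), "aVL")

  # an isolated zero sample does not disqualify
  r5 <- rec
  r5$signal["II", 10] <- 0
  expect_true(as.logical(check_usability(r5)))
})

test_that("usability is monotone: zeroing any full lead breaks a usable record", {
  rec <- make_flat_record(n = 50)
  expect_true(as.logical(check_usability(rec)))
  for (lead in rownames(rec$signal)) {
    r <- rec
    r$signal[lead, ] <- 0
    expect_false(as.logical(check_usability(r)), label = lead)
  }
})

test_that("record CSV writer and reader round-trip bit-identically", {
  rec <- simulate_ecg("SR", seed = 12, duration = 4)
  dir <- write_tmp_deposit(list(rec))
  man <- read_manifest(file.path(dir, "manifest.csv"))
  back <- read_ecg_csv(file.path(dir, paste0(rec$record_id, ".csv")), man)
  expect_identical(dim(back$signal), dim(rec$signal))
  expect_identical(back$signal, rec$signal)
  expect_equal(back$fs, 500)
  expect_true(back$raw_rhythm %in% c("SR", "SI"))
})

test_that("malformed record CSVs and unknown ids are rejected with context", {
  dir <- withr::local_tempdir()
  # 11 columns
  bad <- as.data.frame(matrix(rnorm(55), 5, 11))
  colnames(bad) <- ecg_leads()[1:11]
  utils::write.csv(bad, file.path(dir, "B1.csv"), row.names = FALSE)
  expect_error(read_ecg_csv(file.path(dir, "B1.csv")), "12 lead columns")
  # non-numeric cell
  ugly <- as.data.frame(matrix(rnorm(24), 2, 12))
  colnames(ugly) <- ecg_leads()
  ugly$V2 <- c("x", "y")
  utils::write.csv(ugly, file.path(dir, "B2.csv"), row.names = FALSE)
  expect_error(read_ecg_csv(file.path(dir, "B2.csv")), "V2")
  # id absent from manifest
  good <- make_flat_record(20)
  write_ecg_csv(good, file.path(dir, "FIX1.csv"))
  expect_error(
    read_ecg_csv(file.path(dir, "FIX1.csv"),
                 data.frame(record_id = "OTHER", raw_rhythm = "SB")),
    "not found in manifest")
})

test_that("stratified split honours 70/20/10 with remainder to test", {
  man <- tibble::tibble(
    record_id = sprintf("R%04d", 1:400),
    merged_class = rep(names(rhythm_classes()), each = 100))
  sp <- split_records(man, seed = 5)
  tab <- table(sp$merged_class, sp$split)
  expect_true(all(tab[, "train"] == 70))
  expect_true(all(tab[, "validation"] == 20))
  expect_true(all(tab[, "test"] == 10))

  # 101 ids in one class: floor rule sends the extra to test
  man2 <- tibble::tibble(
    record_id = sprintf("S%04d", 1:101),
    merged_class = "SB")
  man2 <- dplyr::bind_rows(man2, tibble::tibble(
    record_id = sprintf("T%04d", 1:30),
    merged_class = rep(c("AFIB", "GSVT", "SR"), each = 10)))
  sp2 <- split_records(man2, seed = 5)
  tab2 <- table(sp2$merged_class, sp2$split)
  expect_equal(unname(tab2["SB", c("train", "validation", "test")]),
               c(70, 20, 11), ignore_attr = TRUE)
})

test_that("splits are deterministic, disjoint, and exhaustive", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      n <- sample(12:60, 4)
      man <- tibble::tibble(
        record_id = sprintf("R%05d", seq_len(sum(n))),
        merged_class = rep(names(rhythm_classes()), times = n))
      s1 <- split_records(man, seed = rep)
      s2 <- split_records(man, seed = rep)
      expect_identical(s1, s2)
      ids <- split(s1$record_id, s1$split)
      expect_length(intersect(ids$train, ids$validation), 0)
      expect_length(intersect(ids$train, ids$test), 0)
      expect_length(intersect(ids$validation, ids$test), 0)
      expect_setequal(unlist(ids), man$record_id)
      s3 <- split_records(man, seed = rep + 1000)
      expect_false(identical(s1$split, s3$split))
    }
  })
})

test_that("splitting refuses classes too small to populate three splits", {
  man <- tibble::tibble(record_id = c("a", "b", "c", "d", "e"),
                        merged_class = c("SB", "SB", "SR", "SR", "SR"))
  expect_error(split_records(man, seed = 1), "fewer than 3")
  expect_error(split_records(man, fractions = c(0.5, 0.4, 0.2), seed = 1),
               "summing to 1")
})

test_that("deposit summary applies the usability filter and tallies classes", {
  ds <- simulate_dataset(3, seed = 77, duration = 4)
  # plant two unusable records
  ds$records[[1]]$signal["V5", ] <- 0
  ds$records[[6]]$signal["I", 3] <- NA
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  res <- summarise_deposit(dir, file.path(dir, "manifest.csv"))
  expect_equal(sum(res$summary$n_retained), 10)
  expect_equal(nrow(res$dropped), 2)
  expect_match(res$dropped$reason[res$dropped$record_id ==
                                    ds$records[[1]]$record_id], "V5")
  # class totals: one AFIB and one GSVT record were dropped
  tallies <- tibble::deframe(res$summary)
  expect_equal(unname(tallies[c("AFIB", "GSVT", "SB", "SR")]), c(2, 2, 3, 3))
})
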