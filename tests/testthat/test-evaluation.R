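test_that("the confusion matrix tallies true rows against predicted columns", {
  cm <- confusion_matrix(rep(0:3, each = 3), rep(0:3, each = 3))
  expect_equal(unname(diag(cm)), rep(3L, 4))
  expect_equal(sum(cm), 12)

  cm2 <- confusion_matrix(c(0, 0, 1, 2, 3), c(0, 1, 1, 2, 3))
  expect_equal(cm2["AFIB", "AFIB"], 1L, ignore_attr = TRUE)
  expect_equal(cm2["AFIB", "GSVT"], 1L, ignore_attr = TRUE)
  expect_equal(unname(diag(unclass(cm2))[2:4]), rep(1L, 3))

  expect_error(confusion_matrix(c(0, 1), c(0)), "equal length")
  expect_error(confusion_matrix(c(0, 5), c(0, 1)), "0..3")
})

test_that("row sums equal class supports on random label sets", {
  withr::with_seed(31, {
    for (i in 1:10) {
      y <- sample(0:3, 60, replace = TRUE)
      p <- sample(0:3, 60, replace = TRUE)
      cm <- confusion_matrix(y, p)
      expect_equal(unname(rowSums(cm)), unname(tabulate(y + 1, 4)))
      expect_equal(unname(colSums(cm)), unname(tabulate(p + 1, 4)))
    }
  })
})

test_that("per-class metrics match hand evaluation of the binary reductions", {
  # 40 records: class 0 has TP=8, FN=2 (to class 1), others perfect
  cm <- confusion_matrix(
    c(rep(0, 10), rep(1, 10), rep(2, 10), rep(3, 10)),
    c(rep(0, 8), 1, 1, rep(1, 10), rep(2, 10), rep(3, 10)))
  m <- class_metrics(cm)
  r0 <- m[m$class == "AFIB", ]
  # oracle from TP=8, FN=2, FP=0, TN=30
  expect_equal(r0$sensitivity, 80)
  expect_equal(r0$precision, 100)
  expect_equal(r0$specificity, 100)
  expect_equal(r0$f1, 2 * 100 * 80 / 180, tolerance = 1e-12)
  expect_equal(round_half_up(r0$f1, 2), 88.89)
  expect_equal(r0$accuracy, 100 * 38 / 40)
  r1 <- m[m$class == "GSVT", ]
  expect_equal(r1$precision, 100 * 10 / 12, tolerance = 1e-12)
  expect_equal(round_half_up(r1$precision, 2), 83.33)
})

test_that("a perfect classifier scores 100 on every metric", {
  cm <- confusion_matrix(rep(0:3, each = 5), rep(0:3, each = 5))
  m <- class_metrics(cm)
  expect_true(all(abs(as.matrix(m[, -1]) - 100) < 1e-12))
  ov <- overall_row(m)
  expect_true(all(abs(as.matrix(ov[, -1]) - 100) < 1e-12))
})

test_that("F1 equals 2TP / (2TP + FP + FN) computed independently", {
  withr::with_seed(17, {
    for (i in 1:10) {
      y <- sample(0:3, 80, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
      p <- ifelse(runif(80) < 0.7, y, sample(0:3, 80, replace = TRUE))
      cm <- confusion_matrix(y, p)
      m <- class_metrics(cm)
      for (k in 0:3) {
        ct <- ovr_counts(cm, k)
        f1_direct <- 100 * 2 * ct["TP"] / (2 * ct["TP"] + ct["FP"] + ct["FN"])
        expect_equal(m$f1[k + 1], unname(f1_direct), tolerance = 1e-9)
      }
    }
  })
})

test_that("macro one-vs-rest accuracy equals 1 - 2 errors / (4 n)", {
  withr::with_seed(23, {
    for (i in 1:8) {
      n <- 100
      y <- sample(0:3, n, replace = TRUE)
      p <- ifelse(runif(n) < 0.8, y, sample(0:3, n, replace = TRUE))
      cm <- confusion_matrix(y, p)
      m <- class_metrics(cm)
      errors <- sum(y != p)
      expect_equal(mean(m$accuracy) / 100, 1 - 2 * errors / (4 * n),
                   tolerance = 1e-12)
    }
  })
})

test_that("metrics are invariant under a joint permutation of classes", {
  withr::with_seed(41, {
    y <- sample(0:3, 120, replace = TRUE)
    p <- ifelse(runif(120) < 0.75, y, sample(0:3, 120, replace = TRUE))
  })
  cm <- confusion_matrix(y, p)
  m <- class_metrics(cm)
  perm <- c(2, 0, 3, 1)  # relabel classes
  y2 <- perm[y + 1]
  p2 <- perm[p + 1]
  m2 <- class_metrics(confusion_matrix(y2, p2))
  for (k in 0:3) {
    expect_equal(as.numeric(m[k + 1, -1]),
                 as.numeric(m2[perm[k + 1] + 1, -1]), tolerance = 1e-12)
  }
})

test_that("the overall row is the unweighted column mean and maps to itself on
           identical rows", {
  v <- tibble::tibble(class = names(rhythm_classes()),
                      sensitivity = 91.5, precision = 80, specificity = 99,
                      f1 = 85.3, accuracy = 94)
  ov <- overall_row(v)
  expect_equal(as.numeric(ov[, -1]), c(91.5, 80, 99, 85.3, 94))
  expect_error(overall_row(v[1:3, ]), "exactly 4")
})

test_that("empty class support warns rather than silently reporting zero", {
  cm <- confusion_matrix(c(0, 0, 1, 2), c(0, 0, 1, 2))  # SR absent
  expect_warning(m <- class_metrics(cm), "SR")
  expect_true(is.nan(m$sensitivity[4]))
})

test_that("model reports agree with brute-force recomputation from predictions", {
  data <- make_tiny_kd_data()
  fit <- train_teacher(data, tiny_teacher_spec(),
                       distill_config(alpha = 1, epochs = 2, batch_size = 8,
                                      seed = 7))
  ev <- evaluate_model(fit, data$test$x12, data$test$y)
  pred <- ev$predictions
  y <- data$test$y
  # bypass the confusion matrix entirely
  for (k in 0:3) {
    tp <- sum(pred == k & y == k); fn <- sum(pred != k & y == k)
    fp <- sum(pred == k & y != k); tn <- sum(pred != k & y != k)
    row <- ev$report[k + 1, ]
    expect_equal(row$sensitivity, 100 * tp / (tp + fn))
    expect_equal(row$precision, 100 * tp / (tp + fp))
    expect_equal(row$specificity, 100 * tn / (tn + fp))
    expect_equal(row$accuracy, 100 * (tp + tn) / length(y))
  }
  # internal consistency of the Overall row
  expect_equal(as.numeric(ev$report[5, -1]),
               colMeans(as.matrix(ev$report[1:4, -1])), ignore_attr = TRUE)
  expect_equal(ev$accuracy, 100 * mean(pred == y))
})

test_that("a constant predictor yields one full-sensitivity row and zeros elsewhere", {
  y <- rep(0:3, each = 4)
  pred <- rep(2, 16)  # always SB
  cm <- confusion_matrix(y, pred)
  m <- class_metrics(cm)
  expect_equal(m$sensitivity[3], 100)
  expect_equal(m$sensitivity[c(1, 2, 4)], rep(0, 3))
})

test_that("presentation rounding is half-up at 2 decimals", {
  expect_equal(round_half_up(94.435, 2), 94.44)
  expect_equal(round_half_up(91.495, 2), 91.50)
  expect_equal(round_half_up(97.4975, 2), 97.50)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-2.675, 2), -2.68)
  expect_equal(round_half_up(1.23449, 2), 1.23)
})
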