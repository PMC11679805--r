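test_that("temperature softmax matches direct evaluation", {
  # symmetry: equal logits give the uniform distribution at any temperature
  for (temp in c(0.5, 1, 4, 20)) {
    expect_equal(soften(rep(3.7, 4), temp), rep(0.25, 4))
  }
  # T = 1 reduces to the plain softmax
  z <- c(1.2, -0.3, 0.5, 2.0)
  expect_equal(soften(z, 1), exp(z) / sum(exp(z)), tolerance = 1e-12)
  # direct evaluation of the softened form at T = 2
  q <- soften(c(2, 0, 0, 0), 2)
  oracle <- exp(c(2, 0, 0, 0) / 2) / sum(exp(c(2, 0, 0, 0) / 2))
  expect_equal(q, oracle, tolerance = 1e-12)
  expect_equal(q, c(0.47537, 0.17488, 0.17488, 0.17488), tolerance = 1e-5)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  # overflow safety
  expect_equal(soften(c(1e4, 0, 0, 0), 1), c(1, 0, 0, 0))
  expect_error(soften(z, 0), "positive")
  expect_error(soften(c(Inf, 0, 0, 0), 1), "finite")
})

test_that("softened distributions get flatter as temperature rises", {
  entropy <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  withr::with_seed(10, {
    for (i in 1:20) {
      z <- rnorm(4, sd = 3)
      ent <- vapply(c(0.5, 1, 2, 4, 8, 16), function(temp) entropy(soften(z, temp)),
                    numeric(1))
      expect_true(all(diff(ent) >= -1e-12))
    }
  })
})

test_that("distillation loss is a KL divergence with the stated conventions", {
  # identical logits: zero at any temperature
  z <- c(0.4, -1, 2, 0)
  for (temp in c(1, 2, 4)) expect_equal(distill_loss(z, z, temp), 0)
  # 0 log 0 convention: point mass vs uniform gives log 4
  expect_equal(kl_divergence(c(1, 0, 0, 0), rep(0.25, 4)), log(4),
               tolerance = 1e-12)
  # flooring keeps the loss finite when the model assigns zero mass
  expect_true(is.finite(kl_divergence(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0))))
  # T^2 correction is an explicit opt-in factor
  z2 <- c(1, 0, -1, 0.5)
  expect_equal(distill_loss(z, z2, 4, t_squared = TRUE),
               16 * distill_loss(z, z2, 4))
})

test_that("the KL term is nonnegative over 1000 random logit pairs", {
  withr::with_seed(2024, {
    for (i in 1:1000) {
      a <- rnorm(4, sd = 2)
      b <- rnorm(4, sd = 2)
      expect_gte(distill_loss(a, b, temperature = runif(1, 0.5, 8)), 0)
    }
  })
})

test_that("cross-entropy matches direct evaluation and stays bounded", {
  expect_equal(cross_entropy_loss(0, c(1, 0, 0, 0)), 0)
  expect_equal(cross_entropy_loss(2, c(0.2, 0.2, 0.5, 0.1)), log(2),
               tolerance = 1e-12)
  # flooring: a zero probability yields -log(eps), not infinity
  expect_equal(cross_entropy_loss(1, c(1, 0, 0, 0)), -log(1e-12))
  # matrix form indexes row-wise
  p <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(cross_entropy_loss(c(0, 3), p), c(-log(0.7), log(4)),
               tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c("AFIB", "SR"), p), c(-log(0.7), log(4)),
               tolerance = 1e-12)
})

test_that("the total loss is the stated convex combination", {
  expect_equal(total_loss(0.6, 0.4, 1), 0.6)
  expect_equal(total_loss(0.6, 0.4, 0), 0.4)
  expect_equal(total_loss(0.6, 0.4, 0.5), 0.5)
  expect_error(total_loss(1, 1, 1.2), "\\[0, 1\\]")
  withr::with_seed(3, {
    for (i in 1:50) {
      ce <- runif(1, 0, 3); kd <- runif(1, 0, 3); a <- runif(1)
      tl <- total_loss(ce, kd, a)
      expect_gte(tl, min(ce, kd) - 1e-12)
      expect_lte(tl, max(ce, kd) + 1e-12)
    }
  })
})

test_that("the plateau schedule drops the rate after the stated patience", {
  # flat validation accuracy: x0.1 drop at the 11th epoch
  tr <- plateau_schedule(rep(0.5, 12), lr_init = 0.01, lr_patience = 10)
  expect_equal(tr$lr[1:10], rep(0.01, 10))
  expect_equal(tr$lr[11], 0.001)
  expect_false(any(diff(tr$lr) > 0))
  # improvement resets the counter
  acc <- c(0.5, 0.6, rep(0.6, 10))
  tr2 <- plateau_schedule(acc, lr_patience = 10)
  expect_equal(tr2$lr[11], 0.01)
  expect_equal(tr2$lr[12], 0.001)
  # repeated plateaus walk down to the floor and halt
  tr3 <- plateau_schedule(rep(0.3, 45), lr_init = 0.01, lr_min = 1e-5)
  expect_equal(min(tr3$lr), 1e-5)
  expect_true(any(tr3$halted))
})

test_that("configuration invariants are enforced", {
  expect_error(distill_config(temperature = 0), "> 0")
  expect_error(distill_config(alpha = 1.5), "\\[0, 1\\]")
  expect_error(distill_config(lr_init = 1e-6, lr_min = 1e-5), "below")
  cfg <- distill_config()
  expect_equal(cfg$epochs, 200L)
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$lr_init, 0.01)
  expect_equal(cfg$lr_min, 1e-5)
})

test_that("teacher training reduces the loss and is seed-deterministic", {
  data <- make_tiny_kd_data()
  cfg <- distill_config(alpha = 1, epochs = 3, batch_size = 8, seed = 7)
  fit1 <- train_teacher(data, tiny_teacher_spec(), cfg)
  expect_lt(fit1$log$train_loss[3], fit1$log$train_loss[1])
  expect_false(any(diff(fit1$log$lr) > 0))
  expect_lte(nrow(fit1$log), cfg$epochs)
  fit2 <- train_teacher(data, tiny_teacher_spec(), cfg)
  expect_identical(fit1$log, fit2$log)
  g <- glance(fit1)
  expect_equal(g$role, "teacher")
  expect_equal(g$epochs_run, 3L)
})

test_that("distillation trains the student only; the teacher stays bitwise frozen", {
  data <- make_tiny_kd_data()
  ns <- asNamespace("distillecg")
  tfit <- train_teacher(data, tiny_teacher_spec(),
                        distill_config(alpha = 1, epochs = 2, batch_size = 8,
                                       seed = 7))
  before <- ns$network_state(tfit$network)
  sfit <- distill_student(tfit, data, tiny_student_spec(),
                          distill_config(temperature = 4, alpha = 0.5,
                                         epochs = 3, batch_size = 8, seed = 9))
  after <- ns$network_state(tfit$network)
  expect_identical(before, after)
  expect_equal(sfit$role, "student")
  expect_lt(sfit$log$train_loss[3], sfit$log$train_loss[1])
  # training log tidies to one row per epoch
  expect_equal(nrow(tidy(sfit)), 3)
})

test_that("alpha = 1 reproduces plain hard-label training exactly", {
  data <- make_tiny_kd_data()
  cfg <- distill_config(alpha = 1, temperature = 4, epochs = 2,
                        batch_size = 8, seed = 13)
  tfit <- train_teacher(data, tiny_teacher_spec(),
                        distill_config(alpha = 1, epochs = 1, batch_size = 8,
                                       seed = 7))
  kd_off <- distill_student(tfit, data, tiny_student_spec(), cfg)
  # an adversarial teacher must make no difference when alpha = 1
  ns <- asNamespace("distillecg")
  sab <- build_teacher(tiny_teacher_spec(), seed = 999)
  kd_off2 <- distill_student(sab, data, tiny_student_spec(), cfg)
  expect_equal(kd_off$log, kd_off2$log, tolerance = 1e-12)
})

test_that("unpaired views are rejected", {
  data <- make_tiny_kd_data()
  tfit <- train_teacher(data, tiny_teacher_spec(),
                        distill_config(alpha = 1, epochs = 1, batch_size = 8,
                                       seed = 7))
  broken <- data
  broken$train$x1 <- broken$train$x1[, , -1, drop = FALSE]
  expect_error(distill_student(tfit, broken, tiny_student_spec(),
                               distill_config(epochs = 1, seed = 1)),
               "paired")
})
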