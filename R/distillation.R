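#' Temperature-scaled softmax (soft labels)
#'
#' `q_i = exp(z_i / T) / sum_j exp(z_j / T)`: the softened class distribution
#' a teacher produces from its logits. Computed with max subtraction so
#' large logits never overflow. `T = 1` reduces to the ordinary softmax;
#' larger temperatures flatten the distribution.
#'
#' @param logits numeric vector of logits, or a matrix with one sample per
#'   row.
#' @param temperature positive scalar `T`.
#' @return probability vector (or matrix, row per sample) summing to 1.
#' @export
#' @examples
#' soften(c(2, 0, 0, 0), temperature = 2)
soften <- function(logits, temperature = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    abort_param("`temperature` must be a single positive number")
  }
  if (!all(is.finite(logits))) abort_param("logits must be finite")
  if (is.matrix(logits)) return(softmax_rows(logits, temperature))
  z <- logits / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' `KL(q || p) = sum_i q_i log(q_i / p_i)` with the `0 log 0 = 0` convention;
#' `p` is floored at `eps` so the divergence stays finite when the model
#' assigns zero mass where the reference does not.
#'
#' @param q,p probability vectors (or matrices, row per sample).
#' @param eps probability floor.
#' @return nonnegative scalar (or vector, one value per row).
#' @export
kl_divergence <- function(q, p, eps = 1e-12) {
  if (is.matrix(q)) {
    terms <- ifelse(q > 0, q * (log(q) - log(pmax(p, eps))), 0)
    return(rowSums(terms))
  }
  sum(ifelse(q > 0, q * (log(q) - log(pmax(p, eps))), 0))
}

#' Distillation loss
#'
#' KL divergence from the student's temperature-softened distribution to the
#' teacher's: `KL(q^T || p^T)` where `q^T = soften(teacher logits, T)` and
#' `p^T = soften(student logits, T)`. Implemented literally as printed;
#' `t_squared` optionally multiplies by `T^2`, the conventional correction
#' that keeps soft-gradient magnitudes comparable across temperatures.
#'
#' @param teacher_logits,student_logits logit vectors (or matrices, row per
#'   sample).
#' @param temperature positive scalar `T`.
#' @param t_squared multiply the loss by `T^2` (default `FALSE`).
#' @return nonnegative scalar (or vector per sample).
#' @export
distill_loss <- function(teacher_logits, student_logits, temperature = 1,
                         t_squared = FALSE) {
  q <- soften(teacher_logits, temperature)
  p <- soften(student_logits, temperature)
  kl <- kl_divergence(q, p)
  if (t_squared) kl <- kl * temperature^2
  kl
}

#' Hard-label cross-entropy
#'
#' `-sum_i y_i log(p_i)` with one-hot truth: `-log p_y`, probabilities
#' floored at `eps` so the loss stays bounded.
#'
#' @param true_class integer class code(s) 0..3 or class label(s).
#' @param student_probs probability vector (or matrix, row per sample).
#' @param eps probability floor.
#' @return nonnegative scalar (or vector per sample).
#' @export
cross_entropy_loss <- function(true_class, student_probs, eps = 1e-12) {
  codes <- as_class_code(true_class)
  if (is.matrix(student_probs)) {
    py <- student_probs[cbind(seq_len(nrow(student_probs)), codes + 1L)]
  } else {
    py <- student_probs[codes + 1L]
  }
  -log(pmax(py, eps))
}

#' Combined distillation objective
#'
#' `L_total = alpha * L_CE + (1 - alpha) * L_distill`: a convex combination
#' of the hard-label and soft-label losses. `alpha = 1` is plain supervised
#' training; `alpha = 0` is pure distillation.
#'
#' @param ce cross-entropy loss value(s).
#' @param kd distillation loss value(s).
#' @param alpha weight in `[0, 1]`.
#' @return combined loss.
#' @export
total_loss <- function(ce, kd, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    abort_param("`alpha` must be a single number in [0, 1]")
  }
  alpha * ce + (1 - alpha) * kd
}

# accept labels or codes; return 0-based integer codes
as_class_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(x < 0 | x > 3)) abort_param("class codes must lie in 0..3")
    return(x)
  }
  cls <- rhythm_classes()
  idx <- match(as.character(x), names(cls))
  if (anyNA(idx)) {
    abort_param("unknown class label(s): %s",
                paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  unname(cls[idx])
}

#' Distillation / training configuration
#'
#' All knowledge-distillation and optimisation hyperparameters. The
#' optimisation schedule is: Adam, batch size 64, initial learning rate
#' 0.01, reduced by `lr_factor` whenever validation accuracy has not
#' improved for `lr_patience` consecutive epochs; training halts at the
#' epoch budget or once the rate would fall below `lr_min`.
#'
#' @param temperature softening temperature `T` (> 0).
#' @param alpha hard-label weight in `[0, 1]`.
#' @param t_squared_correction multiply the distillation term by `T^2`.
#' @param epochs epoch budget.
#' @param batch_size minibatch size.
#' @param lr_init,lr_min,lr_factor,lr_patience plateau schedule.
#' @param seed master seed for weight init and batch shuffling.
#' @return a `distill_config` list.
#' @export
distill_config <- function(temperature = 4, alpha = 0.5,
                           t_squared_correction = FALSE,
                           epochs = 200, batch_size = 64,
                           lr_init = 0.01, lr_min = 1e-5, lr_factor = 0.1,
                           lr_patience = 10, seed = 1L) {
  if (temperature <= 0) abort_param("`temperature` must be > 0")
  if (alpha < 0 || alpha > 1) abort_param("`alpha` must lie in [0, 1]")
  if (lr_min >= lr_init) abort_param("`lr_min` must be below `lr_init`")
  structure(list(temperature = temperature, alpha = alpha,
                 t_squared_correction = t_squared_correction,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_min = lr_min, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 seed = as.integer(seed)),
            class = "distill_config")
}

#' Reduce-on-plateau learning-rate trace
#'
#' Pure reference implementation of the schedule: given a validation
#' accuracy sequence, returns the learning rate in force at each epoch and
#' whether training halts early (the reduced rate would fall below
#' `lr_min`).
#'
#' @param val_acc numeric vector of per-epoch validation accuracies.
#' @param lr_init,lr_factor,lr_patience,lr_min schedule parameters.
#' @return tibble: `epoch`, `val_acc`, `lr`, `halted`.
#' @export
#' @examples
#' plateau_schedule(rep(0.5, 12))$lr
plateau_schedule <- function(val_acc, lr_init = 0.01, lr_factor = 0.1,
                             lr_patience = 10, lr_min = 1e-5) {
  lr <- lr_init
  best <- -Inf
  wait <- 0L
  n <- length(val_acc)
  lrs <- numeric(n)
  halted <- logical(n)
  for (e in seq_len(n)) {
    if (val_acc[e] > best + 1e-12) {
      best <- val_acc[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= lr_patience) {
      new_lr <- lr * lr_factor
      wait <- 0L
      if (new_lr < lr_min) {
        halted[e] <- TRUE
      } else {
        lr <- new_lr
      }
    }
    lrs[e] <- lr
    if (halted[e] && e < n) {
      lrs[(e + 1):n] <- lr
      halted[(e + 1):n] <- TRUE
      break
    }
  }
  tibble::tibble(epoch = seq_len(n), val_acc = val_acc, lr = lrs,
                 halted = halted)
}

# ---- shared optimisation loop ----------------------------------------------
#
# grad_fn(logits, idx) must return list(loss = scalar, dlogits = matrix):
# the mean batch loss and its gradient w.r.t. the logits. `idx` indexes the
# batch samples within the training arrays.
fit_network <- function(net, x_tr, y_tr, x_va, y_va, config, grad_fn) {
  n <- dim(x_tr)[3]
  state <- adam_state(net)
  lr <- config$lr_init
  best_acc <- -Inf
  best_params <- NULL
  best_epoch <- NA_integer_
  wait <- 0L
  step <- 0L
  log_rows <- list()
  stop_reason <- "epoch budget reached"
  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(derive_seed(config$seed, 1000L + epoch),
                            sample.int(n))
    batch_starts <- seq(1, n, by = config$batch_size)
    tr_loss <- 0
    tr_correct <- 0
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
      xb <- x_tr[, , idx, drop = FALSE]
      logits <- network_forward(net, xb, training = TRUE)
      g <- grad_fn(logits, idx)
      network_backward(net, g$dlogits)
      step <- step + 1L
      state <- adam_step(net, state, lr, step)
      tr_loss <- tr_loss + g$loss * length(idx)
      tr_correct <- tr_correct +
        sum(max.col(logits, ties.method = "first") - 1L == y_tr[idx])
    }
    ev <- evaluate_logits(net, x_va, y_va, config$batch_size)
    val_acc <- ev$accuracy
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr,
      train_loss = tr_loss / n, train_acc = tr_correct / n,
      val_loss = ev$loss, val_acc = val_acc)
    if (val_acc > best_acc + 1e-12) {
      best_acc <- val_acc
      best_params <- network_state(net)
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= config$lr_patience) {
      new_lr <- lr * config$lr_factor
      wait <- 0L
      if (new_lr < config$lr_min) {
        stop_reason <- "learning rate reached its minimum"
        break
      }
      lr <- new_lr
    }
  }
  if (!is.null(best_params)) network_set_state(net, best_params)
  list(log = dplyr::bind_rows(log_rows), best_epoch = best_epoch,
       stop_reason = stop_reason)
}

# mean CE loss and accuracy of a network on (x, y), evaluated in inference
# mode batch by batch
evaluate_logits <- function(net, x, y, batch_size = 64L) {
  n <- dim(x)[3]
  loss <- 0
  correct <- 0
  preds <- integer(n)
  for (bs in seq(1, n, by = batch_size)) {
    idx <- bs:min(bs + batch_size - 1L, n)
    logits <- network_forward(net, x[, , idx, drop = FALSE], training = FALSE)
    p <- softmax_rows(logits)
    loss <- loss + sum(cross_entropy_loss(y[idx], p))
    preds[idx] <- max.col(logits, ties.method = "first") - 1L
    correct <- correct + sum(preds[idx] == y[idx])
  }
  list(loss = loss / n, accuracy = correct / n, predictions = preds)
}

# ---- data marshalling -------------------------------------------------------

#' Stack preprocessed records into model tensors
#'
#' Builds the paired views the distillation protocol needs from a list of
#' preprocessed records and a split table: the 12-lead arrays for the
#' teacher, the lead II arrays for the student, and the integer class codes,
#' for each of the train/validation/test splits.
#'
#' @param records list of preprocessed 12-lead [ecg_record()]s with
#'   `merged_class` set.
#' @param split tibble from [split_records()].
#' @return list of lists (`train`, `validation`, `test`), each holding
#'   `x12` (12 x L x n), `x1` (1 x L x n), `y` (codes 0..3), `ids`.
#' @export
kd_data <- function(records, split) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  out <- list()
  for (sp in levels(split$split)) {
    want <- split$record_id[split$split == sp]
    sel <- records[match(want, ids)]
    if (anyNA(match(want, ids))) abort_param("split refers to unknown record ids")
    L <- ncol(sel[[1]]$signal)
    x12 <- array(0, c(nrow(sel[[1]]$signal), L, length(sel)))
    for (i in seq_along(sel)) x12[, , i] <- sel[[i]]$signal
    x1 <- x12["II" == rownames(sel[[1]]$signal), , , drop = FALSE] |>
      array(c(1, L, length(sel)))
    y <- as_class_code(vapply(sel, function(r) r$merged_class, character(1)))
    out[[sp]] <- list(x12 = x12, x1 = x1, y = y, ids = want)
  }
  out
}

# ---- training entry points --------------------------------------------------

#' Train the teacher on 12-lead data
#'
#' Supervised training with the hard-label cross-entropy objective and the
#' plateau-scheduled Adam optimiser; the weights from the best-validation
#' epoch (ties to the earliest) are returned.
#'
#' @param data result of [kd_data()] (uses `train` and `validation`).
#' @param spec a [teacher_spec()]; its `input` is aligned with the data.
#' @param config a [distill_config()].
#' @return an `ecg_fit`: list with `network`, `log` (tibble), `best_epoch`,
#'   `stop_reason`, `config`, `role = "teacher"`.
#' @export
train_teacher <- function(data, spec = teacher_spec(), config = distill_config()) {
  if (length(data$train$y) == 0) abort_param("empty training split")
  spec$input <- dim(data$train$x12)[1:2]
  net <- build_teacher(spec, seed = derive_seed(config$seed, 11L))
  grad_fn <- function(logits, idx) {
    p <- softmax_rows(logits)
    y <- data$train$y[idx]
    loss <- mean(cross_entropy_loss(y, p))
    d <- p
    d[cbind(seq_along(idx), y + 1L)] <- d[cbind(seq_along(idx), y + 1L)] - 1
    list(loss = loss, dlogits = d / length(idx))
  }
  res <- fit_network(net, data$train$x12, data$train$y,
                     data$validation$x12, data$validation$y, config, grad_fn)
  structure(list(network = net, log = res$log, best_epoch = res$best_epoch,
                 stop_reason = res$stop_reason, config = config,
                 role = "teacher"),
            class = "ecg_fit")
}

#' Distill the student from a frozen teacher
#'
#' The teacher (frozen, inference mode — batch-norm uses running statistics,
#' so each record's soft label is deterministic) consumes the paired 12-lead
#' view; the student consumes the lead II view. The combined objective
#' `alpha * CE(hard labels) + (1 - alpha) * KL(teacher soft || student soft)`
#' is backpropagated into the student only. With `alpha = 1` the teacher
#' term vanishes and training is plain hard-label supervision (the no-KD
#' baseline).
#'
#' @param teacher a trained teacher `ecg_fit` (or bare `ecg_network`).
#' @param data result of [kd_data()]; the 12-lead and lead II views are
#'   paired per record.
#' @param spec a [student_spec()].
#' @param config a [distill_config()].
#' @return an `ecg_fit` with `role = "student"`.
#' @export
distill_student <- function(teacher, data, spec = student_spec(),
                            config = distill_config()) {
  net_t <- if (inherits(teacher, "ecg_fit")) teacher$network else teacher
  if (length(data$train$y) == 0) abort_param("empty training split")
  if (dim(data$train$x12)[3] != dim(data$train$x1)[3]) {
    abort_param("12-lead and lead II views are not paired")
  }
  spec$input <- dim(data$train$x1)[1:2]
  student <- build_student(spec, seed = derive_seed(config$seed, 23L))
  # teacher is frozen: soft labels precomputed once in inference mode
  n <- dim(data$train$x12)[3]
  t_logits <- matrix(0, n, 4)
  for (bs in seq(1, n, by = config$batch_size)) {
    idx <- bs:min(bs + config$batch_size - 1L, n)
    t_logits[idx, ] <- network_forward(net_t, data$train$x12[, , idx, drop = FALSE],
                                       training = FALSE)
  }
  if (ncol(t_logits) != 4) abort_param("teacher output dimension must be 4")
  soft <- soften(t_logits, config$temperature)
  Tt <- config$temperature
  al <- config$alpha
  grad_fn <- function(logits, idx) {
    p <- softmax_rows(logits)
    y <- data$train$y[idx]
    ce <- mean(cross_entropy_loss(y, p))
    pT <- softmax_rows(logits, Tt)
    q <- soft[idx, , drop = FALSE]
    kd <- mean(kl_divergence(q, pT))
    scale <- if (config$t_squared_correction) Tt^2 else 1
    loss <- total_loss(ce, kd * scale, al)
    dce <- p
    dce[cbind(seq_along(idx), y + 1L)] <- dce[cbind(seq_along(idx), y + 1L)] - 1
    dkd <- (pT - q) / Tt * scale
    list(loss = loss,
         dlogits = (al * dce + (1 - al) * dkd) / length(idx))
  }
  res <- fit_network(student, data$train$x1, data$train$y,
                     data$validation$x1, data$validation$y, config, grad_fn)
  structure(list(network = student, log = res$log, best_epoch = res$best_epoch,
                 stop_reason = res$stop_reason, config = config,
                 role = "student", teacher = net_t),
            class = "ecg_fit")
}

#' @export
print.ecg_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<ecg_fit> %s: %d epoch(s), best validation accuracy %.3f (epoch %d)\n",
              x$role, nrow(x$log), max(x$log$val_acc), x$best_epoch))
  cat(sprintf("  stop: %s; final lr %g\n", x$stop_reason, last$lr))
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object an `ecg_fit` or `ecg_network`.
#' @param x a (leads x samples x n) array, a single record, or a list of
#'   records (lead-matched to the model).
#' @param type "class" (0..3 codes), "label", "prob", or "logits".
#' @param batch_size evaluation batch size.
#' @param ... unused.
#' @return vector or matrix of predictions.
#' @export
predict.ecg_fit <- function(object, x, type = c("class", "label", "prob", "logits"),
                            batch_size = 64L, ...) {
  type <- match.arg(type)
  net <- if (inherits(object, "ecg_fit")) object$network else object
  if (inherits(x, "ecg_record")) x <- list(x)
  if (is.list(x)) {
    L <- ncol(x[[1]]$signal)
    arr <- array(0, c(net$input_shape[1], L, length(x)))
    for (i in seq_along(x)) {
      s <- x[[i]]$signal
      if (nrow(s) != net$input_shape[1] && net$input_shape[1] == 1) {
        s <- s["II", , drop = FALSE]
      }
      arr[, , i] <- s
    }
    x <- arr
  }
  n <- dim(x)[3]
  out <- matrix(0, n, 4)
  for (bs in seq(1, n, by = batch_size)) {
    idx <- bs:min(bs + batch_size - 1L, n)
    out[idx, ] <- network_forward(net, x[, , idx, drop = FALSE],
                                  training = FALSE)
  }
  switch(type,
    logits = out,
    prob = softmax_rows(out),
    class = max.col(out, ties.method = "first") - 1L,
    label = names(rhythm_classes())[max.col(out, ties.method = "first")]
  )
}

#' @rdname predict.ecg_fit
#' @export
predict_logits <- function(object, x, batch_size = 64L) {
  predict.ecg_fit(object, x, type = "logits", batch_size = batch_size)
}

#' Tidy a fitted model's training log
#'
#' @param x an `ecg_fit`.
#' @param ... unused.
#' @return tibble: epoch, lr, train_loss, train_acc, val_loss, val_acc.
#' @method tidy ecg_fit
#' @export
tidy.ecg_fit <- function(x, ...) x$log

#' One-row summary of a fitted model
#'
#' @param x an `ecg_fit`.
#' @param ... unused.
#' @return tibble: role, epochs_run, best_epoch, best_val_acc, final_lr,
#'   parameters, stop_reason.
#' @method glance ecg_fit
#' @export
glance.ecg_fit <- function(x, ...) {
  tibble::tibble(
    role = x$role,
    epochs_run = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_acc = max(x$log$val_acc),
    final_lr = x$log$lr[nrow(x$log)],
    parameters = count_parameters(x$network),
    stop_reason = x$stop_reason
  )
}

#' Plot training curves
#'
#' Accuracy and loss per epoch for the training and validation sets.
#'
#' @param object an `ecg_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ecg_fit
#' @export
autoplot.ecg_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log,
                            cols = c("train_loss", "train_acc",
                                     "val_loss", "val_acc"),
                            names_to = c("set", "metric"), names_sep = "_")
  df$metric <- ifelse(df$metric == "acc", "accuracy", "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
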