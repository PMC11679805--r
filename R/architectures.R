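#' Teacher architecture specification
#'
#' Declarative description of the 12-lead teacher: a stem convolution, four
#' residual blocks (two conv+batch-norm layers each, squeeze-and-excitation
#' recalibration, identity/projection shortcut), two LSTM layers for
#' sequence modelling, and a fully connected softmax head over the four
#' rhythm classes. Ablation flags remove one mechanism at a time:
#' `no_resnet` swaps the residual blocks for plain stacked convolutions of
#' matched depth (shortcuts and SE removed), `no_lstm` replaces the
#' recurrent stage with global average pooling, `no_se` drops the SE gates.
#'
#' @param stem_ch,stem_kernel,stem_stride stem convolution shape.
#' @param block_channels output channels of the 4 residual blocks.
#' @param block_kernel,block_stride residual-block conv kernel and entry
#'   stride.
#' @param se_reduction SE bottleneck reduction ratio.
#' @param lstm_hidden LSTM hidden units (2 layers).
#' @param n_classes output classes (4).
#' @param input c(leads, samples) consumed by the network.
#' @param no_resnet,no_lstm,no_se ablation switches.
#' @return a `teacher_spec` list.
#' @export
teacher_spec <- function(stem_ch = 32, stem_kernel = 15, stem_stride = 2,
                         block_channels = c(32, 64, 64, 128),
                         block_kernel = 7, block_stride = 2,
                         se_reduction = 8, lstm_hidden = 64,
                         n_classes = 4, input = c(12, 2500),
                         no_resnet = FALSE, no_lstm = FALSE, no_se = FALSE) {
  if (!no_resnet && length(block_channels) != 4) {
    abort_param("the teacher has exactly 4 residual blocks; `block_channels` must have length 4")
  }
  structure(
    list(stem_ch = stem_ch, stem_kernel = stem_kernel,
         stem_stride = stem_stride, block_channels = block_channels,
         block_kernel = block_kernel, block_stride = block_stride,
         se_reduction = se_reduction, lstm_hidden = lstm_hidden,
         n_lstm = 2L, n_classes = n_classes, input = input,
         no_resnet = no_resnet, no_lstm = no_lstm, no_se = no_se),
    class = "teacher_spec")
}

#' Student architecture specification
#'
#' The lightweight single-lead classifier: exactly two convolutional layers
#' (each followed by ReLU and max-pooling), a flatten, one fully connected
#' layer, and a softmax over the four classes.
#'
#' @param conv1,conv2 lists with `ch`, `kernel`, `stride`, `pool`.
#' @param n_classes output classes (4).
#' @param input c(1, samples).
#' @return a `student_spec` list.
#' @export
student_spec <- function(conv1 = list(ch = 8, kernel = 7, stride = 4, pool = 2),
                         conv2 = list(ch = 16, kernel = 5, stride = 4, pool = 2),
                         n_classes = 4, input = c(1, 2500)) {
  structure(list(conv1 = conv1, conv2 = conv2, n_classes = n_classes,
                 input = input),
            class = "student_spec")
}

#' Build the teacher network
#'
#' @param spec a [teacher_spec()].
#' @param seed optional integer seed for weight initialisation.
#' @return an `ecg_network`.
#' @export
build_teacher <- function(spec = teacher_spec(), seed = NULL) {
  build <- function() {
    layers <- list(
      layer_conv1d(spec$input[1], spec$stem_ch, spec$stem_kernel,
                   spec$stem_stride),
      layer_batchnorm(spec$stem_ch),
      layer_relu()
    )
    in_ch <- spec$stem_ch
    for (out_ch in spec$block_channels) {
      if (spec$no_resnet) {
        # matched-depth plain stack: two convs per stage, no shortcut, no SE
        layers <- c(layers, list(
          layer_conv1d(in_ch, out_ch, spec$block_kernel, spec$block_stride),
          layer_batchnorm(out_ch), layer_relu(),
          layer_conv1d(out_ch, out_ch, spec$block_kernel, 1L),
          layer_batchnorm(out_ch), layer_relu()
        ))
      } else {
        layers <- c(layers, list(
          layer_resblock(in_ch, out_ch, spec$block_kernel, spec$block_stride,
                         use_se = !spec$no_se,
                         se_reduction = spec$se_reduction)
        ))
      }
      in_ch <- out_ch
    }
    if (spec$no_lstm) {
      layers <- c(layers, list(
        layer_meanpool_time(),
        layer_dense(in_ch, spec$n_classes)
      ))
    } else {
      layers <- c(layers, list(
        layer_lstm(in_ch, spec$lstm_hidden),
        layer_lstm(spec$lstm_hidden, spec$lstm_hidden),
        layer_take_last(),
        layer_dense(spec$lstm_hidden, spec$n_classes)
      ))
    }
    layers[[1]]$skip_input_grad <- TRUE  # stem: no upstream layer
    net <- new_network(layers, spec$input, name = "teacher")
    net$spec <- spec
    net
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Build the student network
#'
#' @param spec a [student_spec()].
#' @param seed optional integer seed for weight initialisation.
#' @return an `ecg_network` exposing pre-softmax logits from
#'   [predict_logits()].
#' @export
build_student <- function(spec = student_spec(), seed = NULL) {
  build <- function() {
    L <- spec$input[2]
    c1 <- spec$conv1; c2 <- spec$conv2
    L1 <- conv_out_len(L, c1$kernel, c1$stride, c1$kernel %/% 2) %/% c1$pool
    L2 <- conv_out_len(L1, c2$kernel, c2$stride, c2$kernel %/% 2) %/% c2$pool
    flat <- L2 * c2$ch
    if (flat < 1) abort_param("input length %d collapses to nothing before the fully connected layer", L)
    layers <- list(
      layer_conv1d(spec$input[1], c1$ch, c1$kernel, c1$stride),
      layer_relu(),
      layer_maxpool(c1$pool),
      layer_conv1d(c1$ch, c2$ch, c2$kernel, c2$stride),
      layer_relu(),
      layer_maxpool(c2$pool),
      layer_flatten(),
      layer_dense(flat, spec$n_classes)
    )
    layers[[1]]$skip_input_grad <- TRUE  # stem: no upstream layer
    net <- new_network(layers, spec$input, name = "student")
    net$spec <- spec
    net
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (conv kernels and biases, batch-norm
#' scale/shift, SE and dense weights, LSTM gate matrices).
#'
#' @param model an `ecg_network`.
#' @return integer scalar.
#' @export
count_parameters <- function(model) {
  sum(vapply(network_parameters(model), length, numeric(1)))
}

# MACs and output length for one primitive layer at input length L
layer_macs <- function(ly, L) {
  switch(ly$type,
    conv1d = {
      Lo <- conv_out_len(L, ly$kernel, ly$stride, ly$pad)
      list(macs = Lo * ly$out_ch * ly$in_ch * ly$kernel, L = Lo)
    },
    batchnorm = list(macs = 0, L = L),
    relu = list(macs = 0, L = L),
    maxpool = list(macs = 0, L = L %/% ly$size),
    se = list(macs = ly$ch * ly$hid + ly$hid * ly$ch, L = L),
    lstm = list(macs = L * 4 * ly$hidden * (ly$in_ch + ly$hidden), L = L),
    take_last = list(macs = 0, L = 1L),
    meanpool_time = list(macs = 0, L = 1L),
    flatten = list(macs = 0, L = 1L),
    dense = list(macs = ly$in_dim * ly$out_dim, L = L),
    resblock = {
      main <- 0
      Lm <- L
      for (sub in list(ly$conv1, ly$bn1, ly$conv2, ly$bn2, ly$se)) {
        if (is.null(sub)) next
        r <- layer_macs(sub, Lm)
        main <- main + r$macs
        Lm <- r$L
      }
      if (ly$project) main <- main + layer_macs(ly$shortcut, L)$macs
      list(macs = main, L = Lm)
    },
    abort_param("unknown layer type '%s'", ly$type)
  )
}

#' Count multiply-accumulate operations per forward pass
#'
#' Sums per-layer MAC counts at a given input length: convolution
#' `out_len x out_ch x in_ch x kernel`, dense `in x out`, LSTM per-step gate
#' arithmetic times steps, SE bottleneck as two dense layers. Element-wise
#' work (batch-norm, ReLU, pooling) is not counted, following the usual
#' hardware-profiling convention.
#'
#' @param model an `ecg_network`.
#' @param input_len samples per lead (default: the model's declared input).
#' @return numeric scalar (one record, one forward pass).
#' @export
count_macs <- function(model, input_len = NULL) {
  input_len <- input_len %||% model$input_shape[2]
  if (is.null(input_len) || is.na(input_len)) {
    abort_param("input length unknown; pass `input_len` explicitly")
  }
  L <- input_len
  total <- 0
  for (ly in model$layers) {
    r <- layer_macs(ly, L)
    total <- total + r$macs
    L <- r$L
  }
  total
}

#' Compression ratio between two models
#'
#' Reference (teacher) parameter count divided by subject (student)
#' parameter count.
#'
#' @param reference,subject `ecg_network` objects.
#' @return positive real.
#' @export
compression_ratio <- function(reference, subject) {
  ns <- count_parameters(subject)
  if (ns == 0) abort_param("subject model has no parameters")
  count_parameters(reference) / ns
}

#' Per-layer complexity report
#'
#' @param model an `ecg_network`.
#' @param input_len samples per lead.
#' @return tibble: `layer`, `type`, `parameters`, `macs`, `out_len`.
#' @export
complexity_report <- function(model, input_len = NULL) {
  input_len <- input_len %||% model$input_shape[2]
  L <- input_len
  rows <- list()
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    r <- layer_macs(ly, L)
    prim <- walk_layers(list(ly))
    npar <- sum(vapply(prim, function(p) {
      sum(vapply(p$param_names, function(nm) length(p[[nm]]), numeric(1)), 0)
    }, numeric(1)))
    rows[[i]] <- tibble::tibble(
      layer = sprintf("%02d_%s", i, ly$type), type = ly$type,
      parameters = npar, macs = r$macs, out_len = r$L)
    L <- r$L
  }
  dplyr::bind_rows(rows)
}

# counts of primitive/composite structural elements, used by tests and print
model_structure <- function(model) {
  types <- vapply(model$layers, function(l) l$type, character(1))
  prim_types <- vapply(walk_layers(model$layers), function(l) l$type,
                       character(1))
  list(top = table(types), primitive = table(prim_types))
}
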