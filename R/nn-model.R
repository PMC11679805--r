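# Sequential model container over the native layers, with Adam and the
# utilities (parameter walking, forward in train/eval mode) the training
# loops and complexity profiler share.

new_network <- function(layers, input_shape, name = "network") {
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$input_shape <- input_shape  # c(leads, samples)
  net$name <- name
  class(net) <- "ecg_network"
  net
}

#' @export
print.ecg_network <- function(x, ...) {
  cat(sprintf("<ecg_network> %s: input %d x %d, %s parameters\n",
              x$name, x$input_shape[1], x$input_shape[2],
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# depth-first walk over all primitive layers (composites contribute children)
walk_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (length(ly$children) > 0) {
      out <- c(out, walk_layers(ly$children))
    } else {
      out <- c(out, list(ly))
    }
  }
  out
}

# Forward a (leads, samples, batch) array through the network.
# Returns the final (batch x n_out) matrix (logits for the classifiers).
network_forward <- function(net, x, training = FALSE) {
  stopifnot(length(dim(x)) == 3)
  C <- dim(x)[1]; L <- dim(x)[2]; B <- dim(x)[3]
  if (C != net$input_shape[1]) {
    abort_param("%s expects %d lead(s), got %d", net$name,
                net$input_shape[1], C)
  }
  m <- aperm(x, c(2, 3, 1))                 # (L, B, C)
  dim(m) <- c(L * B, C)
  act <- list(m = m, L = L, B = B)
  for (ly in net$layers) act <- ly$forward(act, training)
  act$m
}

# Backpropagate d(loss)/d(logits); gradients accumulate into the layers.
network_backward <- function(net, dlogits) {
  d <- dlogits
  for (ly in rev(net$layers)) d <- ly$backward(d)
  invisible(NULL)
}

# ---- parameter access -------------------------------------------------------

# named flat list of parameter arrays (copies)
network_parameters <- function(net) {
  prim <- walk_layers(net$layers)
  out <- list()
  for (i in seq_along(prim)) {
    ly <- prim[[i]]
    for (nm in ly$param_names) {
      out[[sprintf("L%02d_%s_%s", i, ly$type, nm)]] <- ly[[nm]]
    }
  }
  out
}

network_set_parameters <- function(net, params) {
  prim <- walk_layers(net$layers)
  k <- 0
  for (i in seq_along(prim)) {
    ly <- prim[[i]]
    for (nm in ly$param_names) {
      k <- k + 1
      ly[[nm]] <- params[[k]]
    }
  }
  invisible(net)
}

# non-trainable state that must travel with a weight snapshot (batch-norm
# running statistics)
layer_buffer_names <- function(ly) {
  if (ly$type == "batchnorm") c("running_mean", "running_var") else character(0)
}

# full state snapshot: trainable parameters plus buffers
network_state <- function(net) {
  prim <- walk_layers(net$layers)
  out <- list()
  for (i in seq_along(prim)) {
    ly <- prim[[i]]
    for (nm in c(ly$param_names, layer_buffer_names(ly))) {
      out[[sprintf("L%02d_%s_%s", i, ly$type, nm)]] <- ly[[nm]]
    }
  }
  out
}

network_set_state <- function(net, state) {
  prim <- walk_layers(net$layers)
  k <- 0
  for (i in seq_along(prim)) {
    ly <- prim[[i]]
    for (nm in c(ly$param_names, layer_buffer_names(ly))) {
      k <- k + 1
      ly[[nm]] <- state[[k]]
    }
  }
  invisible(net)
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(net) {
  prim <- walk_layers(net$layers)
  lapply(prim, function(ly) {
    lapply(stats::setNames(ly$param_names, ly$param_names), function(nm) {
      list(m = array(0, dim(as.array(ly[[nm]])) %||% length(ly[[nm]])),
           v = array(0, dim(as.array(ly[[nm]])) %||% length(ly[[nm]])))
    })
  })
}

adam_step <- function(net, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  prim <- walk_layers(net$layers)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(prim)) {
    ly <- prim[[i]]
    for (nm in ly$param_names) {
      g <- ly[[paste0("g", nm)]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      ly[[nm]] <- ly[[nm]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[nm]] <- st
    }
  }
  state
}

# ---- softmax ----------------------------------------------------------------

# row-wise softmax with max subtraction; `temperature` divides the logits
softmax_rows <- function(z, temperature = 1) {
  z <- z / temperature
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
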