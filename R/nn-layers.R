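# Native neural-network layers.
#
# Every layer is an environment with:
#   $type         layer kind
#   $param_names  fields holding trainable arrays (gradients in g<name>)
#   $forward(act, training)  act = list(m, L, B): m is an (L*B x C) matrix
#                            whose rows run over time fastest, then batch
#   $backward(dm) -> gradient w.r.t. the input matrix, same layout
#   $children     sub-layers (composite layers only)
#
# Activations between temporal layers are kept as (L*B x C) matrices so that
# convolutions become one im2col gather plus one BLAS GEMM; head layers
# (flatten / last-step / pooled) emit plain (B x C) matrices (L = 1).

new_layer <- function(type) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  ly$param_names <- character(0)
  ly$children <- list()
  ly
}

init_matrix <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# ---- 1-D convolution (stride, zero 'same'-style padding) --------------------

conv_out_len <- function(L, kernel, stride, pad) {
  (L + 2 * pad - kernel) %/% stride + 1L
}

layer_conv1d <- function(in_ch, out_ch, kernel, stride = 1L,
                         pad = kernel %/% 2L) {
  ly <- new_layer("conv1d")
  ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$kernel <- as.integer(kernel); ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad)
  ly$W <- init_matrix(kernel * in_ch, out_ch, fan_in = kernel * in_ch)
  ly$b <- numeric(out_ch)
  ly$param_names <- c("W", "b")
  # W rows are ordered tap-fastest: row (j - 1) + (c - 1) * kernel holds the
  # weight of input channel c at kernel tap j.

  # row indices into the padded (Lp*B, C) matrix selecting tap j of every
  # output position for every batch item; cached per (L, B) since shapes are
  # constant across minibatches
  tap_rows <- function(L, B) {
    key <- paste(L, B)
    if (identical(ly$rows_key, key)) return(ly$rows)
    k <- ly$kernel; s <- ly$stride; p <- ly$pad
    Lp <- L + 2L * p
    Lo <- conv_out_len(L, k, s, p)
    base <- outer((seq_len(Lo) - 1L) * s, (seq_len(B) - 1L) * Lp, `+`)
    ly$rows <- lapply(seq_len(k), function(j) as.vector(base + j))
    ly$rows_key <- key
    ly$Lo <- Lo; ly$Lp <- Lp
    ly$rows
  }

  ly$forward <- function(act, training = TRUE) {
    L <- act$L; B <- act$B; C <- ly$in_ch
    k <- ly$kernel; p <- ly$pad
    rows <- tap_rows(L, B)
    Lo <- ly$Lo; Lp <- ly$Lp
    xa <- act$m
    dim(xa) <- c(L, B, C)
    xp <- array(0, c(Lp, B, C))
    xp[(p + 1L):(p + L), , ] <- xa
    dim(xp) <- c(Lp * B, C)
    cs <- (seq_len(C) - 1L) * k
    Y <- matrix(ly$b, Lo * B, ly$out_ch, byrow = TRUE)
    for (j in seq_len(k)) {
      Y <- Y + xp[rows[[j]], , drop = FALSE] %*%
        ly$W[j + cs, , drop = FALSE]
    }
    if (training) ly$cache <- list(xp = xp, L = L, B = B)
    list(m = Y, L = Lo, B = B)
  }

  ly$backward <- function(dY) {
    ca <- ly$cache
    L <- ca$L; B <- ca$B; C <- ly$in_ch
    k <- ly$kernel; p <- ly$pad
    rows <- tap_rows(L, B)
    cs <- (seq_len(C) - 1L) * k
    gW <- matrix(0, k * C, ly$out_ch)
    need_dx <- !isTRUE(ly$skip_input_grad)
    if (need_dx) dxp <- matrix(0, ly$Lp * B, C)
    for (j in seq_len(k)) {
      Xj <- ca$xp[rows[[j]], , drop = FALSE]
      gW[j + cs, ] <- crossprod(Xj, dY)
      if (need_dx) {
        dxp[rows[[j]], ] <- dxp[rows[[j]], , drop = FALSE] +
          dY %*% t(ly$W[j + cs, , drop = FALSE])
      }
    }
    ly$gW <- gW
    ly$gb <- colSums(dY)
    ly$cache <- NULL
    if (!need_dx) return(NULL)
    dim(dxp) <- c(ly$Lp, B, C)
    dx <- dxp[(p + 1L):(p + L), , , drop = FALSE]
    dim(dx) <- c(L * B, C)
    dx
  }
  ly
}

# ---- batch normalisation over (time x batch) per channel --------------------

layer_batchnorm <- function(ch, eps = 1e-5, momentum = 0.1) {
  ly <- new_layer("batchnorm")
  ly$ch <- ch; ly$eps <- eps; ly$momentum <- momentum
  ly$gamma <- rep(1, ch); ly$beta <- numeric(ch)
  ly$running_mean <- numeric(ch); ly$running_var <- rep(1, ch)
  ly$param_names <- c("gamma", "beta")

  ly$forward <- function(act, training = TRUE) {
    x <- act$m
    if (training) {
      mu <- colMeans(x)
      xc <- x - matrix(mu, nrow(x), ly$ch, byrow = TRUE)
      v <- colMeans(xc * xc)
      invstd <- 1 / sqrt(v + ly$eps)
      xhat <- xc * matrix(invstd, nrow(x), ly$ch, byrow = TRUE)
      ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
      ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * v
      ly$cache <- list(xhat = xhat, invstd = invstd, xc = xc)
    } else {
      invstd <- 1 / sqrt(ly$running_var + ly$eps)
      xhat <- (x - matrix(ly$running_mean, nrow(x), ly$ch, byrow = TRUE)) *
        matrix(invstd, nrow(x), ly$ch, byrow = TRUE)
    }
    y <- xhat * matrix(ly$gamma, nrow(x), ly$ch, byrow = TRUE) +
      matrix(ly$beta, nrow(x), ly$ch, byrow = TRUE)
    list(m = y, L = act$L, B = act$B)
  }

  ly$backward <- function(dy) {
    ca <- ly$cache
    n <- nrow(dy)
    ly$ggamma <- colSums(dy * ca$xhat)
    ly$gbeta <- colSums(dy)
    dxhat <- dy * matrix(ly$gamma, n, ly$ch, byrow = TRUE)
    # standard batch-norm backward, vectorised per channel
    sum_dxhat <- colSums(dxhat)
    sum_dxhat_xhat <- colSums(dxhat * ca$xhat)
    dx <- (dxhat -
             matrix(sum_dxhat / n, n, ly$ch, byrow = TRUE) -
             ca$xhat * matrix(sum_dxhat_xhat / n, n, ly$ch, byrow = TRUE)) *
      matrix(ca$invstd, n, ly$ch, byrow = TRUE)
    ly$cache <- NULL
    dx
  }
  ly
}

# ---- ReLU -------------------------------------------------------------------

layer_relu <- function() {
  ly <- new_layer("relu")
  ly$forward <- function(act, training = TRUE) {
    y <- act$m
    y[y < 0] <- 0
    if (training) ly$cache <- act$m > 0
    list(m = y, L = act$L, B = act$B)
  }
  ly$backward <- function(dy) {
    dx <- dy * ly$cache
    ly$cache <- NULL
    dx
  }
  ly
}

# ---- max pooling (non-overlapping, drops the tail remainder) ----------------

layer_maxpool <- function(size) {
  ly <- new_layer("maxpool")
  ly$size <- as.integer(size)
  ly$forward <- function(act, training = TRUE) {
    L <- act$L; B <- act$B; C <- ncol(act$m)
    m <- ly$size
    Lo <- L %/% m
    xa <- array(act$m, c(L, B, C))
    xa <- xa[seq_len(Lo * m), , , drop = FALSE]
    dim(xa) <- c(m, Lo, B, C)
    best <- xa[1, , , , drop = TRUE]
    dim(best) <- c(Lo, B, C)
    arg <- array(1L, c(Lo, B, C))
    if (m > 1) {
      for (j in 2:m) {
        cur <- xa[j, , , , drop = TRUE]
        dim(cur) <- c(Lo, B, C)
        upd <- cur > best
        best[upd] <- cur[upd]
        arg[upd] <- j
      }
    }
    if (training) ly$cache <- list(arg = arg, L = L, B = B, C = C, Lo = Lo)
    y <- best
    dim(y) <- c(Lo * B, C)
    list(m = y, L = Lo, B = B)
  }
  ly$backward <- function(dy) {
    ca <- ly$cache
    m <- ly$size
    # linear index of each winner inside the (L, B, C) input array
    tpos <- (slice.index(ca$arg, 1) - 1L) * m + ca$arg
    lin <- tpos + (slice.index(ca$arg, 2) - 1L) * ca$L +
      (slice.index(ca$arg, 3) - 1L) * ca$L * ca$B
    dx <- numeric(ca$L * ca$B * ca$C)
    dx[as.vector(lin)] <- as.vector(dy)
    dim(dx) <- c(ca$L * ca$B, ca$C)
    ly$cache <- NULL
    dx
  }
  ly
}

# ---- squeeze-and-excitation channel gate ------------------------------------

layer_se <- function(ch, reduction = 8) {
  ly <- new_layer("se")
  hid <- max(1L, ch %/% reduction)
  ly$ch <- ch; ly$hid <- hid; ly$reduction <- reduction
  ly$W1 <- init_matrix(ch, hid, fan_in = ch)
  ly$b1 <- numeric(hid)
  ly$W2 <- init_matrix(hid, ch, fan_in = hid)
  ly$b2 <- numeric(ch)
  ly$param_names <- c("W1", "b1", "W2", "b2")

  ly$forward <- function(act, training = TRUE) {
    L <- act$L; B <- act$B; C <- ly$ch
    xa <- array(act$m, c(L, B, C))
    s <- colMeans(xa, dims = 1)                      # (B, C) squeeze
    z1 <- s %*% ly$W1 + matrix(ly$b1, B, ly$hid, byrow = TRUE)
    h1 <- pmax(z1, 0)
    z2 <- h1 %*% ly$W2 + matrix(ly$b2, B, C, byrow = TRUE)
    g <- 1 / (1 + exp(-z2))                          # (B, C) gates
    gexp <- g[rep(seq_len(B), each = L), , drop = FALSE]
    y <- act$m * gexp
    if (training) {
      ly$cache <- list(x = act$m, s = s, h1 = h1, g = g, gexp = gexp,
                       L = L, B = B)
    }
    list(m = y, L = L, B = B)
  }

  ly$backward <- function(dy) {
    ca <- ly$cache
    L <- ca$L; B <- ca$B; C <- ly$ch
    dx <- dy * ca$gexp
    tmp <- dy * ca$x
    dim(tmp) <- c(L, B, C)
    dg <- colSums(tmp, dims = 1)                     # (B, C)
    dz2 <- dg * ca$g * (1 - ca$g)
    ly$gW2 <- crossprod(ca$h1, dz2)
    ly$gb2 <- colSums(dz2)
    dh1 <- dz2 %*% t(ly$W2)
    dz1 <- dh1 * (ca$h1 > 0)
    ly$gW1 <- crossprod(ca$s, dz1)
    ly$gb1 <- colSums(dz1)
    ds <- dz1 %*% t(ly$W1)                           # (B, C)
    dx <- dx + ds[rep(seq_len(B), each = L), , drop = FALSE] / L
    ly$cache <- NULL
    dx
  }
  ly
}

# ---- LSTM (single layer; full-sequence output) ------------------------------

layer_lstm <- function(in_ch, hidden) {
  ly <- new_layer("lstm")
  ly$in_ch <- in_ch; ly$hidden <- hidden
  H <- hidden
  ly$Wx <- init_matrix(in_ch, 4L * H, fan_in = in_ch)
  ly$Wh <- init_matrix(H, 4L * H, fan_in = H)
  ly$b <- numeric(4L * H)
  ly$param_names <- c("Wx", "Wh", "b")

  gate_split <- function(G, H) {
    list(i = G[, 1:H, drop = FALSE],
         f = G[, (H + 1):(2 * H), drop = FALSE],
         g = G[, (2 * H + 1):(3 * H), drop = FALSE],
         o = G[, (3 * H + 1):(4 * H), drop = FALSE])
  }

  ly$forward <- function(act, training = TRUE) {
    L <- act$L; B <- act$B; H <- ly$hidden
    xa <- array(act$m, c(L, B, ly$in_ch))
    h <- matrix(0, B, H)
    cc <- matrix(0, B, H)
    hs <- array(0, c(L, B, H))
    steps <- vector("list", L)
    bmat <- matrix(ly$b, B, 4L * H, byrow = TRUE)
    for (t in seq_len(L)) {
      xt <- matrix(xa[t, , ], B, ly$in_ch)
      G <- xt %*% ly$Wx + h %*% ly$Wh + bmat
      gs <- gate_split(G, H)
      i <- 1 / (1 + exp(-gs$i))
      f <- 1 / (1 + exp(-gs$f))
      g <- tanh(gs$g)
      o <- 1 / (1 + exp(-gs$o))
      c_prev <- cc
      cc <- f * c_prev + i * g
      tc <- tanh(cc)
      h_prev <- h
      h <- o * tc
      hs[t, , ] <- h
      if (training) {
        steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                           c = cc, tc = tc, c_prev = c_prev, h_prev = h_prev)
      }
    }
    if (training) ly$cache <- list(steps = steps, L = L, B = B)
    y <- hs
    dim(y) <- c(L * B, H)
    list(m = y, L = L, B = B)
  }

  ly$backward <- function(dy) {
    ca <- ly$cache
    L <- ca$L; B <- ca$B; H <- ly$hidden
    dha <- array(dy, c(L, B, H))
    gWx <- matrix(0, nrow(ly$Wx), ncol(ly$Wx))
    gWh <- matrix(0, nrow(ly$Wh), ncol(ly$Wh))
    gb <- numeric(4L * H)
    dxa <- array(0, c(L, B, ly$in_ch))
    dh_carry <- matrix(0, B, H)
    dc_carry <- matrix(0, B, H)
    for (t in rev(seq_len(L))) {
      st <- ca$steps[[t]]
      dh <- matrix(dha[t, , ], B, H) + dh_carry
      dc <- dh * st$o * (1 - st$tc^2) + dc_carry
      d_o <- dh * st$tc * st$o * (1 - st$o)
      d_i <- dc * st$g * st$i * (1 - st$i)
      d_f <- dc * st$c_prev * st$f * (1 - st$f)
      d_g <- dc * st$i * (1 - st$g^2)
      dG <- cbind(d_i, d_f, d_g, d_o)
      gWx <- gWx + crossprod(st$xt, dG)
      gWh <- gWh + crossprod(st$h_prev, dG)
      gb <- gb + colSums(dG)
      dxa[t, , ] <- dG %*% t(ly$Wx)
      dh_carry <- dG %*% t(ly$Wh)
      dc_carry <- dc * st$f
    }
    ly$gWx <- gWx; ly$gWh <- gWh; ly$gb <- gb
    dim(dxa) <- c(L * B, ly$in_ch)
    ly$cache <- NULL
    dxa
  }
  ly
}

# ---- sequence reductions and head layers ------------------------------------

# keep only the final time step: (L*B, C) -> (B, C)
layer_take_last <- function() {
  ly <- new_layer("take_last")
  ly$forward <- function(act, training = TRUE) {
    L <- act$L; B <- act$B; C <- ncol(act$m)
    xa <- array(act$m, c(L, B, C))
    y <- matrix(xa[L, , ], B, C)
    if (training) ly$cache <- list(L = L, B = B, C = C)
    list(m = y, L = 1L, B = B)
  }
  ly$backward <- function(dy) {
    ca <- ly$cache
    dxa <- array(0, c(ca$L, ca$B, ca$C))
    dxa[ca$L, , ] <- dy
    dim(dxa) <- c(ca$L * ca$B, ca$C)
    ly$cache <- NULL
    dxa
  }
  ly
}

# global average over time: (L*B, C) -> (B, C)
layer_meanpool_time <- function() {
  ly <- new_layer("meanpool_time")
  ly$forward <- function(act, training = TRUE) {
    L <- act$L; B <- act$B; C <- ncol(act$m)
    xa <- array(act$m, c(L, B, C))
    y <- colMeans(xa, dims = 1)
    dim(y) <- c(B, C)
    if (training) ly$cache <- list(L = L, B = B, C = C)
    list(m = y, L = 1L, B = B)
  }
  ly$backward <- function(dy) {
    ca <- ly$cache
    dx <- dy[rep(seq_len(ca$B), each = ca$L), , drop = FALSE] / ca$L
    ly$cache <- NULL
    dx
  }
  ly
}

# (L*B, C) -> (B, L*C), time index fastest within each channel block
layer_flatten <- function() {
  ly <- new_layer("flatten")
  ly$forward <- function(act, training = TRUE) {
    L <- act$L; B <- act$B; C <- ncol(act$m)
    xa <- array(act$m, c(L, B, C))
    y <- aperm(xa, c(2, 1, 3))
    dim(y) <- c(B, L * C)
    if (training) ly$cache <- list(L = L, B = B, C = C)
    list(m = y, L = 1L, B = B)
  }
  ly$backward <- function(dy) {
    ca <- ly$cache
    dim(dy) <- c(ca$B, ca$L, ca$C)
    dx <- aperm(dy, c(2, 1, 3))
    dim(dx) <- c(ca$L * ca$B, ca$C)
    ly$cache <- NULL
    dx
  }
  ly
}

layer_dense <- function(in_dim, out_dim) {
  ly <- new_layer("dense")
  ly$in_dim <- in_dim; ly$out_dim <- out_dim
  ly$W <- init_matrix(in_dim, out_dim, fan_in = in_dim)
  ly$b <- numeric(out_dim)
  ly$param_names <- c("W", "b")
  ly$forward <- function(act, training = TRUE) {
    if (ncol(act$m) != ly$in_dim) {
      abort_param("dense layer expects %d inputs, got %d (input length mismatch)",
                  ly$in_dim, ncol(act$m))
    }
    y <- act$m %*% ly$W + matrix(ly$b, nrow(act$m), ly$out_dim, byrow = TRUE)
    if (training) ly$cache <- act$m
    list(m = y, L = act$L, B = act$B)
  }
  ly$backward <- function(dy) {
    ly$gW <- crossprod(ly$cache, dy)
    ly$gb <- colSums(dy)
    dx <- dy %*% t(ly$W)
    ly$cache <- NULL
    dx
  }
  ly
}

# ---- residual SE block ------------------------------------------------------

# conv(k, stride) -> BN -> ReLU -> conv(k, 1) -> BN -> [SE] -> + shortcut -> ReLU
# The shortcut is identity when shape is preserved, else a strided 1x1
# projection conv.
layer_resblock <- function(in_ch, out_ch, kernel = 7L, stride = 2L,
                           use_se = TRUE, se_reduction = 8) {
  ly <- new_layer("resblock")
  ly$use_se <- use_se
  ly$conv1 <- layer_conv1d(in_ch, out_ch, kernel, stride)
  ly$bn1 <- layer_batchnorm(out_ch)
  ly$relu1 <- layer_relu()
  ly$conv2 <- layer_conv1d(out_ch, out_ch, kernel, 1L)
  ly$bn2 <- layer_batchnorm(out_ch)
  ly$se <- if (use_se) layer_se(out_ch, se_reduction) else NULL
  ly$project <- (in_ch != out_ch) || (stride != 1L)
  ly$shortcut <- if (ly$project) {
    layer_conv1d(in_ch, out_ch, kernel = 1L, stride = stride, pad = 0L)
  } else NULL
  ly$relu_out <- layer_relu()
  ly$children <- Filter(Negate(is.null),
                        list(ly$conv1, ly$bn1, ly$conv2, ly$bn2, ly$se,
                             ly$shortcut))

  ly$forward <- function(act, training = TRUE) {
    main <- ly$conv1$forward(act, training)
    main <- ly$bn1$forward(main, training)
    main <- ly$relu1$forward(main, training)
    main <- ly$conv2$forward(main, training)
    main <- ly$bn2$forward(main, training)
    if (ly$use_se) main <- ly$se$forward(main, training)
    sc <- if (ly$project) ly$shortcut$forward(act, training) else act
    stopifnot(main$L == sc$L)
    out <- list(m = main$m + sc$m, L = main$L, B = main$B)
    ly$relu_out$forward(out, training)
  }

  ly$backward <- function(dy) {
    dsum <- ly$relu_out$backward(dy)
    dmain <- dsum
    if (ly$use_se) dmain <- ly$se$backward(dmain)
    dmain <- ly$bn2$backward(dmain)
    dmain <- ly$conv2$backward(dmain)
    dmain <- ly$relu1$backward(dmain)
    dmain <- ly$bn1$backward(dmain)
    dmain <- ly$conv1$backward(dmain)
    dsc <- if (ly$project) ly$shortcut$backward(dsum) else dsum
    dmain + dsc
  }
  ly
}
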