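# Native neural-network engine: 1-D convolution (im2col + BLAS), batch
# normalization, ReLU, max-pooling, dense, dropout and LSTM layers, each
# with an analytic backward pass. Tensors flow as (n, L, C) arrays along
# the conv/recurrent stack and as (n, d) matrices after flattening.
#
# Array layout convention: as.vector() order of an (n, L, C) array is
# sample-major within position within channel, so matrix(x, n*L, C) gives
# one column per channel and array(mat, c(n, Lout, C)) undoes it.

#' Output length of a valid 1-D convolution
#'
#' Number of positions a kernel of length `kernel_size` can take sliding
#' with step `stride` over `input_len` variables without padding:
#' `floor((input_len - kernel_size) / stride) + 1`.
#'
#' @param input_len Input variable count.
#' @param kernel_size Kernel window length.
#' @param stride Step between window starts.
#' @return Integer output length.
#' @examples
#' conv_output_length(2151, 11, 4)  # 536
#' @export
conv_output_length <- function(input_len, kernel_size, stride = 1) {
  if (kernel_size < 1 || stride < 1) stop("kernel_size and stride must be >= 1")
  if (input_len < kernel_size)
    stop(sprintf("input length %d is shorter than kernel size %d",
                 input_len, kernel_size))
  as.integer((input_len - kernel_size) %/% stride) + 1L
}

pad_seq <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * pad, d[3]))
  xp[, pad + seq_len(d[2]), ] <- x
  xp
}

# column-recycled addition/scaling: M (r x c) op v (length c), avoiding
# sweep()'s aperm overhead on hot paths
addcol <- function(M, v) M + rep(v, each = nrow(M))
mulcol <- function(M, v) M * rep(v, each = nrow(M))

im2col <- function(x, k, stride, Lout) {
  d <- dim(x); n <- d[1]; C <- d[3]
  cols <- matrix(0, n * Lout, k * C)
  ch_off <- (seq_len(C) - 1L) * k
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = Lout)
    cols[, ch_off + j] <- x[, idx, ]  # linear order matches (n, Lout, C)
  }
  cols
}

col2im <- function(dcols, dims, k, stride, Lout) {
  n <- dims[1]; C <- dims[3]
  dx <- array(0, dims)
  ch_off <- (seq_len(C) - 1L) * k
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = Lout)
    dsub <- dcols[, ch_off + j]
    dim(dsub) <- c(n, Lout, C)
    dx[, idx, ] <- dx[, idx, , drop = FALSE] + dsub
  }
  dx
}

# ---- layer constructors (architecture only; parameters set by nn_init) ----

layer_conv <- function(filters, kernel_size, stride, pad = 0L) {
  list(type = "conv", filters = as.integer(filters),
       k = as.integer(kernel_size), stride = as.integer(stride),
       pad = as.integer(pad))
}
layer_bn <- function() list(type = "bn")
layer_relu <- function() list(type = "relu")
layer_pool <- function(kernel_size = 3L, stride = 2L)
  list(type = "pool", k = as.integer(kernel_size), stride = as.integer(stride))
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(units) list(type = "dense", units = as.integer(units))
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_lstm <- function(hidden, dropout = 0)
  list(type = "lstm", hidden = as.integer(hidden), dropout = dropout)

# Resolve per-layer input/output shapes along the stack. Shapes are
# list(L, C) for sequence tensors or list(d) for flat matrices.
nn_resolve_shapes <- function(layers, input_len, in_channels = 1L) {
  shape <- list(L = as.integer(input_len), C = as.integer(in_channels))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    ly$in_shape <- shape
    shape <- switch(ly$type,
      conv = {
        Lp <- shape$L + 2L * ly$pad
        if (Lp < ly$k)
          stop(sprintf(
            "input too short at conv layer %d: length %d < kernel %d",
            i, Lp, ly$k))
        list(L = conv_output_length(Lp, ly$k, ly$stride), C = ly$filters)
      },
      pool = {
        if (shape$L < ly$k)
          stop(sprintf("input too short at pool layer %d: length %d < window %d",
                       i, shape$L, ly$k))
        list(L = conv_output_length(shape$L, ly$k, ly$stride), C = shape$C)
      },
      bn = shape,
      relu = shape,
      dropout = shape,
      flatten = list(d = shape$L * shape$C),
      lstm = list(d = ly$hidden),
      dense = list(d = ly$units),
      stop("unknown layer type: ", ly$type)
    )
    ly$out_shape <- shape
    layers[[i]] <- ly
  }
  layers
}

# Parameter initialization: Glorot-uniform kernels for conv/dense, Glorot
# input weights + orthogonal recurrent weights for the LSTM, forget-gate
# bias 1. Uses the current RNG state; callers seed it.
glorot_uniform <- function(fan_in, fan_out, nr, nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

orthogonal_init <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}

nn_init <- function(layers) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      fan_in <- ly$k * ly$in_shape$C
      ly$W <- glorot_uniform(fan_in, ly$k * ly$filters, fan_in, ly$filters)
      ly$b <- numeric(ly$filters)
    } else if (ly$type == "dense") {
      fan_in <- ly$in_shape$d
      ly$W <- glorot_uniform(fan_in, ly$units, fan_in, ly$units)
      ly$b <- numeric(ly$units)
    } else if (ly$type == "bn") {
      C <- ly$in_shape$C
      ly$gamma <- rep(1, C); ly$beta <- numeric(C)
      ly$run_mean <- numeric(C); ly$run_var <- rep(1, C)
    } else if (ly$type == "lstm") {
      H <- ly$hidden; D <- ly$in_shape$C
      rw <- function() cbind(orthogonal_init(H),
                             glorot_uniform(D, H, H, D))
      ly$Wc <- rw(); ly$Wf <- rw(); ly$Wi <- rw(); ly$Wo <- rw()
      ly$bc <- numeric(H); ly$bf <- rep(1, H); ly$bi <- numeric(H)
      ly$bo <- numeric(H)
    }
    layers[[i]] <- ly
  }
  layers
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- forward ----

layer_fwd <- function(ly, x, training) {
  switch(ly$type,
    conv = {
      xp <- pad_seq(x, ly$pad)
      Lout <- ly$out_shape$L
      cols <- im2col(xp, ly$k, ly$stride, Lout)
      out <- addcol(cols %*% ly$W, ly$b)
      dim(out) <- c(dim(x)[1], Lout, ly$filters)
      list(out = out, cache = list(cols = cols, pdims = dim(xp)), layer = ly)
    },
    bn = {
      d <- dim(x); C <- d[3]
      xm <- matrix(x, d[1] * d[2], C)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(addcol(xm, -mu)^2)
        ly$run_mean <- 0.99 * ly$run_mean + 0.01 * mu
        ly$run_var <- 0.99 * ly$run_var + 0.01 * v
      } else {
        mu <- ly$run_mean; v <- ly$run_var
      }
      inv_sd <- 1 / sqrt(v + 1e-3)
      xhat <- mulcol(addcol(xm, -mu), inv_sd)
      out <- addcol(mulcol(xhat, ly$gamma), ly$beta)
      dim(out) <- d
      list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, dims = d),
           layer = ly)
    },
    relu = {
      out <- x * (x > 0)
      list(out = out, cache = list(mask = x > 0), layer = ly)
    },
    pool = {
      d <- dim(x); Lout <- ly$out_shape$L
      out <- array(-Inf, c(d[1], Lout, d[3]))
      for (j in seq_len(ly$k)) {
        idx <- seq.int(j, by = ly$stride, length.out = Lout)
        out <- pmax(out, x[, idx, , drop = FALSE])
      }
      list(out = out, cache = list(x = x, out = out), layer = ly)
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], d[2] * d[3]), cache = list(dims = d),
           layer = ly)
    },
    dense = {
      list(out = addcol(x %*% ly$W, ly$b), cache = list(x = x), layer = ly)
    },
    dropout = {
      if (training && ly$rate > 0) {
        mask <- array(stats::runif(length(x)) >= ly$rate, dim(x) %||% length(x))
        list(out = x * mask / (1 - ly$rate), cache = list(mask = mask),
             layer = ly)
      } else list(out = x, cache = NULL, layer = ly)
    },
    lstm = {
      d <- dim(x); n <- d[1]; Tn <- d[2]; D <- d[3]; H <- ly$hidden
      Wall <- t(rbind(ly$Wc, ly$Wf, ly$Wi, ly$Wo))  # (H+D) x 4H
      ball <- c(ly$bc, ly$bf, ly$bi, ly$bo)
      # input dropout: one mask per sample, shared across all time steps
      mask <- if (training && ly$dropout > 0)
        matrix((stats::runif(n * D) >= ly$dropout) / (1 - ly$dropout), n, D)
      else NULL
      h <- matrix(0, n, H); cstate <- matrix(0, n, H)
      i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
      steps <- vector("list", Tn)
      for (t in seq_len(Tn)) {
        xt <- matrix(x[, t, ], n, D)
        if (!is.null(mask)) xt <- xt * mask
        A <- cbind(h, xt)
        Z <- addcol(A %*% Wall, ball)
        cand <- tanh(Z[, i1, drop = FALSE])
        f <- sigmoid(Z[, i2, drop = FALSE])
        ig <- sigmoid(Z[, i3, drop = FALSE])
        o <- sigmoid(Z[, i4, drop = FALSE])
        c_prev <- cstate
        cstate <- f * c_prev + ig * cand
        tc <- tanh(cstate)
        h <- o * tc
        steps[[t]] <- list(A = A, cand = cand, f = f, i = ig, o = o,
                           c_prev = c_prev, tc = tc)
      }
      list(out = h, cache = list(steps = steps, dims = d, mask = mask),
           layer = ly)
    },
    stop("unknown layer type: ", ly$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer  # BN running stats update
  }
  list(out = x, caches = caches, layers = layers)
}

# ---- backward ----

layer_bwd <- function(ly, cache, dout) {
  switch(ly$type,
    conv = {
      dmat <- matrix(dout, nrow(cache$cols), ly$filters)
      dW <- crossprod(cache$cols, dmat)
      db <- colSums(dmat)
      dcols <- tcrossprod(dmat, ly$W)
      dxp <- col2im(dcols, cache$pdims, ly$k, ly$stride, ly$out_shape$L)
      dx <- if (ly$pad > 0)
        dxp[, ly$pad + seq_len(ly$in_shape$L), , drop = FALSE] else dxp
      list(dx = dx, grads = list(W = dW, b = db))
    },
    bn = {
      d <- cache$dims
      dm <- matrix(dout, d[1] * d[2], d[3])
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      dxhat <- mulcol(dm, ly$gamma)
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cache$xhat)
      dxm <- mulcol(addcol(dxhat, -m1) - mulcol(cache$xhat, m2),
                    cache$inv_sd)
      dim(dxm) <- d
      list(dx = dxm, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    pool = {
      x <- cache$x; out <- cache$out
      d <- dim(x); Lout <- dim(out)[2]
      dx <- array(0, d)
      assigned <- array(FALSE, dim(out))
      for (j in seq_len(ly$k)) {
        idx <- seq.int(j, by = ly$stride, length.out = Lout)
        m <- (x[, idx, , drop = FALSE] == out) & !assigned
        assigned <- assigned | m
        dx[, idx, ] <- dx[, idx, , drop = FALSE] + dout * m
      }
      list(dx = dx, grads = NULL)
    },
    flatten = list(dx = array(dout, cache$dims), grads = NULL),
    dense = list(dx = dout %*% t(ly$W),
                 grads = list(W = crossprod(cache$x, dout), b = colSums(dout))),
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask / (1 - ly$rate), grads = NULL)
    },
    lstm = {
      d <- cache$dims; n <- d[1]; Tn <- d[2]; D <- d[3]; H <- ly$hidden
      Wall <- rbind(ly$Wc, ly$Wf, ly$Wi, ly$Wo)   # 4H x (H+D)
      dWall <- matrix(0, 4L * H, H + D)
      dball <- numeric(4L * H)
      dh <- dout          # gradient w.r.t. final hidden state
      dc <- matrix(0, n, H)
      dx <- array(0, d)
      for (t in rev(seq_len(Tn))) {
        st <- cache$steps[[t]]
        do_ <- dh * st$tc
        dc <- dc + dh * st$o * (1 - st$tc^2)
        dZ <- cbind(dc * st$i * (1 - st$cand^2),            # candidate
                    dc * st$c_prev * st$f * (1 - st$f),     # forget gate
                    dc * st$cand * st$i * (1 - st$i),       # update gate
                    do_ * st$o * (1 - st$o))                # output gate
        dA <- dZ %*% Wall
        dWall <- dWall + crossprod(dZ, st$A)
        dball <- dball + colSums(dZ)
        dh <- dA[, seq_len(H), drop = FALSE]
        dxt <- dA[, H + seq_len(D), drop = FALSE]
        if (!is.null(cache$mask)) dxt <- dxt * cache$mask
        dx[, t, ] <- dxt
        dc <- dc * st$f
      }
      i1 <- seq_len(H)
      list(dx = dx,
           grads = list(Wc = dWall[i1, , drop = FALSE],
                        Wf = dWall[H + i1, , drop = FALSE],
                        Wi = dWall[2L * H + i1, , drop = FALSE],
                        Wo = dWall[3L * H + i1, , drop = FALSE],
                        bc = dball[i1], bf = dball[H + i1],
                        bi = dball[2L * H + i1], bo = dball[3L * H + i1]))
    },
    stop("unknown layer type: ", ly$type)
  )
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)  # [[<-]] with NULL would drop the slot
  }
  grads
}

# Softmax cross-entropy over 2+ classes; y is a 0-based label vector.
softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, prob = p)
}

# ---- Adam optimizer over the layers' parameter arrays ----

TRAINABLE <- list(conv = c("W", "b"), dense = c("W", "b"),
                  bn = c("gamma", "beta"),
                  lstm = c("Wc", "Wf", "Wi", "Wo", "bc", "bf", "bi", "bo"))

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    nm <- TRAINABLE[[ly$type]]
    if (is.null(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = ly[[p]] * 0, v = ly[[p]] * 0))
    names(st) <- nm
    st
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}
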