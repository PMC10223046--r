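# brute-force window count: slide a kernel over positions and count fits
brute_windows <- function(L, k, s) {
  count <- 0L
  start <- 1L
  while (start + k - 1L <= L) {
    count <- count + 1L
    start <- start + s
  }
  count
}

test_that("conv output length matches brute-force window enumeration", {
  expect_equal(conv_output_length(2151, 11, 4), 536L)
  expect_equal(conv_output_length(100, 11, 4), 23L)
  expect_equal(conv_output_length(7, 7, 1), 1L)
  for (L in c(1:20, 33, 64)) {
    for (k in unique(pmin(L, c(1, 2, 3, 5, 8, 11, L)))) {
      for (s in 1:8) {
        expect_equal(conv_output_length(L, k, s), brute_windows(L, k, s),
                     info = sprintf("L=%d k=%d s=%d", L, k, s))
      }
    }
  }
  expect_error(conv_output_length(10, 11, 1), "shorter than kernel")
})

test_that("default CNN follows the published layer plan", {
  m <- build_cnn1d(input_len = 100)
  convs <- Filter(function(l) l$type == "conv", m$layers)
  expect_equal(vapply(convs, `[[`, numeric(1), "filters"), c(64, 64, 92, 92, 64))
  expect_equal(vapply(convs, `[[`, numeric(1), "k"), c(11, 5, 3, 3, 3))
  expect_equal(vapply(convs, `[[`, numeric(1), "stride"), c(4, 1, 1, 1, 1))
  # BN before the first three convolutions only, no pooling anywhere
  types <- vapply(m$layers, `[[`, character(1), "type")
  expect_equal(sum(types == "bn"), 3L)
  expect_equal(sum(types == "pool"), 0L)
  expect_equal(which(types == "bn"), which(types == "conv")[1:3] - 1L)
  # exactly one hidden fully connected layer plus the output layer
  expect_equal(sum(types == "dense"), 2L)
  # per-layer lengths down the chain for a 100-variable input
  lens <- vapply(convs, function(l) l$out_shape$L, integer(1))
  expect_equal(lens, c(23L, 19L, 17L, 15L, 13L))
  # flattened feature size 13 x 64
  flat <- m$layers[[which(types == "flatten")]]
  expect_equal(flat$out_shape$d, 13L * 64L)
  expect_error(build_cnn1d(input_len = 20), "conv layer")
})

test_that("conv-stack parameter count matches the closed-form sum", {
  m <- build_cnn1d(input_len = 2151)
  chain_in <- c(1, 64, 64, 92, 92)
  chain_out <- c(64, 64, 92, 92, 64)
  ksz <- c(11, 5, 3, 3, 3)
  expect_equal(n_parameters(m, types = "conv"),
               sum(ksz * chain_in * chain_out + chain_out))
})

test_that("lstm cell step reproduces hand-computed gate arithmetic", {
  # scalar cell, all weight rows [1, 1], biases 0, prev = (0, 0), x = 1
  p <- lstm_cell_params(Wc = matrix(c(1, 1), 1), Wf = matrix(c(1, 1), 1),
                        Wi = matrix(c(1, 1), 1), Wo = matrix(c(1, 1), 1),
                        bc = 0, bf = 0, bi = 0, bo = 0)
  st <- lstm_cell_step(p, x_t = 1)
  sig1 <- 1 / (1 + exp(-1))
  expect_equal(st$candidate, tanh(1), tolerance = 1e-10)   # 0.76159
  expect_equal(st$f, sig1, tolerance = 1e-10)              # 0.73106
  expect_equal(st$i, sig1, tolerance = 1e-10)
  expect_equal(st$o, sig1, tolerance = 1e-10)
  expect_equal(st$c, sig1 * tanh(1), tolerance = 1e-10)    # 0.55677
  expect_equal(st$h, sig1 * tanh(sig1 * tanh(1)), tolerance = 1e-10) # 0.36960
  # zero parameters: gates 0.5, state fixed at zero
  z <- lstm_cell_params(matrix(0, 2, 5), matrix(0, 2, 5), matrix(0, 2, 5),
                        matrix(0, 2, 5), numeric(2), numeric(2), numeric(2),
                        numeric(2))
  st0 <- lstm_cell_step(z, x_t = rnorm(3))
  expect_equal(st0$f, c(0.5, 0.5))
  expect_equal(st0$c, c(0, 0))
  expect_equal(st0$h, c(0, 0))
  expect_error(lstm_cell_step(p, x_t = c(1, 2)), "dimension mismatch")
})

test_that("lstm cell matches a brute-force oracle on random small instances", {
  # independent elementwise oracle written directly from the update rules
  oracle <- function(p, x, h0, c0) {
    H <- length(h0)
    A <- c(h0, x)
    lin <- function(W, b) {
      out <- numeric(H)
      for (r in seq_len(H)) out[r] <- sum(W[r, ] * A) + b[r]
      out
    }
    cand <- tanh(lin(p$Wc, p$bc))
    f <- 1 / (1 + exp(-lin(p$Wf, p$bf)))
    i <- 1 / (1 + exp(-lin(p$Wi, p$bi)))
    o <- 1 / (1 + exp(-lin(p$Wo, p$bo)))
    cn <- f * c0 + i * cand
    list(h = o * tanh(cn), c = cn)
  }
  set.seed(99)
  for (trial in 1:100) {
    H <- sample(1:3, 1); D <- sample(1:3, 1)
    p <- lstm_cell_params(
      matrix(rnorm(H * (H + D)), H), matrix(rnorm(H * (H + D)), H),
      matrix(rnorm(H * (H + D)), H), matrix(rnorm(H * (H + D)), H),
      rnorm(H), rnorm(H), rnorm(H), rnorm(H))
    x <- rnorm(D); h0 <- rnorm(H); c0 <- rnorm(H)
    got <- lstm_cell_step(p, x, list(h = h0, c = c0))
    want <- oracle(p, x, h0, c0)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
    expect_true(all(got$f > 0 & got$f < 1))
    expect_true(all(abs(got$h) < 1))
  }
})

test_that("hybrid model turns the conv stack into an LSTM-consumable sequence", {
  m100 <- build_cnn_lstm(input_len = 100)
  expect_equal(lstm_input_shape(m100), list(steps = 13L, features = 64L))
  m2151 <- build_cnn_lstm(input_len = 2151)
  expect_equal(lstm_input_shape(m2151), list(steps = 526L, features = 64L))
  types <- vapply(m100$layers, `[[`, character(1), "type")
  expect_equal(sum(types == "dense"), 1L)   # only the output layer
  out <- m100$layers[[length(m100$layers)]]
  expect_equal(out$units, 2L)
})

test_that("alexnet variants keep the classical pooling and two hidden layers", {
  a <- build_variant("alexnet1d", input_len = 100)
  types <- vapply(a$layers, `[[`, character(1), "type")
  expect_equal(sum(types == "pool"), 3L)
  expect_equal(sum(types == "dense"), 3L)  # two hidden + one output
  expect_equal(sum(types == "bn"), 0L)
  al <- build_variant("alexnet_lstm", input_len = 100)
  tl <- vapply(al$layers, `[[`, character(1), "type")
  expect_equal(sum(tl == "lstm"), 1L)
  expect_equal(sum(tl == "pool"), 3L)
  expect_error(build_variant("vgg", 100))
  expect_error(build_model("mystery", 100), "unknown model kind")
})

test_that("lstm classifier defaults and single-step sequences work", {
  m <- build_lstm(input_len = 100)
  expect_equal(m$hidden, 10L)
  lstm_ly <- Filter(function(l) l$type == "lstm", m$layers)[[1]]
  expect_equal(lstm_ly$hidden, 10L)
  drop_ly <- Filter(function(l) l$type == "dropout", m$layers)[[1]]
  expect_equal(drop_ly$rate, 0.3)
  m1 <- build_lstm(input_len = 1)
  tr <- train_classifier(m1, matrix(c(0, 1, 0, 1), 4, 1), c(0, 1, 0, 1),
                         train_config(epochs = 2, seed = 1))
  expect_equal(length(predict(tr, matrix(c(0.2, 0.8), 2, 1))), 2L)
})
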