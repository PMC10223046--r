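#' Architecture of the modified one-dimensional CNN
#'
#' The network is an AlexNet-derived 1-D design adapted for spectra: five
#' valid (unpadded) 1-D convolutions with filter/kernel/stride settings
#' (64,11,4), (64,5,1), (92,3,1), (92,3,1), (64,3,1); batch normalization
#' placed before the first three convolutions only; all pooling layers
#' removed; ReLU after every convolution; then a single hidden fully
#' connected layer with dropout and a fully connected output layer over
#' two classes.
#'
#' @param conv_layers List of conv layer settings, each a list with
#'   `filters`, `kernel_size`, `stride`, `batch_norm_before`.
#' @param fc_width Width of the hidden fully connected layer.
#' @param dropout_rate Dropout probability on the hidden layer (default 0.5).
#' @param n_classes Output class count (default 2).
#' @return Object of class `cnn_spec`.
#' @export
cnn_spec <- function(conv_layers = default_conv_layers(),
                     fc_width = 128, dropout_rate = 0.5, n_classes = 2) {
  for (cl in conv_layers)
    stopifnot(cl$filters > 0, cl$kernel_size >= 1, cl$stride >= 1)
  structure(list(conv_layers = conv_layers, fc_width = as.integer(fc_width),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes)),
            class = "cnn_spec")
}

default_conv_layers <- function() {
  cfg <- list(c(64, 11, 4), c(64, 5, 1), c(92, 3, 1), c(92, 3, 1), c(64, 3, 1))
  lapply(seq_along(cfg), function(i)
    list(filters = cfg[[i]][1], kernel_size = cfg[[i]][2], stride = cfg[[i]][3],
         batch_norm_before = i <= 3))
}

conv_stack_layers <- function(spec, pad = NULL) {
  layers <- list()
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    if (isTRUE(cl$batch_norm_before)) layers <- c(layers, list(layer_bn()))
    p <- if (is.null(pad)) 0L else pad[i]
    layers <- c(layers, list(layer_conv(cl$filters, cl$kernel_size, cl$stride, p),
                             layer_relu()))
  }
  layers
}

new_spectral_model <- function(kind, layers, input_len, n_classes = 2L) {
  layers <- nn_resolve_shapes(layers, input_len)
  structure(list(kind = kind, input_len = as.integer(input_len),
                 n_classes = as.integer(n_classes), layers = layers,
                 trained = FALSE),
            class = "spectral_model")
}

#' Build the modified 1-D CNN classifier
#'
#' @param spec A [cnn_spec()].
#' @param input_len Number of input variables (2151 for raw spectra, 100
#'   after the default PCA).
#' @return An untrained `spectral_model`; parameters are initialized by
#'   [train_classifier()] under its seed.
#' @export
build_cnn1d <- function(spec = cnn_spec(), input_len) {
  layers <- c(conv_stack_layers(spec),
              list(layer_flatten(),
                   layer_dense(spec$fc_width), layer_relu(),
                   layer_dropout(spec$dropout_rate),
                   layer_dense(spec$n_classes)))
  new_spectral_model("cnn", layers, input_len, spec$n_classes)
}

#' Build the LSTM classifier
#'
#' Treats the spectrum (or feature vector) as an ordered sequence of
#' scalar steps; the final hidden state passes through dropout and a
#' fully connected output layer over two classes.
#'
#' @param hidden Hidden state width (study default 10).
#' @param dropout Dropout probability on the final hidden state (default 0.3).
#' @param input_len Sequence length.
#' @return An untrained `spectral_model`.
#' @export
build_lstm <- function(hidden = 10, dropout = 0.3, input_len) {
  stopifnot(hidden >= 1)
  layers <- list(layer_lstm(hidden), layer_dropout(dropout), layer_dense(2L))
  m <- new_spectral_model("lstm", layers, input_len)
  m$hidden <- as.integer(hidden)
  m
}

#' Build the CNN-LSTM hybrid classifier
#'
#' The convolutional stack of the modified CNN (without flatten or fully
#' connected layers) maps the spectrum to a sequence of channel vectors,
#' one per retained spectral position; the LSTM consumes that sequence to
#' extract position information, and its final hidden state feeds a
#' dropout layer and the two-class output layer.
#'
#' @param spec Optional list with elements `cnn` (a [cnn_spec()]),
#'   `lstm_hidden` (default 10) and `lstm_dropout` (default 0.3).
#' @param input_len Number of input variables.
#' @return An untrained `spectral_model`.
#' @export
build_cnn_lstm <- function(spec = list(), input_len) {
  cspec <- spec$cnn %||% cnn_spec()
  hidden <- spec$lstm_hidden %||% 10L
  drop <- spec$lstm_dropout %||% 0.3
  layers <- c(conv_stack_layers(cspec),
              list(layer_lstm(hidden), layer_dropout(drop), layer_dense(2L)))
  new_spectral_model("cnn_lstm", layers, input_len)
}

#' Build an AlexNet-style comparison variant
#'
#' `"alexnet1d"` keeps the classical AlexNet skeleton in one dimension:
#' the five-convolution stack with max pooling (window 3, stride 2) after
#' convolutions 1, 2 and 5, *two* hidden fully connected layers (256 and
#' 128 units, dropout 0.5 on each) and a fully connected output layer —
#' against the modified CNN's single hidden layer and no pooling.
#' Convolutions 2-5 use same-padding (the classical geometry), so the
#' variant runs on both raw spectra and 100-feature PCA inputs.
#' `"alexnet_lstm"` feeds the pooled convolutional sequence into the LSTM
#' exactly as [build_cnn_lstm()] does.
#'
#' @param kind `"alexnet1d"` or `"alexnet_lstm"`.
#' @param input_len Number of input variables.
#' @return An untrained `spectral_model`.
#' @export
build_variant <- function(kind = c("alexnet1d", "alexnet_lstm"), input_len) {
  kind <- match.arg(kind)
  cspec <- cnn_spec(lapply(default_conv_layers(),
                           function(cl) { cl$batch_norm_before <- FALSE; cl }))
  pads <- c(0L, 2L, 1L, 1L, 1L)
  base <- conv_stack_layers(cspec, pad = pads)
  # max-pool after conv layers 1, 2 and 5 (conv+relu pairs at 2,4,10)
  stack <- c(base[1:2], list(layer_pool()), base[3:4], list(layer_pool()),
             base[5:10], list(layer_pool()))
  layers <- if (kind == "alexnet1d") {
    c(stack, list(layer_flatten(),
                  layer_dense(256L), layer_relu(), layer_dropout(0.5),
                  layer_dense(128L), layer_relu(), layer_dropout(0.5),
                  layer_dense(2L)))
  } else {
    c(stack, list(layer_lstm(10L), layer_dropout(0.3), layer_dense(2L)))
  }
  new_spectral_model(kind, layers, input_len)
}

#' Build any supported classifier by kind
#' @param kind One of `"cnn"`, `"lstm"`, `"cnn_lstm"`, `"alexnet1d"`,
#'   `"alexnet_lstm"`.
#' @param input_len Number of input variables.
#' @return An untrained `spectral_model`.
#' @export
build_model <- function(kind, input_len) {
  switch(kind,
    cnn = build_cnn1d(input_len = input_len),
    lstm = build_lstm(input_len = input_len),
    cnn_lstm = build_cnn_lstm(input_len = input_len),
    alexnet1d = build_variant("alexnet1d", input_len),
    alexnet_lstm = build_variant("alexnet_lstm", input_len),
    stop("unknown model kind: ", kind)
  )
}

#' Parameters of a single LSTM cell
#'
#' Weight matrices act on the concatenation `[h_prev, x_t]` (hidden state
#' first), one matrix and bias per role: candidate memory (`Wc`, `bc`),
#' forget ("oblivion") gate (`Wf`, `bf`), update gate (`Wi`, `bi`) and
#' output gate (`Wo`, `bo`).
#'
#' @param Wc,Wf,Wi,Wo Matrices of shape `hidden x (hidden + input)`.
#' @param bc,bf,bi,bo Bias vectors of length `hidden`.
#' @return Object of class `lstm_cell_params`.
#' @export
lstm_cell_params <- function(Wc, Wf, Wi, Wo, bc, bf, bi, bo) {
  Wc <- as.matrix(Wc); Wf <- as.matrix(Wf)
  Wi <- as.matrix(Wi); Wo <- as.matrix(Wo)
  H <- nrow(Wc)
  for (W in list(Wf, Wi, Wo))
    if (!identical(dim(W), dim(Wc))) stop("all weight matrices must share shape")
  for (b in list(bc, bf, bi, bo))
    if (length(b) != H) stop("bias length must equal hidden size")
  if (ncol(Wc) <= H) stop("weight columns must cover hidden + input width")
  structure(list(Wc = Wc, Wf = Wf, Wi = Wi, Wo = Wo,
                 bc = bc, bf = bf, bi = bi, bo = bo,
                 hidden_size = H, input_size = ncol(Wc) - H),
            class = "lstm_cell_params")
}

#' One LSTM cell step
#'
#' Computes, with `A = [h_prev, x_t]` and elementwise products:
#' candidate `Ct~ = tanh(Wc A + bc)`; forget gate `ft = sigmoid(Wf A + bf)`;
#' update gate `it = sigmoid(Wi A + bi)`; output gate
#' `ot = sigmoid(Wo A + bo)`; memory `Ct = ft * C_prev + it * Ct~`; hidden
#' output `ht = ot * tanh(Ct)`.
#'
#' @param params An [lstm_cell_params()] object.
#' @param x_t Input vector of length `params$input_size`.
#' @param prev List with vectors `h` and `c` (previous hidden and memory
#'   state); defaults to zeros.
#' @return List with fields `h`, `c` and the intermediate `candidate`,
#'   `f`, `i`, `o` gate activations.
#' @export
lstm_cell_step <- function(params, x_t, prev = NULL) {
  H <- params$hidden_size
  if (is.null(prev)) prev <- list(h = numeric(H), c = numeric(H))
  if (length(x_t) != params$input_size)
    stop(sprintf("dimension mismatch: x_t has length %d, expected %d",
                 length(x_t), params$input_size))
  if (length(prev$h) != H || length(prev$c) != H)
    stop("dimension mismatch: prev state does not match hidden size")
  A <- c(prev$h, x_t)
  cand <- tanh(drop(params$Wc %*% A) + params$bc)
  f <- sigmoid(drop(params$Wf %*% A) + params$bf)
  i <- sigmoid(drop(params$Wi %*% A) + params$bi)
  o <- sigmoid(drop(params$Wo %*% A) + params$bo)
  cnew <- f * prev$c + i * cand
  list(h = o * tanh(cnew), c = cnew, candidate = cand, f = f, i = i, o = o)
}

#' Count trainable parameters of a model
#' @param model A `spectral_model`.
#' @param types Optional layer types to restrict to (e.g. `"conv"`).
#' @return Integer parameter count. For untrained models the count is
#'   derived from the resolved layer shapes.
#' @export
n_parameters <- function(model, types = NULL) {
  total <- 0L
  for (ly in model$layers) {
    if (!is.null(types) && !(ly$type %in% types)) next
    total <- total + switch(ly$type,
      conv = ly$k * ly$in_shape$C * ly$filters + ly$filters,
      dense = ly$in_shape$d * ly$units + ly$units,
      bn = 2L * ly$in_shape$C,
      lstm = 4L * (ly$hidden * (ly$hidden + ly$in_shape$C) + ly$hidden),
      0L)
  }
  as.integer(total)
}

#' Sequence shape entering the LSTM of a hybrid model
#' @param model A `spectral_model` containing an LSTM layer.
#' @return List with `steps` (sequence length) and `features` (channel
#'   width per step).
#' @export
lstm_input_shape <- function(model) {
  for (ly in model$layers)
    if (ly$type == "lstm")
      return(list(steps = ly$in_shape$L %||% 1L, features = ly$in_shape$C))
  stop("model contains no LSTM layer")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("<spectral_model:%s> input_len=%d, %s, %d parameters\n",
              x$kind, x$input_len,
              if (x$trained) "trained" else "untrained", n_parameters(x)))
  invisible(x)
}
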