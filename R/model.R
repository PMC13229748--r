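# Hybrid conv-attention-BiLSTM respiratory waveform network.
#
# Architecture: per-timestep affine embedding of the 4 input channels into
# d_model features; three 1-D convolution blocks with decreasing kernels
# (7, 5, 3), each conv -> ReLU -> batch norm -> dropout; multi-head
# self-attention with residual connection and layer normalization; a stacked
# bidirectional LSTM whose concatenated directions preserve d_model; and a
# three-stage convolutional decoder (d_model -> 64 -> 32 -> 1, kernels
# 5/3/1) emitting the predicted respiratory waveform. Sequence length is
# preserved at every stage.

#' Network configuration
#'
#' @param d_model Feature embedding width (default 128).
#' @param conv_kernels Encoder kernel sizes, largest first (default 7, 5, 3).
#' @param n_heads Attention heads (default 8); must divide `d_model`.
#' @param lstm_layers Stacked BiLSTM layers (default 2).
#' @param lstm_hidden Per-direction hidden width (default `d_model / 2` so
#'   the concatenated output keeps the embedding width).
#' @param decoder_channels Decoder widths ending in 1 (default 64, 32, 1).
#' @param decoder_kernels Decoder kernel sizes (default 5, 3, 1).
#' @param dropout Dropout rate in the conv blocks, attention and between
#'   LSTM layers.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d_model = 128, conv_kernels = c(7, 5, 3),
                         n_heads = 8, lstm_layers = 2,
                         lstm_hidden = d_model / 2,
                         decoder_channels = c(64, 32, 1),
                         decoder_kernels = c(5, 3, 1),
                         dropout = 0.2) {
  if (d_model %% n_heads != 0) {
    stop("config error: d_model must be divisible by n_heads")
  }
  if (2 * lstm_hidden != d_model) {
    stop("config error: lstm_hidden must equal d_model / 2")
  }
  if (utils::tail(decoder_channels, 1) != 1) {
    stop("config error: decoder must end in 1 channel")
  }
  if (length(decoder_kernels) != length(decoder_channels)) {
    stop("config error: decoder kernels/channels length mismatch")
  }
  if (dropout < 0 || dropout >= 1) stop("config error: dropout must be in [0,1)")
  if (any(conv_kernels %% 2 == 0)) stop("config error: kernels must be odd")
  structure(list(d_model = d_model, conv_kernels = conv_kernels,
                 n_heads = n_heads, d_k = d_model / n_heads,
                 lstm_layers = lstm_layers, lstm_hidden = lstm_hidden,
                 decoder_channels = decoder_channels,
                 decoder_kernels = decoder_kernels, dropout = dropout),
            class = "model_config")
}

unif_init <- function(nr, nc, k) matrix(stats::runif(nr * nc, -k, k), nr, nc)

#' Initialize network parameters
#'
#' Kaiming-style initialization for convolutions, Xavier for projections,
#' uniform `1/sqrt(H)` for LSTM weights with the forget-gate bias at +1.
#'
#' @param cfg A [model_config()].
#' @param seed RNG seed for reproducible initialization.
#' @return List with `params` (flat named list of weight arrays), `state`
#'   (batch-norm running statistics), `cfg` and `seed` — a `respnet_model`.
#' @export
init_model <- function(cfg = model_config(), seed = 1) {
  with_seed(seed, {
    D <- cfg$d_model
    p <- list()
    s <- list()
    k_emb <- sqrt(6 / (4 + D))
    p[["emb.W"]] <- unif_init(4, D, k_emb)
    p[["emb.b"]] <- numeric(D)
    for (l in seq_along(cfg$conv_kernels)) {
      k <- cfg$conv_kernels[l]
      sd <- sqrt(2 / (D * k))
      p[[sprintf("conv%d.W", l)]] <- matrix(stats::rnorm(D * k * D, 0, sd), D * k, D)
      p[[sprintf("conv%d.b", l)]] <- numeric(D)
      p[[sprintf("bn%d.gamma", l)]] <- rep(1, D)
      p[[sprintf("bn%d.beta", l)]] <- numeric(D)
      s[[sprintf("bn%d", l)]] <- list(mean = numeric(D), var = rep(1, D))
    }
    k_att <- sqrt(6 / (2 * D))
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0("attn.", nm)]] <- unif_init(D, D, k_att)
    }
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0("attn.", nm)]] <- numeric(D)
    p[["attn.ln_gamma"]] <- rep(1, D)
    p[["attn.ln_beta"]] <- numeric(D)
    H <- cfg$lstm_hidden
    kh <- 1 / sqrt(H)
    for (l in seq_len(cfg$lstm_layers)) {
      cin <- D  # BiLSTM concat keeps width D between layers
      for (dir in c("f", "b")) {
        pre <- sprintf("lstm%d%s", l, dir)
        p[[paste0(pre, ".Wx")]] <- unif_init(cin, 4 * H, kh)
        p[[paste0(pre, ".Wh")]] <- unif_init(H, 4 * H, kh)
        bias <- numeric(4 * H)
        bias[(H + 1):(2 * H)] <- 1  # forget gate bias
        p[[paste0(pre, ".b")]] <- bias
      }
    }
    cin <- D
    for (l in seq_along(cfg$decoder_channels)) {
      cout <- cfg$decoder_channels[l]
      k <- cfg$decoder_kernels[l]
      sd <- sqrt(2 / (cin * k))
      p[[sprintf("dec%d.W", l)]] <- matrix(stats::rnorm(cin * k * cout, 0, sd),
                                           cin * k, cout)
      p[[sprintf("dec%d.b", l)]] <- numeric(cout)
      cin <- cout
    }
    structure(list(params = p, state = s, cfg = cfg, seed = seed),
              class = "respnet_model")
  })
}

#' @export
print.respnet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<respnet_model: d_model=%d, heads=%d, %d conv blocks, %d BiLSTM layers, %s params>\n",
    x$cfg$d_model, x$cfg$n_heads, length(x$cfg$conv_kernels),
    x$cfg$lstm_layers, format(np, big.mark = ",")))
  invisible(x)
}

#' Project a multi-channel window into the feature embedding
#'
#' Learned affine map applied per timestep, channels -> `d_model`.
#'
#' @param X (B*T) x 4 matrix (batch-major rows) or a T x 4 window matrix.
#' @param W 4 x d_model weight matrix.
#' @param b Length-d_model bias.
#' @return (B*T) x d_model feature matrix.
#' @export
project_embedding <- function(X, W, b) {
  if (ncol(X) != nrow(W)) stop("invalid-parameter: wrong channel count")
  addb(X %*% W, b)
}

# Full forward pass. X: (B*T) x 4 batch-major. Returns yhat (B*T) x 1 plus
# caches (train) and updated batch-norm state.
model_forward <- function(model, X, B, T, mode = c("eval", "train"),
                          keep_cache = (mode == "train")) {
  mode <- match.arg(mode)
  p <- model$params; cfg <- model$cfg; st <- model$state
  cache <- list(B = B, T = T)
  h <- project_embedding(X, p[["emb.W"]], p[["emb.b"]])
  cache$X_in <- X
  for (l in seq_along(cfg$conv_kernels)) {
    cv <- conv1d_forward(h, p[[sprintf("conv%d.W", l)]],
                         p[[sprintf("conv%d.b", l)]],
                         cfg$conv_kernels[l], B, T)
    relu_mask <- cv$out > 0
    a <- cv$out * relu_mask
    bn <- bn_forward(a, p[[sprintf("bn%d.gamma", l)]],
                     p[[sprintf("bn%d.beta", l)]],
                     st[[sprintf("bn%d", l)]], mode)
    st[[sprintf("bn%d", l)]] <- bn$running
    dr <- dropout_forward(bn$out, cfg$dropout, mode)
    if (keep_cache) {
      cache[[sprintf("conv%d", l)]] <- list(conv = cv$cache, relu = relu_mask,
                                            bn = bn$cache, drop = dr$cache)
    }
    h <- dr$out
  }
  attr(h, "B") <- B; attr(h, "T") <- T
  att <- mha_forward(h, p, "attn", cfg, mode)
  if (keep_cache) cache$attn <- att$cache
  h <- att$out
  H <- cfg$lstm_hidden
  for (l in seq_len(cfg$lstm_layers)) {
    fw <- lstm_forward(h, p[[sprintf("lstm%df.Wx", l)]],
                       p[[sprintf("lstm%df.Wh", l)]],
                       p[[sprintf("lstm%df.b", l)]], B, T, "fwd")
    bw <- lstm_forward(h, p[[sprintf("lstm%db.Wx", l)]],
                       p[[sprintf("lstm%db.Wh", l)]],
                       p[[sprintf("lstm%db.b", l)]], B, T, "bwd")
    hcat <- cbind(fw$out, bw$out)
    dr <- dropout_forward(hcat, if (l < cfg$lstm_layers) cfg$dropout else 0,
                          mode)
    if (keep_cache) {
      cache[[sprintf("lstm%d", l)]] <- list(f = fw$cache, b = bw$cache,
                                            drop = dr$cache)
    }
    h <- dr$out
  }
  for (l in seq_along(cfg$decoder_channels)) {
    cv <- conv1d_forward(h, p[[sprintf("dec%d.W", l)]],
                         p[[sprintf("dec%d.b", l)]],
                         cfg$decoder_kernels[l], B, T)
    last <- l == length(cfg$decoder_channels)
    relu_mask <- if (last) NULL else cv$out > 0
    if (keep_cache) {
      cache[[sprintf("dec%d", l)]] <- list(conv = cv$cache, relu = relu_mask)
    }
    h <- if (last) cv$out else cv$out * relu_mask
  }
  list(yhat = h, cache = if (keep_cache) cache else NULL, state = st)
}

# Full backward pass; dY: (B*T) x 1 gradient of the loss wrt yhat.
model_backward <- function(model, dY, cache) {
  p <- model$params; cfg <- model$cfg
  g <- list()
  dh <- dY
  for (l in rev(seq_along(cfg$decoder_channels))) {
    cc <- cache[[sprintf("dec%d", l)]]
    if (!is.null(cc$relu)) dh <- dh * cc$relu
    bk <- conv1d_backward(dh, p[[sprintf("dec%d.W", l)]], cc$conv)
    g[[sprintf("dec%d.W", l)]] <- bk$dW
    g[[sprintf("dec%d.b", l)]] <- bk$db
    dh <- bk$dX
  }
  H <- cfg$lstm_hidden
  for (l in rev(seq_len(cfg$lstm_layers))) {
    cc <- cache[[sprintf("lstm%d", l)]]
    dh <- dropout_backward(dh, cc$drop)
    dfw <- dh[, 1:H, drop = FALSE]
    dbw <- dh[, (H + 1):(2 * H), drop = FALSE]
    bf <- lstm_backward(dfw, p[[sprintf("lstm%df.Wx", l)]],
                        p[[sprintf("lstm%df.Wh", l)]], cc$f)
    bb <- lstm_backward(dbw, p[[sprintf("lstm%db.Wx", l)]],
                        p[[sprintf("lstm%db.Wh", l)]], cc$b)
    g[[sprintf("lstm%df.Wx", l)]] <- bf$dWx
    g[[sprintf("lstm%df.Wh", l)]] <- bf$dWh
    g[[sprintf("lstm%df.b", l)]] <- bf$db
    g[[sprintf("lstm%db.Wx", l)]] <- bb$dWx
    g[[sprintf("lstm%db.Wh", l)]] <- bb$dWh
    g[[sprintf("lstm%db.b", l)]] <- bb$db
    dh <- bf$dX + bb$dX
  }
  att <- mha_backward(dh, p, "attn", cfg, cache$attn)
  g <- c(g, att$grads)
  dh <- att$dX
  for (l in rev(seq_along(cfg$conv_kernels))) {
    cc <- cache[[sprintf("conv%d", l)]]
    dh <- dropout_backward(dh, cc$drop)
    bn <- bn_backward(dh, cc$bn)
    g[[sprintf("bn%d.gamma", l)]] <- bn$dgamma
    g[[sprintf("bn%d.beta", l)]] <- bn$dbeta
    dh <- bn$dX * cc$relu
    bk <- conv1d_backward(dh, p[[sprintf("conv%d.W", l)]], cc$conv)
    g[[sprintf("conv%d.W", l)]] <- bk$dW
    g[[sprintf("conv%d.b", l)]] <- bk$db
    dh <- bk$dX
  }
  g[["emb.W"]] <- crossprod(cache$X_in, dh)
  g[["emb.b"]] <- colSums(dh)
  g
}

#' Predict a respiratory waveform for one window
#'
#' Deterministic evaluation-mode forward pass (dropout off, batch norm on
#' frozen running statistics).
#'
#' @param model A trained `respnet_model`.
#' @param window A `multi_channel_window` (or T x 4 matrix).
#' @param fs Sampling rate to attach when a bare matrix is given.
#' @return A [temporal_signal()] labeled `predicted` of the window's length.
#' @export
predict_waveform <- function(model, window, fs = NULL) {
  if (inherits(window, "multi_channel_window")) {
    X <- window$values
    fs <- window$fs
  } else {
    X <- window
    if (is.null(fs)) stop("invalid-parameter: fs required for a bare matrix")
  }
  if (ncol(X) != 4) stop("invalid-parameter: window must have 4 channels")
  fwd <- model_forward(model, X, B = 1, T = nrow(X), mode = "eval")
  temporal_signal(as.numeric(fwd$yhat), fs, "predicted")
}
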