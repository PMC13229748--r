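# Network components: embeddings, convolution, attention, BiLSTM, decoder,
# gradients, training behavior, k-fold splitting, checkpoints.

test_that("embedding projects channels per timestep with shape preservation", {
  set.seed(25)
  W <- matrix(rnorm(4 * 128, 0, 0.1), 4, 128)
  b <- rnorm(128)
  for (T in c(200, 256, 300)) {
    X <- matrix(rnorm(T * 4), T, 4)
    out <- project_embedding(X, W, numeric(128))
    expect_equal(dim(out), c(T, 128))
  }
  X <- matrix(0, 10, 4)
  expect_true(all(project_embedding(X, W, numeric(128)) == 0))
  # identity-like weights copy channels into the first four feature dims
  Wid <- matrix(0, 4, 8); diag(Wid) <- 1
  Xr <- matrix(rnorm(40), 10, 4)
  expect_equal(project_embedding(Xr, Wid, numeric(8))[, 1:4], Xr)
  expect_error(project_embedding(matrix(0, 5, 3), W, b), "invalid-parameter")
})

test_that("temporal convolution matches a direct summation oracle", {
  # length-5, width-1 toy: centered kernel, zero padding
  x <- c(1, 2, -1, 3, 0.5)
  w <- c(0.2, -0.5, 1)
  cv <- respcam:::conv1d_forward(matrix(x, 5, 1), matrix(w, 3, 1), 0.7,
                                 k = 3, B = 1, T = 5)
  xp <- c(0, x, 0)
  oracle <- vapply(1:5, function(t) {
    sum(w * xp[t:(t + 2)]) + 0.7
  }, numeric(1))
  expect_equal(as.numeric(cv$out), oracle)

  # kernel 1 with identity weight reduces to an affine map
  set.seed(26)
  X <- matrix(rnorm(12), 6, 2)
  cv1 <- respcam:::conv1d_forward(X, diag(2), c(0, 0), k = 1, B = 1, T = 6)
  expect_equal(cv1$out, X)

  # T preserved for kernels 7, 5, 3 across batch sizes
  for (k in c(7, 5, 3)) {
    Xb <- matrix(rnorm(2 * 9 * 3), 18, 3)
    cvk <- respcam:::conv1d_forward(Xb, matrix(rnorm(3 * k * 4), 3 * k, 4),
                                    numeric(4), k = k, B = 2, T = 9)
    expect_equal(dim(cvk$out), c(18, 4))
  }
})

test_that("scaled dot-product attention satisfies its softmax identities", {
  set.seed(27)
  V <- matrix(rnorm(8), 1, 8)
  one <- scaled_dot_attention(matrix(rnorm(8), 1, 8),
                              matrix(rnorm(8), 1, 8), V)
  expect_equal(one$out, V)  # single-row softmax is 1

  T <- 7; dk <- 4
  K <- matrix(rnorm(T * dk), T, dk); Vv <- matrix(rnorm(T * dk), T, dk)
  unif <- scaled_dot_attention(matrix(0, T, dk), K, Vv)
  expect_equal(unif$out, matrix(colMeans(Vv), T, dk, byrow = TRUE),
               tolerance = 1e-12)

  att <- scaled_dot_attention(matrix(rnorm(T * dk), T, dk), K, Vv)
  expect_equal(rowSums(att$weights), rep(1, T), tolerance = 1e-6)
  expect_true(all(att$weights >= 0))
})

test_that("multi-head attention preserves shape and has stochastic rows", {
  cfg <- tiny_model_config()
  model <- init_model(cfg, seed = 3)
  set.seed(28)
  X <- matrix(rnorm(2 * 10 * cfg$d_model), 20, cfg$d_model)
  attr(X, "B") <- 2; attr(X, "T") <- 10
  out <- respcam:::mha_forward(X, model$params, "attn", cfg, "eval")
  expect_equal(dim(out$out), dim(X))
  for (A in out$cache$A) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
  }
  # zeroed output projection leaves the layer-normalized residual
  m0 <- model
  m0$params[["attn.Wo"]] <- m0$params[["attn.Wo"]] * 0
  m0$params[["attn.bo"]] <- m0$params[["attn.bo"]] * 0
  pure <- respcam:::mha_forward(X, m0$params, "attn", cfg, "eval")
  ln <- respcam:::ln_forward(X, m0$params[["attn.ln_gamma"]],
                             m0$params[["attn.ln_beta"]])
  expect_equal(pure$out, ln$out, ignore_attr = TRUE)
  # layer-norm rows are standardized before the affine map
  expect_lt(max(abs(rowMeans(ln$cache$xhat))), 1e-9)
})

test_that("BiLSTM forward matches a hand-stepped recurrence at T=3, width 2", {
  H <- 2; Cin <- 2; T <- 3
  set.seed(29)
  Wx <- matrix(rnorm(Cin * 4 * H, 0, 0.5), Cin, 4 * H)
  Wh <- matrix(rnorm(H * 4 * H, 0, 0.5), H, 4 * H)
  b <- rnorm(4 * H, 0, 0.2)
  X <- matrix(rnorm(T * Cin), T, Cin)
  out <- respcam:::lstm_forward(X, Wx, Wh, b, B = 1, T = T, "fwd")$out

  sig <- function(z) 1 / (1 + exp(-z))
  h <- c(0, 0); cst <- c(0, 0)
  manual <- matrix(0, T, H)
  for (t in 1:T) {
    z <- as.numeric(X[t, ] %*% Wx + h %*% Wh + b)
    i <- sig(z[1:2]); f <- sig(z[3:4]); g <- tanh(z[5:6]); o <- sig(z[7:8])
    cst <- f * cst + i * g
    h <- o * tanh(cst)
    manual[t, ] <- h
  }
  expect_equal(out, manual, tolerance = 1e-12)

  # zero parameters give a zero fixed point
  z0 <- respcam:::lstm_forward(X, Wx * 0, Wh * 0, b * 0, 1, T, "fwd")$out
  expect_true(all(z0 == 0))

  # time reversal: running the backward direction equals reversing input,
  # running forward, and reversing the output
  bwd <- respcam:::lstm_forward(X, Wx, Wh, b, 1, T, "bwd")$out
  fwd_rev <- respcam:::lstm_forward(X[T:1, ], Wx, Wh, b, 1, T, "fwd")$out
  expect_equal(bwd, fwd_rev[T:1, ], tolerance = 1e-12)
})

test_that("end-to-end shape contract holds for T in {200, 256, 300}", {
  model <- init_model(model_config(), seed = 1)
  for (T in c(200, 256, 300)) {
    X <- matrix(rnorm(T * 4), T, 4)
    fwd <- respcam:::model_forward(model, X, B = 1, T = T, mode = "eval")
    expect_equal(dim(fwd$yhat), c(T, 1))
  }
  expect_equal(model$cfg$d_k, 16)
  expect_equal(2 * model$cfg$lstm_hidden, 128)
})

test_that("decoder stage widths follow the 64/32/1 compression", {
  cfg <- model_config()
  expect_equal(cfg$decoder_channels, c(64, 32, 1))
  model <- init_model(cfg, seed = 2)
  expect_equal(dim(model$params[["dec1.W"]]), c(128 * 5, 64))
  expect_equal(dim(model$params[["dec2.W"]]), c(64 * 3, 32))
  expect_equal(dim(model$params[["dec3.W"]]), c(32 * 1, 1))
})

test_that("analytic gradients match finite differences through the whole network", {
  cfg <- tiny_model_config(dropout = 0)
  model <- init_model(cfg, seed = 9)
  set.seed(42)
  B <- 2; T <- 6
  X <- matrix(rnorm(B * T * 4), B * T, 4)
  Y <- matrix(rnorm(B * T), B * T, 1)
  loss_fn <- function(m) {
    fwd <- respcam:::model_forward(m, X, B, T, mode = "train")
    mean((fwd$yhat - Y)^2)
  }
  fwd <- respcam:::model_forward(model, X, B, T, mode = "train")
  dY <- 2 * (fwd$yhat - Y) / length(Y)
  g <- respcam:::model_backward(model, dY, fwd$cache)
  eps <- 1e-6
  for (nm in c("emb.W", "conv1.W", "bn1.gamma", "attn.Wq", "attn.Wo",
               "attn.ln_gamma", "lstm1f.Wx", "lstm2b.Wh", "dec1.W", "dec2.b")) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- model; m2$params[[nm]][i] <- p[i] + eps
      m3 <- model; m3$params[[nm]][i] <- p[i] - eps
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      rel <- abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i]))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("evaluation-mode prediction is a pure function of the window", {
  cfg <- tiny_model_config(dropout = 0.2)
  model <- init_model(cfg, seed = 4)
  w <- structure(list(values = matrix(rnorm(64 * 4), 64, 4),
                      start_index = 0, fs = 30),
                 class = "multi_channel_window")
  p1 <- predict_waveform(model, w)
  p2 <- predict_waveform(model, w)
  expect_identical(p1$samples, p2$samples)
  expect_equal(length(p1$samples), 64)
})

test_that("training is deterministic, reduces loss, and the schedule plateaus", {
  ts <- tiny_training_set()
  cfg <- small_model_config()
  tc <- train_config(epochs = 4, batch_size = 8, seed = 13)
  m1 <- train_model(ts$windows, ts$targets, cfg, tc, val_idx = c(1, 2))
  m2 <- train_model(ts$windows, ts$targets, cfg, tc, val_idx = c(1, 2))
  expect_identical(attr(m1, "history"), attr(m2, "history"))
  h <- attr(m1, "history")
  expect_lt(h$train_loss[4], h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))
  expect_error(train_model(list(), list(), cfg, tc), "empty training set")
})

test_that("subject-level k-fold splits partition without overlap", {
  ids <- sprintf("s%02d", 1:10)
  folds <- subject_kfold_split(ids, k = 5, seed = 3)
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(vapply(tests, length, numeric(1)) == 2))
  expect_setequal(unlist(tests), ids)
  expect_equal(anyDuplicated(unlist(tests)), 0)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val, f$test), ids)
  }
  expect_identical(subject_kfold_split(ids, 5, seed = 3), folds)
  expect_false(identical(subject_kfold_split(ids, 5, seed = 4), folds))
  expect_error(subject_kfold_split(ids[1:3], 5), "invalid-parameter")
})

test_that("checkpoints round-trip parameters, config and seed", {
  cfg <- tiny_model_config()
  model <- init_model(cfg, seed = 21)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$params, model$params)
  expect_equal(back$cfg, model$cfg)
  expect_equal(back$seed, 21)
  w <- matrix(rnorm(32 * 4), 32, 4)
  expect_identical(predict_waveform(model, w, fs = 30)$samples,
                   predict_waveform(back, w, fs = 30)$samples)
  saveRDS(list(format = "other"), path)
  expect_error(load_model(path), "invalid-parameter")
})

test_that("model_config validates its structural constraints", {
  expect_error(model_config(d_model = 100, n_heads = 8), "divisible")
  expect_error(model_config(lstm_hidden = 32), "lstm_hidden")
  expect_error(model_config(decoder_channels = c(64, 32)), "1 channel|length")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(conv_kernels = c(6, 4, 2)), "odd")
})
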