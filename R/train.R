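# Training: AdamW with decoupled weight decay, reduce-on-plateau scheduling,
# subject-level k-fold splitting, and batched prediction.

#' Training configuration
#'
#' @param lr Initial learning rate (default 0.001).
#' @param batch_size Windows per batch (default 32).
#' @param epochs Training epochs (default 100).
#' @param weight_decay Decoupled weight decay (default 1e-4).
#' @param plateau_factor,plateau_patience Reduce-on-plateau settings: the
#'   learning rate is multiplied by `plateau_factor` after
#'   `plateau_patience` epochs without validation improvement.
#' @param k_folds Folds for subject-level cross-validation (default 5).
#' @param val_frac Fraction of subjects held out for validation (default 0.1;
#'   with the 0.2 test fold this yields a 70/10/20 split).
#' @param seed RNG seed controlling shuffling, dropout and initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 32, epochs = 100,
                         weight_decay = 1e-4, plateau_factor = 0.5,
                         plateau_patience = 5, k_folds = 5,
                         val_frac = 0.1, seed = 1) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, k_folds >= 2,
            val_frac >= 0, val_frac < 1)
  structure(list(lr = lr, batch_size = batch_size, epochs = epochs,
                 weight_decay = weight_decay,
                 plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 k_folds = k_folds, val_frac = val_frac, seed = seed),
            class = "train_config")
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adamw_step <- function(params, grads, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, opt = opt)
}

stack_windows <- function(windows, idx) {
  do.call(rbind, lapply(windows[idx], function(w) w$values))
}

# Evaluation-mode mean squared error over a set of windows.
eval_loss <- function(model, windows, targets, idx, batch_size) {
  if (length(idx) == 0) return(NA_real_)
  T <- nrow(windows[[idx[1]]]$values)
  tot <- 0; n <- 0
  for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
    X <- stack_windows(windows, chunk)
    Y <- matrix(unlist(targets[chunk]), ncol = 1)
    fwd <- model_forward(model, X, B = length(chunk), T = T, mode = "eval")
    tot <- tot + sum((fwd$yhat - Y)^2)
    n <- n + length(Y)
  }
  tot / n
}

#' Train the respiratory waveform network
#'
#' Minimizes the mean squared error between the predicted and reference
#' waveforms per window using AdamW (decoupled weight decay) with a
#' reduce-on-plateau learning-rate schedule monitored on validation loss.
#' Returns the parameters of the best validation epoch (final epoch when no
#' validation set is given). Fully seeded: identical inputs and seed yield an
#' identical loss history.
#'
#' @param windows List of `multi_channel_window` objects.
#' @param targets List of numeric vectors: the aligned reference waveform per
#'   window (belt, resampled, bandpassed, three-sigma normalized).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param val_idx Indices of `windows` used for validation; the rest train.
#' @param verbose Print per-epoch losses.
#' @return A `respnet_model` with an attached `history` data frame
#'   (epoch, train_loss, val_loss, lr).
#' @export
train_model <- function(windows, targets, model_cfg = model_config(),
                        train_cfg = train_config(), val_idx = integer(0),
                        verbose = FALSE) {
  stopifnot(length(windows) == length(targets))
  train_idx <- setdiff(seq_along(windows), val_idx)
  if (length(train_idx) == 0) stop("empty training set")
  T <- nrow(windows[[1]]$values)
  model <- init_model(model_cfg, seed = train_cfg$seed)
  opt <- adamw_init(model$params)
  lr <- train_cfg$lr
  best_val <- Inf; best_params <- model$params; best_state <- model$state
  since_improve <- 0
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  with_seed(derive_seed(train_cfg$seed, 7), {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      ep_loss <- 0; ep_n <- 0
      for (bt in batches) {
        X <- stack_windows(windows, bt)
        Y <- matrix(unlist(targets[bt]), ncol = 1)
        fwd <- model_forward(model, X, B = length(bt), T = T, mode = "train")
        model$state <- fwd$state
        resid <- fwd$yhat - Y
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop("training aborted: non-finite loss at epoch ", ep)
        }
        ep_loss <- ep_loss + loss * length(Y); ep_n <- ep_n + length(Y)
        dY <- 2 * resid / length(resid)
        grads <- model_backward(model, dY, fwd$cache)
        upd <- adamw_step(model$params, grads, opt, lr,
                          train_cfg$weight_decay)
        model$params <- upd$params
        opt <- upd$opt
      }
      train_loss <- ep_loss / ep_n
      val_loss <- eval_loss(model, windows, targets, val_idx,
                            train_cfg$batch_size)
      monitor <- if (is.na(val_loss)) train_loss else val_loss
      if (monitor < best_val - 1e-12) {
        best_val <- monitor
        best_params <- model$params
        best_state <- model$state
        since_improve <- 0
      } else {
        since_improve <- since_improve + 1
        if (since_improve >= train_cfg$plateau_patience) {
          lr <- lr * train_cfg$plateau_factor
          since_improve <- 0
        }
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = train_loss,
                                     val_loss = val_loss, lr = lr))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                        ep, train_loss, val_loss, lr))
      }
    }
  })
  model$params <- best_params
  model$state <- best_state
  attr(model, "history") <- hist
  model
}

#' Batched evaluation-mode prediction for many windows
#'
#' @param model A `respnet_model`.
#' @param windows List of `multi_channel_window`s of equal length.
#' @param batch_size Windows per forward pass.
#' @return List of numeric prediction vectors, one per window.
#' @export
predict_windows <- function(model, windows, batch_size = 32) {
  T <- nrow(windows[[1]]$values)
  out <- vector("list", length(windows))
  idx <- seq_along(windows)
  for (chunk in split(idx, ceiling(idx / batch_size))) {
    X <- stack_windows(windows, chunk)
    fwd <- model_forward(model, X, B = length(chunk), T = T, mode = "eval")
    for (j in seq_along(chunk)) {
      out[[chunk[j]]] <- as.numeric(fwd$yhat[((j - 1) * T + 1):(j * T), 1])
    }
  }
  out
}

#' Reconstruct a full predicted waveform from overlapping windows
#'
#' Predicts every window in evaluation mode and averages overlapping samples.
#'
#' @param model A `respnet_model`.
#' @param windows List of `multi_channel_window`s from one recording.
#' @param total_len Recording length in samples.
#' @return A [temporal_signal()] labeled `predicted`.
#' @export
predict_recording <- function(model, windows, total_len) {
  preds <- predict_windows(model, windows)
  starts <- vapply(windows, function(w) w$start_index, numeric(1))
  overlap_average(preds, starts, total_len, windows[[1]]$fs)
}

#' Subject-level k-fold assignments
#'
#' Each subject appears in exactly one test fold; within each fold the
#' remaining subjects are split into train and validation sets (by count,
#' rounded) so no subject ever crosses the train/test boundary.
#'
#' @param subject_ids Vector of unique subject identifiers.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @param val_frac Validation fraction of all subjects (default 0.1).
#' @return List of `k` elements, each with `train`, `val`, `test` id vectors.
#' @export
subject_kfold_split <- function(subject_ids, k = 5, seed = 1, val_frac = 0.1) {
  n <- length(subject_ids)
  if (k > n) stop("invalid-parameter: more folds than subjects")
  with_seed(derive_seed(seed, 11), {
    perm <- sample(subject_ids)
    fold_of <- rep(seq_len(k), length.out = n)
    lapply(seq_len(k), function(f) {
      test <- perm[fold_of == f]
      rest <- perm[fold_of != f]
      n_val <- min(length(rest) - 1, max(1, round(val_frac * n)))
      val <- rest[seq_len(n_val)]
      list(train = setdiff(rest, val), val = val, test = test)
    })
  })
}

#' Save a model checkpoint
#'
#' Single serialized file holding a format version, the configuration, the
#' initialization seed, parameters and batch-norm state.
#'
#' @param model A `respnet_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "respcam-checkpoint-1", cfg = model$cfg,
               seed = model$seed, params = model$params,
               state = model$state, history = attr(model, "history")),
          path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Checkpoint file path.
#' @return A `respnet_model`.
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "respcam-checkpoint-1")) {
    stop("invalid-parameter: unrecognized checkpoint format")
  }
  m <- structure(list(params = x$params, state = x$state, cfg = x$cfg,
                      seed = x$seed), class = "respnet_model")
  attr(m, "history") <- x$history
  m
}
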