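# Primitive differentiable layers for the respiratory waveform network.
#
# Activations are matrices of shape (B*T) x C with rows in batch-major order
# (row (b-1)*T + t holds timestep t of batch item b). Every layer returns its
# output together with a cache consumed by the matching backward function;
# gradients are verified against finite differences in the test suite.

addb <- function(M, b) M + rep(b, each = nrow(M))
sigm <- function(z) 1 / (1 + exp(-z))

## ---- temporal 1-D convolution (same-length zero padding, centered) ----

conv1d_forward <- function(X, W, b, k, B, T) {
  Cin <- ncol(X)
  p <- (k - 1) / 2
  tv <- rep(seq_len(T), B)
  Xcol <- matrix(0, B * T, Cin * k)
  for (j in seq_len(k)) {
    o <- j - 1 - p
    ok <- tv + o >= 1 & tv + o <= T
    cols <- ((j - 1) * Cin + 1):(j * Cin)
    Xcol[ok, cols] <- X[which(ok) + o, , drop = FALSE]
  }
  Y <- addb(Xcol %*% W, b)
  list(out = Y, cache = list(Xcol = Xcol, k = k, B = B, T = T, Cin = Cin))
}

conv1d_backward <- function(dY, W, cache) {
  k <- cache$k; B <- cache$B; T <- cache$T; Cin <- cache$Cin
  p <- (k - 1) / 2
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)
  dX <- matrix(0, B * T, Cin)
  tv <- rep(seq_len(T), B)
  for (j in seq_len(k)) {
    o <- j - 1 - p
    ok <- tv + o >= 1 & tv + o <= T
    cols <- ((j - 1) * Cin + 1):(j * Cin)
    src <- which(ok) + o
    dX[src, ] <- dX[src, , drop = FALSE] + dXcol[ok, cols, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- batch normalization over rows (per feature channel) ----

bn_forward <- function(X, gamma, beta, running, mode, momentum = 0.1,
                       eps = 1e-5) {
  if (mode == "train") {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  xc <- addb(X, -mu)
  xhat <- xc * matrix(inv, nrow(X), ncol(X), byrow = TRUE)
  out <- addb(xhat * matrix(gamma, nrow(X), ncol(X), byrow = TRUE), beta)
  list(out = out, running = running,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, xc = xc))
}

bn_backward <- function(dY, cache) {
  n <- nrow(dY)
  g <- matrix(cache$gamma, n, ncol(dY), byrow = TRUE)
  dxhat <- dY * g
  inv <- matrix(cache$inv, n, ncol(dY), byrow = TRUE)
  m1 <- matrix(colMeans(dxhat), n, ncol(dY), byrow = TRUE)
  m2 <- matrix(colMeans(dxhat * cache$xhat), n, ncol(dY), byrow = TRUE)
  dX <- inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dgamma = colSums(dY * cache$xhat), dbeta = colSums(dY))
}

## ---- layer normalization over features (per row) ----

ln_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans(X^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * inv
  out <- addb(xhat * matrix(gamma, nrow(X), ncol(X), byrow = TRUE), beta)
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

ln_backward <- function(dY, cache) {
  n <- ncol(dY)
  g <- matrix(cache$gamma, nrow(dY), n, byrow = TRUE)
  dxhat <- dY * g
  dX <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dX = dX, dgamma = colSums(dY * cache$xhat), dbeta = colSums(dY))
}

## ---- dropout (inverted scaling) ----

dropout_forward <- function(X, p, mode) {
  if (mode != "train" || p <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

## ---- scaled dot-product attention (single head, single sequence) ----

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with a row-wise softmax; the `1/sqrt(d_k)`
#' scaling keeps logits in a range where the softmax retains gradient.
#'
#' @param Q,K,V T x d_k matrices.
#' @return List with `out` (T x d_k) and `weights` (T x T attention matrix,
#'   rows summing to 1).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  dk <- ncol(K)
  S <- tcrossprod(Q, K) / sqrt(dk)
  rowmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - rowmax)
  A <- E / rowSums(E)
  list(out = A %*% V, weights = A)
}

# Multi-head self-attention over a (B*T) x D activation, followed by output
# projection, dropout, residual connection, and layer normalization.
mha_forward <- function(X, p, prefix, cfg, mode) {
  D <- cfg$d_model; nh <- cfg$n_heads; dk <- D / nh
  B <- attr(X, "B"); T <- attr(X, "T")
  Q <- addb(X %*% p[[paste0(prefix, ".Wq")]], p[[paste0(prefix, ".bq")]])
  K <- addb(X %*% p[[paste0(prefix, ".Wk")]], p[[paste0(prefix, ".bk")]])
  V <- addb(X %*% p[[paste0(prefix, ".Wv")]], p[[paste0(prefix, ".bv")]])
  O <- matrix(0, nrow(X), D)
  A_list <- vector("list", B * nh)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      att <- scaled_dot_attention(Q[rows, cols, drop = FALSE],
                                  K[rows, cols, drop = FALSE],
                                  V[rows, cols, drop = FALSE])
      O[rows, cols] <- att$out
      A_list[[(b - 1) * nh + h]] <- att$weights
    }
  }
  proj <- addb(O %*% p[[paste0(prefix, ".Wo")]], p[[paste0(prefix, ".bo")]])
  drop <- dropout_forward(proj, cfg$dropout, mode)
  res <- X + drop$out
  ln <- ln_forward(res, p[[paste0(prefix, ".ln_gamma")]],
                   p[[paste0(prefix, ".ln_beta")]])
  out <- ln$out
  attr(out, "B") <- B; attr(out, "T") <- T
  list(out = out,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, A = A_list,
                    drop = drop$cache, ln = ln$cache, B = B, T = T))
}

mha_backward <- function(dY, p, prefix, cfg, cache) {
  D <- cfg$d_model; nh <- cfg$n_heads; dk <- D / nh
  B <- cache$B; T <- cache$T
  g <- list()
  ln <- ln_backward(dY, cache$ln)
  g[[paste0(prefix, ".ln_gamma")]] <- ln$dgamma
  g[[paste0(prefix, ".ln_beta")]] <- ln$dbeta
  dres <- ln$dX
  dproj <- dropout_backward(dres, cache$drop)
  g[[paste0(prefix, ".Wo")]] <- crossprod(cache$O, dproj)
  g[[paste0(prefix, ".bo")]] <- colSums(dproj)
  dO <- tcrossprod(dproj, p[[paste0(prefix, ".Wo")]])
  dQ <- matrix(0, nrow(dY), D)
  dK <- matrix(0, nrow(dY), D)
  dV <- matrix(0, nrow(dY), D)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      A <- cache$A[[(b - 1) * nh + h]]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] / sqrt(dk)
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) / sqrt(dk)
    }
  }
  g[[paste0(prefix, ".Wq")]] <- crossprod(cache$X, dQ)
  g[[paste0(prefix, ".bq")]] <- colSums(dQ)
  g[[paste0(prefix, ".Wk")]] <- crossprod(cache$X, dK)
  g[[paste0(prefix, ".bk")]] <- colSums(dK)
  g[[paste0(prefix, ".Wv")]] <- crossprod(cache$X, dV)
  g[[paste0(prefix, ".bv")]] <- colSums(dV)
  dX <- dres +
    tcrossprod(dQ, p[[paste0(prefix, ".Wq")]]) +
    tcrossprod(dK, p[[paste0(prefix, ".Wk")]]) +
    tcrossprod(dV, p[[paste0(prefix, ".Wv")]])
  list(dX = dX, grads = g)
}

## ---- LSTM (one direction, one layer) ----

# X: (B*T) x Cin batch-major. direction "fwd" processes t = 1..T, "bwd"
# processes t = T..1; outputs are always stored at their own timestep.
lstm_forward <- function(X, Wx, Wh, b, B, T, direction = "fwd") {
  H <- nrow(Wh)  # hidden width; gate blocks are 4H wide
  stopifnot(ncol(Wx) == 4 * H, ncol(Wh) == 4 * H)
  order_t <- if (direction == "fwd") seq_len(T) else rev(seq_len(T))
  h_prev <- matrix(0, B, H)
  c_prev <- matrix(0, B, H)
  out <- matrix(0, B * T, H)
  caches <- vector("list", T)
  bmat <- matrix(b, B, 4 * H, byrow = TRUE)
  offs <- T * (0:(B - 1))
  for (s in seq_len(T)) {
    t <- order_t[s]
    rows <- t + offs
    Xt <- X[rows, , drop = FALSE]
    Z <- Xt %*% Wx + h_prev %*% Wh + bmat
    i <- sigm(Z[, 1:H, drop = FALSE])
    f <- sigm(Z[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigm(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * c_prev + i * gg
    tc <- tanh(c_new)
    h_new <- o * tc
    out[rows, ] <- h_new
    caches[[s]] <- list(Xt = Xt, h_prev = h_prev, c_prev = c_prev,
                        i = i, f = f, g = gg, o = o, tc = tc, rows = rows)
    h_prev <- h_new
    c_prev <- c_new
  }
  list(out = out, cache = list(steps = caches, order_t = order_t,
                               B = B, T = T, H = H))
}

lstm_backward <- function(dOut, Wx, Wh, cache) {
  B <- cache$B; T <- cache$T; H <- cache$H
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dX <- matrix(0, nrow(dOut), nrow(Wx))
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (s in rev(seq_len(T))) {
    st <- cache$steps[[s]]
    dh <- dOut[st$rows, , drop = FALSE] + dh_next
    do <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$Xt, dZ)
    dWh <- dWh + crossprod(st$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[st$rows, ] <- tcrossprod(dZ, Wx)
    dh_next <- tcrossprod(dZ, Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}
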