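# Shared neural-network primitives: initializers, Adam, layer normalization,
# numerically stable softmax. All nets in this package are plain R matrices
# with hand-written backward passes; weights are stored (in x out) so the
# forward pass is X %*% W + b.

xavier_init <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

uniform_init <- function(n_in, n_out, r = 0.05) {
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

relu <- function(x) x * (x > 0)

# Row-wise softmax with max subtraction; -Inf entries get probability 0.
softmax_rows <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  mx <- s[cbind(seq_len(nr), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e[is.na(e)] <- 0 # rows that are entirely -Inf (should not occur)
  e / .rowSums(e, nr, nc)
}

# Backward through row-softmax: given probabilities P and upstream dP,
# dS = P * (dP - rowSums(dP * P)).
softmax_rows_backward <- function(P, dP) {
  P * (dP - .rowSums(dP * P, nrow(P), ncol(P)))
}

## ---- Adam -------------------------------------------------------------

# params: named list of numeric arrays. Returns an optimizer state.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

adam_step <- function(params, grads, state) {
  state$t <- state$t + 1
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
    if (is.null(dim(params[[nm]]))) upd <- as.vector(upd)
    params[[nm]] <- upd
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- Layer normalization ----------------------------------------------

# Normalizes each row of X over its features; g, b are per-feature vectors.
layernorm_forward <- function(X, g, b, eps = 1e-5) {
  nr <- nrow(X); nc <- ncol(X)
  mu <- .rowMeans(X, nr, nc)
  xc <- X - mu
  va <- .rowMeans(xc * xc, nr, nc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  list(out = xhat * rep(g, each = nr) + rep(b, each = nr),
       xhat = xhat, inv = inv)
}

layernorm_backward <- function(cache, g, dout) {
  xhat <- cache$xhat
  nr <- nrow(xhat); nc <- ncol(xhat)
  dg <- .colSums(dout * xhat, nr, nc)
  db <- .colSums(dout, nr, nc)
  dxhat <- dout * rep(g, each = nr)
  # dX = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)), means over features
  m1 <- .rowMeans(dxhat, nr, nc)
  m2 <- .rowMeans(dxhat * xhat, nr, nc)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

## ---- Simple batch normalization (training-mode statistics) -------------

batchnorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  list(out = sweep(xhat, 2, g, `*`) + matrix(b, nrow(X), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

batchnorm_backward <- function(cache, g, dout) {
  xhat <- cache$xhat
  N <- nrow(xhat)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, g, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- sweep(sweep(sweep(dxhat, 2, m1), 1, rep(1, N), `*`) - sweep(xhat, 2, m2, `*`),
              2, cache$inv, `*`)
  list(dX = dX, dg = dg, db = db)
}

# Zero-pad (or truncate) the columns of a matrix to a fixed width.
pad_cols <- function(m, width) {
  if (ncol(m) == width) return(m)
  if (ncol(m) > width) return(m[, seq_len(width), drop = FALSE])
  out <- cbind(m, matrix(0, nrow(m), width - ncol(m)))
  rownames(out) <- rownames(m)
  out
}
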