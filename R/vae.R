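#' Variational autoencoder configuration
#'
#' Defaults follow the common choice of a 512-dimensional gene latent space
#' with a single 1024-unit hidden layer on each side, Adam at 1e-3, 200
#' epochs, batch 128 and unit KL weight. For desk-scale data every field can
#' (and should) be reduced.
#'
#' @param latent_dim Latent dimension `d_n` per gene.
#' @param encoder_hidden_dims,decoder_hidden_dims Integer vectors of hidden
#'   layer widths (ReLU activations).
#' @param learning_rate,epochs,batch_size,kl_weight,seed Training controls.
#' @return A `vae_params` list.
#' @export
vae_params <- function(latent_dim = 512, encoder_hidden_dims = 1024,
                       decoder_hidden_dims = rev(encoder_hidden_dims),
                       learning_rate = 1e-3, epochs = 200, batch_size = 128,
                       kl_weight = 1, seed = 1) {
  stopifnot(latent_dim >= 1, epochs >= 1, batch_size >= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_hidden_dims = as.integer(encoder_hidden_dims),
                 decoder_hidden_dims = as.integer(decoder_hidden_dims),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), kl_weight = kl_weight,
                 seed = as.integer(seed)),
            class = "vae_params")
}

vae_init_weights <- function(m, params) {
  dims_enc <- c(m, params$encoder_hidden_dims)
  dims_dec <- c(params$latent_dim, params$decoder_hidden_dims)
  w <- list()
  for (i in seq_len(length(dims_enc) - 1)) {
    w[[paste0("We", i)]] <- xavier_init(dims_enc[i], dims_enc[i + 1])
    w[[paste0("be", i)]] <- rep(0, dims_enc[i + 1])
  }
  hlast <- dims_enc[length(dims_enc)]
  w$Wmu <- xavier_init(hlast, params$latent_dim); w$bmu <- rep(0, params$latent_dim)
  w$Wlv <- xavier_init(hlast, params$latent_dim); w$blv <- rep(0, params$latent_dim)
  for (i in seq_len(length(dims_dec) - 1)) {
    w[[paste0("Wd", i)]] <- xavier_init(dims_dec[i], dims_dec[i + 1])
    w[[paste0("bd", i)]] <- rep(0, dims_dec[i + 1])
  }
  w$Wout <- xavier_init(dims_dec[length(dims_dec)], m); w$bout <- rep(0, m)
  w
}

vae_encode_forward <- function(Xb, w, n_enc) {
  H <- list(Xb)
  for (i in seq_len(n_enc)) {
    H[[i + 1]] <- relu(sweep(H[[i]] %*% w[[paste0("We", i)]], 2,
                             w[[paste0("be", i)]], `+`))
  }
  hl <- H[[n_enc + 1]]
  mu <- sweep(hl %*% w$Wmu, 2, w$bmu, `+`)
  logv <- sweep(hl %*% w$Wlv, 2, w$blv, `+`)
  list(H = H, mu = mu, logv = logv, sigma = exp(0.5 * logv))
}

vae_decode_forward <- function(Z, w, n_dec) {
  D <- list(Z)
  for (i in seq_len(n_dec)) {
    D[[i + 1]] <- relu(sweep(D[[i]] %*% w[[paste0("Wd", i)]], 2,
                             w[[paste0("bd", i)]], `+`))
  }
  list(D = D, Xhat = sweep(D[[n_dec + 1]] %*% w$Wout, 2, w$bout, `+`))
}

#' Encode a block of gene expression rows
#'
#' Maps rows of the expression matrix (one gene's profile across cells per
#' row) to Gaussian posterior parameters. Sigma is parameterized through the
#' exponential of a log-variance head and is therefore strictly positive.
#'
#' @param X_row_block Numeric matrix, one gene per row, `m` cells wide.
#' @param model A fitted [train_vae()] object (or its `$weights`).
#' @return List with `mu` and `sigma`, each `nrow(X_row_block)` x `latent_dim`.
#' @export
encode <- function(X_row_block, model) {
  w <- if (!is.null(model$weights)) model$weights else model
  params <- if (!is.null(model$params)) model$params else
    stop("model must carry its vae_params")
  X_row_block <- as.matrix(X_row_block)
  if (ncol(X_row_block) != nrow(w$We1))
    stop(sprintf("input width %d does not match the model's expected %d cells",
                 ncol(X_row_block), nrow(w$We1)))
  enc <- vae_encode_forward(X_row_block, w, length(params$encoder_hidden_dims))
  list(mu = enc$mu, sigma = enc$sigma)
}

#' Reparameterization trick
#'
#' `Z = mu + sigma * epsilon`, expressing a Gaussian sample as a
#' deterministic transform of the posterior parameters and external noise so
#' gradients can flow through `mu` and `sigma`.
#'
#' @param mu,sigma Matrices of equal shape; `sigma` elementwise positive
#'   (zero allowed, collapsing to `mu`).
#' @param epsilon Optional noise of the same shape; standard normal draws if
#'   omitted.
#' @return The latent sample `Z`.
#' @export
reparameterize <- function(mu, sigma, epsilon = NULL) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  if (!all(dim(mu) == dim(sigma))) stop("mu and sigma shapes differ")
  if (is.null(epsilon))
    epsilon <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  epsilon <- as.matrix(epsilon)
  if (!all(dim(epsilon) == dim(mu))) stop("epsilon shape differs from mu")
  mu + sigma * epsilon
}

#' Negative evidence lower bound for a Gaussian VAE
#'
#' Reconstruction term: Gaussian likelihood with unit variance on the
#' log-normalized input, i.e. half the per-sample sum of squared errors,
#' averaged over the batch. KL term: closed-form divergence between the
#' diagonal Gaussian posterior `N(mu, sigma^2)` and the standard normal
#' prior, `0.5 * sum(mu^2 + sigma^2 - 1 - 2*log(sigma))` per sample, averaged
#' over the batch.
#'
#' @param X,X_hat Input and reconstruction matrices (samples in rows).
#' @param mu,sigma Posterior parameters for the same batch.
#' @param kl_weight Weight on the KL term in the total objective.
#' @return List with `neg_elbo`, `recon_term`, `kl_term`.
#' @export
elbo_loss <- function(X, X_hat, mu, sigma, kl_weight = 1) {
  X <- as.matrix(X); X_hat <- as.matrix(X_hat)
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  recon <- mean(0.5 * rowSums((X - X_hat)^2))
  kl <- mean(gaussian_kl(mu, sigma))
  out <- list(neg_elbo = recon + kl_weight * kl, recon_term = recon, kl_term = kl)
  if (!all(vapply(out, is.finite, TRUE)))
    stop("non-finite ELBO terms: training diverged")
  out
}

#' Per-sample KL divergence of N(mu, diag(sigma^2)) from N(0, I)
#'
#' @param mu,sigma Matrices, one sample per row.
#' @return Numeric vector of per-row KL divergences (always >= 0).
#' @export
gaussian_kl <- function(mu, sigma) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  0.5 * rowSums(mu^2 + sigma^2 - 1 - 2 * log(sigma))
}

#' Train the expression VAE and return per-gene latent embeddings
#'
#' Genes are the samples: each gene's profile across cells is one input row,
#' so the latent space embeds genes, as required by the downstream
#' link-prediction model. The exported embedding is the posterior mean `mu`
#' (deterministic), not a sample.
#'
#' @param X A log-transformed [expression_matrix()].
#' @param params A [vae_params()] object.
#' @return A `latent_embedding` object: `Z` (= `mu`, n x latent_dim, gene ids
#'   as rownames), `mu`, `sigma`, `history` (per-epoch mean negative ELBO,
#'   element 1 is the pre-training loss), `params`, `weights`.
#' @export
train_vae <- function(X, params = vae_params()) {
  if (!inherits(X, "expr_matrix")) stop("X must be an expr_matrix")
  if (!X$is_log) stop("train_vae() expects a log-transformed matrix")
  data <- X$values
  n <- nrow(data); m <- ncol(data)
  set.seed(params$seed)
  w <- vae_init_weights(m, params)
  n_enc <- length(params$encoder_hidden_dims)
  n_dec <- length(params$decoder_hidden_dims)
  opt <- adam_init(w, lr = params$learning_rate)
  klw <- params$kl_weight

  epoch_loss <- function() {
    enc <- vae_encode_forward(data, w, n_enc)
    dec <- vae_decode_forward(enc$mu, w, n_dec)
    elbo_loss(data, dec$Xhat, enc$mu, enc$sigma, klw)$neg_elbo
  }
  history <- numeric(params$epochs + 1)
  history[1] <- epoch_loss()

  for (ep in seq_len(params$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = params$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- idx[starts[bi]:min(starts[bi] + params$batch_size - 1, n)]
      Xb <- data[rows, , drop = FALSE]
      B <- nrow(Xb)
      enc <- vae_encode_forward(Xb, w, n_enc)
      eps <- matrix(stats::rnorm(B * params$latent_dim), B, params$latent_dim)
      Z <- enc$mu + enc$sigma * eps
      dec <- vae_decode_forward(Z, w, n_dec)
      diffm <- dec$Xhat - Xb
      loss <- mean(0.5 * rowSums(diffm^2)) +
        klw * mean(gaussian_kl(enc$mu, enc$sigma))
      if (!is.finite(loss))
        stop(sprintf("VAE training diverged (non-finite loss) at epoch %d", ep))
      batch_losses[bi] <- loss

      g <- list()
      ## decoder backward
      dX <- diffm / B
      g$Wout <- t(dec$D[[n_dec + 1]]) %*% dX
      g$bout <- colSums(dX)
      dcur <- dX %*% t(w$Wout)
      for (i in rev(seq_len(n_dec))) {
        dcur <- dcur * (dec$D[[i + 1]] > 0)
        g[[paste0("Wd", i)]] <- t(dec$D[[i]]) %*% dcur
        g[[paste0("bd", i)]] <- colSums(dcur)
        dcur <- dcur %*% t(w[[paste0("Wd", i)]])
      }
      dZ <- dcur
      ## heads: z = mu + exp(0.5*logv)*eps; KL grads
      dmu <- dZ + klw * enc$mu / B
      dlogv <- dZ * 0.5 * enc$sigma * eps + klw * 0.5 * (enc$sigma^2 - 1) / B
      hl <- enc$H[[n_enc + 1]]
      g$Wmu <- t(hl) %*% dmu; g$bmu <- colSums(dmu)
      g$Wlv <- t(hl) %*% dlogv; g$blv <- colSums(dlogv)
      dcur <- dmu %*% t(w$Wmu) + dlogv %*% t(w$Wlv)
      for (i in rev(seq_len(n_enc))) {
        dcur <- dcur * (enc$H[[i + 1]] > 0)
        g[[paste0("We", i)]] <- t(enc$H[[i]]) %*% dcur
        g[[paste0("be", i)]] <- colSums(dcur)
        dcur <- dcur %*% t(w[[paste0("We", i)]])
      }
      st <- adam_step(w, g, opt)
      w <- st$params; opt <- st$state
    }
    history[ep + 1] <- mean(batch_losses)
  }

  enc <- vae_encode_forward(data, w, n_enc)
  Z <- enc$mu
  rownames(Z) <- rownames(enc$sigma) <- rownames(data)
  structure(list(Z = Z, mu = Z, sigma = enc$sigma, history = history,
                 params = params, weights = w),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("<latent_embedding> %d genes x %d dims; neg-ELBO %.4f -> %.4f over %d epochs\n",
              nrow(x$Z), ncol(x$Z), x$history[1], x$history[length(x$history)],
              x$params$epochs))
  invisible(x)
}
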