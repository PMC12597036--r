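#' Sinusoidal sequence positional encoding
#'
#' Pure function giving coordinate `i` (0-based) of the encoding at sequence
#' position `pos`: `sin(pos / 10000^(i/p_dim))` for even `i`,
#' `cos(pos / 10000^((i-1)/p_dim))` for odd `i`. Values lie in [-1, 1].
#'
#' @param pos Sequence position (0-based; vectorized).
#' @param i Coordinate index, `0 <= i < p_dim` (vectorized).
#' @param p_dim Total encoding dimension.
#' @return Numeric vector of encoding values.
#' @export
sequence_positional_encoding <- function(pos, i, p_dim) {
  if (any(i < 0) || any(i >= p_dim)) stop("require 0 <= i < p_dim")
  even <- i %% 2 == 0
  out <- numeric(length(pos + i)) # recycle to common length
  pos <- rep_len(pos, length(out)); i <- rep_len(i, length(out))
  even <- i %% 2 == 0
  out[even] <- sin(pos[even] / 10000^(i[even] / p_dim))
  out[!even] <- cos(pos[!even] / 10000^((i[!even] - 1) / p_dim))
  out
}

pe_matrix <- function(len, d) {
  outer(seq_len(len) - 1, seq_len(d) - 1,
        function(pos, i) sequence_positional_encoding(pos, i, d))
}

#' Mask gene tokens in a walk corpus
#'
#' Per sequence, exactly `round(mask_rate * walk_length)` gene-token
#' positions (never the leading `[CLS]`) are replaced by `[MASK]`, chosen
#' uniformly at random under the seed. The originals are kept as labels.
#'
#' @param corpus A [sample_walks()] corpus.
#' @param mask_rate Fraction of gene tokens to mask, in (0, 1); 0.20 is the
#'   standard rate.
#' @param seed Integer seed.
#' @return List with `masked_sequences` (integer matrix), `labels` (the
#'   original sequences), and `mask` (logical matrix of masked positions).
#' @export
mask_tokens <- function(corpus, mask_rate = 0.2, seed = 1) {
  if (mask_rate <= 0 || mask_rate >= 1) stop("mask_rate must lie in (0, 1)")
  L <- corpus$walk_length
  k <- round(mask_rate * L)
  if (k == 0)
    stop("round(mask_rate * walk_length) is 0; use longer walks or a higher rate")
  set.seed(as.integer(seed))
  seqs <- corpus$sequences
  mask <- matrix(FALSE, nrow(seqs), ncol(seqs))
  for (b in seq_len(nrow(seqs))) {
    pos <- 1 + sample.int(L, k) # skip column 1 ([CLS])
    mask[b, pos] <- TRUE
  }
  masked <- seqs
  masked[mask] <- corpus$mask_id
  list(masked_sequences = masked, labels = seqs, mask = mask)
}

#' Masked-token cross-entropy loss
#'
#' Sum of `-log p(true token)` over masked positions only; unmasked
#' positions never contribute.
#'
#' @param predicted_probs Array `B x L x V` of row-stochastic predictions
#'   (or a `(B*L) x V` matrix in row-major sequence order).
#' @param labels Integer matrix `B x L` of true token ids.
#' @param mask_indicator Logical matrix `B x L`; `TRUE` where masked.
#' @return The scalar loss (>= 0).
#' @export
mlm_loss <- function(predicted_probs, labels, mask_indicator) {
  if (!any(mask_indicator)) stop("no masked positions: loss undefined")
  idx <- which(mask_indicator, arr.ind = TRUE)
  if (length(dim(predicted_probs)) == 3) {
    p <- predicted_probs[cbind(idx[, 1], idx[, 2], labels[idx])]
  } else {
    flat <- (idx[, 1] - 1) * ncol(labels) + idx[, 2]
    p <- predicted_probs[cbind(flat, labels[idx])]
  }
  -sum(log(p))
}

#' Masked-node model configuration
#'
#' A BERT-style transformer encoder trained to recover masked nodes in
#' random-walk sequences. Defaults: 512-dimensional embeddings, 2 blocks,
#' 4 heads, 20% masking, Adam at 1e-3 for 50 epochs. Reduce the embedding
#' dimension and epochs for desk-scale corpora.
#'
#' @param embedding_dim Token embedding width `d_n` (divisible by `heads`).
#' @param num_blocks Number of encoder blocks `M`.
#' @param heads Attention heads per block.
#' @param ffn_dim Feed-forward hidden width (default `2 * embedding_dim`).
#' @param mask_rate Masking rate (default 0.20).
#' @param tie_decoder If `TRUE`, the output decoder shares the token
#'   embedding matrix (weight tying); the default `FALSE` uses an
#'   independent, uniformly initialized decoding matrix.
#' @param weight_decay Decoupled weight decay on the transformer and
#'   decoder weight matrices (never the embedding matrix): pushes
#'   representational capacity into the embeddings, which are the product
#'   of interest.
#' @param epochs,learning_rate,batch_size,seed Training controls.
#' @return An `mlm_params` list.
#' @export
mlm_params <- function(embedding_dim = 512, num_blocks = 2, heads = 4,
                       ffn_dim = 2 * embedding_dim, mask_rate = 0.2,
                       tie_decoder = FALSE, weight_decay = 0, epochs = 50,
                       learning_rate = 1e-3, batch_size = 64, seed = 1) {
  if (embedding_dim %% heads != 0) stop("embedding_dim must be divisible by heads")
  if (mask_rate <= 0 || mask_rate >= 1) stop("mask_rate must lie in (0, 1)")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 num_blocks = as.integer(num_blocks), heads = as.integer(heads),
                 ffn_dim = as.integer(ffn_dim), mask_rate = mask_rate,
                 tie_decoder = isTRUE(tie_decoder),
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "mlm_params")
}

mlm_init_weights <- function(V, params) {
  d <- params$embedding_dim; f <- params$ffn_dim
  w <- list(E = uniform_init(V, d)) # embedding matrix: uniform init
  for (blk in seq_len(params$num_blocks)) {
    w[[paste0("Wq", blk)]] <- xavier_init(d, d)
    w[[paste0("Wk", blk)]] <- xavier_init(d, d)
    w[[paste0("Wv", blk)]] <- xavier_init(d, d)
    w[[paste0("W1", blk)]] <- xavier_init(d, f)
    w[[paste0("b1", blk)]] <- rep(0, f)
    w[[paste0("W2", blk)]] <- xavier_init(f, d)
    w[[paste0("b2", blk)]] <- rep(0, d)
    w[[paste0("g1", blk)]] <- rep(1, d); w[[paste0("n1", blk)]] <- rep(0, d)
    w[[paste0("g2", blk)]] <- rep(1, d); w[[paste0("n2", blk)]] <- rep(0, d)
  }
  if (!params$tie_decoder)
    w$Wdec <- uniform_init(d, V) # independent decoding layer: uniform init
  w$bdec <- rep(0, V)
  w
}

# Batched self-attention over same-length sequences, vectorized so R-level
# loops run over heads and sequence positions (short), never over the batch.
# Stacked row order throughout: sequence 1 positions 1..L1, sequence 2, ...
seq_attention_forward <- function(Q, K, V, B, L1, H) {
  d <- ncol(Q); dk <- d %/% H
  N <- nrow(Q)
  bidx <- rep(seq_len(B), each = L1)
  posidx <- lapply(seq_len(L1), function(j) seq(j, by = L1, length.out = B))
  expidx <- lapply(posidx, function(pj) pj[bidx]) # broadcast position j over rows
  O <- matrix(0, N, d)
  P_list <- vector("list", H)
  for (h in seq_len(H)) {
    hc <- ((h - 1) * dk + 1):(h * dk)
    Qh <- Q[, hc, drop = FALSE]; Kh <- K[, hc, drop = FALSE]
    Vh <- V[, hc, drop = FALSE]
    S <- matrix(0, N, L1)
    for (j in seq_len(L1))
      S[, j] <- .rowSums(Qh * Kh[expidx[[j]], , drop = FALSE], N, dk)
    P <- softmax_rows(S / sqrt(dk))
    Oh <- matrix(0, N, dk)
    for (j in seq_len(L1))
      Oh <- Oh + P[, j] * Vh[expidx[[j]], , drop = FALSE]
    O[, hc] <- Oh
    P_list[[h]] <- P
  }
  list(O = O, P = P_list)
}

# Sum blocks of L1 consecutive rows: (B*L1) x k -> B x k. Relies on the
# stacked (position-fastest) row order.
block_rowsum <- function(M, B, L1) {
  k <- ncol(M)
  colSums(array(M, c(L1, B, k)), dims = 1)
}

seq_attention_backward <- function(dO, P_list, Q, K, V, B, L1, H) {
  d <- ncol(Q); dk <- d %/% H
  N <- nrow(Q)
  bidx <- rep(seq_len(B), each = L1)
  posidx <- lapply(seq_len(L1), function(j) seq(j, by = L1, length.out = B))
  expidx <- lapply(posidx, function(pj) pj[bidx])
  dQ <- matrix(0, N, d); dK <- dQ; dV <- dQ
  for (h in seq_len(H)) {
    hc <- ((h - 1) * dk + 1):(h * dk)
    Qh <- Q[, hc, drop = FALSE]; Kh <- K[, hc, drop = FALSE]
    Vh <- V[, hc, drop = FALSE]
    dOh <- dO[, hc, drop = FALSE]
    P <- P_list[[h]]
    dP <- matrix(0, N, L1)
    for (j in seq_len(L1)) {
      dP[, j] <- .rowSums(dOh * Vh[expidx[[j]], , drop = FALSE], N, dk)
      dV[posidx[[j]], hc] <- block_rowsum(P[, j] * dOh, B, L1)
    }
    dS <- softmax_rows_backward(P, dP) / sqrt(dk)
    dQh <- matrix(0, N, dk)
    for (j in seq_len(L1)) {
      dQh <- dQh + dS[, j] * Kh[expidx[[j]], , drop = FALSE]
      dK[posidx[[j]], hc] <- block_rowsum(dS[, j] * Qh, B, L1)
    }
    dQ[, hc] <- dQh
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

# Forward pass over a batch of token sequences (rows of `tok`). Returns the
# stacked final hidden states (one row per token, sequences contiguous) and
# caches for backprop; optionally collects per-block attention matrices.
mlm_forward <- function(w, params, tok, collect_attention = FALSE) {
  B <- nrow(tok); L1 <- ncol(tok)
  d <- params$embedding_dim; H <- params$heads
  ids <- as.vector(t(tok)) # stacked row order: seq 1 pos 1..L1, seq 2, ...
  X <- w$E[ids, , drop = FALSE] + pe_matrix(L1, d)[rep(seq_len(L1), B), ]
  cache <- list(ids = ids, X0 = X, blocks = vector("list", params$num_blocks),
                B = B, L1 = L1)
  attn <- if (collect_attention) vector("list", params$num_blocks)
  for (blk in seq_len(params$num_blocks)) {
    Q <- X %*% w[[paste0("Wq", blk)]]
    K <- X %*% w[[paste0("Wk", blk)]]
    V <- X %*% w[[paste0("Wv", blk)]]
    att <- seq_attention_forward(Q, K, V, B, L1, H)
    if (collect_attention) attn[[blk]] <- att$P
    ln1 <- layernorm_forward(X + att$O, w[[paste0("g1", blk)]], w[[paste0("n1", blk)]])
    X1 <- ln1$out
    Fh <- relu(sweep(X1 %*% w[[paste0("W1", blk)]], 2, w[[paste0("b1", blk)]], `+`))
    Fo <- sweep(Fh %*% w[[paste0("W2", blk)]], 2, w[[paste0("b2", blk)]], `+`)
    ln2 <- layernorm_forward(X1 + Fo, w[[paste0("g2", blk)]], w[[paste0("n2", blk)]])
    cache$blocks[[blk]] <- list(Xin = X, Q = Q, K = K, V = V, P = att$P,
                                ln1 = ln1, X1 = X1, Fh = Fh, ln2 = ln2)
    X <- ln2$out
  }
  list(H = X, cache = cache, attention = attn)
}

# Backward pass given gradient on the stacked final hidden states.
mlm_backward <- function(w, params, cache, dH) {
  B <- cache$B; L1 <- cache$L1
  H <- params$heads
  g <- list()
  dX <- dH
  for (blk in rev(seq_len(params$num_blocks))) {
    cb <- cache$blocks[[blk]]
    l2 <- layernorm_backward(cb$ln2, w[[paste0("g2", blk)]], dX)
    g[[paste0("g2", blk)]] <- l2$dg; g[[paste0("n2", blk)]] <- l2$db
    dX1 <- l2$dX
    dFo <- l2$dX
    g[[paste0("W2", blk)]] <- crossprod(cb$Fh, dFo)
    g[[paste0("b2", blk)]] <- colSums(dFo)
    dFh <- (dFo %*% t(w[[paste0("W2", blk)]])) * (cb$Fh > 0)
    g[[paste0("W1", blk)]] <- crossprod(cb$X1, dFh)
    g[[paste0("b1", blk)]] <- colSums(dFh)
    dX1 <- dX1 + dFh %*% t(w[[paste0("W1", blk)]])
    l1 <- layernorm_backward(cb$ln1, w[[paste0("g1", blk)]], dX1)
    g[[paste0("g1", blk)]] <- l1$dg; g[[paste0("n1", blk)]] <- l1$db
    att <- seq_attention_backward(l1$dX, cb$P, cb$Q, cb$K, cb$V, B, L1, H)
    g[[paste0("Wq", blk)]] <- crossprod(cb$Xin, att$dQ)
    g[[paste0("Wk", blk)]] <- crossprod(cb$Xin, att$dK)
    g[[paste0("Wv", blk)]] <- crossprod(cb$Xin, att$dV)
    dX <- l1$dX + att$dQ %*% t(w[[paste0("Wq", blk)]]) +
      att$dK %*% t(w[[paste0("Wk", blk)]]) + att$dV %*% t(w[[paste0("Wv", blk)]])
  }
  dE <- matrix(0, nrow(w$E), ncol(w$E))
  agg <- rowsum(dX, group = cache$ids)
  dE[as.integer(rownames(agg)), ] <- agg
  g$E <- dE
  g
}

#' Train the masked-node model and extract global gene embeddings
#'
#' Trains a transformer encoder (scaled dot-product self-attention followed
#' by a ReLU feed-forward network in each block, with residual connections
#' and layer normalization) to recover masked gene tokens from random-walk
#' context. The embedding matrix and decoding layer are initialized with
#' uniform random values; transformer weights use Xavier initialization. The
#' global embedding of each gene is its row of the learned embedding matrix
#' (not a hidden state); the final `[CLS]` hidden state per sequence is
#' available via [mlm_hidden_states()] but is not used downstream.
#'
#' @param corpus A [sample_walks()] corpus.
#' @param params An [mlm_params()] configuration.
#' @return A `global_embedding` object: `xi` (n_genes x embedding_dim matrix,
#'   gene ids as rownames), `history` (mean masked-token cross-entropy per
#'   epoch; element 1 is pre-training), `params`, `weights`, `vocabulary`.
#' @export
train_mlm <- function(corpus, params = mlm_params()) {
  if (!inherits(corpus, "walk_corpus")) stop("corpus must be a walk_corpus")
  if (!nrow(corpus$sequences)) stop("corpus is empty")
  V <- length(corpus$vocabulary)
  set.seed(params$seed)
  w <- mlm_init_weights(V, params)
  opt <- adam_init(w, lr = params$learning_rate)
  nseq <- nrow(corpus$sequences)
  L <- corpus$walk_length
  k_mask <- round(params$mask_rate * L)
  if (k_mask == 0) stop("mask rate too low for this walk length")

  run_epoch <- function(update) {
    ord <- sample.int(nseq)
    starts <- seq(1, nseq, by = params$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- ord[starts[bi]:min(starts[bi] + params$batch_size - 1, nseq)]
      tok <- corpus$sequences[rows, , drop = FALSE]
      B <- nrow(tok); L1 <- ncol(tok)
      mask <- matrix(FALSE, B, L1)
      for (b in seq_len(B)) mask[b, 1 + sample.int(L, k_mask)] <- TRUE
      labels <- tok
      tok[mask] <- corpus$mask_id
      fw <- mlm_forward(w, params, tok)
      flat_mask <- which(as.vector(t(mask))) # stacked row indices
      Hm <- fw$H[flat_mask, , drop = FALSE]
      Wd <- if (params$tie_decoder) t(w$E) else w$Wdec
      logits <- sweep(Hm %*% Wd, 2, w$bdec, `+`)
      probs <- softmax_rows(logits)
      truth <- as.vector(t(labels))[flat_mask]
      nm <- length(flat_mask)
      loss <- -mean(log(pmax(probs[cbind(seq_len(nm), truth)], 1e-300)))
      if (!is.finite(loss))
        stop(sprintf("masked-node training diverged at epoch %d", attr(update, "epoch") %||% 0L))
      losses[bi] <- loss
      if (update) {
        dlog <- probs
        dlog[cbind(seq_len(nm), truth)] <- dlog[cbind(seq_len(nm), truth)] - 1
        dlog <- dlog / nm
        g <- list(bdec = colSums(dlog))
        if (!params$tie_decoder) g$Wdec <- crossprod(Hm, dlog)
        dH <- matrix(0, nrow(fw$H), params$embedding_dim)
        dH[flat_mask, ] <- dlog %*% t(Wd)
        g <- c(g, mlm_backward(w, params, fw$cache, dH))
        if (params$tie_decoder)
          g$E <- g$E + crossprod(dlog, Hm) # decoder-side gradient (tied)
        if ((params$weight_decay %||% 0) > 0) {
          for (nm in setdiff(names(w), "E"))
            if (!is.null(dim(w[[nm]])))
              w[nm] <- list(w[[nm]] * (1 - params$learning_rate * params$weight_decay))
        }
        st <- adam_step(w, g, opt)
        w <<- st$params; opt <<- st$state
      }
    }
    mean(losses)
  }

  history <- numeric(params$epochs + 1)
  history[1] <- run_epoch(FALSE)
  for (ep in seq_len(params$epochs)) history[ep + 1] <- run_epoch(TRUE)

  xi <- w$E[seq_len(corpus$n_genes), , drop = FALSE]
  rownames(xi) <- corpus$vocabulary[seq_len(corpus$n_genes)]
  structure(list(xi = xi, history = history, params = params, weights = w,
                 vocabulary = corpus$vocabulary, cls_id = corpus$cls_id,
                 mask_id = corpus$mask_id),
            class = "global_embedding")
}

#' @export
print.global_embedding <- function(x, ...) {
  cat(sprintf("<global_embedding> %d genes x %d dims; masked CE %.4f -> %.4f\n",
              nrow(x$xi), ncol(x$xi), x$history[1], x$history[length(x$history)]))
  invisible(x)
}

#' Final hidden states (and attention maps) of the masked-node model
#'
#' @param model A [train_mlm()] fit.
#' @param sequences Integer token matrix (one sequence per row, `[CLS]`
#'   first, as produced by [sample_walks()] / [mask_tokens()]).
#' @param collect_attention If `TRUE`, also return the per-block, per-head
#'   attention matrices.
#' @return List with `hidden` (array B x L x d), `cls` (B x d matrix of
#'   `[CLS]` states), and optionally `attention`.
#' @export
mlm_hidden_states <- function(model, sequences, collect_attention = FALSE) {
  fw <- mlm_forward(model$weights, model$params, sequences, collect_attention)
  B <- nrow(sequences); L1 <- ncol(sequences); d <- model$params$embedding_dim
  hid <- aperm(array(t(fw$H), c(d, L1, B)), c(3, 2, 1))
  list(hidden = hid, cls = hid[, 1, , drop = TRUE], attention = fw$attention)
}

#' Predict masked tokens and report recovery accuracy
#'
#' Masks the corpus at the model's masking rate and measures the fraction of
#' masked gene tokens whose identity the model's argmax prediction recovers.
#'
#' @param model A [train_mlm()] fit.
#' @param corpus The [sample_walks()] corpus to evaluate on.
#' @param seed Seed controlling which positions are masked.
#' @return Accuracy in [0, 1].
#' @export
masked_recovery_accuracy <- function(model, corpus, seed = 1) {
  mk <- mask_tokens(corpus, model$params$mask_rate, seed)
  fw <- mlm_forward(model$weights, model$params, mk$masked_sequences)
  flat_mask <- which(as.vector(t(mk$mask)))
  Wd <- if (model$params$tie_decoder) t(model$weights$E) else model$weights$Wdec
  logits <- sweep(fw$H[flat_mask, , drop = FALSE] %*% Wd, 2,
                  model$weights$bdec, `+`)
  pred <- max.col(logits, ties.method = "first")
  truth <- as.vector(t(mk$labels))[flat_mask]
  mean(pred == truth)
}
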