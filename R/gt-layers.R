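#' Graph-transformer training configuration
#'
#' Defaults come from the usual search grid for this architecture: width
#' 512, 8 heads, 4 layers, learning rate 0.001. Desk-scale runs should use a
#' much smaller width. `norm`, `use_ffn`, `use_residual` and `heads`/`layers`
#' also parameterize the layer-ablation variants.
#'
#' @param d Node feature width inside the transformer (divisible by `heads`).
#' @param heads Attention heads (grid 2/4/8).
#' @param layers Stacked transformer layers (grid 4/6/8).
#' @param learning_rate Adam step size (grid 0.001/0.003/0.0005).
#' @param epochs Training epochs (full-batch).
#' @param negative_ratio Negatives sampled per positive each epoch.
#' @param decoder_hidden Hidden width of the MLP link decoder (default
#'   `4 * d`, which accommodates the similarity initialization).
#' @param decoder_init `"similarity"` (default) initializes the decoder as
#'   an approximate inner-product scorer (four structured ReLU units per
#'   feature dimension realize `|a+b| - |a-b|`); `"random"` uses plain
#'   Xavier initialization. Both are fully trainable thereafter.
#' @param norm `"layer"`, `"batch"`, or `"none"` (ablation).
#' @param use_ffn,use_residual Disable the feed-forward sublayer / the
#'   residual connections (ablations).
#' @param weight_decay Decoupled weight decay applied to weight matrices
#'   (not biases or normalization parameters).
#' @param fusion_init `"dense"` (default) uses full Xavier projections for
#'   every modality; `"block"` initializes each modality's projection in a
#'   disjoint column range of the fused space (fusion by summation then
#'   starts as a concatenation; all entries remain trainable).
#' @param modality_dropout Probability of zeroing each modality's input for
#'   one training epoch (applied only when more than one modality is
#'   present; never all at once). Discourages over-reliance on a single
#'   modality so fusion degrades gracefully and exploits complementary
#'   signal; all modalities are used at evaluation time.
#' @param init_scale Scale applied to the residual-branch output projections
#'   (`Wo`, `W2`) at initialization, so each layer starts close to the
#'   identity map and learns its mixing gradually.
#' @param val_every Epochs between validation-AUROC checkpoints.
#' @param seed Integer seed.
#' @return A `gt_config` list.
#' @export
gt_config <- function(d = 512, heads = 8, layers = 4, learning_rate = 0.001,
                      epochs = 200, negative_ratio = 1, decoder_hidden = 4 * d,
                      decoder_init = c("similarity", "random"),
                      norm = c("layer", "batch", "none"), use_ffn = TRUE,
                      use_residual = TRUE, weight_decay = 0, init_scale = 0.1,
                      fusion_init = c("dense", "block"),
                      modality_dropout = 0.3, val_every = 5, seed = 1) {
  norm <- match.arg(norm)
  decoder_init <- match.arg(decoder_init)
  fusion_init <- match.arg(fusion_init)
  if (d %% heads != 0) stop("d must be divisible by the number of heads")
  structure(list(d = as.integer(d), heads = as.integer(heads),
                 layers = as.integer(layers), learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 negative_ratio = as.integer(negative_ratio),
                 decoder_hidden = as.integer(decoder_hidden),
                 decoder_init = decoder_init, norm = norm,
                 use_ffn = use_ffn, use_residual = use_residual,
                 weight_decay = weight_decay, init_scale = init_scale,
                 fusion_init = fusion_init,
                 modality_dropout = modality_dropout,
                 val_every = as.integer(val_every), seed = as.integer(seed)),
            class = "gt_config")
}

#' Project the three modalities and fuse by summation
#'
#' Each modality matrix is mapped through its own affine projection into a
#' shared `d`-dimensional space and the projections are summed element-wise.
#' A `NULL` modality contributes zero (modality ablation).
#'
#' @param Z,xi,lam Expression, global, and positional embedding matrices
#'   (n rows each; any may be `NULL`).
#' @param proj List with weight/bias pairs `S0`/`s0` (expression), `T0`/`t0`
#'   (global), `U0`/`u0` (positional); weights are (input width x d).
#' @return Fused feature matrix `h` (n x d).
#' @export
project_and_fuse <- function(Z, xi, lam, proj) {
  mats <- list(Z = Z, xi = xi, lam = lam)
  ws <- list(Z = c("S0", "s0"), xi = c("T0", "t0"), lam = c("U0", "u0"))
  present <- !vapply(mats, is.null, TRUE)
  if (!any(present)) stop("at least one modality must be provided")
  ns <- vapply(mats[present], nrow, 1L)
  if (length(unique(ns)) != 1) stop("modalities disagree on the number of genes")
  h <- NULL
  for (nm in names(mats)) {
    if (is.null(mats[[nm]])) next
    W <- proj[[ws[[nm]][1]]]; b <- proj[[ws[[nm]][2]]]
    if (ncol(mats[[nm]]) != nrow(W))
      stop(sprintf("modality '%s' width %d does not match projection input %d",
                   nm, ncol(mats[[nm]]), nrow(W)))
    term <- sweep(mats[[nm]] %*% W, 2, b, `+`)
    h <- if (is.null(h)) term else h + term
  }
  h
}

gt_init_weights <- function(widths, cfg) {
  d <- cfg$d
  w <- list()
  mods <- c("Z", "xi", "lam")[!vapply(widths[c("Z", "xi", "lam")], is.null, TRUE)]
  nmod <- length(mods)
  # Block initialization: each modality's projection starts in its own
  # column range, so fusion-by-summation begins as a concatenation and the
  # decoder's per-dimension readout can gate modalities independently.
  # Off-block entries start at zero but are fully trainable.
  proj_init <- function(width, which_mod) {
    W <- matrix(0, width, d)
    if (identical(cfg$fusion_init %||% "block", "block") && nmod > 1) {
      cols <- split(seq_len(d), cut(seq_len(d), nmod, labels = FALSE))
      blk <- cols[[match(which_mod, mods)]]
      W[, blk] <- xavier_init(width, length(blk))
    } else {
      W <- xavier_init(width, d)
    }
    W
  }
  if (!is.null(widths$Z)) { w$S0 <- proj_init(widths$Z, "Z"); w$s0 <- rep(0, d) }
  if (!is.null(widths$xi)) { w$T0 <- proj_init(widths$xi, "xi"); w$t0 <- rep(0, d) }
  if (!is.null(widths$lam)) { w$U0 <- proj_init(widths$lam, "lam"); w$u0 <- rep(0, d) }
  for (l in seq_len(cfg$layers)) {
    w[[paste0("Wq", l)]] <- xavier_init(d, d)
    w[[paste0("Wk", l)]] <- xavier_init(d, d)
    w[[paste0("Wv", l)]] <- xavier_init(d, d)
    w[[paste0("Wo", l)]] <- xavier_init(d, d) * (cfg$init_scale %||% 1)
    if (cfg$use_ffn) {
      w[[paste0("W1", l)]] <- xavier_init(d, 2 * d) # FFN hidden width is 2d
      w[[paste0("W2", l)]] <- xavier_init(2 * d, d) * (cfg$init_scale %||% 1)
    }
    if (cfg$norm != "none") {
      w[[paste0("g1", l)]] <- rep(1, d); w[[paste0("n1", l)]] <- rep(0, d)
      w[[paste0("g2", l)]] <- rep(1, d); w[[paste0("n2", l)]] <- rep(0, d)
    }
  }
  hid <- cfg$decoder_hidden
  if (identical(cfg$decoder_init, "similarity") && hid >= 4 * d) {
    # Initialize the first 4d hidden units so the decoder starts as an
    # approximate inner-product scorer: for each coordinate k, the four
    # ReLU units realize |a_k + b_k| - |a_k - b_k|, a bounded similarity
    # kernel with the sign of a_k * b_k. Remaining units are random.
    W1 <- xavier_init(2 * d, hid) * 0.1
    W2 <- xavier_init(hid, 1) * 0.1
    for (k in seq_len(d)) {
      u <- 4 * (k - 1) + 1:4
      W1[, u] <- 0
      W1[k, u] <- c(1, -1, 1, -1)
      W1[d + k, u] <- c(1, -1, -1, 1)
      W2[u, 1] <- c(1, 1, -1, -1) / (2 * sqrt(d))
    }
    w$Wd1 <- W1; w$bd1 <- rep(0, hid)
    w$Wd2 <- W2; w$bd2 <- 0
  } else {
    w$Wd1 <- xavier_init(2 * d, hid); w$bd1 <- rep(0, hid)
    w$Wd2 <- xavier_init(hid, 1); w$bd2 <- 0
  }
  w
}

#' Neighborhood-restricted multi-head graph attention
#'
#' Per head `k`, attention of node `i` is a softmax over its neighborhood
#' `N(i)` of scaled dot products `(Q h_i . K h_j) / sqrt(d_k)`; the head
#' outputs are concatenated and passed through the output projection `O_h`.
#' Every attention row sums to 1, so the message graph must give each node
#' at least one neighbor (add self-loops beforehand).
#'
#' @param h Node features (n x d).
#' @param A_message Binary/logical adjacency defining the neighborhoods,
#'   self-loops included.
#' @param layer List with `Wq`, `Wk`, `Wv`, `Wo` (each d x d) and `heads`.
#' @param return_attention If `TRUE`, attach the per-head attention
#'   matrices.
#' @return The attended features (n x d); attribute `attention` optionally.
#' @export
gt_attention <- function(h, A_message, layer, return_attention = FALSE) {
  d <- ncol(h); H <- layer$heads; dk <- d %/% H
  if (d %% H != 0) stop("feature width d must be divisible by the number of heads")
  M <- A_message != 0
  if (any(rowSums(M) == 0))
    stop("every node needs at least one neighbor; add self-loops to A_message")
  Q <- h %*% layer$Wq; K <- h %*% layer$Wk; V <- h %*% layer$Wv
  AttC <- matrix(0, nrow(h), d)
  Ps <- if (return_attention) vector("list", H)
  for (k in seq_len(H)) {
    hc <- ((k - 1) * dk + 1):(k * dk)
    S <- tcrossprod(Q[, hc, drop = FALSE], K[, hc, drop = FALSE]) / sqrt(dk)
    S[!M] <- -Inf
    P <- softmax_rows(S)
    AttC[, hc] <- P %*% V[, hc, drop = FALSE]
    if (return_attention) Ps[[k]] <- P
  }
  out <- AttC %*% layer$Wo
  if (return_attention) attr(out, "attention") <- Ps
  out
}

# Forward through one GT layer with full caching for backprop.
gt_layer_forward <- function(h, mask, w, l, cfg) {
  d <- cfg$d; H <- cfg$heads; dk <- d %/% H
  Q <- h %*% w[[paste0("Wq", l)]]
  K <- h %*% w[[paste0("Wk", l)]]
  V <- h %*% w[[paste0("Wv", l)]]
  AttC <- matrix(0, nrow(h), d)
  Ps <- vector("list", H)
  for (k in seq_len(H)) {
    hc <- ((k - 1) * dk + 1):(k * dk)
    S <- tcrossprod(Q[, hc, drop = FALSE], K[, hc, drop = FALSE]) / sqrt(dk)
    S[!mask] <- -Inf
    Ps[[k]] <- softmax_rows(S)
    AttC[, hc] <- Ps[[k]] %*% V[, hc, drop = FALSE]
  }
  hhat <- AttC %*% w[[paste0("Wo", l)]]
  r1 <- if (cfg$use_residual) h + hhat else hhat
  if (cfg$norm == "layer") {
    ln1 <- layernorm_forward(r1, w[[paste0("g1", l)]], w[[paste0("n1", l)]])
    h1 <- ln1$out
  } else if (cfg$norm == "batch") {
    ln1 <- batchnorm_forward(r1, w[[paste0("g1", l)]], w[[paste0("n1", l)]])
    h1 <- ln1$out
  } else { ln1 <- NULL; h1 <- r1 }
  if (cfg$use_ffn) {
    Fh <- relu(h1 %*% w[[paste0("W1", l)]])
    Fo <- Fh %*% w[[paste0("W2", l)]]
    r2 <- if (cfg$use_residual) h1 + Fo else Fo
    if (cfg$norm == "layer") {
      ln2 <- layernorm_forward(r2, w[[paste0("g2", l)]], w[[paste0("n2", l)]])
      h2 <- ln2$out
    } else if (cfg$norm == "batch") {
      ln2 <- batchnorm_forward(r2, w[[paste0("g2", l)]], w[[paste0("n2", l)]])
      h2 <- ln2$out
    } else { ln2 <- NULL; h2 <- r2 }
  } else { Fh <- NULL; ln2 <- NULL; h2 <- h1 }
  list(out = h2, h = h, Q = Q, K = K, V = V, P = Ps, AttC = AttC,
       ln1 = ln1, h1 = h1, Fh = Fh, ln2 = ln2)
}

gt_layer_backward <- function(cache, mask, w, l, cfg, dout) {
  d <- cfg$d; H <- cfg$heads; dk <- d %/% H
  g <- list()
  if (cfg$use_ffn) {
    if (cfg$norm == "layer") {
      bb <- layernorm_backward(cache$ln2, w[[paste0("g2", l)]], dout)
      g[[paste0("g2", l)]] <- bb$dg; g[[paste0("n2", l)]] <- bb$db
      dr2 <- bb$dX
    } else if (cfg$norm == "batch") {
      bb <- batchnorm_backward(cache$ln2, w[[paste0("g2", l)]], dout)
      g[[paste0("g2", l)]] <- bb$dg; g[[paste0("n2", l)]] <- bb$db
      dr2 <- bb$dX
    } else dr2 <- dout
    dFo <- dr2
    g[[paste0("W2", l)]] <- crossprod(cache$Fh, dFo)
    dFh <- (dFo %*% t(w[[paste0("W2", l)]])) * (cache$Fh > 0)
    g[[paste0("W1", l)]] <- crossprod(cache$h1, dFh)
    dh1 <- dFh %*% t(w[[paste0("W1", l)]])
    if (cfg$use_residual) dh1 <- dh1 + dr2
  } else dh1 <- dout
  if (cfg$norm == "layer") {
    bb <- layernorm_backward(cache$ln1, w[[paste0("g1", l)]], dh1)
    g[[paste0("g1", l)]] <- bb$dg; g[[paste0("n1", l)]] <- bb$db
    dr1 <- bb$dX
  } else if (cfg$norm == "batch") {
    bb <- batchnorm_backward(cache$ln1, w[[paste0("g1", l)]], dh1)
    g[[paste0("g1", l)]] <- bb$dg; g[[paste0("n1", l)]] <- bb$db
    dr1 <- bb$dX
  } else dr1 <- dh1
  dhhat <- dr1
  g[[paste0("Wo", l)]] <- crossprod(cache$AttC, dhhat)
  dAttC <- dhhat %*% t(w[[paste0("Wo", l)]])
  dQ <- matrix(0, nrow(dhhat), d); dK <- dQ; dV <- dQ
  for (k in seq_len(H)) {
    hc <- ((k - 1) * dk + 1):(k * dk)
    P <- cache$P[[k]]
    dA <- dAttC[, hc, drop = FALSE]
    dP <- tcrossprod(dA, cache$V[, hc, drop = FALSE])
    dV[, hc] <- crossprod(P, dA)
    dS <- softmax_rows_backward(P, dP) / sqrt(dk)
    dQ[, hc] <- dS %*% cache$K[, hc, drop = FALSE]
    dK[, hc] <- crossprod(dS, cache$Q[, hc, drop = FALSE])
  }
  g[[paste0("Wq", l)]] <- crossprod(cache$h, dQ)
  g[[paste0("Wk", l)]] <- crossprod(cache$h, dK)
  g[[paste0("Wv", l)]] <- crossprod(cache$h, dV)
  dh <- dQ %*% t(w[[paste0("Wq", l)]]) + dK %*% t(w[[paste0("Wk", l)]]) +
    dV %*% t(w[[paste0("Wv", l)]])
  if (cfg$use_residual) dh <- dh + dr1
  list(dh = dh, grads = g)
}

#' One full graph-transformer layer
#'
#' Attention sublayer followed by a position-wise feed-forward network
#' (hidden width exactly `2d`, ReLU, no biases), each wrapped in a residual
#' connection and a normalization layer:
#' `h1 = Norm(h + Attn(h))`, `h_next = Norm(h1 + W2 ReLU(W1 h1))`.
#' Normalization, residuals and the FFN can be disabled for ablations.
#'
#' @param h Node features (n x d).
#' @param A_message Message-graph adjacency with self-loops.
#' @param layer List with `Wq`, `Wk`, `Wv`, `Wo`, `W1`, `W2`, optional norm
#'   parameters `g1`/`n1`/`g2`/`n2`, plus `heads`, `norm`, `use_ffn`,
#'   `use_residual`.
#' @return Updated node features (n x d).
#' @export
gt_layer <- function(h, A_message, layer) {
  cfg <- list(d = ncol(h), heads = layer$heads,
              norm = layer$norm %||% "layer",
              use_ffn = layer$use_ffn %||% TRUE,
              use_residual = layer$use_residual %||% TRUE)
  w <- list()
  for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2", "g1", "n1", "g2", "n2"))
    if (!is.null(layer[[nm]])) w[[paste0(nm, 1)]] <- layer[[nm]]
  mask <- A_message != 0
  if (any(rowSums(mask) == 0))
    stop("every node needs at least one neighbor; add self-loops to A_message")
  gt_layer_forward(h, mask, w, 1, cfg)$out
}

#' Score a gene pair with the MLP link decoder
#'
#' Concatenates the source and target embeddings (source first, so the score
#' is direction-aware), applies one ReLU hidden layer and a linear output.
#'
#' @param h_final Final node embeddings (n x d).
#' @param i,j Source and target node indices (vectors allowed; `i != j`).
#' @param decoder_params List with `Wd1` (2d x hidden), `bd1`, `Wd2`
#'   (hidden x 1), `bd2`.
#' @return Raw logit score(s); apply `plogis()` for probabilities.
#' @export
predict_link <- function(h_final, i, j, decoder_params) {
  if (any(i == j)) stop("self-regulation pairs (i == j) are rejected")
  C <- cbind(h_final[i, , drop = FALSE], h_final[j, , drop = FALSE])
  Hd <- relu(sweep(C %*% decoder_params$Wd1, 2, decoder_params$bd1, `+`))
  as.vector(Hd %*% decoder_params$Wd2 + decoder_params$bd2)
}
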