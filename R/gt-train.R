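#' Split directed edges into train/validation/test link datasets
#'
#' Positives are shuffled and split by `ratios`. Negatives are ordered
#' non-edges of the full positive set (self-pairs excluded), sampled
#' uniformly at `negative_ratio` per positive and disjoint across splits;
#' these evaluation negatives are frozen. The message-passing graph is built
#' from training positives only (symmetrized, self-loops added), so no
#' validation or test edge leaks into message passing.
#'
#' @param true_edges Two-column integer matrix of directed edges (from, to).
#' @param n Number of nodes.
#' @param ratios Train/validation/test fractions summing to 1.
#' @param negative_ratio Negatives per positive.
#' @param seed Integer seed.
#' @return A `link_splits` object: `train`/`val`/`test` (each with `pos` and
#'   `neg` two-column matrices), `message_mask` (logical n x n with
#'   self-loops), `message_adj` (binary, no self-loops), `n`, `pos_key`
#'   (keys of all positives), `seed`.
#' @export
make_splits <- function(true_edges, n, ratios = c(0.8, 0.1, 0.1),
                        negative_ratio = 1, seed = 1) {
  true_edges <- as.matrix(true_edges)[, 1:2, drop = FALSE]
  storage.mode(true_edges) <- "integer"
  E <- nrow(true_edges)
  if (!E) stop("true_edges is empty")
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  set.seed(as.integer(seed))
  ord <- sample.int(E)
  n_tr <- floor(ratios[1] * E)
  n_va <- floor(ratios[2] * E)
  if (E - n_tr - n_va <= 0 || n_va <= 0)
    stop("split ratios leave an empty validation or test split")
  idx <- list(train = ord[seq_len(n_tr)],
              val = ord[n_tr + seq_len(n_va)],
              test = ord[(n_tr + n_va + 1):E])
  pos_key <- (true_edges[, 1] - 1) * n + true_edges[, 2]
  self_key <- (seq_len(n) - 1) * n + seq_len(n)
  n_neg <- negative_ratio * E
  avail <- n * n - n - E
  if (avail < n_neg) stop("insufficient non-edges to sample negatives")
  neg_key <- integer(0)
  excl <- c(pos_key, self_key)
  while (length(neg_key) < n_neg) {
    cand <- sample.int(n * n, min(4 * (n_neg - length(neg_key)) + 16, n * n))
    cand <- setdiff(cand, c(excl, neg_key))
    neg_key <- c(neg_key, cand[seq_len(min(length(cand), n_neg - length(neg_key)))])
  }
  key_to_pairs <- function(k)
    cbind(from = (k - 1) %/% n + 1, to = (k - 1) %% n + 1)
  neg_split <- split(neg_key, rep(c("train", "val", "test"),
                                  times = c(length(idx$train) * negative_ratio,
                                            length(idx$val) * negative_ratio,
                                            length(idx$test) * negative_ratio)))
  msg <- matrix(FALSE, n, n)
  tr <- true_edges[idx$train, , drop = FALSE]
  msg[tr] <- TRUE
  msg <- msg | t(msg)
  message_adj <- msg * 1
  diag(msg) <- TRUE
  structure(list(
    train = list(pos = true_edges[idx$train, , drop = FALSE],
                 neg = key_to_pairs(neg_split$train)),
    val = list(pos = true_edges[idx$val, , drop = FALSE],
               neg = key_to_pairs(neg_split$val)),
    test = list(pos = true_edges[idx$test, , drop = FALSE],
                neg = key_to_pairs(neg_split$test)),
    message_mask = msg, message_adj = message_adj, n = n,
    pos_key = pos_key, seed = as.integer(seed)),
    class = "link_splits")
}

#' @export
print.link_splits <- function(x, ...) {
  cat(sprintf("<link_splits> %d/%d/%d train/val/test positives over %d nodes\n",
              nrow(x$train$pos), nrow(x$val$pos), nrow(x$test$pos), x$n))
  invisible(x)
}

gt_forward_all <- function(w, cfg, feats, mask) {
  h <- project_and_fuse(feats$Z, feats$xi, feats$lam,
                        list(S0 = w$S0, s0 = w$s0, T0 = w$T0, t0 = w$t0,
                             U0 = w$U0, u0 = w$u0))
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    caches[[l]] <- gt_layer_forward(h, mask, w, l, cfg)
    h <- caches[[l]]$out
  }
  list(h_final = h, caches = caches)
}

decoder_forward <- function(w, h, pairs) {
  C <- cbind(h[pairs[, 1], , drop = FALSE], h[pairs[, 2], , drop = FALSE])
  Hd <- relu(sweep(C %*% w$Wd1, 2, w$bd1, `+`))
  list(logits = as.vector(Hd %*% w$Wd2 + w$bd2), C = C, Hd = Hd)
}

# Stable binary cross-entropy with logits and its gradient.
bce_with_logits <- function(z, y) {
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  list(loss = loss, dz = (stats::plogis(z) - y) / length(z))
}

#' Train the graph-transformer link predictor
#'
#' Full-batch training that minimizes binary cross-entropy on the training
#' positives plus uniformly resampled negatives (fresh each epoch;
#' evaluation negatives stay frozen). The modality embeddings are treated as
#' fixed inputs; the projections, transformer layers and decoder are
#' trained. The checkpoint with the best validation AUROC is returned.
#'
#' @param features List with `Z`, `xi`, `lam` matrices (n rows; a `NULL`
#'   entry disables that modality).
#' @param message_graph Logical/binary n x n message-passing adjacency;
#'   self-loops are added if missing.
#' @param splits A [make_splits()] object.
#' @param cfg A [gt_config()].
#' @return A `gt_fit` list: `weights` (best checkpoint), `cfg`, `h_final`,
#'   `history` (per-epoch train loss), `val_history` (epoch, val AUROC),
#'   `best_val_auroc`, `features`, `mask`.
#' @export
train_gt_link <- function(features, message_graph, splits, cfg = gt_config()) {
  if (!nrow(splits$val$pos)) stop("validation split is empty")
  mask <- message_graph != 0
  diag(mask) <- TRUE
  n <- splits$n
  set.seed(cfg$seed)
  widths <- lapply(features, function(f) if (is.null(f)) NULL else ncol(f))
  w <- gt_init_weights(widths, cfg)
  opt <- adam_init(w, lr = cfg$learning_rate)
  pos <- splits$train$pos
  E <- nrow(pos)
  self_key <- (seq_len(n) - 1) * n + seq_len(n)
  excl <- c(splits$pos_key, self_key)
  val_pairs <- rbind(splits$val$pos, splits$val$neg)
  val_y <- rep(c(1, 0), c(nrow(splits$val$pos), nrow(splits$val$neg)))

  sample_negatives <- function(k) {
    out <- integer(0)
    while (length(out) < k) {
      cand <- setdiff(sample.int(n * n, min(4 * k + 16, n * n)), c(excl, out))
      out <- c(out, cand[seq_len(min(length(cand), k - length(out)))])
    }
    cbind((out - 1) %/% n + 1, (out - 1) %% n + 1)
  }

  present <- names(features)[!vapply(features, is.null, TRUE)]
  md <- cfg$modality_dropout %||% 0
  history <- numeric(cfg$epochs)
  val_history <- NULL
  best <- list(auroc = -Inf, w = w)
  for (ep in seq_len(cfg$epochs)) {
    neg <- sample_negatives(cfg$negative_ratio * E)
    pairs <- rbind(pos, neg)
    y <- rep(c(1, 0), c(nrow(pos), nrow(neg)))
    feats_ep <- features
    if (md > 0 && length(present) > 1) {
      drop <- present[stats::runif(length(present)) < md]
      if (length(drop) == length(present)) drop <- drop[-1] # never all
      for (nm in present) # inverted scaling keeps expectations eval-consistent
        feats_ep[[nm]] <- if (nm %in% drop) features[[nm]] * 0 else
          features[[nm]] / (1 - md)
    }
    fw <- gt_forward_all(w, cfg, feats_ep, mask)
    dec <- decoder_forward(w, fw$h_final, pairs)
    bce <- bce_with_logits(dec$logits, y)
    if (!is.finite(bce$loss))
      stop(sprintf("graph-transformer training diverged at epoch %d", ep))
    history[ep] <- bce$loss
    ## decoder backward
    dz <- bce$dz
    g <- list(Wd2 = crossprod(dec$Hd, dz), bd2 = sum(dz))
    dHd <- (dz %*% t(w$Wd2)) * (dec$Hd > 0)
    g$Wd1 <- crossprod(dec$C, dHd)
    g$bd1 <- colSums(dHd)
    dC <- dHd %*% t(w$Wd1)
    d <- cfg$d
    dh <- matrix(0, n, d)
    agg_i <- rowsum(dC[, seq_len(d), drop = FALSE], group = pairs[, 1])
    dh[as.integer(rownames(agg_i)), ] <- agg_i
    agg_j <- rowsum(dC[, d + seq_len(d), drop = FALSE], group = pairs[, 2])
    dh[as.integer(rownames(agg_j)), ] <-
      dh[as.integer(rownames(agg_j)), , drop = FALSE] + agg_j
    ## transformer backward
    for (l in rev(seq_len(cfg$layers))) {
      bk <- gt_layer_backward(fw$caches[[l]], mask, w, l, cfg, dh)
      g <- c(g, bk$grads)
      dh <- bk$dh
    }
    ## projection backward (dropped modalities were zeroed in the forward)
    if (!is.null(feats_ep$Z)) { g$S0 <- crossprod(feats_ep$Z, dh); g$s0 <- colSums(dh) }
    if (!is.null(feats_ep$xi)) { g$T0 <- crossprod(feats_ep$xi, dh); g$t0 <- colSums(dh) }
    if (!is.null(feats_ep$lam)) { g$U0 <- crossprod(feats_ep$lam, dh); g$u0 <- colSums(dh) }
    if (cfg$weight_decay > 0) { # decoupled decay on weight matrices only
      for (nm in names(w))
        if (!is.null(dim(w[[nm]])))
          w[[nm]] <- w[[nm]] * (1 - cfg$learning_rate * cfg$weight_decay)
    }
    st <- adam_step(w, g, opt)
    w <- st$params; opt <- st$state
    if (ep %% cfg$val_every == 0 || ep == cfg$epochs) {
      fwv <- gt_forward_all(w, cfg, features, mask)
      sc <- decoder_forward(w, fwv$h_final, val_pairs)$logits
      va <- auroc(sc, val_y)
      val_history <- rbind(val_history, c(epoch = ep, val_auroc = va))
      if (va > best$auroc) best <- list(auroc = va, w = w)
    }
  }
  fw <- gt_forward_all(best$w, cfg, features, mask)
  structure(list(weights = best$w, cfg = cfg, h_final = fw$h_final,
                 history = history, val_history = val_history,
                 best_val_auroc = best$auroc, features = features,
                 mask = mask),
            class = "gt_fit")
}

#' Score every ordered gene pair
#'
#' @param model A [train_gt_link()] fit.
#' @param h_final Final node embeddings (defaults to the model's).
#' @return An n x n matrix of logits, `NaN` on the diagonal.
#' @export
score_all_pairs <- function(model, h_final = model$h_final) {
  n <- nrow(h_final)
  pairs <- cbind(rep(seq_len(n), each = n), rep(seq_len(n), n))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  sc <- decoder_forward(model$weights, h_final, pairs)$logits
  out <- matrix(NaN, n, n, dimnames = list(rownames(h_final), rownames(h_final)))
  out[pairs] <- sc
  out
}

split_metrics <- function(model, split) {
  pairs <- rbind(split$pos, split$neg)
  y <- rep(c(1, 0), c(nrow(split$pos), nrow(split$neg)))
  sc <- decoder_forward(model$weights, model$h_final, pairs)$logits
  c(auroc = auroc(sc, y), auprc = auprc(sc, y))
}

#' Modality ablation harness
#'
#' Trains the model under every requested modality subset (default: the
#' three unimodal, three bimodal, and the trimodal configuration) for each
#' seed and reports held-out test AUROC.
#'
#' @param features Full trimodal feature list (`Z`, `xi`, `lam`).
#' @param splits A [make_splits()] object.
#' @param cfg Base [gt_config()]; each run reuses it with a different seed.
#' @param seeds Integer vector of training seeds.
#' @param subsets List of character vectors over
#'   `c("expression", "global", "positional")`.
#' @param message_graph Message-passing adjacency; defaults to the splits'
#'   training-positive graph.
#' @return Data frame with `modality`, `seed`, `test_auroc`, `test_auprc`.
#' @export
ablate_modalities <- function(features, splits, cfg, seeds = 1:5,
                              subsets = NULL,
                              message_graph = splits$message_mask) {
  if (is.null(subsets)) {
    mods <- c("expression", "global", "positional")
    subsets <- c(lapply(mods, identity),
                 utils::combn(mods, 2, simplify = FALSE),
                 list(mods))
  }
  res <- NULL
  for (sub in subsets) {
    feats <- list(Z = if ("expression" %in% sub) features$Z,
                  xi = if ("global" %in% sub) features$xi,
                  lam = if ("positional" %in% sub) features$lam)
    for (s in seeds) {
      cfg_s <- cfg; cfg_s$seed <- as.integer(s)
      fit <- train_gt_link(feats, message_graph, splits, cfg_s)
      m <- split_metrics(fit, splits$test)
      res <- rbind(res, data.frame(modality = paste(sub, collapse = "+"),
                                   seed = s, test_auroc = m["auroc"],
                                   test_auprc = m["auprc"], row.names = NULL))
    }
  }
  res
}

#' Transformer-layer ablation harness
#'
#' Runs the architectural variants (full model, single attention head, two
#' layers, FFN removed, normalization disabled, residual connections
#' removed) and reports held-out test AUROC per seed.
#'
#' @inheritParams ablate_modalities
#' @return Data frame with `variant`, `seed`, `test_auroc`.
#' @export
ablate_layers <- function(features, splits, cfg, seeds = 1,
                          message_graph = splits$message_mask) {
  variants <- list(
    full = identity,
    reduced_heads = function(cf) { cf$heads <- 1L; cf },
    reduced_depth = function(cf) { cf$layers <- 2L; cf },
    no_ffn = function(cf) { cf$use_ffn <- FALSE; cf },
    no_norm = function(cf) { cf$norm <- "none"; cf },
    no_residual = function(cf) { cf$use_residual <- FALSE; cf })
  res <- NULL
  for (nm in names(variants)) {
    for (s in seeds) {
      cf <- variants[[nm]](cfg)
      cf$seed <- as.integer(s)
      fit <- train_gt_link(features, message_graph, splits, cf)
      m <- split_metrics(fit, splits$test)
      res <- rbind(res, data.frame(variant = nm, seed = s,
                                   test_auroc = m["auroc"], row.names = NULL))
    }
  }
  res
}
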