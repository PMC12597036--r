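toy_layer <- function(d, heads = 2, seed = 1, scale = 1) {
  set.seed(seed)
  r <- function(a, b) matrix(stats::rnorm(a * b, sd = 0.3), a, b)
  list(Wq = r(d, d), Wk = r(d, d), Wv = r(d, d), Wo = r(d, d) * scale,
       W1 = r(d, 2 * d), W2 = r(2 * d, d),
       g1 = rep(1, d), n1 = rep(0, d), g2 = rep(1, d), n2 = rep(0, d),
       heads = heads, norm = "layer")
}

test_that("project_and_fuse sums the three affine projections", {
  set.seed(2)
  n <- 5; dn <- 3; d <- 4
  proj <- list(S0 = matrix(stats::rnorm(dn * d), dn, d), s0 = stats::rnorm(d),
               T0 = matrix(stats::rnorm(dn * d), dn, d), t0 = stats::rnorm(d),
               U0 = matrix(stats::rnorm(dn * d), dn, d), u0 = stats::rnorm(d))
  Z <- matrix(stats::rnorm(n * dn), n, dn)
  zero <- matrix(0, n, dn)
  # xi = lam = 0 with zero biases -> h = Z S0 + s0
  proj0 <- proj; proj0$t0 <- proj0$u0 <- rep(0, d)
  h <- project_and_fuse(Z, zero, zero, proj0)
  expect_equal(h, sweep(Z %*% proj$S0, 2, proj$s0, `+`))
  # all-zero inputs -> every row is s0 + t0 + u0
  h0 <- project_and_fuse(zero, zero, zero, proj)
  expect_equal(h0[3, ], proj$s0 + proj$t0 + proj$u0)
  # fusion commutes with a joint row permutation
  xi <- matrix(stats::rnorm(n * dn), n, dn)
  lam <- matrix(stats::rnorm(n * dn), n, dn)
  perm <- sample(n)
  expect_equal(project_and_fuse(Z, xi, lam, proj)[perm, ],
               project_and_fuse(Z[perm, ], xi[perm, ], lam[perm, ], proj))
  expect_error(project_and_fuse(Z, xi[1:3, ], lam, proj), "disagree")
  expect_error(project_and_fuse(Z[, 1:2], xi, lam, proj), "width")
})

test_that("graph attention: softmax over neighborhoods behaves as stated", {
  d <- 4
  layer <- toy_layer(d)
  set.seed(3)
  h <- matrix(stats::rnorm(5 * d), 5, d)
  # node whose only neighbor is itself: output = Wo applied to its own value
  A <- diag(5); A[2, 3] <- A[3, 2] <- 1
  out <- gt_attention(h, A, layer, return_attention = TRUE)
  Ps <- attr(out, "attention")
  for (P in Ps) {
    expect_true(all(abs(rowSums(P) - 1) < 1e-6))
    expect_equal(P[1, 1], 1) # self-loop only
  }
  V <- h %*% layer$Wv
  expect_equal(out[1, ], as.vector(V[1, ] %*% layer$Wo))
  # two neighbors with identical keys/values -> weights (1/2, 1/2)
  h2 <- h; h2[3, ] <- h2[4, ]
  A2 <- diag(5) * 0; A2[1, 3] <- A2[1, 4] <- 1; diag(A2) <- 1; A2[1, 1] <- 0
  out2 <- gt_attention(h2, A2, layer, return_attention = TRUE)
  P1 <- attr(out2, "attention")[[1]]
  expect_equal(P1[1, 3], 0.5, tolerance = 1e-9)
  expect_equal(P1[1, 4], 0.5, tolerance = 1e-9)
  # attention restricted to N(i): changing a non-neighbor leaves output alone
  h3 <- h; h3[5, ] <- 0
  expect_equal(gt_attention(h, A, layer)[1, ], gt_attention(h3, A, layer)[1, ])
  expect_error(gt_attention(h, matrix(0, 5, 5), layer), "self-loops")
})

test_that("gt_layer reduces to the residual path with zero weights, no norm", {
  d <- 4
  layer <- toy_layer(d)
  layer$norm <- "none"
  for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) layer[[nm]][] <- 0
  set.seed(4)
  h <- matrix(stats::rnorm(6 * d), 6, d)
  A <- diag(6)
  expect_equal(gt_layer(h, A, layer), h)
  # output shape is n x d in all modes
  layer2 <- toy_layer(d)
  expect_equal(dim(gt_layer(h, A, layer2)), c(6, d))
})

test_that("gt_layer is equivariant to joint node permutation (LayerNorm)", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    d <- 8
    layer <- toy_layer(d, heads = 2, seed = rep)
    h <- matrix(stats::rnorm(n * d), n, d)
    A <- random_adjacency(n, 0.4, seed = rep, symmetric = TRUE)
    diag(A) <- 1
    perm <- sample(n)
    P <- diag(n)[perm, ]
    lhs <- gt_layer(h, A, layer)[perm, ]
    rhs <- gt_layer(h[perm, ], A[perm, perm], layer)
    expect_lt(max(abs(lhs - rhs)), 1e-5)
  }
})

test_that("link decoder is deterministic, direction-aware and validates pairs", {
  set.seed(6)
  d <- 4
  h <- matrix(stats::rnorm(5 * d), 5, d)
  dec <- list(Wd1 = matrix(stats::rnorm(2 * d * 3), 2 * d, 3),
              bd1 = stats::rnorm(3),
              Wd2 = matrix(stats::rnorm(3), 3, 1), bd2 = 0.2)
  s1 <- predict_link(h, 1, 2, dec)
  expect_identical(s1, predict_link(h, 1, 2, dec))
  # identical embeddings -> symmetric score
  h2 <- h; h2[2, ] <- h2[1, ]
  expect_equal(predict_link(h2, 1, 2, dec), predict_link(h2, 2, 1, dec))
  # zero weights -> bias logit for every pair
  dec0 <- dec; dec0$Wd1[] <- 0; dec0$Wd2[] <- 0
  expect_equal(predict_link(h, 3, 4, dec0), 0.2)
  expect_error(predict_link(h, 2, 2, dec), "self-regulation")
})

test_that("make_splits partitions edges without leakage, deterministically", {
  set.seed(7)
  n <- 30
  edges <- unique(cbind(sample.int(n, 200, TRUE), sample.int(n, 200, TRUE)))
  edges <- edges[edges[, 1] != edges[, 2], ][1:100, ]
  sp <- make_splits(edges, n, ratios = c(0.8, 0.1, 0.1), negative_ratio = 2,
                    seed = 5)
  expect_equal(nrow(sp$train$pos) + nrow(sp$val$pos) + nrow(sp$test$pos), 100)
  key <- function(m) (m[, 1] - 1) * n + m[, 2]
  # splits disjoint
  expect_length(intersect(key(sp$train$pos), key(sp$test$pos)), 0)
  expect_length(intersect(key(sp$val$pos), key(sp$test$pos)), 0)
  # negatives are non-edges, disjoint across splits, 2 per positive
  allneg <- rbind(sp$train$neg, sp$val$neg, sp$test$neg)
  expect_length(intersect(key(allneg), key(edges)), 0)
  expect_equal(anyDuplicated(key(allneg)), 0)
  expect_true(all(allneg[, 1] != allneg[, 2]))
  expect_equal(nrow(sp$train$neg), 2 * nrow(sp$train$pos))
  # no test positive in the message graph
  msg_keys <- key(which(sp$message_adj != 0, arr.ind = TRUE))
  expect_length(intersect(key(sp$test$pos), msg_keys), 0)
  # deterministic under seed
  sp2 <- make_splits(edges, n, ratios = c(0.8, 0.1, 0.1), negative_ratio = 2,
                     seed = 5)
  expect_identical(sp, sp2)
  expect_error(make_splits(edges, n, negative_ratio = 1000), "insufficient")
})

test_that("training improves the loss and is reproducible; scoring is consistent", {
  set.seed(8)
  n <- 25
  A <- generate_grn(n, 2.5, seed = 3)
  edges <- which(A != 0, arr.ind = TRUE)
  sp <- make_splits(edges, n, seed = 4)
  feats <- list(Z = matrix(stats::rnorm(n * 6), n, 6),
                xi = matrix(stats::rnorm(n * 6), n, 6),
                lam = matrix(stats::rnorm(n * 6), n, 6))
  cfg <- gt_config(d = 8, heads = 2, layers = 2, epochs = 30, val_every = 10,
                   seed = 9)
  fit <- train_gt_link(feats, sp$message_mask, sp, cfg)
  expect_lt(fit$history[length(fit$history)], fit$history[1])
  fit2 <- train_gt_link(feats, sp$message_mask, sp, cfg)
  expect_identical(fit$best_val_auroc, fit2$best_val_auroc)
  expect_identical(fit$h_final, fit2$h_final)
  # score matrix: NaN diagonal, entries equal pairwise predict_link calls
  sc <- score_all_pairs(fit)
  expect_equal(dim(sc), c(n, n))
  expect_true(all(is.nan(diag(sc))))
  expect_equal(sc[2, 5], predict_link(fit$h_final, 2, 5, fit$weights))
  expect_equal(sc[5, 2], predict_link(fit$h_final, 5, 2, fit$weights))
  sc2 <- score_all_pairs(fit)
  expect_identical(order(sc[!is.nan(sc)]), order(sc2[!is.nan(sc2)]))
  sp_noval <- sp
  sp_noval$val$pos <- sp$val$pos[0, , drop = FALSE]
  expect_error(train_gt_link(feats, sp$message_mask, sp_noval, cfg),
               "validation")
})

test_that("full model is permutation equivariant end to end (LayerNorm)", {
  set.seed(10)
  n <- 12
  A <- generate_grn(n, 2, seed = 2)
  edges <- which(A != 0, arr.ind = TRUE)
  sp <- make_splits(edges, n, seed = 2)
  feats <- list(Z = matrix(stats::rnorm(n * 4), n, 4), xi = NULL,
                lam = matrix(stats::rnorm(n * 4), n, 4))
  cfg <- gt_config(d = 8, heads = 2, layers = 2, epochs = 5, val_every = 5,
                   seed = 3)
  fit <- train_gt_link(feats, sp$message_mask, sp, cfg)
  perm <- sample(n)
  featsp <- list(Z = feats$Z[perm, ], xi = NULL, lam = feats$lam[perm, ])
  fwd <- grnfusion:::gt_forward_all(fit$weights, cfg, feats, fit$mask)
  fwdp <- grnfusion:::gt_forward_all(fit$weights, cfg, featsp,
                                     fit$mask[perm, perm])
  expect_lt(max(abs(fwd$h_final[perm, ] - fwdp$h_final)), 1e-5)
  # scores of corresponding pairs equal
  i <- perm[3]; j <- perm[7]
  s1 <- predict_link(fwd$h_final, i, j, fit$weights)
  s2 <- predict_link(fwdp$h_final, 3, 7, fit$weights)
  expect_equal(s1, s2, tolerance = 1e-5)
})

test_that("gradients of the full GT stack match finite differences", {
  set.seed(11)
  n <- 6
  cfg <- gt_config(d = 4, heads = 2, layers = 2, epochs = 1,
                   decoder_hidden = 3, init_scale = 1, seed = 1)
  feats <- list(Z = matrix(stats::rnorm(n * 3), n, 3),
                xi = matrix(stats::rnorm(n * 3), n, 3), lam = NULL)
  w <- grnfusion:::gt_init_weights(list(Z = 3, xi = 3, lam = NULL), cfg)
  mask <- random_adjacency(n, 0.5, seed = 2, symmetric = TRUE) != 0
  diag(mask) <- TRUE
  pairs <- cbind(c(1, 2, 4), c(3, 5, 1)); y <- c(1, 0, 1)
  loss_fn <- function(w) {
    fw <- grnfusion:::gt_forward_all(w, cfg, feats, mask)
    dec <- grnfusion:::decoder_forward(w, fw$h_final, pairs)
    grnfusion:::bce_with_logits(dec$logits, y)$loss
  }
  fw <- grnfusion:::gt_forward_all(w, cfg, feats, mask)
  dec <- grnfusion:::decoder_forward(w, fw$h_final, pairs)
  bce <- grnfusion:::bce_with_logits(dec$logits, y)
  g <- list(Wd2 = crossprod(dec$Hd, bce$dz), bd2 = sum(bce$dz))
  dHd <- (bce$dz %*% t(w$Wd2)) * (dec$Hd > 0)
  g$Wd1 <- crossprod(dec$C, dHd); g$bd1 <- colSums(dHd)
  dC <- dHd %*% t(w$Wd1)
  dh <- matrix(0, n, cfg$d)
  for (r in seq_len(nrow(pairs))) {
    dh[pairs[r, 1], ] <- dh[pairs[r, 1], ] + dC[r, 1:cfg$d]
    dh[pairs[r, 2], ] <- dh[pairs[r, 2], ] + dC[r, cfg$d + 1:cfg$d]
  }
  for (l in rev(seq_len(cfg$layers))) {
    bk <- grnfusion:::gt_layer_backward(fw$caches[[l]], mask, w, l, cfg, dh)
    g <- c(g, bk$grads); dh <- bk$dh
  }
  g$S0 <- crossprod(feats$Z, dh); g$s0 <- colSums(dh)
  g$T0 <- crossprod(feats$xi, dh); g$t0 <- colSums(dh)
  eps <- 1e-6
  for (nm in names(w)) {
    idxs <- seq_len(min(4, length(w[[nm]])))
    for (ii in idxs) {
      wp <- w; wp[[nm]][ii] <- wp[[nm]][ii] + eps
      wm <- w; wm[[nm]][ii] <- wm[[nm]][ii] - eps
      num <- (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
      expect_equal(g[[nm]][ii], num, tolerance = 1e-4,
                   info = paste("param", nm, ii))
    }
  }
})

test_that("configuration invariants are enforced", {
  expect_error(gt_config(d = 10, heads = 4), "divisible")
  expect_error(gt_attention(matrix(0, 2, 5), diag(2),
                            list(Wq = diag(5), Wk = diag(5), Wv = diag(5),
                                 Wo = diag(5), heads = 3)), "divisible")
})
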