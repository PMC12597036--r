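test_that("gene fraction filter applies the >= boundary convention", {
  vals <- matrix(0, 3, 20)
  vals[1, 1] <- 5          # 1/20 = 0.05 < 0.10 -> removed
  vals[2, 1:2] <- 5        # 2/20 = 0.10 >= 0.10 -> kept
  X <- expression_matrix(vals, gene_ids = c("a", "b", "zero"))
  out <- filter_genes_by_cell_fraction(X, 0.10)
  expect_identical(gene_ids(out), "b")
  expect_error(filter_genes_by_cell_fraction(X, 0.9), "all genes filtered")
  expect_error(filter_genes_by_cell_fraction(X, 0), "min_fraction")
})

test_that("cell filter keeps cells at the min_genes boundary", {
  vals <- matrix(0, 300, 3)
  vals[1:199, 1] <- 1
  vals[1:200, 2] <- 1
  vals[1:250, 3] <- 1
  X <- expression_matrix(vals)
  out <- filter_cells_by_gene_count(X, 200)
  expect_identical(cell_ids(out), c("c2", "c3"))
  expect_identical(dim(filter_cells_by_gene_count(X, 0)), dim(X))
})

test_that("total-count normalization scales columns exactly", {
  X <- expression_matrix(cbind(c(1, 1, 2), c(3, 3, 4)))
  out <- normalize_total_counts(X, 10000)
  expect_equal(out$values[, 1], c(g1 = 2500, g2 = 2500, g3 = 5000))
  expect_equal(unname(colSums(out$values)), c(10000, 10000), tolerance = 1e-9)
  already <- expression_matrix(matrix(c(5000, 5000), 2, 1))
  expect_equal(normalize_total_counts(already, 10000)$values,
               already$values)
  Xz <- expression_matrix(cbind(c(1, 2), c(0, 0)),
                          cell_ids = c("ok", "empty"))
  expect_error(normalize_total_counts(Xz), "empty")
})

test_that("count-based steps reject log-transformed input (pipeline order)", {
  Xl <- log_transform(toy_counts())
  expect_error(filter_genes_by_cell_fraction(Xl, 0.1), "log")
  expect_error(filter_cells_by_gene_count(Xl, 1), "log")
  expect_error(normalize_total_counts(Xl), "log")
  expect_error(log_transform(Xl), "already")
})

test_that("filters are idempotent", {
  X <- toy_counts(n = 40, m = 15, seed = 7, lambda = 0.8)
  f1 <- filter_genes_by_cell_fraction(X, 0.2)
  expect_identical(filter_genes_by_cell_fraction(f1, 0.2)$values, f1$values)
  c1 <- filter_cells_by_gene_count(X, 5)
  expect_identical(filter_cells_by_gene_count(c1, 5)$values, c1$values)
})

test_that("log transform is log2(x + 1)", {
  X <- expression_matrix(matrix(c(0, 1, 3, 7), 2, 2))
  out <- log_transform(X)
  expect_equal(as.vector(out$values), c(0, 1, 2, 3))
  expect_true(out$is_log)
})

test_that("variance selection: constant genes never pass, Bonferroni applies", {
  vals <- rbind(rep(3, 10), stats::rnorm(10, 0, 50))
  X <- expression_matrix(vals, is_log = TRUE)
  sel <- select_variable_genes(X, alpha = 0.01)
  expect_equal(unname(sel$per_gene_pvalue["g1"]), 1)
  expect_false("g1" %in% sel$kept_gene_ids)
  expect_true(all(sel$per_gene_pvalue >= 0 & sel$per_gene_pvalue <= 1))
  # Bonferroni: adjusted = min(1, p * n_tests)
  expect_equal(unname(sel$adjusted_pvalue),
               unname(pmin(1, sel$per_gene_pvalue * length(sel$per_gene_pvalue))))
  Xc <- expression_matrix(matrix(2, 5, 6))
  selc <- select_variable_genes(Xc)
  expect_length(selc$kept_gene_ids, 0)
  expect_true(all(selc$per_gene_pvalue == 1))
})

test_that("variance selection recovers spiked genes and controls nulls", {
  n_null <- 500; n_spike <- 10; m <- 40
  spike_hits <- 0; null_rates <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    null_part <- matrix(stats::rnorm(n_null * m, sd = 1), n_null, m)
    spike_part <- matrix(stats::rnorm(n_spike * m, sd = 6), n_spike, m)
    X <- expression_matrix(rbind(null_part, spike_part),
                           gene_ids = c(paste0("null", 1:n_null),
                                        paste0("spike", 1:n_spike)),
                           is_log = TRUE)
    sel <- select_variable_genes(X, alpha = 0.01)
    if (s == 1)
      spike_recovery <- mean(paste0("spike", 1:n_spike) %in% sel$kept_gene_ids)
    null_rates[s] <- sum(grepl("^null", sel$kept_gene_ids)) / n_null
  }
  expect_gte(spike_recovery, 0.95)
  # Bonferroni at alpha keeps the familywise null rate far below alpha
  expect_lte(mean(null_rates), 0.01)
})

test_that("top-k by variance uses the stated tie and always-keep rules", {
  vals <- rbind(a = c(0, 5, 10), b = c(0, 3, 6), c = c(6, 3, 0), d = c(1, 2, 3))
  X <- expression_matrix(vals)
  v <- apply(vals, 1, var)
  expect_equal(unname(v["b"]), unname(v["c"])) # b and c tie; id order breaks it
  expect_setequal(gene_ids(top_k_by_variance(X, 2)), c("a", "b"))
  expect_setequal(gene_ids(top_k_by_variance(X, 1, always_keep = "d")),
                  c("d", "a"))
  expect_setequal(gene_ids(top_k_by_variance(X, 4)), c("a", "b", "c", "d"))
  expect_error(top_k_by_variance(X, 1, always_keep = "nope"), "unknown gene_id")
})

test_that("preprocess_expression composes stages and reports QC", {
  X <- toy_counts(n = 60, m = 25, seed = 3)
  res <- preprocess_expression(X, min_fraction = 0.1, min_genes = 1,
                               target_sum = 10000, alpha = NULL, top_k = 10)
  expect_true(res$X$is_log)
  expect_equal(n_genes(res$X), 10)
  expect_named(res$qc, c("gene_fraction_filter", "cell_gene_count_filter",
                         "total_count_normalization", "log_transform",
                         "top_k_by_variance"))
})
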