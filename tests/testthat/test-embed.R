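# Normalization, HVG, PCA, sketching, batch alignment.

test_that("lognormalize matches an element-wise dense oracle", {
  m <- random_counts(50, 30, seed = 8)
  norm <- lognormalize(m, scale_factor = 1e4)
  dense <- as.matrix(m)
  totals <- colSums(dense)
  oracle <- log1p(sweep(dense, 2, totals, "/") * 1e4)
  expect_equal(as.matrix(norm), oracle, tolerance = 1e-12)
  # zero counts stay exactly zero (sparsity preserved)
  expect_equal(length(norm@x), length(m@x))
})

test_that("lognormalize cancels the library size and flags empty cells", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(10, 9990),
                            dims = c(2, 2),
                            dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(lognormalize(m), "c2")
  m2 <- m[, 1, drop = FALSE]
  norm <- lognormalize(m2, scale_factor = 1e4)
  expect_equal(norm["g1", "c1"], log(1 + 10))  # total equals the scale factor

  # invariance to scaling one cell's counts
  a <- random_counts(20, 5, seed = 2)
  b <- a; b[, 3] <- b[, 3] * 7
  expect_equal(as.matrix(lognormalize(a)), as.matrix(lognormalize(b)),
               tolerance = 1e-12)
})

test_that("HVG selection excludes constant genes and breaks ties by id", {
  # select_hvg operates on normalized values; constant rows carry no signal
  set.seed(1)
  norm <- matrix(2, nrow = 8, ncol = 20)
  norm[1:5, ] <- matrix(runif(100, 0, 4), nrow = 5)
  dimnames(norm) <- list(sprintf("G%02d", 1:8), sprintf("c%02d", 1:20))
  hvg <- select_hvg(methods::as(norm, "CsparseMatrix"), n = 8)
  expect_setequal(hvg, sprintf("G%02d", 1:5))  # only non-constant genes

  # two identical duplicated genes tie; id order decides
  norm2 <- norm[c(1, 1, 2:5), ]
  rownames(norm2) <- c("GB", "GA", sprintf("G%02d", 2:5))
  hvg2 <- select_hvg(methods::as(norm2, "CsparseMatrix"), n = 6)
  expect_lt(which(hvg2 == "GA"), which(hvg2 == "GB"))
})

test_that("HVG selection recovers planted variable genes", {
  sim <- shared_sim(1)
  norm <- lognormalize(sim$human)
  hvg <- select_hvg(norm, n = 2000)
  gt <- sim$truth$gene_table
  planted <- gt$gene_id[gt$species == "human" &
                          (!is.na(gt$marker_of) | gt$archetype != "flat")]
  expect_gte(mean(planted %in% hvg), 0.9)
})

test_that("PCA captures rank-1 structure and supports exact self-projection", {
  set.seed(3)
  t_axis <- seq(-1, 1, length.out = 40)
  X <- outer(rnorm(10), t_axis)   # rank-1 data: genes x cells
  dimnames(X) <- list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:40))
  suppressWarnings(emb <- run_pca(methods::as(X, "CsparseMatrix"), d = 3,
                                  seed = 1))  # rank-1 by construction
  ev <- emb$explained_variance
  expect_gte(ev[1] / sum(ev), 0.999)
  expect_true(all(diff(ev) <= 1e-8))

  sim_norm <- lognormalize(random_counts(40, 25, seed = 5))
  emb2 <- run_pca(sim_norm, d = 5, seed = 2)
  reproj <- project_cells(emb2, sim_norm)
  expect_lt(max(abs(reproj - emb2$scores)), 1e-8)
  # orthonormal loadings
  expect_equal(crossprod(emb2$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("top PCA eigenvalue matches a dense eigendecomposition oracle", {
  m <- random_counts(30, 20, seed = 9)
  norm <- lognormalize(m)
  emb <- run_pca(norm, d = 5, seed = 1)
  # oracle: full eigendecomposition of the covariance of the z-scored data
  X <- as.matrix(norm)
  Z <- (X - rowMeans(X)) / apply(X, 1, sd)
  Z[!is.finite(Z)] <- 0
  Z <- pmin(pmax(Z, -10), 10)
  ev_oracle <- eigen(stats::cov(t(Z)), symmetric = TRUE)$values
  expect_equal(emb$explained_variance[1], ev_oracle[1], tolerance = 1e-6)
})

test_that("run_pca warns and zero-pads beyond the rank", {
  X <- outer(rnorm(6), rnorm(5))  # rank 1
  dimnames(X) <- list(sprintf("g%d", 1:6), sprintf("c%d", 1:5))
  expect_warning(emb <- run_pca(methods::as(X, "CsparseMatrix"), d = 5,
                                seed = 1), "rank")
  expect_length(emb$explained_variance, 5)
})

test_that("geometric sketch meets its size contract", {
  set.seed(10)
  scores <- matrix(rnorm(400 * 3), ncol = 3)
  expect_identical(geometric_sketch(scores, nrow(scores)), seq_len(400))
  for (i in 1:10) {
    k <- sample(1:400, 1)
    s <- sample(1e4, 1)
    idx <- geometric_sketch(scores, k, seed = s)
    expect_length(idx, k)
    expect_false(anyDuplicated(idx) > 0)
    expect_identical(idx, geometric_sketch(scores, k, seed = s))
  }
})

test_that("sketching retains a rare planted population better than uniform", {
  sim <- shared_sim(1)
  truth <- sim$truth$cell_table
  truth <- truth[truth$species == "human", ]
  norm <- lognormalize(sim$human)
  emb <- run_pca(norm, select_hvg(norm, 1000), d = 10, seed = 1)
  rare <- truth$true_type == "MONOs"
  expect_lt(mean(rare), 0.05)
  k <- round(0.2 * nrow(emb$scores))
  kept_sketch <- kept_unif <- numeric(20)
  for (s in 1:20) {
    idx <- geometric_sketch(emb, k, seed = s)
    kept_sketch[s] <- sum(rare[idx])
    set.seed(s)
    kept_unif[s] <- sum(rare[sample(nrow(emb$scores), k)])
  }
  expect_gte(mean(kept_sketch > 0), 0.95)
  # geometry-aware sampling over-represents the rare type vs uniform
  expect_gte(mean(kept_sketch), mean(kept_unif))
})

test_that("batch alignment is a no-op guard on degenerate batch structure", {
  norm <- lognormalize(random_counts(40, 30, seed = 6))
  emb <- run_pca(norm, d = 5, seed = 1)
  expect_warning(out <- align_batches(emb, rep("b1", 30), d_out = 5),
                 "single batch")
  expect_equal(out$scores, emb$scores[, 1:5])
  expect_warning(out2 <- align_batches(emb, sprintf("b%d", 1:30), d_out = 5),
                 "distinct")
  expect_equal(out2$scores, emb$scores[, 1:5])
})

test_that("alignment converges with nothing to correct on identical batches", {
  set.seed(21)
  scores <- matrix(rnorm(300 * 6), ncol = 6)
  emb <- structure(list(scores = scores, loadings = diag(6),
                        gene_means = rep(0, 6), gene_sds = rep(1, 6),
                        explained_variance = rep(1, 6),
                        genes = sprintf("g%d", 1:6), clip = 10),
                   class = "Embedding")
  batch <- rep(c("a", "b"), 150)
  out <- align_batches(emb, batch, n_clusters = 10, d_out = 6, seed = 2)
  expect_lt(out$iterations, 100)
  # output columns are unit variance
  expect_equal(unname(apply(out$scores, 2, sd)), rep(1, 6), tolerance = 1e-6)
  # cells keep identity and order
  expect_equal(nrow(out$scores), 300)
})

test_that("alignment mixes platforms while preserving planted cell types", {
  sim <- shared_sim(1)
  truth <- sim$truth$cell_table
  tm <- truth[truth$species == "mouse" & !truth$doublet, ]
  norm <- lognormalize(sim$mouse$counts[, tm$cell_id])
  emb <- run_pca(norm, select_hvg(norm, 2000), d = 20, seed = 3)
  aligned <- align_batches(emb, tm$batch, d_out = 20, seed = 3)
  ent_before <- batch_mixing_entropy(emb$scores, tm$batch)
  ent_after <- batch_mixing_entropy(aligned$scores, tm$batch)
  expect_gt(ent_after, ent_before)
  labels <- cluster_graph(build_knn_graph(aligned, k = 20), seed = 3)
  ann <- annotate_clusters(lognormalize(sim$mouse$counts[, tm$cell_id]),
                           labels,
                           mouse_symbols(default_marker_dictionary()))
  types <- unname(ann[as.character(labels)])
  expect_gte(ari(types, tm$true_type), 0.8)
})
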