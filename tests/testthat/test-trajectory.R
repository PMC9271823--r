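# Trajectory gene filters, ordering genes, centroid-MST pseudotime,
# NB-spline pseudotime tests, phase assignment, density curves.

test_that("trajectory gene filter applies the combined 10-cell / 5% rule", {
  mk <- function(n_expressing, n_cells) {
    m <- Matrix::sparseMatrix(i = rep(1, max(n_expressing, 1)),
                              j = seq_len(max(n_expressing, 1)),
                              x = rep(1, max(n_expressing, 1)) *
                                (n_expressing > 0),
                              dims = c(2, n_cells))
    rownames(m) <- c("target", "keeper")
    m[2, ] <- 1  # always passes
    colnames(m) <- sprintf("c%04d", seq_len(n_cells))
    "target" %in% filter_trajectory_genes(Matrix::drop0(m))
  }
  expect_false(mk(9, 1000))    # below the 10-cell floor
  expect_false(mk(49, 1000))   # 4.9% of cells
  expect_true(mk(50, 1000))    # exactly 5%
  expect_true(mk(10, 100))     # thresholds coincide at 10
  expect_false(mk(9, 100))
})

test_that("ordering-gene selection keeps dynamic genes and rejects constants", {
  sim <- shared_sim(1)
  ct <- sim$truth$cell_table
  th <- ct[ct$species == "human" & !ct$doublet & ct$true_type == "CMs", ]
  norm <- lognormalize(sim$human$counts[, th$cell_id])
  stages <- ct$stage[match(th$cell_id, ct$cell_id)]
  ord <- select_ordering_genes(norm, stages, top_n = 1000)
  gt <- sim$truth$gene_table
  dyn <- gt$gene_id[gt$species == "human" & gt$archetype %in% c("early", "late")]
  expect_gte(mean(dyn %in% ord), 0.9)

  # a constant gene can never be selected
  const <- norm
  const[1, ] <- 0
  rownames(const)[1] <- "CONSTANT"
  expect_false("CONSTANT" %in%
                 select_ordering_genes(Matrix::drop0(const), stages))
})

test_that("ordering-gene selection is calibrated under permuted stages", {
  sim <- shared_sim(1)
  ct <- sim$truth$cell_table
  th <- ct[ct$species == "human" & !ct$doublet & ct$true_type == "FBs", ]
  norm <- lognormalize(sim$human$counts[, th$cell_id])
  stages <- ct$stage[match(th$cell_id, ct$cell_id)]
  for (s in 1:3) {
    set.seed(s)
    perm <- sample(as.character(stages))
    sel <- select_ordering_genes(norm, perm, q_cut = 0.01)
    # FDR sanity: roughly no more selections than twice the nominal rate
    expect_lte(length(sel), 0.01 * nrow(norm) * 2)
  }
})

test_that("pseudotime recovers a noiseless 1-D gradient", {
  set.seed(5)
  grad <- seq(0, 1, length.out = 120)
  X <- rbind(3 * grad, 1 - grad, 2 * grad + 0.5, grad^1)
  X <- X + matrix(rnorm(length(X), sd = 1e-4), nrow = nrow(X))
  dimnames(X) <- list(sprintf("g%d", 1:4), sprintf("c%03d", 1:120))
  norm <- methods::as(X, "CsparseMatrix")
  traj <- fit_trajectory(norm, rownames(norm), n_nodes = 10, d = 2, seed = 1,
                         stages = factor(rep(c("A", "B"), each = 60),
                                         levels = c("A", "B"), ordered = TRUE))
  rho <- suppressWarnings(cor(traj$pseudotime, grad, method = "spearman"))
  expect_gte(abs(rho), 0.99)
  # root anchored at the earliest stage: pseudotime increases with the stage
  expect_lt(mean(traj$pseudotime[1:60]), mean(traj$pseudotime[61:120]))
  expect_gte(rho, 0.99)  # orientation follows the stage order, not chance
})

test_that("trajectory object satisfies its structural invariants", {
  sim <- shared_sim(1)
  ct <- sim$truth$cell_table
  th <- ct[ct$species == "human" & !ct$doublet & ct$true_type == "CMs", ]
  norm <- lognormalize(sim$human$counts[, th$cell_id])
  stages <- droplevels(sim$meta_h$stage[match(th$cell_id, sim$meta_h$cell_id)])
  ord <- select_ordering_genes(norm, stages, top_n = 500)
  traj <- fit_trajectory(norm, ord, seed = 2, stages = stages)
  expect_true(all(traj$pseudotime >= 0 & traj$pseudotime <= 1))
  # the MST is a spanning tree
  expect_equal(nrow(traj$edges), nrow(traj$nodes) - 1)
  # earliest-stage cells sit earlier than latest-stage cells
  expect_lt(mean(traj$pseudotime[stages == levels(stages)[1]]),
            mean(traj$pseudotime[stages == levels(stages)[nlevels(stages)]]))
  # pseudotime tracks the planted maturation
  mat <- ct$maturation[match(th$cell_id, ct$cell_id)]
  rho <- suppressWarnings(cor(traj$pseudotime, mat, method = "spearman"))
  expect_gte(abs(rho), 0.8)
})

test_that("pseudotime is stable under cell permutation", {
  sim <- shared_sim(1)
  ct <- sim$truth$cell_table
  th <- ct[ct$species == "human" & !ct$doublet & ct$true_type == "ECs", ]
  norm <- lognormalize(sim$human$counts[, th$cell_id])
  stages <- droplevels(sim$meta_h$stage[match(th$cell_id, sim$meta_h$cell_id)])
  ord <- select_ordering_genes(norm, stages, top_n = 300)
  t1 <- fit_trajectory(norm, ord, seed = 3, stages = stages)
  set.seed(99)
  perm <- sample(ncol(norm))
  t2 <- fit_trajectory(norm[, perm], ord, seed = 3, stages = stages[perm])
  rho <- suppressWarnings(cor(t1$pseudotime[perm], t2$pseudotime,
                              method = "spearman"))
  expect_gte(abs(rho), 0.99)
})

test_that("NB spline test flags planted dynamics and degenerate genes", {
  sim <- shared_sim(1)
  ct <- sim$truth$cell_table
  th <- ct[ct$species == "human" & !ct$doublet & ct$true_type == "CMs", ]
  cts <- sim$human$counts[, th$cell_id]
  mat <- ct$maturation[match(th$cell_id, ct$cell_id)]
  gt <- sim$truth$gene_table
  late <- head(gt$gene_id[gt$species == "human" & gt$archetype == "late"], 25)
  flat <- head(gt$gene_id[gt$species == "human" & gt$archetype == "flat" &
                            is.na(gt$marker_of)], 25)
  sub <- cts[c(late, flat), ]
  res <- test_pseudotime_dependence(sub, mat, lib_sizes = Matrix::colSums(cts))
  expect_true(all(res$lrt_stat >= 0))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_gte(mean(res$q_value[match(late, res$gene)] < 0.01), 0.8)

  # constant-zero gene gets p = 1 and a convergence flag
  z <- sub
  z[1, ] <- 0
  rownames(z)[1] <- "ZERO"
  r0 <- test_pseudotime_dependence(Matrix::drop0(z[1:3, ]), mat,
                                   lib_sizes = Matrix::colSums(cts))
  expect_equal(r0$p_value[r0$gene == "ZERO"], 1)
  expect_false(r0$converged[r0$gene == "ZERO"])
})

test_that("phase assignment maps archetypes to the expected tertiles", {
  set.seed(7)
  n <- 300
  pt <- runif(n)
  lib <- rep(1, n)
  early <- 5 * plogis(-(pt - 0.5) / 0.1)
  late <- 5 * plogis((pt - 0.5) / 0.1)
  bump <- 5 * exp(-(pt - 0.5)^2 / (2 * 0.1^2))
  X <- rbind(early, late, bump) + matrix(rnorm(3 * n, sd = 0.05), nrow = 3)
  X <- pmax(X, 0)
  dimnames(X) <- list(c("E", "L", "B"), sprintf("c%03d", 1:n))
  ph <- assign_trajectory_phases(methods::as(X, "CsparseMatrix"), pt,
                                 c("E", "L", "B"))
  expect_equal(unname(ph["E"]), "initial")
  expect_equal(unname(ph["L"]), "terminal")
  expect_equal(unname(ph["B"]), "transitional")
  # the partition covers every gene handed in
  expect_length(ph, 3)
})

test_that("subpopulation densities are normalized and ordered correctly", {
  pt <- c(rep(0.5, 100))
  d <- subpopulation_density(pt, rep("only", 100))
  expect_equal(d$grid[which.max(d$density[1, ])], 0.5, tolerance = 0.01)

  set.seed(8)
  pt2 <- c(rbeta(150, 2, 8), rbeta(150, 8, 2))  # early and late groups
  lab <- rep(c("early_pop", "late_pop"), each = 150)
  d2 <- subpopulation_density(pt2, lab)
  integrals <- apply(d2$density, 1, function(y)
    sum(diff(d2$grid) * (head(y, -1) + tail(y, -1)) / 2))
  expect_true(all(abs(integrals - 1) <= 0.01))
  expect_lt(d2$grid[which.max(d2$density["early_pop", ])],
            d2$grid[which.max(d2$density["late_pop", ])])

  # singleton groups fall back to the fixed minimum bandwidth
  d3 <- subpopulation_density(c(0.4, 0.9), c("a", "b"))
  expect_true(all(is.finite(d3$density)))
})
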