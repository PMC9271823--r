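# Shared fixtures and independent oracles for the suite. Simulations are
# cached per seed so several test files can reuse the same experiment.

.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function(seed = 1L) {
  key <- paste0("sim_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_two_species(sim_config(seed = seed))
  }
  .fixture_env[[key]]
}

# small random sparse count fixture
random_counts <- function(n_genes = 50, n_cells = 30, seed = 1,
                          mito_genes = 0) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda = 2), nrow = n_genes)
  rn <- sprintf("G%03d", seq_len(n_genes))
  if (mito_genes > 0) rn[seq_len(mito_genes)] <- sprintf("MT-%02d", seq_len(mito_genes))
  dimnames(m) <- list(rn, sprintf("c%03d", seq_len(n_cells)))
  methods::as(m, "CsparseMatrix")
}

# independent adjusted Rand index (mclust is the oracle when available)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# mean neighbor-batch entropy of an embedding (k nearest neighbors)
batch_mixing_entropy <- function(scores, batch, k = 20) {
  nn <- RANN::nn2(scores, k = k + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  batch <- as.character(batch)
  ent <- apply(idx, 1, function(r) {
    p <- table(batch[r]) / length(r)
    -sum(p * log(p))
  })
  mean(ent)
}

# exact two-sided rank-sum p-value by complete enumeration (tiny n)
exact_ranksum_p <- function(x, in_group) {
  n <- length(x)
  n1 <- sum(in_group)
  r <- rank(x)
  obs <- sum(r[in_group])
  combs <- utils::combn(n, n1)
  sums <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

isTRUE_v <- function(x) !is.na(x) & x

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multi-seed end-to-end runs shared by the acceptance checks: each seed
# simulates a fresh experiment and runs the pipeline through stage mapping
# (plus cross-species correlation and per-type trajectories for the first
# five seeds). Only small summaries are retained.
acceptance_cache <- function(n_seeds = 20) {
  if (!is.null(.fixture_env$acc)) return(.fixture_env$acc)
  runs <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    sim <- if (s == 1) shared_sim(1) else
      simulate_two_species(sim_config(seed = s))
    steps <- c("qc", "doublets", "sketch", "integrate", "cluster",
               "annotate", "stagemap")
    if (s <= 5) steps <- c(steps, "crossspecies")
    rep <- run_pipeline(sim, pipeline_config(seed = s, steps = steps))
    entry <- list(correspondence = as.data.frame(rep$correspondence),
                  truth = sim$truth$correspondence,
                  correlation = rep$correlation)
    if (s <= 5) {
      # module-level trajectory recovery on each planted type's cells
      ct <- sim$truth$cell_table
      rho <- list()
      for (ty in c("CMs", "FBs", "ECs")) {
        cells <- ct$cell_id[ct$species == "human" & !ct$doublet &
                              ct$true_type == ty]
        if (length(cells) < 50) next
        nrm <- lognormalize(sim$human$counts[, cells])
        stg <- droplevels(sim$meta_h$stage[match(cells, sim$meta_h$cell_id)])
        ord <- select_ordering_genes(nrm, stg, top_n = 500)
        traj <- fit_trajectory(nrm, ord, seed = s, stages = stg)
        matv <- ct$maturation[match(cells, ct$cell_id)]
        rho[[ty]] <- suppressWarnings(
          abs(cor(traj$pseudotime, matv, method = "spearman")))
        if (s == 1 && ty == "CMs") {
          entry$cm_cells <- cells
          entry$cm_pseudotime <- traj$pseudotime
        }
      }
      entry$pt_rho <- unlist(rho)
    }
    runs[[s]] <- entry
    rm(sim, rep); invisible(gc(verbose = FALSE))
  }
  .fixture_env$acc <- runs
  runs
}

# null two-group experiment: no type effects, no dynamic genes
null_sim <- function(seed = 77) {
  key <- paste0("null_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(seed = seed, n_genes = 3000, markers_per_type = 0,
                      n_dynamic_genes = 0, doublet_rate = 0,
                      human_stages = data.frame(label = c("5W", "9W"),
                                                maturation = c(0.2, 0.8),
                                                n_cells = 300,
                                                batch = "h_strt"),
                      mouse_stages = data.frame(label = c("e9.5", "e13.5"),
                                                maturation = c(0.3, 0.7),
                                                n_cells = 5,
                                                batch = "m_smartseq"))
    .fixture_env[[key]] <- simulate_two_species(cfg)
  }
  .fixture_env[[key]]
}

# brute-force hypergeometric upper tail by direct summation
hyper_upper_sum <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
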