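# Two-species generator: determinism, planted structure, truth tables.

test_that("config validation rejects impossible layouts", {
  expect_error(sim_config(n_genes = 10, n_types = 6, markers_per_type = 8),
               "exceeds n_genes")
  expect_error(sim_config(doublet_rate = 0.6), "implausible")
  bad <- data.frame(label = c("a", "b"), maturation = c(0.5, 0.4),
                    n_cells = 10, batch = "h_strt")
  expect_error(sim_config(human_stages = bad), "strictly increasing")
})

test_that("doublet_rate = 0 plants no doublets", {
  cfg <- sim_config(n_genes = 400, n_dynamic_genes = 30, doublet_rate = 0,
                    seed = 5,
                    human_stages = data.frame(label = c("5W", "9W"),
                                              maturation = c(0.2, 0.8),
                                              n_cells = 40, batch = "h_strt"),
                    mouse_stages = data.frame(label = c("e9.5", "e13.5"),
                                              maturation = c(0.3, 0.7),
                                              n_cells = 40,
                                              batch = "m_smartseq"))
  sim <- simulate_two_species(cfg)
  expect_equal(sum(sim$truth$cell_table$doublet), 0)
})

test_that("same config and seed give byte-identical outputs", {
  cfg <- sim_config(n_genes = 300, n_dynamic_genes = 30, seed = 11,
                    human_stages = data.frame(label = c("5W", "9W"),
                                              maturation = c(0.2, 0.8),
                                              n_cells = 30, batch = "h_strt"),
                    mouse_stages = data.frame(label = c("e9.5", "e13.5"),
                                              maturation = c(0.3, 0.7),
                                              n_cells = 30,
                                              batch = "m_smartseq"))
  a <- simulate_two_species(cfg)
  b <- simulate_two_species(cfg)
  expect_identical(a$human$counts, b$human$counts)
  expect_identical(a$mouse$counts, b$mouse$counts)
  expect_identical(a$truth, b$truth)
})

test_that("truth correspondence matches a brute-force nearest-maturation oracle", {
  # default calibration
  cfg <- sim_config()
  corr <- nearest_stage_correspondence(cfg$mouse_stages, cfg$human_stages)
  for (i in seq_len(nrow(cfg$mouse_stages))) {
    d <- abs(cfg$human_stages$maturation - cfg$mouse_stages$maturation[i])
    minimizers <- cfg$human_stages$label[d <= min(d) + 1e-12]
    expect_true(corr$human_stage[i] %in% minimizers)
    if (corr$tie[i]) {
      expect_setequal(c(corr$human_stage[i], corr$human_stage_alt[i]),
                      minimizers)
    } else {
      expect_equal(corr$human_stage[i], minimizers)
    }
  }
  # e10.5 at 0.60 is exactly equidistant from 9W and 13W
  r <- corr[corr$mouse_stage == "e10.5", ]
  expect_true(r$tie)
  expect_setequal(c(r$human_stage, r$human_stage_alt), c("9W", "13W"))

  # randomized stage tables against the same exhaustive rule
  set.seed(42)
  for (rep in 1:20) {
    hs <- data.frame(label = sprintf("h%d", 1:4),
                     maturation = sort(runif(4)), n_cells = 5,
                     batch = "h_strt")
    ms <- data.frame(label = sprintf("m%d", 1:3),
                     maturation = sort(runif(3)), n_cells = 5,
                     batch = "m_smartseq")
    corr <- nearest_stage_correspondence(ms, hs)
    for (i in 1:3) {
      d <- abs(hs$maturation - ms$maturation[i])
      expect_true(corr$human_stage[i] %in% hs$label[d <= min(d) + 1e-12])
    }
  }
})

test_that("planted doublet fraction is binomially consistent with the rate", {
  sim <- shared_sim(1)
  ct <- sim$truth$cell_table
  rate <- sim$config$doublet_rate
  n <- nrow(ct)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mean(ct$doublet) - rate), 3 * se)
})

test_that("detected genes per cell increase with platform depth", {
  base <- list(label = c("s1", "s2"), maturation = c(0.2, 0.8), n_cells = 50)
  mk <- function(depth) {
    plat <- list(h_strt = list(depth = 1, capture = 1),
                 m_smartseq = list(depth = depth, capture = 1))
    cfg <- sim_config(n_genes = 500, n_dynamic_genes = 30, seed = 9,
                      human_stages = data.frame(base, batch = "h_strt"),
                      mouse_stages = data.frame(base, batch = "m_smartseq"),
                      platform_params = plat)
    sim <- simulate_two_species(cfg)
    mean(compute_cell_qc(sim$mouse)$n_genes_detected)
  }
  expect_lt(mk(0.2), mk(2))
})

test_that("gene naming follows the cross-species symbol conventions", {
  sim <- shared_sim(1)
  gt <- sim$truth$gene_table
  orth <- sim$orthologs
  expect_true(all(orth$mouse == ifelse(startsWith(orth$human, "MT-"),
                                       orth$mouse,  # no mito orthologs planted
                                       paste0(toupper(substr(orth$human, 1, 1)),
                                              tolower(substr(orth$human, 2,
                                                             nchar(orth$human)))))))
  expect_true("TNNT2" %in% gt$gene_id[gt$species == "human"])
  expect_true("Tnnt2" %in% gt$gene_id[gt$species == "mouse"])
  expect_true(any(startsWith(gt$gene_id[gt$species == "human"], "MT-")))
  expect_true(any(startsWith(gt$gene_id[gt$species == "mouse"], "mt-")))
  # ortholog table size matches the truth table count
  n_truth <- sum(!is.na(gt$ortholog[gt$species == "human"]))
  expect_equal(nrow(orth), n_truth)
  expect_equal(nrow(orth), round(sim$config$frac_ortholog * sim$config$n_genes))
})

test_that("bundles round-trip through core_io and refuse silent overwrite", {
  cfg <- sim_config(n_genes = 300, n_dynamic_genes = 30, seed = 13,
                    human_stages = data.frame(label = c("5W", "9W"),
                                              maturation = c(0.2, 0.8),
                                              n_cells = 25, batch = "h_strt"),
                    mouse_stages = data.frame(label = c("e9.5", "e13.5"),
                                              maturation = c(0.3, 0.7),
                                              n_cells = 25,
                                              batch = "m_smartseq"))
  sim <- simulate_two_species(cfg)
  d <- withr::local_tempdir()
  out <- file.path(d, "bundle")
  write_bundle(sim, out)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_gte(length(manifest$files), 8)
  expect_equal(manifest$seed, 13)

  back <- read_bundle(out)
  expect_equal(as.matrix(back$human$counts), as.matrix(sim$human$counts))
  expect_equal(as.matrix(back$mouse$counts), as.matrix(sim$mouse$counts))
  expect_equal(nrow(back$orthologs), nrow(sim$orthologs))

  expect_error(write_bundle(sim, out), "force")
  expect_silent(write_bundle(sim, out, force = TRUE))
})
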