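## Two-species synthetic single-cell generator. Both species share a latent
## maturation axis expressed through orthologous gene programs; cell types
## carry conserved and species-specific marker programs; platforms differ in
## depth and capture efficiency; mitochondrial genes receive a fixed share of
## each cell's expected mass; a controlled fraction of cells are doublets.

# Fixed generator constants (the study conditions; not dials).
.SIM <- list(
  marker_effect = 2.0,     # natural-log effect of a marker in its own type
  arch_amplitude = 1.2,    # natural-log amplitude of dynamic archetypes
  logistic_scale = 0.15,   # steepness of the early/late logistic in maturation
  bump_sd = 0.12,          # sd of the mid-maturation Gaussian bump
  maturation_jitter = 0.02,# per-cell jitter around the stage maturation value
  libsize_sd = 0.25,       # log-normal cell-to-cell depth variation
  base_depth = 2e4,        # expected counts per cell at depth x capture = 1
  n_mito = 13              # mtDNA-sized mitochondrial gene set
)

.default_platforms <- function() {
  list(
    h_strt     = list(depth = 1.0, capture = 1.0),
    m_smartseq = list(depth = 2.0, capture = 1.0),
    m_droplet  = list(depth = 0.3, capture = 0.6)
  )
}

#' Configuration for the two-species simulator
#'
#' Defaults reproduce the study conditions exercised throughout the test
#' suite: 3,000 genes per species, 70% one-to-one orthologs, six cardiac cell
#' types (CMs dominant, a 2% rare immune type), five human stages sampling the
#' maturation axis at 0.1--0.9 and four mouse stages at 0.15/0.35/0.60/0.85,
#' a deep full-length platform for human, a deep plate platform plus a shallow
#' droplet platform for mouse, 10% mitochondrial mass and a 5% doublet rate.
#'
#' @param n_genes Genes per species.
#' @param frac_ortholog Fraction of genes forming one-to-one ortholog pairs.
#' @param n_types Number of cell types.
#' @param markers_per_type Planted marker genes per type (per species).
#' @param frac_specific_markers Fraction of each type's markers that are
#'   species-specific (the rest are conserved orthologs).
#' @param n_dynamic_genes Ortholog genes whose mean follows a maturation
#'   archetype (split equally early/mid/late).
#' @param human_stages,mouse_stages Data frames with columns `label`,
#'   `maturation` (strictly increasing within a species), `n_cells`, `batch`.
#' @param platform_params Named list (by batch) of `depth` multiplier and
#'   `capture` efficiency in (0, 1].
#' @param mito_frac_mean Expected mitochondrial fraction of each cell's mass.
#' @param doublet_rate Bernoulli doublet probability per cell.
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param type_names,type_props Cell-type names and proportions.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 3000,
                       frac_ortholog = 0.7,
                       n_types = 6,
                       markers_per_type = 8,
                       frac_specific_markers = 0.25,
                       n_dynamic_genes = 300,
                       human_stages = NULL,
                       mouse_stages = NULL,
                       platform_params = .default_platforms(),
                       mito_frac_mean = 0.10,
                       doublet_rate = 0.05,
                       dispersion = 0.3,
                       seed = 1L,
                       type_names = c("CMs", "FBs", "ECs", "EPs", "MACs", "MONOs"),
                       type_props = c(0.30, 0.25, 0.20, 0.13, 0.10, 0.02)) {
  if (is.null(human_stages)) {
    human_stages <- data.frame(
      label = c("5W", "7W", "9W", "13W", "25W"),
      maturation = c(0.1, 0.3, 0.5, 0.7, 0.9),
      n_cells = 400, batch = "h_strt", stringsAsFactors = FALSE)
  }
  if (is.null(mouse_stages)) {
    mouse_stages <- data.frame(
      label = c("e8.5", "e9.5", "e10.5", "e13.5"),
      maturation = c(0.15, 0.35, 0.60, 0.85),
      n_cells = 500,
      batch = c("m_smartseq", "m_smartseq", "m_smartseq", "m_droplet"),
      stringsAsFactors = FALSE)
  }
  cfg <- list(n_genes = n_genes, frac_ortholog = frac_ortholog,
              n_types = n_types, markers_per_type = markers_per_type,
              frac_specific_markers = frac_specific_markers,
              n_dynamic_genes = n_dynamic_genes,
              human_stages = human_stages, mouse_stages = mouse_stages,
              platform_params = platform_params,
              mito_frac_mean = mito_frac_mean, doublet_rate = doublet_rate,
              dispersion = dispersion, seed = as.integer(seed),
              type_names = type_names[seq_len(n_types)],
              type_props = type_props[seq_len(n_types)] /
                sum(type_props[seq_len(n_types)]))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_ortholog, cfg$frac_specific_markers, cfg$mito_frac_mean,
          cfg$doublet_rate)
  .assert(all(fr >= 0 & fr <= 1), "all fractions must lie in [0, 1]")
  .assert(cfg$dispersion > 0, "dispersion must be positive")
  .assert(cfg$doublet_rate < 0.5, "doublet_rate >= 0.5 is implausible")
  .assert(cfg$markers_per_type * cfg$n_types <= cfg$n_genes,
          "markers_per_type x n_types exceeds n_genes")
  for (st in list(cfg$human_stages, cfg$mouse_stages)) {
    .assert(all(diff(st$maturation) > 0),
            "stage maturation values must be strictly increasing")
    .assert(all(st$maturation >= 0 & st$maturation <= 1),
            "maturation values must lie in [0, 1]")
    .assert(all(st$n_cells >= 1), "every stage needs n_cells >= 1")
    .assert(all(st$batch %in% names(cfg$platform_params)),
            "stage batch without platform_params entry")
  }
  invisible(cfg)
}

.title_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

## mouse symbol of a human symbol (TNNT2 -> Tnnt2; MT-ND1 -> mt-Nd1)
.mouse_symbol <- function(x) {
  ifelse(startsWith(x, "MT-"),
         paste0("mt-", .title_case(substr(x, 4, nchar(x)))),
         .title_case(x))
}

.mito_names_human <- function(n) {
  base <- c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3", "ND3",
            "ND4L", "ND4", "ND5", "ND6", "CYB")
  paste0("MT-", base[seq_len(n)])
}

## archetype response at maturation m
.archetype_value <- function(arch, m) {
  A <- .SIM$arch_amplitude
  s <- .SIM$logistic_scale
  switch(arch,
         early = A * stats::plogis(-(m - 0.5) / s),
         late  = A * stats::plogis((m - 0.5) / s),
         mid   = A * exp(-(m - 0.5)^2 / (2 * .SIM$bump_sd^2)),
         flat  = rep(0, length(m)))
}

## Lay out the gene panel for both species. Markers and dynamic genes live
## among the ortholog pairs: conserved markers act in both species,
## species-specific markers are ortholog pairs whose marker effect acts in
## one species only (the gene exists in both genomes, as for CKMT2-like
## markers). Mitochondrial genes live among the non-ortholog genes.
.build_gene_tables <- function(cfg) {
  n_orth <- round(cfg$frac_ortholog * cfg$n_genes)
  n_spec_only <- cfg$n_genes - n_orth
  n_cons_mk <- round(cfg$markers_per_type * (1 - cfg$frac_specific_markers))
  n_spec_mk <- cfg$markers_per_type - n_cons_mk
  .assert((n_cons_mk + 2 * n_spec_mk) * cfg$n_types +
            cfg$n_dynamic_genes <= n_orth,
          "not enough ortholog genes for markers and dynamic genes")
  .assert(.SIM$n_mito <= n_spec_only,
          "not enough non-ortholog genes for the mitochondrial set")

  dict <- default_marker_dictionary()
  human_orth <- sprintf("GENE%04d", seq_len(n_orth))
  marker_h <- rep(NA_character_, n_orth)  # marker effect in human cells
  marker_m <- rep(NA_character_, n_orth)  # marker effect in mouse cells
  conserved <- rep(NA, n_orth)
  arch <- rep("flat", n_orth)
  idx <- 1
  if (n_cons_mk > 0) {
    # conserved markers take canonical cardiac symbols where the dictionary
    # provides them, so annotation machinery runs unchanged on synthetic data
    for (t in cfg$type_names) {
      nm <- c(dict[[t]] %||% character(0),
              sprintf("%s.MK%d", toupper(sub("/", ".", t)), seq_len(n_cons_mk)))
      rows <- idx:(idx + n_cons_mk - 1)
      human_orth[rows] <- nm[seq_len(n_cons_mk)]
      marker_h[rows] <- marker_m[rows] <- t
      conserved[rows] <- TRUE
      idx <- idx + n_cons_mk
    }
  }
  if (n_spec_mk > 0) {
    for (t in cfg$type_names) {  # human-only marker effect
      rows <- idx:(idx + n_spec_mk - 1)
      human_orth[rows] <- sprintf("HS.%s.SP%d", toupper(sub("/", ".", t)),
                                  seq_len(n_spec_mk))
      marker_h[rows] <- t
      conserved[rows] <- FALSE
      idx <- idx + n_spec_mk
    }
    for (t in cfg$type_names) {  # mouse-only marker effect
      rows <- idx:(idx + n_spec_mk - 1)
      human_orth[rows] <- sprintf("MS.%s.SP%d", toupper(sub("/", ".", t)),
                                  seq_len(n_spec_mk))
      marker_m[rows] <- t
      conserved[rows] <- FALSE
      idx <- idx + n_spec_mk
    }
  }
  if (cfg$n_dynamic_genes > 0) {
    dyn_idx <- idx:(idx + cfg$n_dynamic_genes - 1)
    arch[dyn_idx] <- rep(c("early", "mid", "late"),
                         length.out = cfg$n_dynamic_genes)
  }
  mouse_orth <- .mouse_symbol(human_orth)

  mito_h <- .mito_names_human(.SIM$n_mito)
  mito_m <- .mouse_symbol(mito_h)
  n_fill <- n_spec_only - .SIM$n_mito
  fill_h <- sprintf("HGENE%04d", seq_len(n_fill))
  fill_m <- sprintf("Mgene%04d", seq_len(n_fill))

  gt_h <- data.frame(
    gene_id = c(human_orth, mito_h, fill_h),
    species = "human",
    ortholog = c(mouse_orth, rep(NA_character_, n_spec_only)),
    marker_of = c(marker_h, rep(NA_character_, n_spec_only)),
    conserved = c(conserved, rep(NA, n_spec_only)),
    archetype = c(arch, rep("flat", n_spec_only)),
    mito = c(rep(FALSE, n_orth), rep(TRUE, .SIM$n_mito),
             rep(FALSE, n_fill)),
    stringsAsFactors = FALSE)
  gt_m <- gt_h
  gt_m$gene_id <- c(mouse_orth, mito_m, fill_m)
  gt_m$species <- "mouse"
  gt_m$ortholog <- c(human_orth, rep(NA_character_, n_spec_only))
  gt_m$marker_of <- c(marker_m, rep(NA_character_, n_spec_only))
  list(human = gt_h, mouse = gt_m,
       orthologs = data.frame(human = human_orth, mouse = mouse_orth,
                              stringsAsFactors = FALSE))
}

## simulate one species given its gene table and shared baselines
.simulate_species <- function(cfg, gt, base, stages, species) {
  n_cells <- sum(stages$n_cells)
  stage_of <- rep(stages$label, stages$n_cells)
  batch_of <- rep(stages$batch, stages$n_cells)
  m_nom <- rep(stages$maturation, stages$n_cells)
  m <- pmin(pmax(m_nom + rnorm(n_cells, 0, .SIM$maturation_jitter), 0), 1)
  type_of <- sample(cfg$type_names, n_cells, replace = TRUE,
                    prob = cfg$type_props)

  n_genes <- nrow(gt)
  # log-weight = baseline + marker effect + archetype(maturation)
  W <- matrix(rep(base, n_cells), nrow = n_genes)
  is_marker <- !is.na(gt$marker_of)
  if (any(is_marker)) {
    mk_rows <- which(is_marker)
    eff <- outer(gt$marker_of[mk_rows], type_of, "==") * .SIM$marker_effect
    W[mk_rows, ] <- W[mk_rows, ] + eff
  }
  for (a in c("early", "mid", "late")) {
    rows <- which(gt$archetype == a)
    if (length(rows)) {
      W[rows, ] <- W[rows, ] +
        matrix(rep(.archetype_value(a, m), each = length(rows)),
               nrow = length(rows))
    }
  }
  W <- exp(W)
  # mitochondrial genes receive mito_frac_mean of each cell's expected mass
  mito <- gt$mito
  if (any(mito) && cfg$mito_frac_mean > 0) {
    ratio <- cfg$mito_frac_mean / (1 - cfg$mito_frac_mean)
    s <- ratio * colSums(W[!mito, , drop = FALSE]) /
      colSums(W[mito, , drop = FALSE])
    W[mito, ] <- sweep(W[mito, , drop = FALSE], 2, s, "*")
  }
  plat <- cfg$platform_params
  depth <- vapply(batch_of, function(b) plat[[b]]$depth * plat[[b]]$capture,
                  numeric(1))
  total <- .SIM$base_depth * depth * exp(rnorm(n_cells, 0, .SIM$libsize_sd))
  mu <- sweep(W, 2, total / colSums(W), "*")
  counts <- matrix(rnbinom(length(mu), size = 1 / cfg$dispersion, mu = mu),
                   nrow = n_genes)

  # doublets: the cell's own profile plus a randomly chosen same-species cell
  dbl <- as.logical(rbinom(n_cells, 1, cfg$doublet_rate))
  if (any(dbl) && n_cells > 1) {
    di <- which(dbl)
    partner <- vapply(di, function(i) sample(seq_len(n_cells)[-i], 1), integer(1))
    counts[, di] <- counts[, di, drop = FALSE] + counts[, partner, drop = FALSE]
  }
  cell_ids <- sprintf("%s_c%04d", species, seq_len(n_cells))
  dimnames(counts) <- list(gt$gene_id, cell_ids)
  meta <- data.frame(cell_id = cell_ids, species = species, stage = stage_of,
                     batch = batch_of,
                     platform = sub("^[hm]_", "", batch_of),
                     stringsAsFactors = FALSE)
  truth <- data.frame(cell_id = cell_ids, species = species, stage = stage_of,
                      maturation = m, true_type = type_of, doublet = dbl,
                      batch = batch_of, stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, truth = truth)
}

#' Nearest-maturation stage correspondence
#'
#' Pairs every mouse stage with the human stage of minimal absolute
#' maturation difference. Exact ties resolve to the later human stage: under
#' saturating (logistic) expression dynamics the expression-space image of a
#' maturation midpoint lies closer to the later stage, so the later call is
#' the one an expression-based mapping identifies.
#'
#' When a mouse stage is exactly equidistant from two human stages, both are
#' minimizers of the maturation distance: `human_stage` records the later one
#' (under saturating logistic dynamics the expression image of the midpoint
#' lies closer to the later stage) and `human_stage_alt` the other minimizer;
#' `tie` flags such rows. For untied stages `human_stage_alt` is `NA`.
#'
#' @param mouse_stages,human_stages Stage tables as in [sim_config()].
#' @return Data frame with columns `mouse_stage`, `human_stage`,
#'   `human_stage_alt`, `tie`.
#' @export
nearest_stage_correspondence <- function(mouse_stages, human_stages) {
  rows <- lapply(seq_len(nrow(mouse_stages)), function(i) {
    d <- abs(human_stages$maturation - mouse_stages$maturation[i])
    ties <- which(d <= min(d) + 1e-12)
    data.frame(mouse_stage = mouse_stages$label[i],
               human_stage = human_stages$label[max(ties)],
               human_stage_alt = if (length(ties) > 1)
                 human_stages$label[min(ties)] else NA_character_,
               tie = length(ties) > 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a two-species single-cell experiment
#'
#' Counts are negative binomial with mean depth x capture x exp(type effect +
#' archetype(maturation) + gene baseline). Orthologous genes share baselines,
#' type effects and archetype curves across species; species-specific markers
#' act in one species only. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `human`, `mouse` (ExpressionMatrix), `meta_h`,
#'   `meta_m` (cell metadata), `orthologs` (one-to-one pair table) and
#'   `truth` (list: `cell_table`, `gene_table`, `correspondence`).
#' @export
simulate_two_species <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  gt <- .build_gene_tables(config)
  n_orth <- nrow(gt$orthologs)
  # shared baselines for ortholog pairs; independent draws for the rest
  base_orth <- rnorm(n_orth, 0, 1)
  base_h <- c(base_orth, rnorm(config$n_genes - n_orth, 0, 1))
  base_m <- c(base_orth, rnorm(config$n_genes - n_orth, 0, 1))

  sim_h <- .simulate_species(config, gt$human, base_h, config$human_stages, "human")
  sim_m <- .simulate_species(config, gt$mouse, base_m, config$mouse_stages, "mouse")

  em_h <- expression_matrix(sim_h$counts, "human")
  em_m <- expression_matrix(sim_m$counts, "mouse")
  meta_h <- cell_meta(sim_h$meta, config$human_stages$label)
  meta_m <- cell_meta(sim_m$meta, config$mouse_stages$label)
  truth <- list(
    cell_table = rbind(sim_h$truth, sim_m$truth),
    gene_table = rbind(gt$human, gt$mouse),
    correspondence = nearest_stage_correspondence(config$mouse_stages,
                                                  config$human_stages))
  list(human = em_h, mouse = em_m, meta_h = meta_h, meta_m = meta_m,
       orthologs = gt$orthologs, truth = truth, config = config)
}

#' Write a simulated experiment as an on-disk bundle
#'
#' Produces, per species, a Matrix Market counts file with `genes.tsv`,
#' `barcodes.tsv`, `cells.tsv` and `stage_order.txt` sidecars, plus
#' `orthologs.tsv`, truth tables and a `manifest.json` recording the files
#' and the seed.
#'
#' @param sim Result of [simulate_two_species()].
#' @param directory Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return The directory, invisibly.
#' @export
write_bundle <- function(sim, directory, force = FALSE) {
  if (dir.exists(directory) && length(list.files(directory)) > 0 && !force) {
    stop("directory ", directory, " is not empty; use force = TRUE", call. = FALSE)
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$human, sim$meta_h, file.path(directory, "human"))
  write_counts(sim$mouse, sim$meta_m, file.path(directory, "mouse"))
  utils::write.table(sim$orthologs, file.path(directory, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(sim$truth$cell_table,
                     file.path(directory, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$gene_table,
                     file.path(directory, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$correspondence,
                     file.path(directory, "truth_correspondence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- list.files(directory, recursive = TRUE)
  manifest <- list(seed = sim$config$seed,
                   n_genes = sim$config$n_genes,
                   n_cells_human = ncol(sim$human$counts),
                   n_cells_mouse = ncol(sim$mouse$counts),
                   files = files)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(directory)
}
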