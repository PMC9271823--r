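## Config-driven orchestration of the full two-species pipeline.

#' Pipeline configuration
#'
#' Parameter blocks for every stage, with defaults matched to the synthetic
#' data scale. For real datasets pass [qc_preset()] thresholds per species.
#'
#' @param seed Global seed; per-stage seeds are derived from it with
#'   [derive_seed()] so stages are independently reproducible.
#' @param qc_human,qc_mouse [qc_thresholds()] per species.
#' @param doublet_rate Expected doublet rate for [detect_doublets()].
#' @param scale_factor,hvg_n,pcs Normalization and embedding parameters.
#' @param sketch_balance Sketch any batch larger than `sketch_ratio` times
#'   the smallest batch down to the smallest batch's size.
#' @param sketch_ratio Imbalance ratio that triggers sketching.
#' @param align_clusters,align_iter,align_dims Batch-alignment parameters.
#' @param knn,resolution Clustering parameters.
#' @param dict,composites,delta Annotation parameters.
#' @param min_pct,min_logfc Marker-detection parameters.
#' @param cell_type Cell type used for trajectory and stage mapping.
#' @param core_min_fraction Core-gene detection floor for the stage axis.
#' @param traj_nodes,traj_dims Trajectory parameters.
#' @param gmt Optional gene-set collection for enrichment.
#' @param steps Stages to execute, in pipeline order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            qc_human = qc_thresholds(200, 500, 0.30),
                            qc_mouse = qc_thresholds(200, 500, 0.30),
                            doublet_rate = 0.075,
                            scale_factor = 1e4, hvg_n = 2000, pcs = 20,
                            sketch_balance = TRUE, sketch_ratio = 2,
                            align_clusters = 50, align_iter = 100,
                            align_dims = 20,
                            knn = 20, resolution = 1.0,
                            dict = default_marker_dictionary(),
                            composites = default_composites(), delta = 0.25,
                            min_pct = 0.1, min_logfc = 0.25,
                            cell_type = "CMs", core_min_fraction = 0.75,
                            traj_nodes = 15, traj_dims = 2,
                            gmt = NULL,
                            steps = c("qc", "doublets", "sketch", "integrate",
                                      "cluster", "annotate", "markers",
                                      "crossspecies", "trajectory",
                                      "stagemap", "enrich")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a simulated (or compatible) two-species bundle
#'
#' @param directory Directory written by [write_bundle()], containing
#'   `human/`, `mouse/` and `orthologs.tsv`.
#' @return List with `human`, `mouse` (ExpressionMatrix), `meta_h`,
#'   `meta_m`, `orthologs`.
#' @export
read_bundle <- function(directory) {
  .assert(file.exists(file.path(directory, "orthologs.tsv")),
          "missing ortholog table: %s",
          file.path(directory, "orthologs.tsv"))
  h <- read_counts(file.path(directory, "human"), species = "human")
  m <- read_counts(file.path(directory, "mouse"), species = "mouse")
  list(human = h$matrix, mouse = m$matrix, meta_h = h$meta, meta_m = m$meta,
       orthologs = read_ortholog_table(file.path(directory, "orthologs.tsv")))
}

.stage_guard <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

## per-species single-platform processing: qc -> doublets -> embedding
.process_species <- function(em, meta, cfg, thr, label) {
  report <- list(n_raw = ncol(em$counts))
  qc <- compute_cell_qc(em)
  filt <- if ("qc" %in% cfg$steps) filter_cells(em, qc, thr) else em
  meta <- meta[match(colnames(filt$counts), meta$cell_id), ]
  report$n_post_qc <- ncol(filt$counts)
  if ("doublets" %in% cfg$steps && cfg$doublet_rate > 0) {
    keep_cells <- character(0)
    for (b in unique(meta$batch)) {  # doublets are a within-dataset artifact
      cells_b <- meta$cell_id[meta$batch == b]
      sub <- filt$counts[, cells_b, drop = FALSE]
      calls <- detect_doublets(sub, expected_rate = cfg$doublet_rate,
                               seed = derive_seed(cfg$seed,
                                                  paste0("doublets_", label, b)))
      keep_cells <- c(keep_cells, calls$cell_id[!calls$is_doublet])
    }
    filt <- expression_matrix(filt$counts[, keep_cells, drop = FALSE],
                              filt$species)
    meta <- meta[match(colnames(filt$counts), meta$cell_id), ]
  }
  report$n_post_doublet <- ncol(filt$counts)
  list(matrix = filt, meta = meta, qc = qc, report = report)
}

#' Run the full cross-species pipeline
#'
#' Executes, in order: QC filtering, doublet removal, platform balancing by
#' geometric sketching, normalization + HVG + PCA with batch alignment for
#' multi-batch species, graph clustering, marker-dictionary annotation,
#' marker detection, ortholog-based cross-species correlation and
#' conservation calls, pseudotime trajectory with phase assignment for the
#' configured cell type, the PC1 stage-similarity map, and enrichment.
#' Stage seeds derive deterministically from the global seed. Any stage
#' error aborts with the stage name.
#'
#' @param data List with `human`, `mouse` (ExpressionMatrix), `meta_h`,
#'   `meta_m`, `orthologs` — e.g. from [simulate_two_species()] or
#'   [read_bundle()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for `report.json` and stage TSVs.
#' @return A run report list; key elements: `cells` (counts per filter),
#'   `annotation` (per-cluster types per species), `correlation` (type
#'   Pearson matrix), `correspondence` (stage mapping table), `markers`,
#'   `conservation`, `trajectory`, `enrichment`, `seeds`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  steps <- cfg$steps
  report <- list(seeds = list(global = cfg$seed))
  t0 <- Sys.time()

  h <- .stage_guard("qc", .process_species(data$human, data$meta_h, cfg,
                                           cfg$qc_human, "h"))
  m <- .stage_guard("qc", .process_species(data$mouse, data$meta_m, cfg,
                                           cfg$qc_mouse, "m"))
  report$cells <- list(human = h$report, mouse = m$report)

  ## platform balancing: sketch oversized batches down to the smallest batch
  if ("sketch" %in% steps && cfg$sketch_balance &&
      length(unique(m$meta$batch)) > 1) {
    m <- .stage_guard("sketch", {
      sizes <- table(m$meta$batch)
      target <- min(sizes)
      keep <- character(0)
      for (b in names(sizes)) {
        cells_b <- m$meta$cell_id[m$meta$batch == b]
        if (sizes[[b]] > cfg$sketch_ratio * target) {
          sub <- m$matrix$counts[, cells_b, drop = FALSE]
          norm_b <- lognormalize(sub, cfg$scale_factor)
          hvg_b <- select_hvg(norm_b, min(cfg$hvg_n, nrow(norm_b)))
          emb_b <- run_pca(norm_b, hvg_b, d = min(cfg$pcs, length(hvg_b)),
                           seed = derive_seed(cfg$seed, paste0("sketch_", b)))
          idx <- geometric_sketch(emb_b, target,
                                  seed = derive_seed(cfg$seed,
                                                     paste0("sketchpick_", b)))
          cells_b <- cells_b[idx]
        }
        keep <- c(keep, cells_b)
      }
      keep <- m$meta$cell_id[m$meta$cell_id %in% keep]
      mat <- expression_matrix(m$matrix$counts[, keep, drop = FALSE], "mouse")
      list(matrix = mat, meta = m$meta[match(keep, m$meta$cell_id), ],
           qc = m$qc, report = c(m$report, list(n_post_sketch = length(keep))))
    })
    report$cells$mouse <- m$report
  }

  ## normalization and embeddings
  norm_h <- norm_m <- emb_h <- emb_m <- NULL
  if ("integrate" %in% steps) {
    .stage_guard("integrate", {
      norm_h <- lognormalize(h$matrix, cfg$scale_factor)
      hvg_h <- select_hvg(norm_h, min(cfg$hvg_n, nrow(norm_h)))
      emb_h <- run_pca(norm_h, hvg_h, d = cfg$pcs,
                        seed = derive_seed(cfg$seed, "pca_h"))
      norm_m <- lognormalize(m$matrix, cfg$scale_factor)
      hvg_m <- select_hvg(norm_m, min(cfg$hvg_n, nrow(norm_m)))
      emb_m <- run_pca(norm_m, hvg_m, d = cfg$pcs,
                        seed = derive_seed(cfg$seed, "pca_m"))
      if (length(unique(m$meta$batch)) > 1) {
        emb_m <- align_batches(emb_m, m$meta$batch,
                                n_clusters = cfg$align_clusters,
                                max_iter = cfg$align_iter,
                                d_out = min(cfg$align_dims, cfg$pcs),
                                seed = derive_seed(cfg$seed, "align_m"))
      }
      NULL
    })
  }

  ## clustering and annotation
  types_h <- types_m <- NULL
  if ("cluster" %in% steps) {
    .stage_guard("cluster", {
      gh <- build_knn_graph(emb_h, k = cfg$knn)
      labels_h <- cluster_graph(gh, cfg$resolution,
                                seed = derive_seed(cfg$seed, "louvain_h"))
      gm <- build_knn_graph(emb_m, k = cfg$knn)
      labels_m <- cluster_graph(gm, cfg$resolution,
                                seed = derive_seed(cfg$seed, "louvain_m"))
      h$clusters <- labels_h
      m$clusters <- labels_m
      NULL
    })
    report$n_clusters <- list(human = length(unique(h$clusters)),
                              mouse = length(unique(m$clusters)))
  }
  if ("annotate" %in% steps) {
    .stage_guard("annotate", {
      ann_h <- annotate_clusters(norm_h, h$clusters, cfg$dict,
                                 cfg$composites, cfg$delta)
      ann_m <- annotate_clusters(norm_m, m$clusters,
                                 mouse_symbols(cfg$dict),
                                 cfg$composites, cfg$delta)
      types_h <- unname(ann_h[as.character(h$clusters)])
      types_m <- unname(ann_m[as.character(m$clusters)])
      report$annotation <- list(human = as.list(ann_h),
                                 mouse = as.list(ann_m))
      report$cell_assignments <- list(
        human = data.frame(cell_id = colnames(h$matrix$counts),
                           cluster = unname(h$clusters), type = types_h,
                           stringsAsFactors = FALSE),
        mouse = data.frame(cell_id = colnames(m$matrix$counts),
                           cluster = unname(m$clusters), type = types_m,
                           stringsAsFactors = FALSE))
      NULL
    })
  }

  markers_h <- markers_m <- NULL
  if ("markers" %in% steps && !is.null(types_h)) {
    .stage_guard("markers", {
      markers_h <- find_markers(norm_h, types_h, cfg$min_pct, cfg$min_logfc)
      markers_m <- find_markers(norm_m, types_m, cfg$min_pct, cfg$min_logfc)
      NULL
    })
    report$markers <- list(human = markers_h, mouse = markers_m)
  }

  if ("crossspecies" %in% steps && !is.null(types_h)) {
    .stage_guard("crossspecies", {
      orth <- collapse_to_orthologs(norm_h, norm_m, data$orthologs)
      prof_h <- type_profiles(orth$human, types_h)
      prof_m <- type_profiles(orth$mouse, types_m)
      report$correlation <- correlate_types(prof_h, prof_m)
      if (!is.null(markers_h)) {
        report$conservation <- classify_marker_conservation(
          markers_h, markers_m, data$orthologs,
          detection_by_type(h$matrix, types_h),
          detection_by_type(m$matrix, types_m))
      }
      NULL
    })
  }

  if ("trajectory" %in% steps && !is.null(types_h)) {
    .stage_guard("trajectory", {
      sel <- types_h == cfg$cell_type
      .assert(sum(sel) >= 50, "fewer than 50 '%s' cells in human",
              cfg$cell_type)
      cts <- h$matrix$counts[, sel, drop = FALSE]
      nrm <- norm_h[, sel, drop = FALSE]
      stg <- h$meta$stage[sel]
      keep_genes <- filter_trajectory_genes(cts)
      ord_genes <- select_ordering_genes(nrm[keep_genes, , drop = FALSE], stg)
      traj <- fit_trajectory(nrm, ord_genes, n_nodes = cfg$traj_nodes,
                             d = cfg$traj_dims,
                             seed = derive_seed(cfg$seed, "trajectory"),
                             stages = stg)
      de <- test_pseudotime_dependence(cts[ord_genes, , drop = FALSE],
                                       traj$pseudotime,
                                       lib_sizes = Matrix::colSums(cts))
      sig <- de$gene[de$q_value < 0.01]
      phases <- if (length(sig)) {
        assign_trajectory_phases(nrm, traj$pseudotime, sig)
      } else character(0)
      report$trajectory <- list(pseudotime = traj$pseudotime,
                                 de = de, phases = phases,
                                 stages = as.character(stg))
      NULL
    })
  }

  if ("stagemap" %in% steps && !is.null(types_h)) {
    .stage_guard("stagemap", {
      sel_h <- types_h == cfg$cell_type
      sel_m <- types_m == cfg$cell_type
      .assert(sum(sel_h) >= 25 && sum(sel_m) >= 25,
              "cell type '%s' too small in one species", cfg$cell_type)
      core <- select_core_genes(h$matrix$counts[, sel_h, drop = FALSE],
                                cfg$core_min_fraction)
      model <- fit_stage_axis(norm_h[, sel_h, drop = FALSE],
                              droplevels(h$meta$stage[sel_h]), core,
                              seed = derive_seed(cfg$seed, "stageaxis"))
      pc1_m <- project_other_species(model, norm_m[, sel_m, drop = FALSE],
                                     data$orthologs)
      corr <- map_stages(model, pc1_m,
                         as.character(m$meta$stage[sel_m]))
      report$stage_model <- model
      report$correspondence <- corr
      NULL
    })
  }

  if ("enrich" %in% steps && !is.null(cfg$gmt) && !is.null(markers_h)) {
    .stage_guard("enrich", {
      query <- build_deg_query(markers_h, cfg$cell_type)
      report$enrichment <- run_ora(query, rownames(norm_h), cfg$gmt)
      NULL
    })
  }

  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(cells = report$cells, n_clusters = report$n_clusters,
             annotation = report$annotation, seeds = report$seeds)
  if (!is.null(report$correspondence)) {
    js$correspondence <- as.data.frame(report$correspondence)
    utils::write.table(report$correspondence,
                       file.path(out_dir, "correspondence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$correlation)) {
    utils::write.table(report$correlation,
                       file.path(out_dir, "correlation.tsv"),
                       sep = "\t", quote = FALSE)
  }
  for (sp in c("human", "mouse")) {
    mk <- report$markers[[sp]]
    if (!is.null(mk)) {
      utils::write.table(mk, file.path(out_dir, paste0("markers_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
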