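## Per-cell quality metrics, species-specific filter presets, and an
## artificial-nearest-neighbor (pANN) doublet detector.

#' Quality-control thresholds
#'
#' @param min_genes Minimum detected genes (count > 0) per cell.
#' @param min_transcripts Minimum total counts per cell. For full-length
#'   (read-count) chemistries this is a read threshold; column sums are used
#'   uniformly for UMI and read counts.
#' @param max_mito_frac Maximum mitochondrial fraction.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes
#'   (matched case-insensitively, so "MT-" covers mouse "mt-" symbols).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 0, min_transcripts = 0,
                          max_mito_frac = 1, mito_prefix = "MT-") {
  .assert(min_genes >= 0, "min_genes must be >= 0")
  .assert(max_mito_frac >= 0 && max_mito_frac <= 1,
          "max_mito_frac must lie in [0, 1]")
  structure(list(min_genes = min_genes, min_transcripts = min_transcripts,
                 max_mito_frac = max_mito_frac, mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Species/platform QC presets
#'
#' `human`: at least 1,000 detected genes and 5,000 transcripts.
#' `mouse_smartseq`: more than 1,800 detected genes (encoded as >= 1,801) and
#' at least 1e6 transcripts, the full-length read-count regime.
#' `mouse_droplet`: the droplet dataset is filtered with the human-style
#' thresholds, since read-count thresholds are not attainable for shallow
#' droplet libraries. All presets cap the mitochondrial fraction at 30%,
#' reflecting the high mitochondrial content of cardiomyocytes.
#'
#' @param name One of `"human"`, `"mouse_smartseq"`, `"mouse_droplet"`.
#' @return A [qc_thresholds()] object.
#' @export
qc_preset <- function(name = c("human", "mouse_smartseq", "mouse_droplet")) {
  switch(match.arg(name),
         human = qc_thresholds(1000, 5000, 0.30),
         mouse_smartseq = qc_thresholds(1801, 1e6, 0.30),
         mouse_droplet = qc_thresholds(1000, 5000, 0.30))
}

#' Compute per-cell QC metrics
#'
#' @param matrix ExpressionMatrix or sparse gene x cell counts.
#' @param mito_prefix Prefix identifying mitochondrial genes
#'   (case-insensitive).
#' @return Data frame: `cell_id`, `n_genes_detected`, `n_transcripts`,
#'   `mito_frac`, `degenerate` (zero-total cells, which get `mito_frac` 0).
#' @export
compute_cell_qc <- function(matrix, mito_prefix = "MT-") {
  counts <- .counts(matrix)
  totals <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mito <- startsWith(tolower(rownames(counts)), tolower(mito_prefix))
  mito_tot <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else
    rep(0, ncol(counts))
  mito_frac <- ifelse(totals > 0, mito_tot / totals, 0)
  data.frame(cell_id = colnames(counts),
             n_genes_detected = as.integer(ngene),
             n_transcripts = totals,
             mito_frac = mito_frac,
             degenerate = totals == 0,
             stringsAsFactors = FALSE)
}

#' Filter cells on QC metrics
#'
#' Keeps exactly the cells with `n_genes_detected >= min_genes` and
#' `n_transcripts >= min_transcripts` and `mito_frac <= max_mito_frac`.
#' Cell order and the gene set are unchanged.
#'
#' @param matrix ExpressionMatrix or sparse counts.
#' @param qc Table from [compute_cell_qc()] covering all cells.
#' @param thr A [qc_thresholds()] object.
#' @return The filtered matrix (same class as the input container).
#' @export
filter_cells <- function(matrix, qc, thr) {
  counts <- .counts(matrix)
  .assert(all(colnames(counts) %in% qc$cell_id),
          "qc table does not cover all cells")
  qc <- qc[match(colnames(counts), qc$cell_id), ]
  keep <- qc$n_genes_detected >= thr$min_genes &
    qc$n_transcripts >= thr$min_transcripts &
    qc$mito_frac <= thr$max_mito_frac
  if (!any(keep)) {
    stop("all cells removed by QC thresholds; review min_genes/",
         "min_transcripts/max_mito_frac", call. = FALSE)
  }
  out <- counts[, keep, drop = FALSE]
  if (is(matrix, "ExpressionMatrix")) {
    expression_matrix(out, matrix$species)
  } else out
}

#' Artificial-nearest-neighbor doublet detection
#'
#' Simplified pANN scheme: artificial doublets are averages of random cell
#' pairs; real and artificial cells are jointly embedded by PCA of
#' log-normalized highly variable genes; each real cell is scored by the
#' fraction of artificial points among its k nearest neighbors; the top
#' `round(expected_rate * n_cells)` scores are flagged.
#'
#' @param matrix ExpressionMatrix or sparse counts.
#' @param n_artificial Number of artificial doublets (default 25% of cells).
#' @param k_neighbors Neighborhood size.
#' @param expected_rate Expected doublet fraction; must be < 0.5.
#' @param seed Integer seed (pair sampling and PCA are randomized).
#' @param n_hvg,d Highly variable genes and PCA dimensions of the joint
#'   embedding.
#' @return Data frame: `cell_id`, `pann_score`, `is_doublet`.
#' @export
detect_doublets <- function(matrix, n_artificial = NULL, k_neighbors = 20,
                            expected_rate = 0.075, seed = 1L,
                            n_hvg = 1000, d = 20) {
  counts <- .counts(matrix)
  n <- ncol(counts)
  .assert(expected_rate < 0.5, "expected_rate >= 0.5 is implausible")
  .assert(n >= k_neighbors + 1, "need at least k_neighbors + 1 cells")
  n_flag <- round(expected_rate * n)
  if (n_flag == 0) {
    return(data.frame(cell_id = colnames(counts), pann_score = 0,
                      is_doublet = FALSE, stringsAsFactors = FALSE))
  }
  n_artificial <- n_artificial %||% max(2L, round(0.25 * n))
  set.seed(seed)
  i <- sample.int(n, n_artificial, replace = TRUE)
  j <- sample.int(n, n_artificial, replace = TRUE)
  same <- which(i == j)
  if (length(same)) j[same] <- (j[same] %% n) + 1L
  art <- (counts[, i, drop = FALSE] + counts[, j, drop = FALSE]) / 2
  colnames(art) <- sprintf("ARTIFICIAL_%d", seq_len(n_artificial))
  joint <- cbind(counts, art)
  norm <- lognormalize(joint)
  hvg <- select_hvg(norm, n = min(n_hvg, nrow(norm)))
  emb <- run_pca(norm, hvg, d = min(d, length(hvg), ncol(joint) - 1),
                 seed = seed)
  nn <- RANN::nn2(emb$scores, query = emb$scores[seq_len(n), , drop = FALSE],
                  k = k_neighbors + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]  # drop self
  pann <- rowMeans(idx > n)
  ord <- order(pann, decreasing = TRUE)
  flag <- logical(n)
  flag[ord[seq_len(min(n_flag, n))]] <- TRUE
  data.frame(cell_id = colnames(counts), pann_score = pann,
             is_doublet = flag, stringsAsFactors = FALSE)
}
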