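## Ortholog-restricted pseudobulk profiles, human x mouse cell-type Pearson
## correlation, and shared/species-specific marker classification.

#' Restrict two matrices to their shared one-to-one ortholog pairs
#'
#' Both matrices are subset to the ortholog pairs whose genes are present in
#' both datasets, with rows aligned in identical pair order and indexed by
#' the human symbol.
#'
#' @param norm_h,norm_m Human and mouse gene x cell matrices.
#' @param map Ortholog table from [read_ortholog_table()] (columns `human`,
#'   `mouse`), injective in both columns.
#' @return List: `human`, `mouse` (row-aligned matrices), `pairs` (the
#'   retained pair table).
#' @export
collapse_to_orthologs <- function(norm_h, norm_m, map) {
  .assert(!anyDuplicated(map$human) && !anyDuplicated(map$mouse),
          "ortholog map must be one-to-one")
  keep <- map$human %in% rownames(norm_h) & map$mouse %in% rownames(norm_m)
  .assert(any(keep), "no ortholog pair present in both matrices")
  pairs <- map[keep, , drop = FALSE]
  h <- norm_h[pairs$human, , drop = FALSE]
  m <- norm_m[pairs$mouse, , drop = FALSE]
  rownames(h) <- rownames(m) <- pairs$human
  list(human = h, mouse = m, pairs = pairs)
}

#' Mean expression profile per cell type
#'
#' @param norm Gene x cell matrix of log-normalized values.
#' @param type_labels Cell-type label per cell.
#' @return Gene x type matrix of mean log-normalized expression.
#' @export
type_profiles <- function(norm, type_labels) {
  norm <- .as_dgc(norm)
  type_labels <- as.character(type_labels)
  types <- sort(unique(type_labels))
  prof <- vapply(types, function(t)
    Matrix::rowMeans(norm[, type_labels == t, drop = FALSE]),
    numeric(nrow(norm)))
  if (nrow(norm) == 1) prof <- matrix(prof, nrow = 1)
  dimnames(prof) <- list(rownames(norm), types)
  prof
}

#' Pearson correlation of cell types across species
#'
#' Entry (i, j) is the Pearson correlation between human type i and mouse
#' type j over the shared ortholog rows of two row-aligned profile matrices.
#'
#' @param prof_h,prof_m Row-aligned profile matrices from [type_profiles()]
#'   on ortholog-collapsed data.
#' @return Human-type x mouse-type correlation matrix; zero-variance columns
#'   give NA with a warning.
#' @export
correlate_types <- function(prof_h, prof_m) {
  .assert(nrow(prof_h) == nrow(prof_m), "profiles are not row-aligned")
  flat_h <- apply(prof_h, 2, sd) == 0
  flat_m <- apply(prof_m, 2, sd) == 0
  if (any(flat_h) || any(flat_m)) {
    warning("zero-variance profile column(s); correlations set to NA")
  }
  suppressWarnings(r <- cor(prof_h, prof_m))
  r[flat_h, ] <- NA
  r[, flat_m] <- NA
  r
}

#' Detection fraction of each gene within each cell type
#'
#' @param matrix ExpressionMatrix, counts or log-normalized values.
#' @param type_labels Cell-type label per cell.
#' @return Gene x type matrix of detection fractions (value > 0).
#' @export
detection_by_type <- function(matrix, type_labels) {
  counts <- .counts(matrix)
  det <- counts
  det@x <- rep(1, length(det@x))
  type_profiles(det, type_labels)
}

#' Classify marker conservation across species
#'
#' For each ortholog pair and each cell type annotated in both species:
#' `shared` if the gene is a significant marker (`p_adj < p_cut`,
#' `avg_logFC > fc_cut`) of the homologous type in both species;
#' `human_specific` / `mouse_specific` if significant in that species while
#' in the other the gene is either detected in fewer than `min_detect` of the
#' type's cells or not even nominally significant (`p_adj >= 0.05`, with an
#' absent test record treated as non-significant); `neither` otherwise.
#'
#' @param markers_h,markers_m Marker tables from [find_markers()] whose
#'   `cluster` column holds homologous cell-type names.
#' @param map Ortholog table (columns `human`, `mouse`).
#' @param detect_h,detect_m Detection matrices from [detection_by_type()].
#' @param p_cut,fc_cut Significance and fold-change cutoffs for a marker.
#' @param min_detect Detection floor in the other species.
#' @return Data frame: `human_gene`, `mouse_gene`, `cell_type`, `status`.
#' @export
classify_marker_conservation <- function(markers_h, markers_m, map,
                                         detect_h, detect_m,
                                         p_cut = 0.01, fc_cut = 0.25,
                                         min_detect = 0.1) {
  types <- intersect(unique(markers_h$cluster), unique(markers_m$cluster))
  skipped <- setdiff(union(unique(markers_h$cluster),
                           unique(markers_m$cluster)), types)
  if (length(skipped)) {
    warning("types absent in one species skipped: ",
            paste(skipped, collapse = ", "))
  }
  keep <- map$human %in% rownames(detect_h) & map$mouse %in% rownames(detect_m)
  pairs <- map[keep, , drop = FALSE]
  key_h <- paste(markers_h$gene, markers_h$cluster)
  key_m <- paste(markers_m$gene, markers_m$cluster)
  out <- list()
  for (t in types) {
    ih <- match(paste(pairs$human, t), key_h)
    im <- match(paste(pairs$mouse, t), key_m)
    sig_h <- !is.na(ih) & markers_h$p_adj[ih] < p_cut &
      markers_h$avg_logFC[ih] > fc_cut
    sig_m <- !is.na(im) & markers_m$p_adj[im] < p_cut &
      markers_m$avg_logFC[im] > fc_cut
    padj_h <- markers_h$p_adj[ih]  # NA where the gene was not tested
    padj_m <- markers_m$p_adj[im]
    weak_m <- detect_m[pairs$mouse, t] < min_detect |
      is.na(padj_m) | padj_m >= 0.05
    weak_h <- detect_h[pairs$human, t] < min_detect |
      is.na(padj_h) | padj_h >= 0.05
    status <- rep("neither", nrow(pairs))
    status[sig_h & sig_m] <- "shared"
    status[sig_h & !sig_m & weak_m] <- "human_specific"
    status[sig_m & !sig_h & weak_h] <- "mouse_specific"
    out[[t]] <- data.frame(human_gene = pairs$human, mouse_gene = pairs$mouse,
                           cell_type = t, status = status,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
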