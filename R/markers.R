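## One-vs-rest rank-sum marker detection and marker-dictionary annotation.

#' Default cardiac marker dictionary
#'
#' Canonical marker genes of the major embryonic-heart cell types:
#' cardiomyocytes (CMs), fibroblasts (FBs), endothelial cells (ECs),
#' epicardial cells (EPs), macrophages (MACs), monocytes (MONOs),
#' natural-killer/T cells (NKTs) and blood cells. Mouse symbols are obtained
#' by title-casing. NKX2-5 is excluded from the EC set, following its
#' canonical cardiomyocyte role.
#'
#' @return Named list of gene symbol vectors.
#' @export
default_marker_dictionary <- function() {
  list(
    CMs   = c("TTN", "MYH6", "TNNT2", "TNNC1", "ACTN2"),
    FBs   = c("COL3A1", "COL1A2", "FN1"),
    ECs   = c("CDH5", "EMCN", "PECAM1", "CD93", "TEK", "KDR", "ESAM"),
    EPs   = c("UPK3B", "MSLN", "WT1"),
    MACs  = c("MS4A4A", "SEPP1", "CD68"),
    MONOs = c("LYZ", "S100A8", "S100A6"),
    NKTs  = c("NKG7", "GNLY"),
    Blood = c("HBB", "HBA1", "ALAS2")
  )
}

#' Convert human gene symbols to mouse symbol convention
#'
#' Title-cases symbols (`TNNT2` to `Tnnt2`); mitochondrial `MT-` symbols
#' become `mt-` with a title-cased stem.
#'
#' @param genes Character vector (or list of vectors) of human symbols.
#' @return The converted symbols, same shape as the input.
#' @export
mouse_symbols <- function(genes) {
  if (is.list(genes)) return(lapply(genes, .mouse_symbol))
  .mouse_symbol(genes)
}

#' Default composite cell-type declarations
#'
#' Mixed populations called when two type scores are within the annotation
#' margin of one another.
#' @return Named list mapping composite names to their two member types.
#' @export
default_composites <- function() {
  list("ECs/FBs" = c("ECs", "FBs"), "MACs/MONOs" = c("MACs", "MONOs"))
}

## two-sided Wilcoxon rank-sum p for group 1 vs rest, from precomputed ranks
## of the full vector; normal approximation with tie correction and
## continuity correction (the conventional large-sample marker test).
.ranksum_p <- function(r, in1, tie_term, n) {
  n1 <- sum(in1); n2 <- n - n1
  W <- sum(r[in1])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' One-vs-rest marker detection
#'
#' For each cluster, each gene is tested cluster-vs-rest with a two-sided
#' Wilcoxon rank-sum test on the log-normalized values (normal approximation
#' with tie correction). Genes are tested only if expressed in at least
#' `min_pct` of either group and showing `|avg_logFC| >= min_logfc`, where
#' `avg_logFC` is the natural-log fold change of mean `expm1` expression with
#' a pseudocount of 1. BH adjustment is applied within each cluster across
#' its tested genes.
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param labels Cluster label per cell.
#' @param min_pct Minimum detection fraction in either group.
#' @param min_logfc Minimum absolute log fold change.
#' @return Data frame of marker records: `gene`, `cluster`, `avg_logFC`,
#'   `p_value`, `p_adj`, `pct_in`, `pct_out`.
#' @export
find_markers <- function(norm, labels, min_pct = 0.1, min_logfc = 0.25) {
  norm <- .as_dgc(norm)
  n <- ncol(norm)
  .assert(length(labels) == n, "one label per cell required")
  labels <- as.character(labels)
  tab <- table(labels)
  .assert(length(tab) >= 2, "need at least two clusters")
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("skipping clusters of size < 3: ", paste(small, collapse = ", "))
  }
  clusters <- setdiff(names(tab), small)
  .assert(length(clusters) >= 1, "no cluster of size >= 3")

  genes <- rownames(norm)
  expm <- norm; expm@x <- expm1(norm@x)
  det <- norm; det@x <- rep(1, length(det@x))
  memb <- lapply(clusters, function(cl) labels == cl)
  names(memb) <- clusters
  sum_in <- vapply(memb, function(m)
    Matrix::rowSums(expm[, m, drop = FALSE]), numeric(nrow(norm)))
  det_in <- vapply(memb, function(m)
    Matrix::rowSums(det[, m, drop = FALSE]), numeric(nrow(norm)))
  tot <- Matrix::rowSums(expm)
  dtot <- Matrix::rowSums(det)
  n_in <- vapply(memb, sum, numeric(1))

  recs <- list()
  tnorm <- Matrix::t(norm)  # cells x genes: fast per-gene column access
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    m <- memb[[cl]]
    mean_in <- sum_in[, ci] / n_in[ci]
    mean_out <- (tot - sum_in[, ci]) / (n - n_in[ci])
    pct_in <- det_in[, ci] / n_in[ci]
    pct_out <- (dtot - det_in[, ci]) / (n - n_in[ci])
    lfc <- log(mean_in + 1) - log(mean_out + 1)
    test <- (pct_in >= min_pct | pct_out >= min_pct) & abs(lfc) >= min_logfc
    if (!any(test)) next
    gi <- which(test)
    pv <- vapply(gi, function(g) {
      x <- as.numeric(tnorm[, g])
      r <- rank(x)
      rl <- rle(sort(x, method = "quick"))$lengths
      tie_term <- sum(rl^3 - rl)
      .ranksum_p(r, m, tie_term, n)
    }, numeric(1))
    recs[[cl]] <- data.frame(
      gene = genes[gi], cluster = cl, avg_logFC = lfc[gi],
      p_value = pv, p_adj = p.adjust(pv, "BH"),
      pct_in = pct_in[gi], pct_out = pct_out[gi],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Annotate clusters from a marker dictionary
#'
#' Each cluster is scored per cell type as the mean (over the type's
#' dictionary genes present in the matrix) of the z-scored cluster-mean
#' expression, and assigned the argmax type. When the top two scores lie
#' within `delta` of one another and their pair is a declared composite, the
#' composite name is assigned. Ties break alphabetically.
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param labels Cluster label per cell.
#' @param dict Named list of marker genes per cell type.
#' @param composites Named list of declared composite types (pairs).
#' @param delta Score margin for composite calls.
#' @return Named character vector: cell type per cluster.
#' @export
annotate_clusters <- function(norm, labels, dict = default_marker_dictionary(),
                              composites = default_composites(),
                              delta = 0.25) {
  norm <- .as_dgc(norm)
  labels <- as.character(labels)
  dict <- lapply(dict, function(g) intersect(g, rownames(norm)))
  dict <- dict[vapply(dict, length, integer(1)) > 0]
  .assert(length(dict) > 0, "no dictionary gene present in the matrix")
  clusters <- sort(unique(labels))
  all_genes <- unique(unlist(dict))
  sub <- as.matrix(norm[all_genes, , drop = FALSE])
  cm <- vapply(clusters, function(cl)
    rowMeans(sub[, labels == cl, drop = FALSE]), numeric(length(all_genes)))
  if (length(all_genes) == 1) cm <- matrix(cm, nrow = 1,
                                           dimnames = list(all_genes, clusters))
  mu <- rowMeans(cm)
  sdv <- apply(cm, 1, sd)
  sdv[sdv == 0] <- 1
  z <- (cm - mu) / sdv
  scores <- vapply(dict, function(g)
    colMeans(z[g, , drop = FALSE]), numeric(length(clusters)))
  if (length(clusters) == 1) scores <- matrix(scores, nrow = 1,
                                              dimnames = list(clusters, names(dict)))
  out <- character(length(clusters))
  for (i in seq_along(clusters)) {
    s <- scores[i, ]
    ord <- order(-s, names(s))  # ties alphabetical
    top <- names(s)[ord[1]]
    lab <- top
    if (length(s) >= 2) {
      second <- names(s)[ord[2]]
      if (s[ord[1]] - s[ord[2]] <= delta) {
        for (comp in names(composites)) {
          if (setequal(composites[[comp]], c(top, second))) lab <- comp
        }
      }
    }
    out[i] <- lab
  }
  setNames(out, clusters)
}
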