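## Normalization, HVG selection, PCA with out-of-sample projection,
## geometric sketching, and iterative centroid batch alignment.

#' Log-normalize counts
#'
#' Each value becomes `log(1 + count / cell_total * scale_factor)`. The
#' sparsity pattern is preserved.
#'
#' @param matrix ExpressionMatrix or sparse gene x cell counts.
#' @param scale_factor Library-size scale factor.
#' @return A sparse gene x cell matrix of log-normalized values.
#' @export
lognormalize <- function(matrix, scale_factor = 1e4) {
  counts <- .counts(matrix)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop("zero-total cells: ", paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5),
         call. = FALSE)
  }
  norm <- counts
  norm@x <- log1p(counts@x / totals[.col_of(counts)] * scale_factor)
  norm
}

#' Select highly variable genes
#'
#' Genes are ranked by a variance-stabilized dispersion: the variance of the
#' log-normalized values divided by the median variance of the gene's
#' mean-expression bin (20 quantile bins), which removes the mean-variance
#' trend. Constant genes are excluded; ties break by gene identifier.
#'
#' @param norm Log-normalized matrix from [lognormalize()].
#' @param n Number of genes to return (capped at the number of non-constant
#'   genes).
#' @param n_bins Mean-expression bins for the trend.
#' @return Character vector of gene identifiers, most variable first.
#' @export
select_hvg <- function(norm, n = 2000, n_bins = 20) {
  norm <- .as_dgc(norm)
  .assert(n <= nrow(norm), "n exceeds the number of genes")
  mu <- Matrix::rowMeans(norm)
  v <- .row_vars(norm)
  ok <- v > 0
  if (!any(ok)) return(character(0))
  breaks <- unique(quantile(mu[ok], probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = breaks, include.lowest = TRUE)
  med <- tapply(v[ok], bin[ok], median)
  ref <- med[as.character(bin)]
  ref[is.na(ref) | ref == 0] <- median(v[ok])
  disp <- ifelse(ok, v / ref, -Inf)
  ids <- rownames(norm)
  ord <- order(-disp, ids)
  ord <- ord[ok[ord]]
  ids[head(ord, n)]
}

#' Principal component analysis with stored projection statistics
#'
#' Genes are centered and scaled (z-scores clipped at +/-10) before a
#' truncated SVD. The returned object carries the gene statistics and
#' loadings needed to project new cells onto the same axes. Each component's
#' sign is fixed so that its largest-magnitude loading is positive.
#'
#' @param norm Log-normalized matrix.
#' @param genes Genes to use (subset of rownames).
#' @param d Number of components.
#' @param seed Integer seed (truncated SVD initialization).
#' @param clip Z-score clipping bound.
#' @return An `Embedding`: list with `scores` (cell x d), `loadings`
#'   (gene x d, orthonormal columns), `gene_means`, `gene_sds`,
#'   `explained_variance` (non-increasing), `genes`, `clip`.
#' @export
run_pca <- function(norm, genes = rownames(norm), d = 20, seed = 1L,
                    clip = 10) {
  norm <- .as_dgc(norm)
  .assert(all(genes %in% rownames(norm)), "genes absent from the matrix")
  .assert(d >= 1, "d must be >= 1")
  .assert(d <= length(genes), "d exceeds the number of genes")
  X <- as.matrix(norm[genes, , drop = FALSE])
  mu <- rowMeans(X)
  sds <- apply(X, 1, sd)
  sds_safe <- ifelse(sds > 0, sds, 1)
  Z <- (X - mu) / sds_safe
  Z <- pmin(pmax(Z, -clip), clip)
  M <- t(Z)  # cells x genes
  n <- nrow(M)
  set.seed(seed)
  sv <- NULL
  if (d <= min(dim(M)) / 3 && d < min(dim(M)) - 1) {
    sv <- tryCatch(irlba::irlba(M, nv = d), error = function(e) NULL)
  }
  if (is.null(sv)) {
    sv <- svd(M, nu = min(d, min(dim(M))), nv = min(d, min(dim(M))))
    sv$d <- sv$d[seq_len(ncol(sv$u))]
  }
  U <- sv$u; D <- sv$d; V <- sv$v
  if (ncol(U) < d) {  # requested more components than the rank
    warning("d exceeds the matrix rank; trailing components have zero variance")
    pad <- d - ncol(U)
    U <- cbind(U, matrix(0, nrow(U), pad))
    V <- cbind(V, matrix(0, nrow(V), pad))
    D <- c(D, rep(0, pad))
  }
  zero <- D < max(D, 1) * 1e-12
  if (any(zero) && !all(zero)) {
    warning("d exceeds the matrix rank; trailing components have zero variance")
    D[zero] <- 0
  }
  for (jj in seq_len(d)) {  # sign convention
    iref <- which.max(abs(V[, jj]))
    if (length(iref) && V[iref, jj] < 0) {
      V[, jj] <- -V[, jj]; U[, jj] <- -U[, jj]
    }
  }
  scores <- U %*% diag(D, nrow = d)
  rownames(scores) <- colnames(norm)
  rownames(V) <- genes
  structure(list(scores = scores, loadings = V,
                 gene_means = setNames(mu, genes),
                 gene_sds = setNames(sds_safe, genes),
                 explained_variance = D^2 / max(n - 1, 1),
                 genes = genes, clip = clip),
            class = "Embedding")
}

#' Project cells onto an existing embedding
#'
#' @param embedding An `Embedding` from [run_pca()].
#' @param norm Log-normalized matrix containing the embedding's genes.
#' @return A cell x d score matrix.
#' @export
project_cells <- function(embedding, norm) {
  norm <- .as_dgc(norm)
  .assert(all(embedding$genes %in% rownames(norm)),
          "matrix lacks genes of the embedding")
  X <- as.matrix(norm[embedding$genes, , drop = FALSE])
  Z <- (X - embedding$gene_means) / embedding$gene_sds
  Z <- pmin(pmax(Z, -embedding$clip), embedding$clip)
  scores <- t(Z) %*% embedding$loadings
  rownames(scores) <- colnames(norm)
  scores
}

.box_ids <- function(scores, mins, side) {
  idx <- floor(sweep(scores, 2, mins) / side)
  do.call(paste, c(as.data.frame(idx), sep = ","))
}

#' Geometric sketching
#'
#' Covers the embedding's bounding box with equal-sided hypercubes,
#' binary-searching the side length until the number of occupied boxes lies
#' in `[k_target, 2 k_target]`, then samples boxes uniformly without
#' replacement, one random cell per box (topping up from remaining cells if
#' the occupied-box count cannot reach `k_target`). Sampling geometry rather
#' than density retains rare cell populations.
#'
#' @param embedding An `Embedding` or a cell x d score matrix.
#' @param k_target Number of cells to keep, `1 <= k_target <= n_cells`.
#' @param seed Integer seed.
#' @return Sorted integer vector of selected cell indices, length `k_target`.
#' @export
geometric_sketch <- function(embedding, k_target, seed = 1L) {
  scores <- if (is(embedding, "Embedding")) embedding$scores else
    as.matrix(embedding)
  n <- nrow(scores)
  .assert(k_target >= 1, "k_target must be >= 1")
  .assert(k_target <= n, "k_target exceeds the number of cells")
  if (k_target == n) return(seq_len(n))
  set.seed(seed)
  mins <- apply(scores, 2, min)
  span <- max(apply(scores, 2, function(x) diff(range(x))), .Machine$double.eps)
  lo <- span / 1e6; hi <- span * (1 + 1e-9)
  best_side <- lo  # smallest boxes: as many occupied boxes as distinct points
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    cnt <- length(unique(.box_ids(scores, mins, mid)))
    if (cnt >= k_target && cnt <= 2 * k_target) { best_side <- mid; break }
    if (cnt > 2 * k_target) lo <- mid else hi <- mid
    if (cnt >= k_target) best_side <- mid
  }
  ids <- .box_ids(scores, mins, best_side)
  boxes <- split(seq_len(n), ids)
  n_boxes <- length(boxes)
  take <- if (n_boxes >= k_target) sample(boxes, k_target) else boxes
  picked <- vapply(take, function(cells)
    if (length(cells) == 1) cells else sample(cells, 1), integer(1))
  if (length(picked) < k_target) {  # degenerate geometry: top up uniformly
    rest <- setdiff(seq_len(n), picked)
    picked <- c(picked, sample(rest, k_target - length(picked)))
  }
  sort(unname(picked))
}

#' Iterative centroid batch alignment
#'
#' A simplified integration scheme: soft k-means clusters the current scores
#' (at most `n_clusters` centroids); within each cluster the
#' responsibility-weighted difference between each batch's conditional
#' centroid and the overall cluster centroid is subtracted from that batch's
#' cells; iteration stops when the maximum cell displacement falls below
#' `tol` or after `max_iter` iterations. The first `d_out` corrected
#' dimensions are returned with each column rescaled to unit variance.
#'
#' @param embedding An `Embedding`.
#' @param batch_labels Batch label per cell.
#' @param n_clusters Maximum number of clusters.
#' @param max_iter Maximum iterations.
#' @param d_out Output dimensionality.
#' @param tol Convergence tolerance on the maximum cell displacement.
#' @param seed Integer seed (k-means initialization).
#' @return An `Embedding` with corrected `scores`; loadings and gene
#'   statistics are carried through unchanged for provenance. The number of
#'   alignment iterations is recorded as `$iterations`.
#' @export
align_batches <- function(embedding, batch_labels, n_clusters = 50,
                          max_iter = 100, d_out = 20, tol = 1e-4, seed = 1L) {
  .assert(is(embedding, "Embedding"), "embedding must come from run_pca()")
  S <- embedding$scores
  n <- nrow(S)
  .assert(length(batch_labels) == n, "one batch label per cell required")
  .assert(d_out <= ncol(S), "d_out exceeds embedding dimensionality")
  batch_labels <- as.character(batch_labels)
  batches <- unique(batch_labels)
  out <- embedding
  if (length(batches) < 2 || max(table(batch_labels)) == 1) {
    warning(if (length(batches) < 2) "single batch: identity transform"
            else "all batch labels distinct: identity transform")
    out$scores <- S[, seq_len(d_out), drop = FALSE]
    out$explained_variance <- embedding$explained_variance[seq_len(d_out)]
    out$iterations <- 0L
    return(out)
  }
  kc <- max(2L, min(n_clusters, n - 1))
  set.seed(seed)
  km <- kmeans(S, centers = kc, iter.max = 25, nstart = 1)
  C <- km$centers
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- outer(rowSums(S^2), rowSums(C^2), "+") - 2 * S %*% t(C)
    d2 <- pmax(d2, 0)
    sigma2 <- median(apply(d2, 1, min)) + 1e-8
    R <- exp(-(d2 - apply(d2, 1, min)) / (2 * sigma2))
    R <- R / rowSums(R)
    colR <- colSums(R)
    live <- colR > 1e-8
    Cnew <- (t(R) %*% S) / pmax(colR, 1e-8)
    delta <- matrix(0, n, ncol(S))
    for (b in batches) {
      ib <- batch_labels == b
      Rb <- R[ib, , drop = FALSE]
      cb <- colSums(Rb)
      ok <- live & cb > 1e-8
      if (!any(ok)) next
      Mb <- (t(Rb) %*% S[ib, , drop = FALSE]) / pmax(cb, 1e-8)
      diffs <- Mb[ok, , drop = FALSE] - Cnew[ok, , drop = FALSE]
      delta[ib, ] <- Rb[, ok, drop = FALSE] %*% diffs
    }
    S <- S - delta
    C <- Cnew
    move <- sqrt(max(rowSums(delta^2)))
    if (move < tol || iter >= max_iter) break
  }
  S <- S[, seq_len(d_out), drop = FALSE]
  sds <- apply(S, 2, sd)
  sds[sds == 0] <- 1
  S <- sweep(S, 2, sds, "/")
  out$scores <- S
  out$explained_variance <- embedding$explained_variance[seq_len(d_out)]
  out$iterations <- iter
  out
}
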