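## Pseudotime per cell type: gene filters, stage-DE ordering genes,
## centroid-MST trajectory, negative-binomial spline pseudotime tests,
## three-phase gene clustering, and subpopulation density curves.

#' Filter genes for trajectory analysis
#'
#' Keeps genes expressed (count > 0) in at least `max(10, ceil(0.05 *
#' n_cells))` cells: the 10-cell floor and the 5%-of-cells rule combined.
#'
#' @param matrix ExpressionMatrix or sparse counts.
#' @return Character vector of retained gene identifiers.
#' @export
filter_trajectory_genes <- function(matrix) {
  counts <- .counts(matrix)
  thr <- max(10, ceiling(0.05 * ncol(counts)))
  n_expr <- Matrix::rowSums(counts > 0)
  out <- rownames(counts)[n_expr >= thr]
  .assert(length(out) > 0, "no gene passes the trajectory expression filter")
  out
}

#' Select ordering genes as stage-differential genes
#'
#' Kruskal-Wallis test of each gene across developmental-stage groups,
#' BH-adjusted; genes with `q < q_cut` are ranked by the test statistic and
#' the top `top_n` kept. Stages with fewer than 3 cells are excluded from
#' the test with a warning.
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param stages Stage label per cell.
#' @param q_cut BH-adjusted significance cutoff.
#' @param top_n Maximum number of ordering genes.
#' @return Character vector of gene identifiers, strongest first.
#' @export
select_ordering_genes <- function(norm, stages, q_cut = 0.01, top_n = 1000) {
  norm <- .as_dgc(norm)
  stages <- as.character(stages)
  tab <- table(stages)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("stages with < 3 cells excluded from the ordering test: ",
            paste(small, collapse = ", "))
  }
  use <- !(stages %in% small)
  g <- factor(stages[use])
  .assert(nlevels(g) >= 2, "need at least two stages with >= 3 cells")
  sub <- Matrix::t(norm[, use, drop = FALSE])
  # vectorized Kruskal-Wallis: H from group rank sums with tie correction
  n <- nrow(sub)
  stat <- vapply(seq_len(ncol(sub)), function(j) {
    x <- as.numeric(sub[, j])
    r <- rank(x)
    rs <- tapply(r, g, sum)
    ns <- tabulate(g)
    H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
    rl <- rle(sort(x, method = "quick"))$lengths
    corr <- 1 - sum(rl^3 - rl) / (n^3 - n)
    if (corr <= 0) return(NA_real_)
    H / corr
  }, numeric(1))
  p <- pchisq(stat, df = nlevels(g) - 1, lower.tail = FALSE)
  p[is.na(p)] <- 1
  q <- p.adjust(p, "BH")
  sel <- which(q < q_cut)
  sel <- sel[order(-stat[sel])]
  rownames(norm)[head(sel, top_n)]
}

#' Fit a centroid-MST trajectory with pseudotime
#'
#' Cells are reduced by PCA on the ordering genes, centroids found by
#' k-means, a minimum spanning tree built over the centroids (Euclidean
#' edge weights), and each cell assigned to its nearest centroid. The root
#' is the centroid with the largest fraction of earliest-stage cells.
#' Pseudotime is the geodesic tree distance from the root to the assigned
#' centroid plus the signed projection of the cell onto its node's incident
#' edge, min-max scaled to `[0, 1]`.
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param genes Ordering genes.
#' @param n_nodes Number of tree nodes (k-means centroids).
#' @param d Reduced dimensionality.
#' @param seed Integer seed.
#' @param stages Ordered factor of stage labels per cell (earliest level
#'   anchors the root).
#' @return A `Trajectory`: list with `nodes` (centroid matrix), `edges`
#'   (MST edge list), `cell_assignment`, `pseudotime`, `root_node`,
#'   `embedding`.
#' @export
fit_trajectory <- function(norm, genes, n_nodes = 15, d = 2, seed = 1L,
                           stages = NULL) {
  norm <- .as_dgc(norm)
  n <- ncol(norm)
  .assert(length(genes) >= d, "need at least d ordering genes")
  .assert(n_nodes <= n, "n_nodes exceeds the number of cells")
  .assert(n_nodes >= 2, "need at least two nodes")
  emb <- run_pca(norm, genes, d = d, seed = seed)
  S <- emb$scores
  set.seed(seed)
  km <- suppressWarnings(kmeans(S, centers = n_nodes, iter.max = 50,
                                nstart = 5))
  C <- km$centers
  D <- as.matrix(stats::dist(C))
  g_full <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                                weighted = TRUE)
  mst <- igraph::mst(g_full)
  nn <- RANN::nn2(C, query = S, k = 1)
  assign <- as.integer(nn$nn.idx[, 1])

  if (!is.null(stages)) {
    st <- if (is.factor(stages)) stages else factor(stages)
    earliest <- levels(st)[levels(st) %in% unique(as.character(st))][1]
    frac_early <- vapply(seq_len(n_nodes), function(v) {
      cells <- assign == v
      if (!any(cells)) return(-1)
      mean(st[cells] == earliest)
    }, numeric(1))
    root <- which.max(frac_early)
  } else root <- 1L

  node_dist <- igraph::distances(mst, v = root)[1, ]
  bfs <- igraph::bfs(mst, root = root, father = TRUE, unreachable = FALSE)
  father <- as.integer(bfs$father)
  # unit direction of each node's incident edge (from its parent)
  dirs <- matrix(0, n_nodes, ncol(C))
  for (v in seq_len(n_nodes)) {
    p <- father[v]
    if (!is.na(p) && p > 0) {
      u <- C[v, ] - C[p, ]
    } else {  # root: direction toward its nearest tree neighbor
      nb <- as.integer(igraph::neighbors(mst, v))
      u <- if (length(nb)) C[nb[1], ] - C[v, ] else rep(0, ncol(C))
    }
    len <- sqrt(sum(u^2))
    if (len > 0) dirs[v, ] <- u / len
  }
  proj <- rowSums((S - C[assign, , drop = FALSE]) * dirs[assign, , drop = FALSE])
  pt <- node_dist[assign] + proj
  rng <- range(pt)
  pt <- if (diff(rng) > 0) (pt - rng[1]) / diff(rng) else rep(0, n)
  names(pt) <- colnames(norm)
  structure(list(nodes = C, edges = igraph::as_edgelist(mst),
                 cell_assignment = assign, pseudotime = pt,
                 root_node = root, embedding = emb),
            class = "Trajectory")
}

## robust method-of-moments / ML theta for a NB fit with offsets
.estimate_theta <- function(y, olib) {
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ 1 + offset(olib))),
    error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$theta)) {
    return(min(max(fit$theta, 1e-3), 1e6))
  }
  mu <- mean(y)
  v <- var(y)
  if (!is.finite(v) || v <= mu) return(1e6)  # at or below Poisson
  min(max(mu^2 / (v - mu), 1e-3), 1e6)
}

#' Test genes for pseudotime-dependent expression
#'
#' Per gene, a likelihood-ratio test of negative-binomial regression (log
#' link, library-size offset) with a natural cubic spline in pseudotime
#' (`df` degrees of freedom) against the intercept-only model, compared to a
#' chi-square with `df` degrees of freedom. The NB dispersion is estimated
#' once under the null and held fixed in both fits. Non-converging genes are
#' recorded with p = 1 and flagged.
#'
#' @param counts ExpressionMatrix or raw counts (genes x cells).
#' @param pseudotime Finite pseudotime per cell.
#' @param df Spline degrees of freedom.
#' @param lib_sizes Optional per-cell library sizes for the offset; defaults
#'   to the column sums of `counts` (pass the full-matrix totals when
#'   testing a gene subset).
#' @return Data frame: `gene`, `lrt_stat`, `p_value`, `q_value`,
#'   `converged`.
#' @export
test_pseudotime_dependence <- function(counts, pseudotime, df = 3,
                                       lib_sizes = NULL) {
  counts <- .counts(counts)
  .assert(all(is.finite(pseudotime)), "pseudotime must be finite")
  .assert(length(pseudotime) == ncol(counts), "one pseudotime per cell")
  lib <- lib_sizes %||% Matrix::colSums(counts)
  .assert(length(lib) == ncol(counts), "one library size per cell")
  .assert(all(lib > 0), "zero-total cells; filter before testing")
  olib <- log(lib)
  B <- splines::ns(pseudotime, df = df)
  genes <- rownames(counts)
  tc <- Matrix::t(counts)
  res <- lapply(seq_along(genes), function(gi) {
    y <- as.numeric(tc[, gi])
    if (all(y == 0)) {
      return(data.frame(gene = genes[gi], lrt_stat = 0, p_value = 1,
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    out <- tryCatch({
      theta <- .estimate_theta(y, olib)
      fam <- MASS::negative.binomial(theta)
      f0 <- suppressWarnings(glm(y ~ 1 + offset(olib), family = fam))
      f1 <- suppressWarnings(glm(y ~ B + offset(olib), family = fam))
      stat <- max(0, f0$deviance - f1$deviance)
      conv <- isTRUE(f0$converged) && isTRUE(f1$converged)
      p <- if (conv) pchisq(stat, df = df, lower.tail = FALSE) else 1
      data.frame(gene = genes[gi], lrt_stat = if (conv) stat else 0,
                 p_value = p, converged = conv, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(gene = genes[gi], lrt_stat = 0, p_value = 1,
                 converged = FALSE, stringsAsFactors = FALSE))
    out
  })
  res <- do.call(rbind, res)
  res$q_value <- p.adjust(res$p_value, "BH")
  res[, c("gene", "lrt_stat", "p_value", "q_value", "converged")]
}

#' Assign trajectory phases to pseudotime-dependent genes
#'
#' Each gene's log-normalized expression is smoothed by a natural-spline
#' fit evaluated on a 100-point pseudotime grid and z-scored; the phase is
#' the tertile of `[0, 1]` with the largest mean smoothed value: `initial`,
#' `transitional` or `terminal` (ties resolve to `transitional`).
#'
#' @param norm Log-normalized gene x cell matrix.
#' @param pseudotime Pseudotime per cell, in `[0, 1]`.
#' @param significant_genes Genes to assign (non-empty).
#' @param df Spline degrees of freedom for smoothing.
#' @return Named character vector of phases per gene.
#' @export
assign_trajectory_phases <- function(norm, pseudotime, significant_genes,
                                     df = 3) {
  .assert(length(significant_genes) > 0, "significant_genes is empty")
  norm <- .as_dgc(norm)
  .assert(all(significant_genes %in% rownames(norm)),
          "genes absent from the matrix")
  grid <- seq(0, 1, length.out = 100)
  B <- splines::ns(pseudotime, df = df)
  Bg <- predict(B, grid)
  tert <- cut(grid, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
              labels = c("initial", "transitional", "terminal"))
  sub <- as.matrix(norm[significant_genes, , drop = FALSE])
  phases <- vapply(seq_along(significant_genes), function(i) {
    y <- sub[i, ]
    fit <- lm.fit(cbind(1, B), y)
    pred <- drop(cbind(1, Bg) %*% fit$coefficients)
    if (sd(pred) == 0) return("transitional")
    z <- (pred - mean(pred)) / sd(pred)
    m <- tapply(z, tert, mean)
    mx <- max(m)
    winners <- names(m)[m >= mx - 1e-12]
    if (length(winners) > 1) "transitional" else winners
  }, character(1))
  setNames(phases, significant_genes)
}

#' Density of subpopulations along pseudotime
#'
#' Gaussian kernel density per subpopulation over `[0, 1]` (Scott's
#' bandwidth, floor 0.05 for singleton groups), evaluated on a shared
#' 200-point grid and renormalized so each curve integrates to 1.
#'
#' @param pseudotime Pseudotime per cell, in `[0, 1]`.
#' @param subpop_labels Subpopulation label per cell.
#' @param n_grid Grid size.
#' @return List with `grid` and `density` (subpopulation x grid matrix).
#' @export
subpopulation_density <- function(pseudotime, subpop_labels, n_grid = 200) {
  .assert(length(subpop_labels) == length(pseudotime),
          "one label per pseudotime value")
  labs <- sort(unique(as.character(subpop_labels)))
  .assert(length(labs) >= 1, "need at least one subpopulation")
  grid <- seq(0, 1, length.out = n_grid)
  dens <- t(vapply(labs, function(l) {
    x <- pseudotime[subpop_labels == l]
    bw <- if (length(x) > 1) sd(x) * length(x)^(-1 / 5) else 0
    bw <- max(bw, 0.05 * (length(x) == 1), 1e-3)
    f <- vapply(grid, function(g) mean(dnorm(g - x, sd = bw)), numeric(1))
    f / .trapz(grid, f)
  }, numeric(n_grid)))
  list(grid = grid, density = dens)
}
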