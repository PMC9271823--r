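## kNN-graph construction and modularity clustering.

#' Build a shared-nearest-neighbor weighted kNN graph
#'
#' Undirected edges connect each cell to its k Euclidean nearest neighbors;
#' the edge weight is the Jaccard overlap of the two cells' neighborhoods
#' (each neighborhood includes the cell itself). Self-edges are excluded.
#'
#' @param embedding An `Embedding` or a cell x d score matrix.
#' @param k Neighborhood size, `k < n_cells`.
#' @return An igraph undirected weighted graph with one node per cell.
#' @export
build_knn_graph <- function(embedding, k = 20) {
  scores <- if (is(embedding, "Embedding")) embedding$scores else
    as.matrix(embedding)
  n <- nrow(scores)
  .assert(k > 0, "k must be positive")
  .assert(k < n, "k must be smaller than the number of cells")
  nn <- RANN::nn2(scores, k = k + 1)
  idx <- nn$nn.idx
  # guarantee self is excluded even under exact ties
  nbr <- t(vapply(seq_len(n), function(i) {
    row <- idx[i, ]
    row <- row[row != i]
    row[seq_len(k)]
  }, integer(k)))
  if (k == 1) nbr <- matrix(nbr, ncol = 1)
  # neighborhood sets (including self) as a sparse indicator matrix
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1),
                            j = c(as.vector(nbr), seq_len(n)),
                            x = 1, dims = c(n, n))
  inter <- A %*% Matrix::t(A)  # |N(i) & N(j)|
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nbr)
  ov <- inter[cbind(ii, jj)]
  w <- ov / (2 * (k + 1) - ov)
  g <- igraph::graph_from_edgelist(cbind(ii, jj), directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = "max")
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- rownames(scores) %||% as.character(seq_len(n))
  g
}

#' Modularity community detection on a cell graph
#'
#' Louvain-family multilevel modularity maximization; labels are relabeled
#' by decreasing community size and are contiguous from 0.
#'
#' @param graph Weighted graph from [build_knn_graph()].
#' @param resolution Modularity resolution parameter.
#' @param seed Integer seed (the refinement order is randomized).
#' @return Integer vector of 0-based cluster labels, one per cell.
#' @export
cluster_graph <- function(graph, resolution = 1.0, seed = 1L) {
  .assert(igraph::vcount(graph) > 0, "empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- as.integer(relab[as.character(memb)])
  names(out) <- igraph::V(graph)$name
  out
}
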