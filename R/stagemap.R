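## The developmental-stage similarity procedure: core-gene selection, an
## oriented PC1 axis with per-stage kernel densities fit on human cells, and
## projection of mouse cells through ortholog loadings onto that axis.

#' Select core genes by detection fraction
#'
#' Genes detected (count > 0) in at least `min_fraction` of the given cells.
#'
#' @param norm Gene x cell matrix (counts or log-normalized values; only the
#'   sparsity pattern matters).
#' @param min_fraction Detection floor, in `(0, 1]`.
#' @return Character vector of core gene identifiers.
#' @export
select_core_genes <- function(norm, min_fraction = 0.75) {
  .assert(min_fraction > 0 && min_fraction <= 1,
          "min_fraction must lie in (0, 1]")
  counts <- .counts(norm)
  frac <- Matrix::rowSums(counts > 0) / ncol(counts)
  out <- rownames(counts)[frac >= min_fraction]
  if (length(out) == 0) {
    stop("no gene detected in at least ", min_fraction * 100,
         "% of cells; consider a lower min_fraction", call. = FALSE)
  }
  out
}

.scott_bw <- function(x, floor_bw) {
  bw <- if (length(x) > 1) sd(x) * length(x)^(-1 / 5) else 0
  max(bw, floor_bw)
}

#' Fit the oriented PC1 stage axis with per-stage densities
#'
#' Core genes are z-scored on the given (human) cells and PC1 extracted.
#' The axis is oriented so that PC1 increases with developmental stage
#' (non-negative Spearman correlation with the stage rank). A Gaussian
#' kernel density of the oriented PC1 scores is estimated per stage
#' (Scott's bandwidth with a floor of 1% of the PC1 range) on a shared
#' 512-point grid spanning the observed range plus three bandwidths.
#'
#' @param norm_h Log-normalized human matrix restricted to one cell type.
#' @param stages Ordered factor of stage labels per cell; at least two
#'   stages with five or more cells each.
#' @param core_genes Genes from [select_core_genes()].
#' @param seed Integer seed for the SVD.
#' @return A `StageAxisModel`: `core_genes`, `gene_means`, `gene_sds`,
#'   `pc1_loadings` (unit norm), `orientation`, `grid`, `stage_densities`
#'   (stage x grid, each integrating to 1), `bandwidths`, `stage_scores`,
#'   `scores` (oriented per-cell PC1), `clip`.
#' @export
fit_stage_axis <- function(norm_h, stages, core_genes, seed = 1L) {
  norm_h <- .as_dgc(norm_h)
  st <- if (is.factor(stages)) stages else factor(stages)
  st <- droplevels(st)
  .assert(nlevels(st) >= 2, "need at least two stages")
  .assert(all(table(st) >= 5), "every stage needs at least 5 cells")
  .assert(length(stages) == ncol(norm_h), "one stage per cell")
  keep <- core_genes[.row_vars(norm_h[core_genes, , drop = FALSE]) > 0]
  .assert(length(keep) >= 2, "fewer than two non-constant core genes")
  emb <- run_pca(norm_h, keep, d = 1, seed = seed)
  pc1 <- drop(emb$scores)
  srank <- as.integer(st)
  rho <- suppressWarnings(cor(pc1, srank, method = "spearman"))
  orientation <- if (!is.na(rho) && rho < 0) -1 else 1
  s <- orientation * pc1
  floor_bw <- 0.01 * max(diff(range(s)), .Machine$double.eps)
  bws <- vapply(levels(st), function(l) .scott_bw(s[st == l], floor_bw),
                numeric(1))
  pad <- 3 * max(bws)
  grid <- seq(min(s) - pad, max(s) + pad, length.out = 512)
  dens <- t(vapply(levels(st), function(l) {
    x <- s[st == l]
    f <- vapply(grid, function(g) mean(dnorm(g - x, sd = bws[[l]])),
                numeric(1))
    f / .trapz(grid, f)
  }, numeric(512)))
  structure(list(core_genes = keep,
                 gene_means = emb$gene_means,
                 gene_sds = emb$gene_sds,
                 pc1_loadings = setNames(drop(emb$loadings), keep),
                 orientation = orientation,
                 grid = grid, stage_densities = dens, bandwidths = bws,
                 stage_levels = levels(st),
                 stage_scores = tapply(s, st, mean),
                 scores = setNames(s, colnames(norm_h)),
                 clip = emb$clip),
            class = "StageAxisModel")
}

#' Project another species onto the stage axis
#'
#' Loadings are restricted to the core genes whose orthologs are present in
#' the query matrix and renormalized to unit norm (compensating ortholog
#' dropout); query values are standardized with the HUMAN gene statistics so
#' the dot product lives on the human axis.
#'
#' @param model A `StageAxisModel`.
#' @param norm_m Log-normalized query (mouse) matrix.
#' @param map Ortholog table (columns `human`, `mouse`).
#' @param min_coverage Minimum fraction of core genes with orthologs present
#'   in the query matrix.
#' @return Named numeric vector: oriented PC1 value per query cell.
#' @export
project_other_species <- function(model, norm_m, map, min_coverage = 0.5) {
  norm_m <- .as_dgc(norm_m)
  partner <- setNames(map$mouse, map$human)
  shared_h <- model$core_genes[model$core_genes %in% names(partner) &
                                 partner[model$core_genes] %in% rownames(norm_m)]
  coverage <- length(shared_h) / length(model$core_genes)
  if (coverage < min_coverage) {
    stop(sprintf(paste0("only %.1f%% of core genes have orthologs detected ",
                        "in the query matrix (minimum %.0f%%)"),
                 100 * coverage, 100 * min_coverage), call. = FALSE)
  }
  l <- model$pc1_loadings[shared_h]
  l <- l / sqrt(sum(l^2))
  X <- as.matrix(norm_m[partner[shared_h], , drop = FALSE])
  Z <- (X - model$gene_means[shared_h]) / model$gene_sds[shared_h]
  Z <- pmin(pmax(Z, -model$clip), model$clip)
  pc1 <- model$orientation * drop(t(Z) %*% l)
  setNames(pc1, colnames(norm_m))
}

#' Map query stages onto the human stage densities
#'
#' For each query stage the mean PC1 is computed and every human stage's
#' kernel density is evaluated at that point (linear interpolation on the
#' grid; values outside the grid use the nearest endpoint and are flagged).
#' The best human stage is the density argmax (exact ties resolve to the
#' earlier stage, flagged); the runner-up is reported alongside. Per-cell
#' soft assignments are attached as stage-posterior fractions.
#'
#' @param model A `StageAxisModel`.
#' @param query_pc1 Projected PC1 values from [project_other_species()].
#' @param query_stage_labels Stage label per query cell.
#' @return Data frame (class `StageCorrespondence`): `query_stage`,
#'   `mean_pc1`, `best_human_stage`, `best_density`, `runner_up_stage`,
#'   `runner_up_density`, `out_of_range`, `tie`. Per-cell posteriors are in
#'   `attr(, "posterior")`.
#' @export
map_stages <- function(model, query_pc1, query_stage_labels) {
  .assert(length(query_pc1) == length(query_stage_labels),
          "every query cell needs a stage label")
  labs <- unique(as.character(query_stage_labels))
  gr <- model$grid
  dens_at <- function(x) {
    out_of_range <- x < gr[1] | x > gr[length(gr)]
    d <- vapply(seq_along(model$stage_levels), function(i)
      approx(gr, model$stage_densities[i, ], xout = min(max(x, gr[1]),
                                                        gr[length(gr)]))$y,
      numeric(1))
    list(d = setNames(d, model$stage_levels), oob = out_of_range)
  }
  rows <- lapply(labs, function(l) {
    mu <- mean(query_pc1[query_stage_labels == l])
    da <- dens_at(mu)
    d <- da$d
    ord <- order(-d, seq_along(d))  # earlier stage wins exact ties
    tie <- length(d) >= 2 && abs(d[ord[1]] - d[ord[2]]) < 1e-12
    data.frame(query_stage = l, mean_pc1 = mu,
               best_human_stage = names(d)[ord[1]],
               best_density = unname(d[ord[1]]),
               runner_up_stage = if (length(d) >= 2) names(d)[ord[2]] else NA,
               runner_up_density = if (length(d) >= 2) unname(d[ord[2]]) else NA,
               out_of_range = da$oob, tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # per-cell stage posteriors
  post <- t(vapply(query_pc1, function(x) {
    d <- dens_at(x)$d
    tot <- sum(d)
    if (tot <= 0) rep(1 / length(d), length(d)) else d / tot
  }, numeric(length(model$stage_levels))))
  colnames(post) <- model$stage_levels
  attr(out, "posterior") <- post
  class(out) <- c("StageCorrespondence", class(out))
  out
}
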