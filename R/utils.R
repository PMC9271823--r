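#' @importFrom Matrix colSums rowSums rowMeans t readMM writeMM sparseMatrix Diagonal
#' @importFrom methods as is
#' @importFrom stats var sd cor kmeans p.adjust pchisq pnorm phyper dnorm
#'   quantile median approx rnbinom rnorm rbinom runif logLik glm lm predict
#'   setNames kruskal.test complete.cases
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each pipeline stage gets its own RNG seed so that stages can be rerun
#' independently of one another while the whole run stays reproducible from a
#' single integer.
#'
#' @param seed Global integer seed.
#' @param label Stage name.
#' @return An integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

## column index for each entry of a dgCMatrix
.col_of <- function(m) rep.int(seq_len(ncol(m)), diff(m@p))

.as_dgc <- function(m) {
  if (is(m, "dgCMatrix")) return(m)
  as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

## row variances of a sparse genes x cells matrix
.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(0, nrow(m)))
  mu <- Matrix::rowMeans(m)
  s2 <- Matrix::rowSums(m^2)
  pmax((s2 - n * mu^2) / (n - 1), 0)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' @importFrom utils head tail
NULL
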