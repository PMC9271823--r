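## Data model and on-disk formats: sparse count bundles (Matrix Market +
## TSV sidecars), one-to-one ortholog tables, GMT gene-set collections.

#' Construct an expression matrix
#'
#' The central container of the package: a sparse, non-negative gene x cell
#' count matrix with unique gene and cell identifiers and a species tag.
#' Internally a `dgCMatrix` with genes as rows (the Matrix Market convention
#' used by 10x-style bundles).
#'
#' @param counts Matrix-like, genes as rows. Coerced to sparse.
#' @param species One of `"human"`, `"mouse"`, `"other"`.
#' @param gene_ids,cell_ids Identifier vectors; default to the dimnames.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `counts` (dgCMatrix) and `species`.
#' @export
expression_matrix <- function(counts, species = c("human", "mouse", "other"),
                              gene_ids = rownames(counts),
                              cell_ids = colnames(counts)) {
  species <- match.arg(species)
  counts <- .as_dgc(counts)
  .assert(!is.null(gene_ids) && !is.null(cell_ids),
          "gene and cell identifiers are required")
  .assert(length(gene_ids) == nrow(counts), "gene_ids length != nrow(counts)")
  .assert(length(cell_ids) == ncol(counts), "cell_ids length != ncol(counts)")
  .assert(!anyDuplicated(gene_ids), "duplicate gene identifiers")
  .assert(!anyDuplicated(cell_ids), "duplicate cell identifiers")
  .assert(all(counts@x >= 0), "negative values in count matrix")
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, species = species),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$counts)

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s), %.1f%% nonzero\n",
              nrow(x$counts), ncol(x$counts), x$species,
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

## Accept either an ExpressionMatrix or a bare matrix everywhere downstream.
.counts <- function(x) {
  if (is(x, "ExpressionMatrix")) x$counts else .as_dgc(x)
}

#' Construct per-cell metadata with an explicit stage order
#'
#' Stage order is explicit metadata, never inferred by string sorting
#' ("e10.5" would sort before "e8.5" lexically).
#'
#' @param df Data frame with at least columns `cell_id`, `stage`, `batch`.
#' @param stage_order Character vector giving the developmental order of all
#'   observed stage labels.
#' @return The data frame with `stage` converted to an ordered factor.
#' @export
cell_meta <- function(df, stage_order) {
  .assert(all(c("cell_id", "stage", "batch") %in% names(df)),
          "cell_meta needs cell_id, stage, batch columns")
  .assert(!anyDuplicated(df$cell_id), "duplicate cell_id in metadata")
  missing <- setdiff(unique(as.character(df$stage)), stage_order)
  .assert(length(missing) == 0, "stages not in stage_order: %s",
          paste(missing, collapse = ", "))
  df$stage <- factor(as.character(df$stage), levels = stage_order, ordered = TRUE)
  df
}

#' Read a count bundle from disk
#'
#' Expects `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `cells.tsv` and
#' `stage_order.txt` (one label per line) in `directory`.
#'
#' @param directory Bundle directory.
#' @param species Species tag for the returned matrix; if `NULL`, taken from
#'   the `species` column of `cells.tsv` when unique.
#' @return A list with elements `matrix` (ExpressionMatrix) and `meta`
#'   (data frame from [cell_meta()]).
#' @export
read_counts <- function(directory, species = NULL) {
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "cells.tsv", "stage_order.txt")
  for (f in need) {
    .assert(file.exists(file.path(directory, f)), "missing %s in %s", f, directory)
  }
  m <- Matrix::readMM(file.path(directory, "matrix.mtx"))
  genes <- utils::read.delim(file.path(directory, "genes.tsv"),
                             header = FALSE, stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(file.path(directory, "barcodes.tsv"),
                                header = FALSE, stringsAsFactors = FALSE)
  .assert(nrow(genes) == nrow(m),
          "genes.tsv lists %d genes but matrix.mtx declares %d rows",
          nrow(genes), nrow(m))
  .assert(nrow(barcodes) == ncol(m),
          "barcodes.tsv lists %d cells but matrix.mtx declares %d columns",
          nrow(barcodes), ncol(m))
  .assert(!anyDuplicated(genes[[1]]), "duplicate ids in genes.tsv")
  .assert(!anyDuplicated(barcodes[[1]]), "duplicate ids in barcodes.tsv")
  cells <- utils::read.delim(file.path(directory, "cells.tsv"),
                             stringsAsFactors = FALSE)
  .assert(setequal(cells$cell_id, barcodes[[1]]),
          "cells.tsv does not cover the cells in barcodes.tsv")
  cells <- cells[match(barcodes[[1]], cells$cell_id), , drop = FALSE]
  stage_order <- readLines(file.path(directory, "stage_order.txt"))
  stage_order <- stage_order[nzchar(stage_order)]
  meta <- cell_meta(cells, stage_order)
  if (is.null(species)) {
    sp <- unique(cells$species)
    species <- if (length(sp) == 1 && sp %in% c("human", "mouse")) sp else "other"
  }
  em <- expression_matrix(m, species = species,
                          gene_ids = genes[[1]], cell_ids = barcodes[[1]])
  list(matrix = em, meta = meta)
}

#' Write a count bundle to disk
#'
#' @param em ExpressionMatrix (or bare matrix).
#' @param meta Cell metadata from [cell_meta()].
#' @param directory Output directory (created if needed).
#' @export
write_counts <- function(em, meta, directory) {
  counts <- .counts(em)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(directory, "matrix.mtx"))
  utils::write.table(data.frame(rownames(counts), rownames(counts)),
                     file.path(directory, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(directory, "barcodes.tsv"))
  utils::write.table(meta, file.path(directory, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(levels(meta$stage), file.path(directory, "stage_order.txt"))
  invisible(directory)
}

#' Read a one-to-one ortholog table
#'
#' Rows whose gene appears more than once in either column violate the
#' one-to-one contract and are dropped (all copies), with a message giving
#' the count.
#'
#' @param path TSV with two columns (gene in species A, gene in species B).
#'   A header line is detected and skipped if present.
#' @return Data frame with columns `human` and `mouse`, injective in both.
#' @export
read_ortholog_table <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  tab <- tryCatch(utils::read.delim(path, header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) NULL)
  .assert(!is.null(tab) && nrow(tab) > 0, "empty ortholog table: %s", path)
  if (identical(tolower(tab[1, 1]), "human") ||
      identical(tolower(tab[1, 1]), "gene_a")) tab <- tab[-1, , drop = FALSE]
  .assert(nrow(tab) > 0 && ncol(tab) >= 2, "ortholog table needs two columns")
  tab <- tab[, 1:2]
  names(tab) <- c("human", "mouse")
  dup <- tab$human %in% tab$human[duplicated(tab$human)] |
    tab$mouse %in% tab$mouse[duplicated(tab$mouse)]
  if (any(dup)) {
    warning(sprintf("dropped %d rows violating one-to-one orthology", sum(dup)))
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Read a GMT gene-set collection (Broad dialect)
#'
#' One set per line: name, description, then genes. Duplicate genes within a
#' line are deduplicated; duplicate set names are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors; each element carries its
#'   description as an attribute.
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    .assert(length(fields) >= 3, "GMT line %d has %d fields (need >= 3)",
            i, length(fields))
    name <- fields[[1]]
    .assert(is.null(sets[[name]]), "duplicate set name '%s' at GMT line %d",
            name, i)
    genes <- unique(fields[-(1:2)])
    attr(genes, "description") <- fields[[2]]
    sets[[name]] <- genes
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, attr(sets[[nm]], "description") %||% nm, sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
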