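#' Construct a validated gene-by-cell UMI count matrix
#'
#' A thin validator around an integer matrix with gene ids as row names and
#' cell ids as column names. Counts are whole molecules; fractional values
#' are rejected.
#'
#' @param counts numeric/integer matrix, genes in rows, cells in columns.
#' @param gene_ids,cell_ids optional id vectors; default to `dimnames(counts)`.
#' @return integer matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) && nrow(counts) > 0)
    stop("gene ids are required")
  if (is.null(cell_ids) && ncol(counts) > 0)
    stop("cell ids are required")
  gene_ids <- as.character(gene_ids %||% character())
  cell_ids <- as.character(cell_ids %||% character())
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (length(counts)) {
    if (any(is.na(counts))) stop("counts contain NA")
    if (any(counts < 0)) stop("counts must be non-negative")
    if (any(counts != round(counts))) stop("counts must be integers")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, cell_ids)
  class(counts) <- c("count_matrix", class(matrix()))
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a count matrix as tab-delimited text
#'
#' Fixed dialect for byte-reproducible outputs: UTF-8, tab separators, Unix
#' newlines, no quoting. The header row is `gene_id` followed by the cell
#' ids; one row per gene. [read_count_matrix()] round-trips the file
#' losslessly.
#'
#' @param matrix a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path) {
  m <- count_matrix(matrix)  # re-validate
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con, sep = "\n")
  if (nrow(m) > 0) {
    body <- apply(cbind(rownames(m), format(m, scientific = FALSE, trim = TRUE)),
                  1L, paste, collapse = "\t")
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path file path.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty count matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "gene_id")
    stop("line 1: header must start with 'gene_id'")
  cell_ids <- header[-1L]
  ncells <- length(cell_ids)
  if (anyDuplicated(cell_ids)) stop("line 1: duplicate cell ids")
  n <- length(lines) - 1L
  gene_ids <- character(n)
  counts <- matrix(0L, nrow = n, ncol = ncells)
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != ncells + 1L)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, ncells + 1L, length(row)))
    gene_ids[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (ncells > 0) {
      if (any(is.na(vals)) || any(vals != round(vals)))
        stop(sprintf("line %d: non-integer count", i + 1L))
      if (any(vals < 0))
        stop(sprintf("line %d: negative count", i + 1L))
      counts[i, ] <- as.integer(vals)
    }
  }
  if (anyDuplicated(gene_ids)) {
    dup <- which(duplicated(gene_ids))[1L]
    stop(sprintf("line %d: duplicated gene id '%s'", dup + 1L, gene_ids[dup]))
  }
  count_matrix(counts, gene_ids, cell_ids)
}

#' Bundle cells, gene annotations and the count matrix of one run
#'
#' The experiment container every pipeline stage reads and appends to: a cell
#' annotation table (one row per well/cell, accumulating per-stage file paths
#' and QC metrics), a gene annotation table, and optionally the UMI count
#' matrix. When the matrix is present its row/column ids must match the
#' annotation tables exactly.
#'
#' @param cells data.frame with at least columns `cell_id`, `experiment_id`,
#'   `barcode`; `cell_id` must be unique.
#' @param genes data.frame with at least columns `gene_id`, `gene_name`,
#'   `biotype`, `is_spike_in`; `gene_id` must be unique.
#' @param matrix optional [count_matrix()].
#' @return An object of class `experiment_set`.
#' @export
experiment_set <- function(cells, genes = NULL, matrix = NULL) {
  cells <- as.data.frame(cells)
  need <- c("cell_id", "experiment_id", "barcode")
  if (!all(need %in% names(cells)))
    stop("cells table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id in cells table")
  if (!is.null(genes)) {
    genes <- as.data.frame(genes)
    if (!"gene_id" %in% names(genes)) stop("genes table needs a gene_id column")
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in genes table")
  }
  if (!is.null(matrix)) {
    matrix <- count_matrix(matrix)
    if (!identical(colnames(matrix), as.character(cells$cell_id)))
      stop("matrix cell ids do not match the cells table")
    if (is.null(genes))
      stop("a matrix requires a genes table")
    if (!identical(rownames(matrix), as.character(genes$gene_id)))
      stop("matrix gene ids do not match the genes table")
  }
  structure(list(cells = cells, genes = genes, matrix = matrix),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("experiment_set: %d cells, %d genes, matrix %s\n",
              nrow(x$cells), if (is.null(x$genes)) 0L else nrow(x$genes),
              if (is.null(x$matrix)) "absent" else "present"))
  invisible(x)
}

#' Serialize an experiment set to a directory of TSV files
#'
#' Writes `cells.tsv`, `genes.tsv` and (if present) `counts.tsv` under `dir`.
#'
#' @param es an [experiment_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_set <- function(es, dir) {
  stopifnot(inherits(es, "experiment_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, path)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(es$cells, file.path(dir, "cells.tsv"))
  if (!is.null(es$genes)) write_tsv(es$genes, file.path(dir, "genes.tsv"))
  if (!is.null(es$matrix))
    write_count_matrix(es$matrix, file.path(dir, "counts.tsv"))
  invisible(dir)
}
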