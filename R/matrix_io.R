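#' Construct a validated expression matrix
#'
#' The package's central container: a nonnegative genes-by-cells matrix with
#' unique gene and cell identifiers. All clustering functions consume this
#' type; values are kept exactly as supplied (any normalisation is the
#' caller's choice and should happen before construction).
#'
#' @param values numeric matrix, genes in rows, cells in columns; all entries
#'   must be finite and >= 0.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)` (or `gene_1, gene_2, ...` when absent).
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `colnames(values)` (or `cell_1, cell_2, ...` when absent).
#' @return an object of class `expression_matrix` with fields `values`,
#'   `gene_ids`, `cell_ids`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (length(cell_ids) != ncol(values))
    stop("length(cell_ids) must equal ncol(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:min(3, sum(duplicated(gene_ids)))],
               collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)])[1:min(3, sum(duplicated(cell_ids)))],
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (any(values < 0))
    stop("expression values must be nonnegative; found ", min(values))
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells\n",
              length(x$gene_ids), length(x$cell_ids)))
  invisible(x)
}

#' Number of cells / genes in an expression matrix
#' @param E an `expression_matrix`.
#' @return integer count.
#' @export
n_cells <- function(E) length(E$cell_ids)

#' @rdname n_cells
#' @export
n_genes <- function(E) length(E$gene_ids)

# column subset preserving validation invariants
subset_cells <- function(E, cells) {
  expression_matrix(E$values[, cells, drop = FALSE])
}

#' Read an expression matrix from disk
#'
#' Supported layouts: dense delimited text (first row of cell ids, first
#' column of gene ids) and the Matrix Market triplet convention with
#' `genes.tsv` / `barcodes.tsv` side files (10x CellRanger v1/v2 layout; pass
#' the directory or the `.mtx` file). Orientation is normalised to genes in
#' rows regardless of the on-disk layout via `genes_as`.
#'
#' @param path file (csv/tsv/mtx) or directory (mtx10x) to read.
#' @param format one of `"csv"`, `"tsv"`, `"mtx10x"`.
#' @param genes_as `"rows"` if the on-disk matrix stores genes in rows,
#'   `"columns"` if it is transposed (ignored for mtx10x, which is always
#'   genes x cells).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("csv", "tsv", "mtx10x"),
                            genes_as = c("rows", "columns")) {
  format <- match.arg(format)
  genes_as <- match.arg(genes_as)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (format == "mtx10x") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(dir, "matrix.mtx") else path
    genes_f <- file.path(dir, "genes.tsv")
    barcodes_f <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, genes_f, barcodes_f))
      if (!file.exists(f)) stop("mtx10x layout incomplete, missing: ", f)
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("failed to parse ", mtx, ": ",
                                           conditionMessage(e)))
    genes <- read.delim(genes_f, header = FALSE,
                        colClasses = "character")[[1L]]
    barcodes <- read.delim(barcodes_f, header = FALSE,
                           colClasses = "character")[[1L]]
    if (length(genes) != nrow(m))
      stop("genes.tsv has ", length(genes), " entries but matrix has ",
           nrow(m), " rows")
    if (length(barcodes) != ncol(m))
      stop("barcodes.tsv has ", length(barcodes), " entries but matrix has ",
           ncol(m), " columns")
    return(expression_matrix(as.matrix(m), genes, barcodes))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 2) stop("failed to parse ", path, ": fewer than 2 columns")
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  not_num <- !vapply(vals, is.numeric, logical(1))
  if (any(not_num))
    stop("non-numeric values in column(s): ",
         paste(colnames(vals)[not_num], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (genes_as == "columns") m <- t(m)
  expression_matrix(m)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()] for the dense dialect: first row of cell
#' ids, first column of gene ids.
#'
#' @param E an [expression_matrix()].
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_expression <- function(E, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene_id = E$gene_ids, E$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", E$cell_ids)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clustering result as a tab-separated table
#'
#' Columns: `cell_id`, `cluster_label`, `iteration_found`. Re-reading with
#' [read_partition()] reproduces the mapping exactly.
#'
#' @param partition a `cell_partition` (see [iterate_clusters()]) or a named
#'   vector of cluster labels.
#' @param path output file.
#' @export
write_partition <- function(partition, path) {
  labels <- partition_labels(partition)
  if (length(labels) == 0) stop("partition is empty")
  iter <- if (inherits(partition, "cell_partition")) {
    unname(partition$iteration_found[as.character(labels)])
  } else rep(NA_integer_, length(labels))
  df <- data.frame(cell_id = names(labels),
                   cluster_label = unname(labels),
                   iteration_found = iter,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clustering result written by [write_partition()]
#'
#' @param path file to read.
#' @return a `cell_partition` object.
#' @export
read_partition <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cluster_label", "iteration_found")
  if (!all(need %in% colnames(df)))
    stop("failed to parse ", path, ": expected columns ",
         paste(need, collapse = ", "))
  labels <- df$cluster_label
  names(labels) <- df$cell_id
  first <- !duplicated(df$cluster_label)
  iter <- as.integer(df$iteration_found[first])
  names(iter) <- as.character(df$cluster_label[first])
  cell_partition(labels, iteration_found = iter)
}

# internal constructor for partitions
cell_partition <- function(labels, iteration_found = NULL,
                           merged_from = NULL, trace = NULL) {
  stopifnot(!is.null(names(labels)), !anyDuplicated(names(labels)))
  if (is.null(iteration_found)) {
    iteration_found <- rep(1L, length(unique(labels)))
    names(iteration_found) <- as.character(sort(unique(labels)))
  }
  structure(list(labels = labels,
                 iteration_found = iteration_found,
                 merged_from = merged_from,
                 trace = trace),
            class = "cell_partition")
}

#' Extract the cell -> cluster label vector from a partition
#' @param partition a `cell_partition` or a named label vector.
#' @return named vector of cluster labels.
#' @export
partition_labels <- function(partition) {
  if (inherits(partition, "cell_partition")) partition$labels else partition
}

#' @export
print.cell_partition <- function(x, ...) {
  k <- length(unique(x$labels))
  cat(sprintf("cell_partition: %d cells in %d clusters\n",
              length(x$labels), k))
  print(table(cluster = x$labels))
  invisible(x)
}
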