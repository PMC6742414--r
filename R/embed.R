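#' Project cells onto their top three principal components
#'
#' Computes exact scores of the cells on the first three principal components
#' of the cells-by-variable-genes submatrix (genes are centred; no variance
#' scaling by default, so Euclidean distances between score rows reflect the
#' centred expression geometry the density clustering operates on). Scores
#' are obtained from the eigendecomposition of the cell Gram matrix, which is
#' exact and cheap when genes outnumber cells.
#'
#' Component signs are fixed so the entry of largest magnitude in each score
#' column is positive; downstream clustering uses Euclidean distances only
#' and is sign-invariant regardless.
#'
#' @param E an [expression_matrix()].
#' @param variable_genes integer indices of the genes to embed on (at least
#'   3); typically from [select_variable_genes()].
#' @param scale_genes `"none"` (default) or `"unit"` to scale genes to unit
#'   variance before the decomposition.
#' @return an N x 3 numeric matrix of component scores with cell ids as row
#'   names; column variances are non-increasing.
#' @export
pca3 <- function(E, variable_genes, scale_genes = c("none", "unit")) {
  scale_genes <- match.arg(scale_genes)
  nc <- n_cells(E)
  if (nc < 4)
    stop("degenerate input: need at least 4 cells for a 3-D embedding")
  if (length(variable_genes) < 3)
    stop("degenerate input: need at least 3 variable genes")
  X <- t(E$values[variable_genes, , drop = FALSE])   # cells x genes
  X <- scale(X, center = TRUE, scale = FALSE)
  if (scale_genes == "unit") {
    sds <- sqrt(colSums(X^2) / max(1L, nrow(X) - 1L))
    sds[sds == 0] <- 1
    X <- sweep(X, 2L, sds, "/")
  }
  G <- tcrossprod(X)                                 # cells x cells Gram
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values[1:3], 0)
  coords <- sweep(eg$vectors[, 1:3, drop = FALSE], 2L, sqrt(ev), "*")
  for (j in 1:3) {                                   # deterministic signs
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- E$cell_ids
  colnames(coords) <- paste0("PC", 1:3)
  coords
}
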