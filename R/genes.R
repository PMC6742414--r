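#' Select variable genes by binned dispersion z-score
#'
#' Genes are grouped into `n_bins` equal-count bins on mean expression, the
#' dispersion (variance / mean) of each gene is z-normalised within its bin,
#' and genes whose z-score exceeds `zscore_cut` and whose mean expression is
#' at least `gene_low` are returned. The iterative engine recomputes this set
#' on the remaining cells at every iteration, so the PCA subspace evolves as
#' clusters are extracted.
#'
#' Genes with mean expression 0 have undefined dispersion and are dropped
#' before binning. When fewer than `n_bins` genes remain, the bin count
#' shrinks to the number of eligible genes. The within-bin standard deviation
#' uses the population (n) denominator; a single-gene bin gets z = 0.
#'
#' @param E an [expression_matrix()].
#' @param zscore_cut dispersion z-score threshold (default 1.5).
#' @param gene_low minimum mean expression, in the units of `E` (default 0.5);
#'   lower-expressed genes are excluded however dispersed.
#' @param n_bins number of mean-expression bins (default 20).
#' @param log_transform apply `log1p` before computing means and dispersions.
#' @return increasing integer vector of selected gene indices (possibly
#'   empty, which signals the iterative engine to stop).
#' @export
select_variable_genes <- function(E, zscore_cut = 1.5, gene_low = 0.5,
                                  n_bins = 20, log_transform = FALSE) {
  x <- E$values
  if (ncol(x) == 0) stop("expression matrix has zero cells")
  if (log_transform) x <- log1p(x)
  nc <- ncol(x)
  mu <- rowMeans(x)
  eligible <- which(mu > 0)
  if (length(eligible) == 0) return(integer(0))
  xs <- x[eligible, , drop = FALSE]
  vr <- rowSums((xs - mu[eligible])^2) / max(1L, nc - 1L)
  disp <- vr / mu[eligible]

  nb <- min(n_bins, length(eligible))
  ord <- order(mu[eligible], seq_along(eligible))   # ties broken by gene order
  bin <- integer(length(eligible))
  bin[ord] <- ceiling(seq_along(ord) * nb / length(ord))

  z <- numeric(length(eligible))
  for (b in unique(bin)) {
    idx <- bin == b
    m <- mean(disp[idx])
    s <- sqrt(mean((disp[idx] - m)^2))              # population denominator
    z[idx] <- if (s > 0) (disp[idx] - m) / s else 0
  }
  sort(unname(eligible[z > zscore_cut & mu[eligible] >= gene_low]))
}
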