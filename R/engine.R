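#' Parameters for the full iterative clustering pipeline
#'
#' The eight user-facing knobs with their defaults, plus the dialect
#' switches recorded by the package.
#'
#' @param zscore dispersion z-score cut for variable genes (default 1.5).
#' @param gene_low minimum mean expression for variable genes (default 0.5).
#' @param gini Gini-index threshold on cluster-variance inequality; the
#'   iteration continues while any prefix Gini exceeds it (default 0.05,
#'   must lie in (0, 1)).
#' @param bc,bg,maxbb,cell_number density-clustering knobs; see
#'   [hull_params()].
#' @param fclust_height dendrogram merge threshold (default 0.20). Under the
#'   default `"absolute"` height mode this is a correlation-distance cut:
#'   clusters whose centroids join below it (centroid correlation above
#'   1 - `fclust_height`) merge. Under `"relative"` it is a fraction of the
#'   maximum merge height.
#' @param merge_height `"absolute"` (default) or `"relative"`; see
#'   [merge_clusters()].
#' @param log_transform log1p-transform values for variable-gene selection.
#' @param scale_genes gene scaling before PCA; see [pca3()].
#' @param quality_gene_space compute cluster variances on the `"variable"`
#'   gene submatrix of the current iteration (default) or on `"all"` genes.
#' @param radius_convention see [hull_params()].
#' @return a list of validated parameters, class `hullclust_params`.
#' @export
hullclust_params <- function(zscore = 1.5, gene_low = 0.5, gini = 0.05,
                             bc = 20, bg = 20, maxbb = 20, cell_number = 1000,
                             fclust_height = 0.20, log_transform = FALSE,
                             merge_height = c("absolute", "relative"),
                             scale_genes = c("none", "unit"),
                             quality_gene_space = c("variable", "all"),
                             radius_convention = c("range", "max")) {
  if (!is.finite(zscore)) stop("`zscore` must be finite")
  if (gene_low < 0) stop("`gene_low` must be >= 0")
  if (gini <= 0 || gini >= 1) stop("`gini` must lie in (0, 1)")
  if (fclust_height <= 0 || fclust_height > 2)
    stop("`fclust_height` must lie in (0, 2]")
  structure(list(zscore = zscore, gene_low = gene_low, gini = gini,
                 hull = hull_params(bc = bc, bg = bg, maxbb = maxbb,
                                    cell_number = cell_number,
                                    radius_convention =
                                      match.arg(radius_convention)),
                 fclust_height = fclust_height,
                 merge_height = match.arg(merge_height),
                 log_transform = isTRUE(log_transform),
                 scale_genes = match.arg(scale_genes),
                 quality_gene_space = match.arg(quality_gene_space)),
            class = "hullclust_params")
}

#' Correlation distance between two expression vectors
#'
#' One minus the Pearson correlation; ranges over \[0, 2\] with 0 for
#' identical profiles and 2 for perfectly anti-correlated ones.
#'
#' @param v,w numeric vectors of equal length >= 2, neither constant.
#' @return scalar in \[0, 2\].
#' @export
correlation_distance <- function(v, w) {
  if (length(v) != length(w)) stop("vectors must have equal length")
  if (length(v) < 2) stop("vectors must have length >= 2")
  cv <- v - mean(v)
  cw <- w - mean(w)
  nv <- sqrt(sum(cv^2))
  nw <- sqrt(sum(cw^2))
  if (nv == 0 || nw == 0)
    stop("correlation distance undefined for a constant vector")
  1 - sum(cv * cw) / (nv * nw)
}

#' Gini index of inequality over a set of cluster variances
#'
#' Mean absolute difference over all ordered pairs divided by twice the
#' mean: sum_ij |s_i - s_j| / (2 n^2 mu). Zero means all variances equal;
#' values below the engine's threshold signal that the remaining clusters
#' are comparably tight. When every variance is zero the index is defined
#' as 0 (perfect equality).
#'
#' @param variances numeric vector of >= 2 nonnegative values.
#' @return scalar in \[0, 1).
#' @export
gini_index <- function(variances) {
  if (length(variances) < 2) stop("need at least 2 variances")
  if (any(variances < 0)) stop("variances must be nonnegative")
  mu <- mean(variances)
  if (mu == 0) return(0)
  n <- length(variances)
  sum(abs(outer(variances, variances, "-"))) / (2 * n^2 * mu)
}

#' Per-cluster variance of within-cluster correlation distances
#'
#' For each cluster, the pairwise correlation distances between its member
#' cells are computed on the supplied gene space and their (sample) variance
#' taken. Singleton clusters have no pairs and get variance 0 (maximally
#' tight) by convention; a constant expression profile contributes distance
#' 1 to its pairs.
#'
#' @param values numeric genes x cells matrix (typically the variable-gene
#'   submatrix of the current iteration).
#' @param labels integer cluster labels, one per column of `values`.
#' @return numeric vector of variances indexed by cluster label 1..K.
#' @export
cluster_distance_variances <- function(values, labels) {
  stopifnot(ncol(values) == length(labels))
  ks <- sort(unique(labels))
  out <- numeric(length(ks))
  for (i in seq_along(ks)) {
    idx <- which(labels == ks[i])
    if (length(idx) < 2) { out[i] <- 0; next }
    cc <- suppressWarnings(stats::cor(values[, idx, drop = FALSE]))
    d <- 1 - cc
    d[is.na(d)] <- 1                  # constant profiles: distance 1
    v <- stats::var(d[upper.tri(d)])
    out[i] <- if (is.na(v)) 0 else v  # a single pair has no spread
  }
  names(out) <- ks
  out
}

#' Decide whether an iteration yields a mature cluster
#'
#' Clusters are ranked by variance in descending order and the Gini index is
#' computed over every top-i prefix (i = 2..n). If any prefix index exceeds
#' the threshold the clusters are unequal: the minimum-variance cluster is
#' "mature" and is extracted. If all prefix indices are at or below the
#' threshold (or there is a single cluster) the iteration stops and every
#' current cluster is final. Equality at the threshold counts as below it.
#'
#' @param variances per-cluster variances from
#'   [cluster_distance_variances()].
#' @param gini_threshold threshold in (0, 1) (default 0.05).
#' @return list with `action` (`"continue"` or `"stop"`), `mature` (label of
#'   the minimum-variance cluster when continuing; ties go to the smallest
#'   label) and `gini` (the prefix index sequence).
#' @export
select_mature <- function(variances, gini_threshold = 0.05) {
  n <- length(variances)
  if (n == 0) stop("need at least one cluster")
  if (n == 1) return(list(action = "stop", mature = NA_integer_,
                          gini = numeric(0)))
  ord <- order(variances, decreasing = TRUE)
  g <- vapply(2:n, function(i) gini_index(variances[ord[seq_len(i)]]),
              numeric(1))
  if (any(g > gini_threshold)) {
    list(action = "continue", mature = which.min(variances), gini = g)
  } else {
    list(action = "stop", mature = NA_integer_, gini = g)
  }
}

#' Iterative cluster search over evolving PCA subspaces
#'
#' The outer loop: select variable genes on the remaining cells, embed them
#' on the top three principal components, cluster with the convex-hull
#' density walk, and evaluate cluster-variance inequality with the Gini
#' index. While the clusters are unequal the tightest one is frozen as
#' "mature", its cells are removed, and everything (variable genes, PCA
#' subspace, clustering) is recomputed on the remainder. The output is the
#' union of the mature clusters and the final iteration's cluster set.
#' Residues too small to embed (fewer than 4 cells, or fewer than 3 variable
#' genes) become one terminal cluster.
#'
#' @param E an [expression_matrix()].
#' @param params a [hullclust_params()] object.
#' @return a `cell_partition` with per-cluster `iteration_found` and an
#'   iteration `trace` data frame (cells, variable genes, clusters, chosen
#'   bin size, mature-cluster size, max prefix Gini).
#' @export
iterate_clusters <- function(E, params = hullclust_params()) {
  stopifnot(inherits(E, "expression_matrix"))
  if (n_cells(E) < 4) stop("need at least 4 cells")

  active <- E$cell_ids
  labels <- integer(0)
  iteration_found <- integer(0)
  trace <- list()
  it <- 1L
  next_label <- 1L

  add_cluster <- function(cells, iter) {
    lab <- next_label
    labels[cells] <<- lab
    iteration_found[as.character(lab)] <<- iter
    next_label <<- next_label + 1L
    lab
  }

  repeat {
    nc <- length(active)
    if (nc == 0) break
    Ei <- subset_cells(E, active)
    vg <- if (nc >= 4) {
      select_variable_genes(Ei, zscore_cut = params$zscore,
                            gene_low = params$gene_low,
                            log_transform = params$log_transform)
    } else integer(0)
    if (nc < 4 || length(vg) < 3) {       # terminal residue
      add_cluster(active, it)
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = it, n_cells = nc, n_var_genes = length(vg),
        n_clusters = 1L, bg_used = NA_integer_, mature_size = NA_integer_,
        max_gini = NA_real_, action = "terminal")
      break
    }

    pts <- pca3(Ei, vg, scale_genes = params$scale_genes)
    cl <- hull_cluster(pts, params$hull)
    qspace <- if (params$quality_gene_space == "variable") {
      Ei$values[vg, , drop = FALSE]
    } else Ei$values
    vars <- cluster_distance_variances(qspace, cl)
    dec <- select_mature(vars, params$gini)

    if (dec$action == "stop") {
      for (k in sort(unique(cl))) add_cluster(active[cl == k], it)
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = it, n_cells = nc, n_var_genes = length(vg),
        n_clusters = length(unique(cl)),
        bg_used = attr(cl, "bg_used"), mature_size = NA_integer_,
        max_gini = if (length(dec$gini)) max(dec$gini) else NA_real_,
        action = "stop")
      break
    }

    ml <- dec$mature
    mature_cells <- active[cl == ml]
    add_cluster(mature_cells, it)
    trace[[length(trace) + 1L]] <- data.frame(
      iteration = it, n_cells = nc, n_var_genes = length(vg),
      n_clusters = length(unique(cl)), bg_used = attr(cl, "bg_used"),
      mature_size = length(mature_cells), max_gini = max(dec$gini),
      action = "continue")
    active <- setdiff(active, mature_cells)
    it <- it + 1L
  }

  labels <- labels[E$cell_ids]
  names(labels) <- E$cell_ids
  cell_partition(labels, iteration_found = iteration_found,
                 trace = do.call(rbind, trace))
}

#' Merge similar clusters on a centroid dendrogram
#'
#' Builds an average-linkage dendrogram over cluster centroids (mean
#' expression profiles) using correlation distance and merges clusters whose
#' merge height falls below the threshold. Under the default `"absolute"`
#' mode the dendrogram is cut at `fclust_height` correlation-distance units
#' (0.20 means centroids correlating above 0.8 merge), which also collapses
#' the fragments of a homogeneous population; under `"relative"` the cut is
#' `fclust_height` times the maximum merge height, making the threshold
#' scale-free per dendrogram. A single cluster is returned unchanged.
#'
#' @param E the [expression_matrix()] the partition was computed on (used
#'   for centroids, full gene space).
#' @param partition a `cell_partition` from [iterate_clusters()].
#' @param fclust_height merge threshold (default 0.20); units depend on
#'   `height_mode`.
#' @param height_mode `"absolute"` (default) or `"relative"`.
#' @return a `cell_partition` with labels renumbered 1..K', provenance in
#'   `merged_from`, and `iteration_found` inherited as the minimum over the
#'   merged clusters.
#' @export
merge_clusters <- function(E, partition, fclust_height = 0.20,
                           height_mode = c("absolute", "relative")) {
  height_mode <- match.arg(height_mode)
  stopifnot(inherits(partition, "cell_partition"))
  labs <- partition$labels
  ks <- sort(unique(labs))
  if (length(ks) < 2) return(partition)

  cent <- vapply(ks, function(k) {
    rowMeans(E$values[, names(labs)[labs == k], drop = FALSE])
  }, numeric(n_genes(E)))
  cc <- suppressWarnings(stats::cor(cent))
  d <- 1 - cc
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cut_h <- if (height_mode == "absolute") fclust_height
           else fclust_height * max(hc$height)
  grp <- stats::cutree(hc, h = cut_h)

  new_labels <- grp[match(labs, ks)]
  names(new_labels) <- names(labs)
  merged_from <- split(ks, grp)
  names(merged_from) <- seq_along(merged_from)
  iter <- vapply(merged_from, function(old) {
    min(partition$iteration_found[as.character(old)])
  }, numeric(1))
  iter <- as.integer(iter)
  names(iter) <- names(merged_from)
  cell_partition(new_labels, iteration_found = iter,
                 merged_from = merged_from, trace = partition$trace)
}

#' Full clustering pipeline: iterative search plus dendrogram merge
#'
#' Runs [iterate_clusters()] and then [merge_clusters()] with the package
#' defaults; this is the partition all benchmarks score.
#'
#' @param E an [expression_matrix()].
#' @param params a [hullclust_params()] object.
#' @return a `cell_partition` (see [iterate_clusters()]).
#' @export
hullclust <- function(E, params = hullclust_params()) {
  merge_clusters(E, iterate_clusters(E, params), params$fclust_height,
                 params$merge_height)
}
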