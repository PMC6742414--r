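# Synthetic data: isotropic Gaussian clusters in high-dimensional gene
# space, mimicking the make_blobs-style generator the benchmarks are built
# on. These blobs are deliberately idealised -- no dropout, library-size
# variation or count noise -- so they probe the clustering geometry, not
# scRNA-seq measurement noise.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration of one Gaussian-blob dataset
#'
#' Defaults are the benchmark study conditions: 500 cells, 20,000 genes,
#' cluster centres drawn uniformly from (-10, 10) per gene, cells dispersed
#' isotropically around their centre, and the whole matrix affinely rescaled
#' to the range 0..10,000.
#'
#' @param n_centers number of clusters (>= 2).
#' @param cluster_sd within-cluster standard deviation per gene.
#' @param n_cells,n_genes matrix dimensions.
#' @param center_box interval the centre coordinates are drawn from.
#' @param seed integer seed making the dataset reproducible.
#' @return a list of class `blob_config`.
#' @export
blob_config <- function(n_centers, cluster_sd = 1, n_cells = 500,
                        n_genes = 20000, center_box = c(-10, 10), seed = 0) {
  if (n_centers < 2) stop("`n_centers` must be >= 2")
  if (cluster_sd <= 0) stop("`cluster_sd` must be positive")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_centers = as.integer(n_centers),
                 cluster_sd = cluster_sd,
                 center_box = center_box,
                 seed = as.integer(seed)),
            class = "blob_config")
}

#' Configuration of one rare-cell dataset
#'
#' A blob dataset (SD 1 by default) in which one randomly chosen cluster is
#' down-sampled to `rare_keep_fraction` of its members, defining the rare
#' subpopulation (about 0.6%--3% of the 500 cells for 3--15 centres).
#'
#' @param n_centers number of clusters before down-sampling (3..15 in the
#'   benchmark sweep).
#' @param seed seed of the underlying blob dataset.
#' @param choice_seed seed governing which cluster is rare and which of its
#'   cells are removed (defaults to a fixed offset of `seed`).
#' @param rare_keep_fraction fraction of the chosen cluster kept
#'   (default 0.10); the number removed is `floor(0.9 * size)`.
#' @param cluster_sd,n_cells,n_genes,center_box see [blob_config()].
#' @return a list of class `rare_config` with fields `base` (a
#'   `blob_config`), `rare_keep_fraction`, `choice_seed`.
#' @export
rare_config <- function(n_centers, seed = 0, choice_seed = seed + 500009L,
                        rare_keep_fraction = 0.10, cluster_sd = 1,
                        n_cells = 500, n_genes = 20000,
                        center_box = c(-10, 10)) {
  if (rare_keep_fraction <= 0 || rare_keep_fraction >= 1)
    stop("`rare_keep_fraction` must lie in (0, 1)")
  structure(list(base = blob_config(n_centers, cluster_sd = cluster_sd,
                                    n_cells = n_cells, n_genes = n_genes,
                                    center_box = center_box, seed = seed),
                 rare_keep_fraction = rare_keep_fraction,
                 choice_seed = as.integer(choice_seed)),
            class = "rare_config")
}

#' Generate one Gaussian-blob expression dataset
#'
#' Cells are split as evenly as possible across `n_centers` isotropic
#' Gaussian clusters around uniformly drawn centres, the cell order is
#' shuffled, and the matrix is affinely rescaled to span 0..10,000 (a single
#' global min-max transform; disable with `rescale = FALSE` to inspect raw
#' blob coordinates).
#'
#' @param cfg a [blob_config()].
#' @param rescale rescale values to the 0..10,000 range (default TRUE). When
#'   FALSE the raw blob coordinates are kept up to a global translation to
#'   zero minimum (distances and cluster geometry unchanged), which is
#'   convenient for inspecting the generator's geometry directly.
#' @return list with `matrix` (an [expression_matrix()]) and `labels`
#'   (integer ground-truth labels named by cell id).
#' @export
generate_blobs <- function(cfg, rescale = TRUE) {
  stopifnot(inherits(cfg, "blob_config"))
  with_seed(cfg$seed, {
    k <- cfg$n_centers
    centers <- matrix(runif(k * cfg$n_genes, cfg$center_box[1],
                            cfg$center_box[2]), nrow = k)
    sizes <- rep(cfg$n_cells %/% k, k)
    extra <- cfg$n_cells %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    labels <- rep(seq_len(k), sizes)
    X <- centers[labels, , drop = FALSE] +
      matrix(rnorm(cfg$n_cells * cfg$n_genes, sd = cfg$cluster_sd),
             nrow = cfg$n_cells)
    shuf <- sample.int(cfg$n_cells)
    X <- X[shuf, , drop = FALSE]
    labels <- labels[shuf]
    rng <- range(X)
    X <- if (rescale) {
      (X - rng[1]) / (rng[2] - rng[1]) * 10000
    } else {
      X - rng[1]      # translation only: raw blob geometry, nonnegative
    }
    cell_ids <- sprintf("cell_%04d", seq_len(cfg$n_cells))
    gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
    names(labels) <- cell_ids
    E <- expression_matrix(t(X), gene_ids, cell_ids)
    list(matrix = E, labels = labels)
  })
}

#' Generate one rare-cell dataset
#'
#' Generates the underlying blob dataset, then deletes `floor(0.9 * size)`
#' uniformly chosen cells from one randomly picked cluster, which becomes
#' the ground-truth rare subpopulation.
#'
#' @param cfg a [rare_config()].
#' @return list with `matrix`, `labels` (truth labels of the remaining
#'   cells) and `rare_label` (the down-sampled cluster's label).
#' @export
generate_rare <- function(cfg) {
  stopifnot(inherits(cfg, "rare_config"))
  blobs <- generate_blobs(cfg$base)
  with_seed(cfg$choice_seed, {
    rare <- sample.int(cfg$base$n_centers, 1L)
    in_rare <- which(blobs$labels == rare)
    if (length(in_rare) == 0) stop("chosen cluster is empty")
    n_remove <- floor((1 - cfg$rare_keep_fraction) * length(in_rare))
    drop_idx <- if (n_remove > 0) sample(in_rare, n_remove) else integer(0)
    if (length(in_rare) - n_remove < 1)
      stop("rare cluster would be empty after down-sampling")
    keep <- setdiff(seq_along(blobs$labels), drop_idx)
    list(matrix = subset_cells(blobs$matrix, keep),
         labels = blobs$labels[keep],
         rare_label = rare)
  })
}

#' The main benchmark sweep of blob configurations
#'
#' All combinations of 3..22 centres and within-cluster SD 0.5, 1 and 2,
#' with `reps` replicate datasets per combination: 20 x 3 x 20 = 1,200
#' configurations at the defaults. Every configuration carries a distinct
#' seed derived from `seed_base`.
#'
#' @param reps replicate datasets per (centres, SD) combination
#'   (default 20).
#' @param seed_base offset added to every derived seed, so independent
#'   sweeps can be replayed.
#' @return list of [blob_config()] objects.
#' @export
sweep_blobs <- function(reps = 20, seed_base = 0) {
  grid <- expand.grid(rep = seq_len(reps) - 1L,
                      n_centers = 3:22,
                      cluster_sd = c(0.5, 1, 2))
  combo <- (match(grid$cluster_sd, c(0.5, 1, 2)) - 1L) * 20L +
    (grid$n_centers - 3L)
  lapply(seq_len(nrow(grid)), function(i) {
    blob_config(n_centers = grid$n_centers[i],
                cluster_sd = grid$cluster_sd[i],
                seed = seed_base + combo[i] * reps + grid$rep[i])
  })
}

#' The rare-cell benchmark sweep
#'
#' 3..15 centres, within-cluster SD fixed at 1, `reps` replicate datasets
#' per centre count: 13 x 20 = 260 configurations at the defaults, each with
#' a distinct seed derived from `seed_base`.
#'
#' @param reps replicate datasets per centre count (default 20).
#' @param seed_base offset added to every derived seed.
#' @return list of [rare_config()] objects.
#' @export
sweep_rare <- function(reps = 20, seed_base = 0) {
  grid <- expand.grid(rep = seq_len(reps) - 1L, n_centers = 3:15)
  lapply(seq_len(nrow(grid)), function(i) {
    s <- seed_base + (grid$n_centers[i] - 3L) * reps + grid$rep[i]
    rare_config(n_centers = grid$n_centers[i], seed = s,
                choice_seed = s + 500009L)
  })
}
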