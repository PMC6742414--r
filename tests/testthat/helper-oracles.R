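# Independent oracles and small fixture builders shared across tests.

# Pair-counting Adjusted Rand Index: classify every pair of items as
# together/apart in each labeling and use the closed form on the four pair
# counts. Independent of the contingency-table implementation in the package.
ari_pair_counting <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  num <- 2 * (n00 * n11 - n01 * n10)
  den <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (den == 0) return(1)
  num / den
}

# Brute-force neighbour counts from the full distance matrix.
neighbor_counts_oracle <- function(points, radius) {
  D <- as.matrix(dist(points))
  as.integer(rowSums(D <= radius) - 1L)
}

# Well-separated isotropic Gaussian blobs in d dimensions: centres on a
# scaled simplex-ish layout so separation / sd is controlled exactly.
make_point_blobs <- function(k, n_per, d = 3, sd = 1, sep = 20, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), nrow = k)
  if (k > 1) {
    cd <- as.matrix(dist(centers))
    centers <- centers * sep * sd / min(cd[cd > 0])
  }
  pts <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * d, sd = sd), ncol = d), 2, centers[i, ], "+")
  }))
  rownames(pts) <- sprintf("p%03d", seq_len(nrow(pts)))
  list(points = pts, labels = rep(seq_len(k), each = n_per))
}

# Small expression fixture: k well-separated clusters in gene space.
make_expression_blobs <- function(k = 3, n_per = 30, n_genes = 300,
                                  sd = 0.5, seed = 1) {
  generate_blobs(blob_config(n_centers = k, cluster_sd = sd,
                             n_cells = k * n_per, n_genes = n_genes,
                             seed = seed))
}

# Is every point of `pts` inside the 2-D convex hull with the given vertex
# coordinates? Sign test against each hull edge (counter-clockwise order
# from grDevices::chull).
points_in_hull_2d <- function(pts, hull_xy) {
  hull_xy <- hull_xy[rev(seq_len(nrow(hull_xy))), , drop = FALSE] # ccw
  nh <- nrow(hull_xy)
  tol <- 1e-9 * max(abs(hull_xy))
  ok <- rep(TRUE, nrow(pts))
  for (e in seq_len(nh)) {
    a <- hull_xy[e, ]
    b <- hull_xy[if (e == nh) 1 else e + 1, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
      (b[2] - a[2]) * (pts[, 1] - a[1])
    ok <- ok & (cross >= -tol)
  }
  ok
}
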