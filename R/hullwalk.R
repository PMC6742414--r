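#' Parameters for the convex-hull density clustering
#'
#' @param bc number of bins for the pairwise-distance histogram whose bin
#'   interval defines the neighbourhood radius (default 20).
#' @param bg number of bins for the distance-to-peak histograms that seed
#'   each group's first convex hull (default 20; on point sets smaller than
#'   `cell_number` this is replaced by the saturation scan of
#'   [optimize_bin_size()]).
#' @param bg_step increment of the saturation scan (fixed at 5).
#' @param maxbb number of scan steps, so the bin-size ceiling is
#'   `bg_step * maxbb` = 100 (default 20).
#' @param cell_number point-count threshold above which the saturation scan
#'   is skipped and `bg` used as-is (default 1000).
#' @param radius_convention `"range"` (default) sets the neighbourhood radius
#'   to (max - min pairwise distance) / `bc`, the observed-range histogram
#'   bin width; `"max"` uses max distance / `bc`.
#' @return a list of validated parameters, class `hull_params`.
#' @export
hull_params <- function(bc = 20, bg = 20, bg_step = 5, maxbb = 20,
                        cell_number = 1000,
                        radius_convention = c("range", "max")) {
  radius_convention <- match.arg(radius_convention)
  for (nm in c("bc", "bg", "bg_step", "maxbb", "cell_number")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("`", nm, "` must be a positive integer")
  }
  structure(list(bc = as.integer(bc), bg = as.integer(bg),
                 bg_step = as.integer(bg_step), maxbb = as.integer(maxbb),
                 cell_number = as.integer(cell_number),
                 radius_convention = radius_convention),
            class = "hull_params")
}

point_coords <- function(points) {
  m <- as.matrix(points)
  if (!is.numeric(m) || ncol(m) < 2 || ncol(m) > 3)
    stop("`points` must be an N x 2 or N x 3 numeric matrix")
  if (any(!is.finite(m))) stop("point coordinates must be finite")
  m
}

#' Neighbourhood radius from the pairwise-distance histogram
#'
#' The radius is the bin interval of a `bc`-bin histogram of all pairwise
#' Euclidean distances: (d_max - d_min) / bc under the default observed-range
#' convention (or d_max / bc under `"max"`).
#'
#' @param points N x 2 or N x 3 coordinate matrix (N >= 2).
#' @param bc number of histogram bins.
#' @param convention `"range"` or `"max"`; see [hull_params()].
#' @return positive scalar radius.
#' @export
neighbor_radius <- function(points, bc = 20,
                            convention = c("range", "max")) {
  convention <- match.arg(convention)
  m <- point_coords(points)
  if (nrow(m) < 2) stop("need at least 2 points")
  dv <- stats::dist(m)
  dmax <- max(dv)
  dmin <- min(dv)
  r <- if (convention == "range") (dmax - dmin) / bc else dmax / bc
  if (!is.finite(r) || r <= 0)
    stop("degenerate input: pairwise distances span no range")
  r
}

#' Rank cells by local density
#'
#' Counts, for every point, the neighbours within `radius_rc` (closed ball,
#' self excluded) and orders points by decreasing count, ties broken by
#' ascending point index. The top-ranked point is the global density maximum
#' from which the hull walk starts.
#'
#' @param points N x 2 or N x 3 coordinate matrix.
#' @param radius_rc neighbourhood radius, usually from [neighbor_radius()].
#' @return a `density_field`: list with `radius_rc`, `neighbor_counts`
#'   (integer, length N) and `ranking` (permutation of 1..N).
#' @export
density_ranking <- function(points, radius_rc) {
  m <- point_coords(points)
  if (!is.numeric(radius_rc) || length(radius_rc) != 1 || radius_rc <= 0)
    stop("`radius_rc` must be a positive scalar")
  counts <- cpp_neighbor_counts(m, radius_rc)
  structure(list(radius_rc = radius_rc,
                 neighbor_counts = as.integer(counts),
                 ranking = order(-counts, seq_len(nrow(m)))),
            class = "density_field")
}

#' Discover local density maxima by expanding convex hulls
#'
#' Walks the density ranking: the top-ranked point seeds the first group from
#' the first of `bg` equal-width bins of the histogram of distances to it,
#' and a convex hull is built on those seed points. Each subsequent
#' unassigned point is compared to every live hull: if its distance to the
#' nearest hull vertex is below that hull's mean vertex-vertex distance it
#' joins the closest such group and the hull expands; otherwise it is a new
#' local maximum and seeds its own group the same way. The walk stops when
#' the unassigned remainder is too small to form a hull (fewer than
#' dimension + 1 points).
#'
#' Distance-to-peak histograms are binned over the full observed distance
#' scale (distances from the peak to every point), while only unassigned
#' points in the first bin become seed members; this keeps the bin width on
#' the data's scale even when just a tight remnant is left unassigned.
#'
#' @param points N x 2 or N x 3 coordinate matrix.
#' @param field a `density_field` from [density_ranking()].
#' @param bg number of bins of the distance-to-peak histograms.
#' @return list of disjoint groups; each has `peak_index`, `member_indices`
#'   and `hull_vertices` (all 1-based point indices). Points left unassigned
#'   by the walk belong to no group and are labelled later by
#'   [assign_to_maxima()].
#' @export
find_local_maxima <- function(points, field, bg = 20) {
  m <- point_coords(points)
  stopifnot(inherits(field, "density_field"))
  if (nrow(m) < ncol(m) + 1)
    stop("too few points to build a convex hull")
  res <- cpp_density_walk(m, as.integer(field$ranking) - 1L, as.integer(bg))
  lapply(res$groups, function(g) {
    list(peak_index = g$peak + 1L,
         member_indices = sort(g$members + 1L),
         hull_vertices = sort(g$verts + 1L))
  })
}

#' Assign every point to its nearest local maximum
#'
#' Group members keep their group's label; remaining points get the label of
#' the group whose peak is nearest in Euclidean distance (ties go to the
#' lowest group label).
#'
#' @param points N x 2 or N x 3 coordinate matrix.
#' @param maxima list of groups from [find_local_maxima()].
#' @return integer vector of cluster labels 1..K, named by row names of
#'   `points` when present.
#' @export
assign_to_maxima <- function(points, maxima) {
  m <- point_coords(points)
  if (length(maxima) == 0) stop("need at least one group")
  labels <- integer(nrow(m))
  for (g in seq_along(maxima)) labels[maxima[[g]]$member_indices] <- g
  un <- which(labels == 0L)
  if (length(un)) {
    peaks <- m[vapply(maxima, `[[`, 1L, "peak_index"), , drop = FALSE]
    d2 <- outer(rowSums(m[un, , drop = FALSE]^2), rowSums(peaks^2), "+") -
      2 * m[un, , drop = FALSE] %*% t(peaks)
    labels[un] <- max.col(-d2, ties.method = "first")
  }
  names(labels) <- rownames(m)
  labels
}

#' Choose the seeding bin size by saturation of the maxima count
#'
#' Runs [find_local_maxima()] for bin sizes 5, 10, ..., `bg_step * maxbb`
#' (default ceiling 100) and returns the smallest bin size at which the
#' number of local maxima first equals the count at the next step (the
#' saturated state), or the ceiling when the count never stabilises. Skipped
#' for point sets of `cell_number` or more, where the default `bg` is
#' returned unchanged.
#'
#' @param points N x 2 or N x 3 coordinate matrix.
#' @param field a `density_field` from [density_ranking()].
#' @param params a [hull_params()] object.
#' @return integer bin size.
#' @export
optimize_bin_size <- function(points, field, params = hull_params()) {
  m <- point_coords(points)
  if (nrow(m) >= params$cell_number) return(params$bg)
  grid <- seq(params$bg_step, params$bg_step * params$maxbb,
              by = params$bg_step)
  prev_k <- -1L
  prev_b <- grid[1]
  for (b in grid) {
    k <- length(find_local_maxima(m, field, b))
    if (k == prev_k) return(prev_b)
    prev_k <- k
    prev_b <- b
  }
  grid[length(grid)]
}

#' Density clustering of a low-dimensional point cloud
#'
#' The full pipeline on one point set: neighbourhood radius from the
#' pairwise-distance histogram, density ranking, bin-size saturation scan
#' (for point sets below `cell_number`), hull walk, and nearest-maximum
#' assignment. Degenerate geometry (pairwise distances spanning no range)
#' yields a single cluster with a warning.
#'
#' @param points N x 2 or N x 3 coordinate matrix (N >= dimension + 1).
#' @param params a [hull_params()] object.
#' @return integer cluster labels 1..K named by point row names, with
#'   attributes `bg_used` (seeding bin size) and `n_maxima`.
#' @export
hull_cluster <- function(points, params = hull_params()) {
  m <- point_coords(points)
  if (nrow(m) < ncol(m) + 1)
    stop("need at least dimension + 1 points")
  field <- tryCatch({
    r <- neighbor_radius(m, params$bc, params$radius_convention)
    density_ranking(m, r)
  }, error = function(e) e)
  if (inherits(field, "error")) {
    warning("degenerate geometry (", conditionMessage(field),
            "); returning a single cluster")
    labels <- rep(1L, nrow(m))
    names(labels) <- rownames(m)
    attr(labels, "bg_used") <- NA_integer_
    attr(labels, "n_maxima") <- 1L
    return(labels)
  }
  bg_used <- optimize_bin_size(m, field, params)
  maxima <- find_local_maxima(m, field, bg_used)
  labels <- assign_to_maxima(m, maxima)
  attr(labels, "bg_used") <- as.integer(bg_used)
  attr(labels, "n_maxima") <- length(maxima)
  labels
}

#' Convex hull vertices of a small 2-D/3-D point set
#'
#' Exposes the hull-vertex primitive used by the density walk; handles
#' rank-deficient sets by falling back to the hull within the affine
#' subspace the points span.
#'
#' @param points N x 2 or N x 3 coordinate matrix.
#' @return increasing integer vector of vertex row indices.
#' @export
hull_vertices <- function(points) {
  m <- point_coords(points)
  sort(cpp_hull_vertices(m) + 1L)
}
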