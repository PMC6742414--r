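# The density walk and its primitives.

test_that("neighbour radius is the pairwise-distance histogram bin width", {
  pts <- cbind(c(0, 1, 2), 0, 0)        # distances {1, 1, 2}
  expect_equal(neighbor_radius(pts, bc = 20), (2 - 1) / 20)
  # homogeneity: scaling coordinates scales the radius
  expect_equal(neighbor_radius(17.3 * pts, bc = 20), 17.3 * (2 - 1) / 20)
  # two points span no range
  expect_error(neighbor_radius(cbind(c(0, 3), 0, 0), 20), "degenerate")
  # alternative dialect divides the maximum distance
  expect_equal(neighbor_radius(pts, bc = 10, convention = "max"), 0.2)
})

test_that("density ranking counts neighbours exactly and orders by count", {
  pts <- cbind(c(0, 1, 2), 0, 0)
  f <- density_ranking(pts, 1.1)
  expect_identical(f$neighbor_counts, c(1L, 2L, 1L))
  expect_identical(f$ranking[1], 2L)     # middle point is the density peak
  expect_identical(f$ranking, c(2L, 1L, 3L))  # ties by ascending index

  f0 <- density_ranking(pts, 0.5)        # radius below all pairwise distances
  expect_identical(f0$neighbor_counts, c(0L, 0L, 0L))

  # property: counts match the brute-force O(N^2) oracle on random clouds
  for (seed in 1:5) {
    set.seed(seed)
    p <- matrix(rnorm(60 * 3), ncol = 3)
    r <- neighbor_radius(p, 20)
    f <- density_ranking(p, r)
    expect_identical(f$neighbor_counts, neighbor_counts_oracle(p, r))
    expect_true(all(diff(f$neighbor_counts[f$ranking]) <= 0))
  }
})

test_that("well-separated modes yield one group per mode", {
  # dense modes far apart relative to their spread (the geometry the walk
  # sees on PCA embeddings of clustered expression data)
  for (k in 2:3) {
    for (d in 2:3) {
      blobs <- make_point_blobs(k = k, n_per = 60, d = d, sd = 1, sep = 25,
                                seed = 30 + k + d)
      f <- density_ranking(blobs$points, neighbor_radius(blobs$points, 20))
      mx <- find_local_maxima(blobs$points, f,
                              optimize_bin_size(blobs$points, f))
      expect_length(mx, k)
      # each peak is the densest point of its own mode
      for (g in mx) {
        mode_lab <- blobs$labels[g$peak_index]
        in_mode <- which(blobs$labels == mode_lab)
        expect_identical(max(f$neighbor_counts[in_mode]),
                         f$neighbor_counts[g$peak_index])
      }
    }
  }
  # a single dense isotropic blob seeds one hull that absorbs everything:
  # every later walked point lies within the hull's mean vertex spacing
  for (s in 1:3) {
    one <- make_point_blobs(k = 1, n_per = 200, d = 2, sd = 1, seed = 300 + s)
    f <- density_ranking(one$points, neighbor_radius(one$points, 20))
    expect_length(find_local_maxima(one$points, f, bg = 5), 1L)
  }
})

test_that("groups are disjoint and hulls contain their seed points", {
  blobs <- make_point_blobs(k = 3, n_per = 30, d = 2, sd = 1, sep = 15,
                            seed = 77)
  f <- density_ranking(blobs$points, neighbor_radius(blobs$points, 20))
  mx <- find_local_maxima(blobs$points, f, bg = 20)
  members <- unlist(lapply(mx, `[[`, "member_indices"))
  expect_identical(anyDuplicated(members), 0L)
  for (g in mx) {
    expect_true(g$peak_index %in% g$member_indices)
    expect_true(all(g$hull_vertices %in% g$member_indices))
    # independent hull check (grDevices::chull in 2-D): every member lies
    # inside the hull spanned by the reported vertices
    hull_xy <- blobs$points[g$hull_vertices, , drop = FALSE]
    ch <- grDevices::chull(hull_xy)
    expect_true(all(points_in_hull_2d(
      blobs$points[g$member_indices, , drop = FALSE],
      hull_xy[ch, , drop = FALSE])))
  }
})

test_that("a tetrahedron with a distant singleton leaves one group", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(50, 50, 50))
  f <- density_ranking(pts, 1.5)
  mx <- find_local_maxima(pts, f, bg = 20)
  expect_length(mx, 1L)
  expect_false(5L %in% mx[[1]]$member_indices)
  # the singleton is still labelled afterwards, by nearest peak
  lab <- assign_to_maxima(pts, mx)
  expect_identical(unname(lab), rep(1L, 5))
})

test_that("assignment matches the exhaustive nearest-peak oracle", {
  set.seed(31)
  blobs <- make_point_blobs(k = 2, n_per = 25, d = 3, sd = 1, sep = 12)
  f <- density_ranking(blobs$points, neighbor_radius(blobs$points, 20))
  mx <- find_local_maxima(blobs$points, f, bg = 20)
  lab <- assign_to_maxima(blobs$points, mx)
  peaks <- blobs$points[vapply(mx, `[[`, 1L, "peak_index"), , drop = FALSE]
  in_group <- unlist(lapply(mx, `[[`, "member_indices"))
  for (i in seq_len(nrow(blobs$points))) {
    if (i %in% in_group) next
    d2 <- colSums((t(peaks) - blobs$points[i, ])^2)
    expect_identical(unname(lab[i]), unname(which.min(d2)))
  }
})

test_that("equidistant points break assignment ties to the lower label", {
  pts <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(10, 0, 0), c(9.6, 0, 0),
               c(5, 0, 0))
  mx <- list(list(peak_index = 1L, member_indices = c(1L, 2L),
                  hull_vertices = c(1L, 2L)),
             list(peak_index = 3L, member_indices = c(3L, 4L),
                  hull_vertices = c(3L, 4L)))
  lab <- assign_to_maxima(pts, mx)
  expect_identical(unname(lab[5]), 1L)
})

test_that("bin-size scan stops at the first plateau of the maxima count", {
  blobs <- make_point_blobs(k = 3, n_per = 30, d = 3, sd = 1, sep = 10,
                            seed = 55)
  f <- density_ranking(blobs$points, neighbor_radius(blobs$points, 20))
  params <- hull_params()
  # independent scan of the count sequence
  grid <- seq(5, 100, by = 5)
  counts <- vapply(grid, function(b)
    length(find_local_maxima(blobs$points, f, b)), integer(1))
  plateau <- which(diff(counts) == 0)
  expected <- if (length(plateau)) grid[min(plateau)] else 100L
  expect_equal(optimize_bin_size(blobs$points, f, params), expected)
  # above the cell-number cut the scan is skipped entirely
  small <- hull_params(cell_number = 10)
  expect_identical(optimize_bin_size(blobs$points, f, small), small$bg)
})

test_that("the composite clustering recovers well-separated blobs exactly", {
  for (seed in c(1, 2)) {
    blobs <- make_point_blobs(k = 3, n_per = 80, d = 3, sd = 1, sep = 10,
                              seed = seed)
    lab <- hull_cluster(blobs$points)
    expect_equal(adjusted_rand_index(blobs$labels, as.integer(lab)), 1)
  }
})

test_that("the partition is exhaustive and rigid-motion invariant", {
  blobs <- make_point_blobs(k = 3, n_per = 25, d = 3, sd = 1, sep = 15,
                            seed = 91)
  lab <- hull_cluster(blobs$points)
  expect_length(lab, nrow(blobs$points))
  expect_false(anyNA(lab))

  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta),  cos(theta), 0),
               c(0, 0, 1))
  moved <- blobs$points %*% rot + matrix(c(5, -3, 2),
                                         nrow(blobs$points), 3, byrow = TRUE)
  lab2 <- hull_cluster(moved)
  expect_equal(adjusted_rand_index(as.integer(lab), as.integer(lab2)), 1)
})

test_that("degenerate geometry collapses to a single cluster with warning", {
  pts <- matrix(1, nrow = 6, ncol = 3)   # all points coincide
  expect_warning(lab <- hull_cluster(pts), "degenerate")
  expect_identical(as.integer(lab), rep(1L, 6))
})
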