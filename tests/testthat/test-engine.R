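test_that("correlation distance hits its analytic anchor points", {
  v <- c(3, 1, 4, 1, 5)
  expect_equal(correlation_distance(v, v), 0)
  expect_equal(correlation_distance(v, 10 - v), 2)
  expect_equal(correlation_distance(c(1, -1, 0, 0), c(0, 0, 1, -1)), 1)
  expect_error(correlation_distance(v, rep(2, 5)), "constant")
  expect_error(correlation_distance(v, v[-1]), "equal length")
})

test_that("gini index matches hand-computed values and is scale-free", {
  expect_equal(gini_index(c(7, 7, 7)), 0)
  expect_equal(gini_index(c(0, 3)), 0.5)      # sum|diff| = 6; 2 n^2 mu = 12
  set.seed(41)
  x <- rexp(9)
  expect_equal(gini_index(13 * x), gini_index(x))
  expect_equal(gini_index(c(0, 0, 0)), 0)     # all-zero convention
  expect_error(gini_index(5), "at least 2")
})

test_that("mature-cluster selection follows the prefix-gini gate", {
  # close variances: G2 ~ 0.0025, G3 ~ 0.0033, all below 0.05 -> stop
  d1 <- select_mature(c(10, 10.1, 10.2), 0.05)
  expect_identical(d1$action, "stop")
  expect_true(all(d1$gini < 0.05))

  # one dominant variance: G2 = 99/(2*2*101/2... ) ~ 0.49 -> continue,
  # mature is the minimum-variance cluster, ties to the smaller label
  d2 <- select_mature(c(100, 1, 1), 0.05)
  expect_identical(d2$action, "continue")
  expect_identical(d2$mature, 2L)
  expect_gt(max(d2$gini), 0.05)

  expect_identical(select_mature(c(3.2), 0.05)$action, "stop")
})

test_that("cluster variance handles singletons, pairs and constant cells", {
  set.seed(42)
  vals <- matrix(runif(30 * 12), nrow = 30)
  labels <- c(rep(1L, 9), rep(2L, 2), 3L)
  v <- cluster_distance_variances(vals, labels)
  expect_equal(unname(v[2]), 0)   # one pair, no spread
  expect_equal(unname(v[3]), 0)   # singleton
  # independent recomputation for the 9-cell cluster
  idx <- 1:9
  dmat <- 1 - cor(vals[, idx])
  expect_equal(unname(v[1]), var(dmat[upper.tri(dmat)]))
  # a constant cell contributes distance 1, not NA
  vals[, 12] <- 5
  expect_false(anyNA(cluster_distance_variances(vals, rep(1L, 12))))
})

test_that("three separated blobs are recovered exactly by the full loop", {
  data <- make_expression_blobs(k = 3, n_per = 30, n_genes = 300, sd = 0.5,
                                seed = 7)
  part <- hullclust(data$matrix)
  expect_equal(adjusted_rand_index(data$labels, partition_labels(part)), 1)
  expect_identical(length(unique(partition_labels(part))), 3L)
})

test_that("a homogeneous blob terminates as one cluster", {
  data <- make_expression_blobs(k = 2, n_per = 30, n_genes = 200, sd = 0.5,
                                seed = 9)
  # collapse to a single blob by keeping one label's cells
  keep <- names(data$labels)[data$labels == 1]
  E <- expression_matrix(data$matrix$values[, keep])
  part <- hullclust(E)
  expect_identical(unname(unique(partition_labels(part))), 1L)
})

test_that("iteration and coverage invariants hold along the trace", {
  data <- make_expression_blobs(k = 4, n_per = 20, n_genes = 250, sd = 0.5,
                                seed = 13)
  pre <- iterate_clusters(data$matrix)
  expect_lte(nrow(pre$trace), n_cells(data$matrix))
  expect_setequal(names(pre$labels), data$matrix$cell_ids)
  expect_false(anyNA(pre$labels))
  # every cluster label carries the iteration it was frozen in
  expect_setequal(names(pre$iteration_found),
                  as.character(unique(pre$labels)))
})

test_that("permuting cell order only relabels the output", {
  data <- make_expression_blobs(k = 3, n_per = 20, n_genes = 200, sd = 0.5,
                                seed = 15)
  part1 <- hullclust(data$matrix)
  set.seed(99)
  perm <- sample(n_cells(data$matrix))
  Ep <- expression_matrix(data$matrix$values[, perm])
  part2 <- hullclust(Ep)
  l1 <- partition_labels(part1)
  l2 <- partition_labels(part2)
  expect_equal(adjusted_rand_index(l1, l2[names(l1)]), 1)
})

test_that("centroid dendrogram merging follows the height threshold", {
  set.seed(44)
  # three final clusters: two with nearly identical centroids, one far off
  g <- 40
  a <- runif(g, 0, 10)
  b <- a + rnorm(g, sd = 0.05)           # near-duplicate of a
  c <- rev(a) + runif(g)                 # unrelated profile
  mk <- function(centroid, n, tag) {
    m <- abs(sapply(seq_len(n), function(i) centroid + rnorm(g, sd = 0.01)))
    colnames(m) <- paste0(tag, seq_len(n))
    m
  }
  vals <- cbind(mk(a, 5, "a"), mk(b, 5, "b"), mk(c, 5, "c"))
  E <- expression_matrix(vals)
  labels <- rep(1:3, each = 5)
  names(labels) <- colnames(vals)
  part <- hullclust:::cell_partition(
    labels, iteration_found = c("1" = 1L, "2" = 2L, "3" = 3L))

  # hand-computed 3-leaf dendrogram: a-b merge near 0, c joins far above;
  # at the default height only the near-duplicate pair merges
  merged <- merge_clusters(E, part, fclust_height = 0.2)
  ml <- partition_labels(merged)
  expect_identical(length(unique(ml)), 2L)
  expect_identical(unname(ml[1]), unname(ml[6]))    # a and b together
  expect_false(unname(ml[1]) == unname(ml[11]))     # c apart
  # provenance: merged label inherits the earliest iteration
  joint <- as.character(ml[1])
  expect_identical(unname(merged$iteration_found[joint]), 1L)

  # two clusters with exactly identical centroids merge at height zero
  vals2 <- cbind(matrix(a, g, 4), matrix(a, g, 4))
  colnames(vals2) <- paste0("z", 1:8)
  E2 <- expression_matrix(vals2)
  labels2 <- rep(1:2, each = 4)
  names(labels2) <- colnames(vals2)
  part2 <- hullclust:::cell_partition(labels2)
  m2 <- merge_clusters(E2, part2, fclust_height = 0.2)
  expect_identical(length(unique(partition_labels(m2))), 1L)

  # the vanishing-threshold limit never merges distinct centroids
  m0 <- merge_clusters(E, part, fclust_height = 1e-12)
  expect_identical(length(unique(partition_labels(m0))), 3L)

  # single cluster passes through unchanged
  single <- hullclust:::cell_partition(
    structure(rep(1L, 5), names = colnames(vals)[1:5]))
  expect_identical(merge_clusters(E, single, 0.2)$labels, single$labels)
})
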