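#' Adjusted Rand Index between two partitions of the same cells
#'
#' The permutation-model-adjusted Rand index computed from the contingency
#' table of the two labelings: 1 for identical membership, about 0 for
#' independent partitions, possibly negative for worse-than-chance
#' agreement. When both partitions are trivial in the same way (so the
#' adjustment denominator vanishes) the index is defined as 1.
#'
#' @param a,b cluster label vectors. When both are named, cells are aligned
#'   by name and the cell sets must coincide; otherwise the vectors are
#'   aligned by position and must have equal length.
#' @return scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions are over different cell sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("label vectors must have equal length")
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  np <- comb2(sum(tab))
  expected <- si * sj / np
  maximum <- (si + sj) / 2
  if (maximum == expected) return(1)
  (sij - expected) / (maximum - expected)
}

#' Score a predicted partition against a rare-cell ground truth
#'
#' `recovered` is TRUE iff some predicted cluster contains exactly the
#' ground-truth rare cells and nothing else (strict set equality: "perfectly
#' detected with the correct number of cells"). `false_positive` is TRUE iff
#' some ground-truth major cluster is split across predicted clusters such
#' that at least one fragment is smaller than 10% of that cluster.
#'
#' @param truth named ground-truth labels.
#' @param rare_label the label of the rare cluster in `truth`.
#' @param predicted named predicted labels over the same cells.
#' @param min_jaccard optional lenient recovery rule for sensitivity
#'   analysis: when set (e.g. 0.8), `recovered` additionally accepts a
#'   predicted cluster whose Jaccard overlap with the rare set reaches the
#'   value. The default (NULL) is the strict rule, which is what the
#'   benchmark reports.
#' @return list with `recovered`, `false_positive`, `rare_truth_size`,
#'   `predicted_sizes`.
#' @export
rare_outcome <- function(truth, rare_label, predicted, min_jaccard = NULL) {
  if (!setequal(names(truth), names(predicted)))
    stop("truth and prediction cover different cell sets")
  predicted <- predicted[names(truth)]
  rare_cells <- names(truth)[truth == rare_label]

  pred_of_rare <- unique(predicted[rare_cells])
  recovered <- length(pred_of_rare) == 1 &&
    sum(predicted == pred_of_rare) == length(rare_cells)
  if (!recovered && !is.null(min_jaccard)) {
    jac <- vapply(unique(predicted), function(p) {
      cl <- names(predicted)[predicted == p]
      length(intersect(cl, rare_cells)) / length(union(cl, rare_cells))
    }, numeric(1))
    recovered <- any(jac >= min_jaccard)
  }

  false_positive <- FALSE
  for (lab in setdiff(unique(truth), rare_label)) {
    cells <- names(truth)[truth == lab]
    frag <- table(predicted[cells])
    if (length(frag) >= 2 && any(frag < 0.1 * length(cells))) {
      false_positive <- TRUE
      break
    }
  }

  list(recovered = recovered, false_positive = false_positive,
       rare_truth_size = length(rare_cells),
       predicted_sizes = as.integer(sort(table(predicted), decreasing = TRUE)))
}

#' Run the rare-cell detection benchmark
#'
#' Generates each configured dataset, runs the full clustering pipeline on
#' it, and scores the final (post-merge) partition with [rare_outcome()].
#' A pipeline failure on a dataset is recorded as not recovered and flagged
#' in the per-dataset table rather than aborting the sweep.
#'
#' @param configs list of [rare_config()] objects, e.g. from [sweep_rare()].
#' @param params a [hullclust_params()] object.
#' @param verbose print one progress line per dataset.
#' @return list with `recovery_rate` and `false_positive_rate` (percent of
#'   datasets) and `results`, a per-dataset data frame (centres, seed,
#'   rare-cluster size, recovered, false_positive, ARI, cluster count,
#'   failure flag).
#' @export
run_rare_benchmark <- function(configs, params = hullclust_params(),
                               verbose = FALSE) {
  stopifnot(length(configs) >= 1)
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    data <- generate_rare(cfg)
    part <- tryCatch(hullclust(data$matrix, params), error = function(e) e)
    if (inherits(part, "error")) {
      rows[[i]] <- data.frame(
        n_centers = cfg$base$n_centers, seed = cfg$base$seed,
        rare_size = sum(data$labels == data$rare_label),
        recovered = FALSE, false_positive = FALSE, ari = NA_real_,
        n_clusters = NA_integer_, failed = TRUE)
      if (verbose) message(sprintf("[%d/%d] FAILED: %s", i, length(configs),
                                   conditionMessage(part)))
      next
    }
    pred <- partition_labels(part)
    out <- rare_outcome(data$labels, data$rare_label, pred)
    rows[[i]] <- data.frame(
      n_centers = cfg$base$n_centers, seed = cfg$base$seed,
      rare_size = out$rare_truth_size,
      recovered = out$recovered, false_positive = out$false_positive,
      ari = adjusted_rand_index(data$labels, pred),
      n_clusters = length(unique(pred)), failed = FALSE)
    if (verbose) message(sprintf(
      "[%d/%d] n=%d seed=%d rare=%d recovered=%s fp=%s ari=%.3f",
      i, length(configs), cfg$base$n_centers, cfg$base$seed,
      out$rare_truth_size, out$recovered, out$false_positive,
      rows[[i]]$ari))
  }
  results <- do.call(rbind, rows)
  list(recovery_rate = 100 * mean(results$recovered),
       false_positive_rate = 100 * mean(results$false_positive),
       results = results)
}

#' Run the clustering-accuracy benchmark on blob datasets
#'
#' Generates each configured blob dataset, runs the full pipeline, and
#' records the Adjusted Rand Index of the final partition against the
#' generating labels.
#'
#' @param configs list of [blob_config()] objects, e.g. from
#'   [sweep_blobs()].
#' @param params a [hullclust_params()] object.
#' @param verbose print one progress line per dataset.
#' @return per-dataset data frame (centres, SD, seed, ARI, cluster count,
#'   failure flag).
#' @export
run_blob_benchmark <- function(configs, params = hullclust_params(),
                               verbose = FALSE) {
  stopifnot(length(configs) >= 1)
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    data <- generate_blobs(cfg)
    part <- tryCatch(hullclust(data$matrix, params), error = function(e) e)
    failed <- inherits(part, "error")
    rows[[i]] <- data.frame(
      n_centers = cfg$n_centers, cluster_sd = cfg$cluster_sd,
      seed = cfg$seed,
      ari = if (failed) NA_real_
            else adjusted_rand_index(data$labels, partition_labels(part)),
      n_clusters = if (failed) NA_integer_
                   else length(unique(partition_labels(part))),
      failed = failed)
    if (verbose) message(sprintf(
      "[%d/%d] n=%d sd=%.1f seed=%d ari=%s", i, length(configs),
      cfg$n_centers, cfg$cluster_sd, cfg$seed,
      if (failed) "FAILED" else sprintf("%.3f", rows[[i]]$ari)))
  }
  do.call(rbind, rows)
}
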