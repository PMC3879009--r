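# Stability-based validation: resampled consensus clustering per algorithm,
# merged consensus across algorithms (unweighted average of the per-algorithm
# consensus matrices), and membership/cluster robustness.

# run one clustering algorithm on a distance matrix at u clusters
.cluster_at <- function(d, algorithm, u) {
  if (algorithm == "kmedoids") kmedoids(d, u)
  else if (algorithm == "diana") cut_partition(divisive(d), u)
  else cut_partition(agglomerate(d, algorithm), u)
}

#' Resampled consensus matrix for one clustering algorithm
#'
#' Repeatedly subsamples the data (without replacement), rebuilds the method
#' distance matrix on the subsample, clusters into `u` groups and records
#' which method pairs land in the same cluster. The consensus entry
#' `M(i, j)` is the fraction of resamples, among those where both methods
#' were evaluable, in which i and j co-clustered. With
#' `resample_unit = "items"` (the default — the clustered objects are only a
#' dozen methods, while items number in the thousands) every method is
#' evaluable in every resample. With `resample_unit = "methods"` a resample
#' that retains fewer than `u` methods is skipped and counted.
#'
#' Resample `r` uses seed `seed + r`, so runs are reproducible and
#' individual resamples can be recomputed independently.
#'
#' @param m a [classification_matrix()].
#' @param algorithm one of [clustering_algorithms()].
#' @param u number of clusters per resample.
#' @param B number of resamples (default 100).
#' @param rate subsample fraction in (0, 1] (default 0.8).
#' @param measure binary similarity measure for the distances.
#' @param resample_unit `"items"` or `"methods"`.
#' @param seed base seed for the resampling schedule.
#' @return An object of class `consensus_matrix`: `values` (methods x
#'   methods co-clustering frequencies, diagonal 1), `counts` (evaluable
#'   resamples per pair), `skipped`, and the call parameters.
#' @export
consensus_matrix <- function(m, algorithm = "average", u = 2L, B = 100L,
                             rate = 0.8, measure = similarity_measures(),
                             resample_unit = c("items", "methods"),
                             seed = 1L) {
  stopifnot(inherits(m, "classification_matrix"))
  algorithm <- match.arg(algorithm, clustering_algorithms())
  measure <- match.arg(measure)
  resample_unit <- match.arg(resample_unit)
  if (B < 1L) stop("B must be >= 1")
  if (rate <= 0 || rate > 1) stop("rate must be in (0, 1]")
  ids <- m$method_ids
  p <- length(ids)
  co <- matrix(0, p, p, dimnames = list(ids, ids))
  ev <- matrix(0, p, p, dimnames = list(ids, ids))
  skipped <- 0L
  for (r in seq_len(B)) {
    set.seed(seed + r)
    if (resample_unit == "items") {
      n <- length(m$item_ids)
      idx <- sample.int(n, max(3L, floor(rate * n)))
      sub <- classification_matrix(m$values[idx, , drop = FALSE])
      keep <- seq_len(p)
    } else {
      keep <- sort(sample.int(p, max(2L, floor(rate * p))))
      if (length(keep) < u) {
        skipped <- skipped + 1L
        next
      }
      sub <- classification_matrix(m$values[, keep, drop = FALSE])
    }
    part <- .cluster_at(distance_matrix(sub, measure), algorithm, u)
    same <- outer(part, part, "==") * 1
    co[keep, keep] <- co[keep, keep] + same
    ev[keep, keep] <- ev[keep, keep] + 1
  }
  if (skipped > 0L)
    message(skipped, " of ", B, " resamples skipped (fewer than u = ", u,
            " methods retained)")
  if (skipped == B) stop("all ", B, " resamples were skipped")
  vals <- ifelse(ev > 0, co / ev, NA_real_)
  diag(vals) <- 1
  structure(list(values = vals, counts = ev, skipped = skipped,
                 method_ids = ids, algorithm = algorithm, u = u, B = B,
                 rate = rate, measure = measure,
                 resample_unit = resample_unit, seed = seed),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("Consensus matrix (", x$algorithm, ", u = ", x$u, ", B = ", x$B,
      ", rate = ", x$rate, ", ", x$measure, ", resampling ",
      x$resample_unit, ")\n", sep = "")
  print(round(x$values, 2))
  invisible(x)
}

#' Merged consensus matrix across clustering algorithms
#'
#' Unweighted element-wise average of per-algorithm consensus matrices.
#'
#' @param matrices list of [consensus_matrix()] objects over the same
#'   methods in the same order.
#' @return A `consensus_matrix` with `algorithm = "merged"`.
#' @export
merge_consensus <- function(matrices) {
  if (inherits(matrices, "consensus_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "consensus_matrix")))
  ids <- matrices[[1L]]$method_ids
  for (cm in matrices)
    if (!identical(cm$method_ids, ids))
      stop("consensus matrices have mismatched method ids")
  vals <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  counts <- Reduce(`+`, lapply(matrices, `[[`, "counts"))
  structure(list(values = vals, counts = counts,
                 skipped = sum(vapply(matrices, `[[`, integer(1), "skipped")),
                 method_ids = ids, algorithm = "merged",
                 u = matrices[[1L]]$u,
                 B = sum(vapply(matrices, `[[`, numeric(1), "B")),
                 rate = matrices[[1L]]$rate,
                 measure = matrices[[1L]]$measure,
                 resample_unit = matrices[[1L]]$resample_unit,
                 seed = matrices[[1L]]$seed,
                 components = vapply(matrices, `[[`, character(1),
                                     "algorithm")),
            class = "consensus_matrix")
}

#' Partition the methods from a consensus matrix
#'
#' Treats `1 - M` as a distance matrix and clusters it with a hierarchical
#' algorithm (average linkage by default), cutting at `u`.
#'
#' @param cm a [consensus_matrix()] (typically merged).
#' @param u number of clusters.
#' @param algorithm an agglomerative linkage or `"diana"`.
#' @return Named integer vector of cluster labels.
#' @export
cluster_from_consensus <- function(cm, u = 2L, algorithm = "average") {
  stopifnot(inherits(cm, "consensus_matrix"))
  algorithm <- match.arg(algorithm, setdiff(clustering_algorithms(),
                                            "kmedoids"))
  vals <- cm$values
  if (anyNA(vals))
    stop("consensus matrix has unevaluated pairs; increase B or rate")
  d <- as.dist(1 - vals)
  if (algorithm == "diana") cut_partition(divisive(d), u)
  else cut_partition(agglomerate(d, algorithm), u)
}

#' Membership and cluster robustness
#'
#' Membership robustness of method i is its average consensus connectivity
#' to the other members of its cluster; cluster robustness of cluster k is
#' the average consensus over the unordered within-cluster pairs. Singleton
#' clusters have no within pairs: the singleton's *cluster* robustness is 1
#' (a one-member cluster is trivially self-consistent), while its
#' *membership* robustness is its mean consensus connectivity to all other
#' methods of the panel — an isolated method should score by how weakly it
#' connects to everyone else, not be awarded the maximum by convention,
#' since isolation is precisely the outlier signature the audit looks for.
#' Singletons are flagged in the report. Low membership robustness relative
#' to the rest of the panel marks an outlier classifier.
#'
#' @param cm a [consensus_matrix()].
#' @param partition named integer labels over the same methods.
#' @return An object of class `robustness_report`: `membership` (named
#'   per-method values), `cluster` (per-cluster values), `singleton`
#'   (logical per method) and `partition`.
#' @export
consensus_robustness <- function(cm, partition) {
  stopifnot(inherits(cm, "consensus_matrix"))
  ids <- cm$method_ids
  if (!is.null(names(partition))) {
    if (!setequal(names(partition), ids))
      stop("partition names do not match consensus matrix methods")
    partition <- partition[ids]
  }
  if (length(partition) != length(ids))
    stop("partition length does not match number of methods")
  M <- cm$values
  membership <- setNames(numeric(length(ids)), ids)
  singleton <- setNames(logical(length(ids)), ids)
  for (i in seq_along(ids)) {
    mates <- which(partition == partition[i])
    mates <- mates[mates != i]
    if (length(mates) == 0L) {
      membership[i] <- mean(M[i, -i])
      singleton[i] <- TRUE
    } else {
      membership[i] <- mean(M[i, mates])
    }
  }
  ks <- sort(unique(partition))
  cluster <- setNames(numeric(length(ks)), paste0("cluster", ks))
  for (j in seq_along(ks)) {
    members <- which(partition == ks[j])
    if (length(members) < 2L) {
      cluster[j] <- 1
    } else {
      pairs <- utils::combn(members, 2L)
      cluster[j] <- mean(M[cbind(pairs[1L, ], pairs[2L, ])])
    }
  }
  structure(list(membership = membership, cluster = cluster,
                 singleton = singleton, partition = partition),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Membership robustness:\n")
  print(round(x$membership, 3))
  if (any(x$singleton))
    cat("(singletons, scored by whole-panel connectivity: ",
        paste(names(x$singleton)[x$singleton], collapse = ", "), ")\n",
        sep = "")
  cat("Cluster robustness:\n")
  print(round(x$cluster, 3))
  invisible(x)
}

#' Write a consensus matrix as a labelled square TSV
#'
#' @param cm a [consensus_matrix()].
#' @param path output file path.
#' @param order optional leaf order (e.g. from a dendrogram) for the rows
#'   and columns.
#' @return `path`, invisibly.
#' @export
write_consensus_matrix <- function(cm, path, order = NULL) {
  stopifnot(inherits(cm, "consensus_matrix"))
  vals <- cm$values
  if (!is.null(order)) vals <- vals[order, order, drop = FALSE]
  out <- data.frame(id = rownames(vals), vals, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
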