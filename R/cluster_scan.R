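# Clustering of the method-by-method distance matrix and the Baker-Hubert
# Gamma scan over similarity measure x algorithm x cluster count.
#
# Standard algorithms are delegated: agglomerative linkages to stats::hclust
# (Lance-Williams), divisive clustering to cluster::diana
# (Kaufman-Rousseeuw splinter algorithm) and k-medoids to cluster::pam
# (BUILD + SWAP). The Gamma index and the scan itself are implemented here.

.HIERARCHICAL_LINKAGES <- c("single", "complete", "average", "mcquitty",
                            "ward", "centroid", "median")

# mapping to stats::hclust method names; "ward" is Ward.D2 (dissimilarities
# treated as Euclidean-like, heights on the original distance scale)
.hclust_method <- function(linkage) {
  switch(linkage, ward = "ward.D2", linkage)
}

#' Names of the clustering algorithms available to the scan
#' @return Character vector: the seven agglomerative linkages plus
#'   `"diana"` (divisive) and `"kmedoids"` (PAM).
#' @export
clustering_algorithms <- function() {
  c(.HIERARCHICAL_LINKAGES, "diana", "kmedoids")
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard agglomerative clustering via Lance-Williams updates
#' (`stats::hclust`). `mcquitty` is WPGMA (weighted average); `ward` is
#' implemented as Ward.D2, i.e. on squared dissimilarities with heights
#' back-transformed to the original scale. Heights are non-decreasing for
#' the monotone linkages (single, complete, average, mcquitty, ward);
#' centroid and median can produce inversions.
#'
#' @param d a `dist` object (e.g. from [distance_matrix()]).
#' @param linkage one of `"single"`, `"complete"`, `"average"`,
#'   `"mcquitty"`, `"ward"`, `"centroid"`, `"median"`.
#' @return An `hclust` object.
#' @export
agglomerate <- function(d, linkage = .HIERARCHICAL_LINKAGES) {
  linkage <- match.arg(linkage)
  stats::hclust(as.dist(d), method = .hclust_method(linkage))
}

#' Divisive hierarchical clustering of a distance matrix
#'
#' Kaufman-Rousseeuw divisive analysis: repeatedly split the cluster with
#' the largest diameter by the splinter procedure (seeded by the object with
#' maximal average dissimilarity, moving objects while they are closer on
#' average to the splinter than to the remainder). Delegates to
#' `cluster::diana` and returns the standard `hclust` representation.
#'
#' @param d a `dist` object.
#' @return An `hclust` object (converted from the `diana` result).
#' @export
divisive <- function(d) {
  stats::as.hclust(cluster::diana(as.dist(d), diss = TRUE))
}

#' k-medoids partition of a distance matrix
#'
#' Partitioning Around Medoids (BUILD followed by SWAP to a local optimum of
#' total within-cluster dissimilarity to the medoid), via `cluster::pam` on
#' the precomputed dissimilarities. The algorithm is deterministic; `seed`
#' is accepted for interface uniformity with the resampling functions and is
#' not consumed.
#'
#' @param d a `dist` object.
#' @param u number of clusters, `2 <= u <= n`.
#' @param seed unused; PAM on a fixed matrix is deterministic.
#' @return A partition: named integer vector of cluster labels `1..u`.
#' @export
kmedoids <- function(d, u, seed = NULL) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (u < 1L || u > n) stop("u must be in [1, ", n, "]")
  if (u == n) {
    return(setNames(seq_len(n), attr(d, "Labels")))
  }
  cluster::pam(d, k = u, diss = TRUE, cluster.only = TRUE)
}

#' Cut a dendrogram into u clusters
#'
#' Undoes the last `u - 1` merges of the agglomeration (or keeps the first
#' `u - 1` splits of a divisive tree).
#'
#' @param dend an `hclust` object.
#' @param u number of clusters, `1 <= u <= n`.
#' @return Named integer vector of cluster labels.
#' @export
cut_partition <- function(dend, u) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$labels)
  if (u < 1L || u > n) stop("u must be in [1, ", n, "]")
  cutree(dend, k = u)
}

#' Dendrogram as a Newick string
#'
#' Branch lengths are derived from the merge heights, so cophenetic
#' distances are preserved.
#'
#' @param dend an `hclust` object.
#' @return A single Newick-format character string.
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  ape::write.tree(ape::as.phylo(dend))
}

#' Baker-Hubert Gamma cluster-validity index
#'
#' A rank-based adaptation of Goodman-Kruskal's Gamma: every within-cluster
#' distance `w` is compared with every between-cluster distance `b`;
#' `s+` counts concordant comparisons (`b > w`), `s-` discordant ones
#' (`b < w`), ties count in neither, and
#' `G = (s+ - s-) / (s+ + s-)`. `G = 1` when every within-cluster pair is
#' closer than every between-cluster pair (perfect separation), `-1` for
#' the inverted structure. The cluster count maximising `G` over a scan is
#' taken as the optimal number of clusters.
#'
#' @param d a `dist` object.
#' @param partition integer cluster labels in the order of `d`'s objects
#'   (or named, matching `d`'s labels).
#' @return Gamma in `[-1, 1]`, or `NA` (with a warning) if all comparisons
#'   are ties.
#' @export
baker_hubert <- function(d, partition) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  labs <- attr(d, "Labels")
  if (!is.null(names(partition)) && !is.null(labs)) {
    if (!setequal(names(partition), labs))
      stop("partition names do not match distance matrix labels")
    partition <- partition[labs]
  }
  if (length(partition) != n)
    stop("partition length ", length(partition), " != number of objects ", n)
  if (length(unique(partition)) < 2L)
    stop("partition must have at least 2 clusters")
  same <- as.vector(as.dist(outer(partition, partition, "==")))
  within <- as.vector(d)[same == 1]
  between <- as.vector(d)[same == 0]
  if (length(within) == 0L)
    stop("no within-cluster pairs (all clusters are singletons)")
  if (length(between) == 0L)
    stop("no between-cluster pairs")
  cmp <- outer(between, within, "-")
  s_plus <- sum(cmp > 0)
  s_minus <- sum(cmp < 0)
  if (s_plus + s_minus == 0) {
    warning("all within/between comparisons are ties; Gamma undefined")
    return(NA_real_)
  }
  (s_plus - s_minus) / (s_plus + s_minus)
}

#' Gamma scan over measures, algorithms and cluster counts
#'
#' For every combination of binary similarity measure, clustering algorithm
#' and cluster count `u`, builds the method distance matrix, clusters it
#' (hierarchical algorithms are cut at `u`; k-medoids partitions at `u`
#' directly) and records the Baker-Hubert Gamma. The combination(s)
#' attaining the maximum Gamma identify the optimal cluster structure.
#'
#' @param m a [classification_matrix()].
#' @param measures similarity measures to scan (default all three).
#' @param algorithms algorithms to scan (default the full suite, see
#'   [clustering_algorithms()]).
#' @param u_range cluster counts; default `2:min(8, n_methods - 1)`.
#' @return An object of class `gamma_scan`: a list with `table` (data frame
#'   of measure, algorithm, u, gamma), `best` (the rows attaining the
#'   maximum gamma), and `partitions` (list of label vectors, one per row of
#'   `table`).
#' @export
gamma_scan <- function(m, measures = similarity_measures(),
                       algorithms = clustering_algorithms(),
                       u_range = NULL) {
  stopifnot(inherits(m, "classification_matrix"))
  measures <- match.arg(measures, similarity_measures(), several.ok = TRUE)
  algorithms <- match.arg(algorithms, clustering_algorithms(),
                          several.ok = TRUE)
  n <- length(m$method_ids)
  if (is.null(u_range)) u_range <- 2:min(8L, n - 1L)
  if (any(u_range < 2L) || any(u_range > n - 1L))
    stop("u_range must lie within [2, ", n - 1L, "]")
  rows <- list()
  partitions <- list()
  k <- 0L
  for (measure in measures) {
    d <- distance_matrix(m, measure)
    for (alg in algorithms) {
      dend <- if (alg == "diana") divisive(d)
              else if (alg != "kmedoids") agglomerate(d, alg)
      for (u in u_range) {
        part <- if (alg == "kmedoids") kmedoids(d, u)
                else cut_partition(dend, u)
        gamma <- withCallingHandlers(
          baker_hubert(d, part),
          warning = function(w) invokeRestart("muffleWarning"))
        k <- k + 1L
        rows[[k]] <- data.frame(measure = measure, algorithm = alg, u = u,
                                gamma = gamma, stringsAsFactors = FALSE)
        partitions[[k]] <- part
      }
    }
  }
  table <- do.call(rbind, rows)
  best_idx <- which(table$gamma == max(table$gamma, na.rm = TRUE))
  structure(list(table = table, best = table[best_idx, , drop = FALSE],
                 best_idx = best_idx, partitions = partitions),
            class = "gamma_scan")
}

#' @export
print.gamma_scan <- function(x, ...) {
  cat("Gamma scan over ", nrow(x$table), " combinations; max gamma = ",
      format(max(x$table$gamma, na.rm = TRUE), digits = 4), " attained by ",
      nrow(x$best), " combination(s), e.g.:\n", sep = "")
  print(head(x$best, 5), row.names = FALSE)
  invisible(x)
}

#' Partitions attaining the scan optimum
#'
#' @param scan a [gamma_scan()] result.
#' @return List of label vectors, one per row of `scan$best`.
#' @export
best_partitions <- function(scan) {
  stopifnot(inherits(scan, "gamma_scan"))
  scan$partitions[scan$best_idx]
}

#' Is a given method isolated at the scan optimum?
#'
#' Checks whether the named method is a singleton cluster in every (or any)
#' optimal partition of a scan — the signature of an outlier classifier.
#'
#' @param scan a [gamma_scan()] result.
#' @param method method id to test.
#' @param all require isolation in all optimal partitions (`TRUE`, default)
#'   or in at least one.
#' @return Logical.
#' @export
is_isolated <- function(scan, method, all = TRUE) {
  parts <- best_partitions(scan)
  iso <- vapply(parts, function(p) {
    if (!method %in% names(p)) stop("unknown method: ", method)
    sum(p == p[[method]]) == 1L
  }, logical(1))
  if (all) base::all(iso) else base::any(iso)
}
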