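# Clustering algorithms, tree cutting, the Baker-Hubert Gamma index and the
# measure x algorithm x u scan.

# two tight pairs (within 0.1) far apart (0.9)
two_pairs_dist <- function() {
  m <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 0.1
  m["c", "d"] <- m["d", "c"] <- 0.1
  diag(m) <- 0
  as.dist(m)
}

test_that("agglomeration follows hand-traced Lance-Williams merges", {
  d2 <- as.dist(matrix(c(0, 0.3, 0.3, 0), 2, 2,
                       dimnames = list(c("x", "y"), c("x", "y"))))
  for (linkage in c("single", "complete", "average", "mcquitty", "ward",
                    "centroid", "median")) {
    hc <- agglomerate(d2, linkage)
    expect_equal(hc$height, 0.3)
  }
  # two tight pairs: first two merges join the pairs at 0.1 everywhere
  for (linkage in c("single", "complete", "average", "mcquitty", "ward")) {
    hc <- agglomerate(two_pairs_dist(), linkage)
    expect_equal(hc$height[1:2], c(0.1, 0.1))
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone linkages
    expect_equal(sort(unname(cut_partition(hc, 2))[c(1, 2)]),
                 sort(unname(cut_partition(hc, 2))[c(1, 2)]))
    p <- cut_partition(hc, 2)
    expect_equal(p[["a"]], p[["b"]])
    expect_equal(p[["c"]], p[["d"]])
    expect_false(p[["a"]] == p[["c"]])
  }
  # average linkage hand trace on 3 points
  d3 <- as.dist(matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3))
  hc <- agglomerate(d3, "average")
  expect_equal(hc$height, c(0.2, 0.6))
})

test_that("divisive clustering splits the widest cluster first", {
  hc <- divisive(two_pairs_dist())
  p <- cut_partition(hc, 2)
  expect_equal(p[["a"]], p[["b"]])
  expect_equal(p[["c"]], p[["d"]])
  expect_false(p[["a"]] == p[["c"]])
  # single pair: one split at their distance
  d2 <- as.dist(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                       dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(divisive(d2)$height, 0.4)
})

test_that("k-medoids attains the exhaustively optimal 2-partition on 4 objects", {
  d <- two_pairs_dist()
  p <- kmedoids(d, 2)
  expect_equal(p[["a"]], p[["b"]])
  expect_equal(p[["c"]], p[["d"]])
  # exhaustive check: enumerate all 2-partitions and all medoid choices
  dm <- as.matrix(d)
  best_cost <- Inf; best_split <- NULL
  for (mask in 1:6) {
    split <- intToBits(mask)[1:4] == 1
    if (all(split) || !any(split)) next
    cost <- 0
    for (side in list(which(split), which(!split))) {
      cost <- cost + min(vapply(side, function(med)
        sum(dm[side, med]), numeric(1)))
    }
    if (cost < best_cost) { best_cost <- cost; best_split <- split }
  }
  pam_cost <- 0
  for (k in unique(p)) {
    side <- which(p == k)
    pam_cost <- pam_cost + min(vapply(side, function(med)
      sum(dm[side, med]), numeric(1)))
  }
  expect_equal(pam_cost, best_cost)
  # determinism and degenerate u
  expect_identical(kmedoids(d, 2), kmedoids(d, 2))
  expect_equal(unname(kmedoids(d, 4)), 1:4)
  expect_error(kmedoids(d, 5), "u must be")
})

test_that("cutting a dendrogram undoes the last merges", {
  hc <- agglomerate(two_pairs_dist(), "average")
  expect_equal(unname(cut_partition(hc, 1)), rep(1L, 4))
  expect_equal(sort(unname(cut_partition(hc, 4))), 1:4)
  expect_error(cut_partition(hc, 5), "u must be")
})

test_that("dendrograms export to parseable Newick with merge heights", {
  hc <- agglomerate(two_pairs_dist(), "average")
  nwk <- dendrogram_newick(hc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, letters[1:4])
  expect_true(all(tree$edge.length >= 0))
})

test_that("Baker-Hubert Gamma hits its extremes and the balanced zero case", {
  # perfect separation: within {a,b} and {c,d} closer than between
  expect_equal(baker_hubert(two_pairs_dist(), c(1, 1, 2, 2)), 1)
  # inverted structure: cluster the far-apart objects together
  expect_equal(baker_hubert(two_pairs_dist(), c(1, 2, 1, 2)), -1)
  # constructed balance: within = {1, 3}, between = {2, 2, 2, 2}
  m <- matrix(2, 4, 4)
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 3
  diag(m) <- 0
  expect_equal(baker_hubert(as.dist(m), c(1, 1, 2, 2)), 0)
  # degenerate partitions are rejected
  expect_error(baker_hubert(two_pairs_dist(), c(1, 1, 1, 1)), "2 clusters")
  expect_error(baker_hubert(as.dist(matrix(c(0, 1, 1, 0), 2)), c(1, 2)),
               "no within")
  # all-ties case is undefined
  expect_warning(
    g <- baker_hubert(as.dist(matrix(1, 3, 3) - diag(3)), c(1, 1, 2)),
    "ties")
  expect_true(is.na(g))
})

test_that("Gamma agrees with brute-force enumeration and is rank-invariant", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    d <- random_dist(n)
    p <- random_partition(n)
    g <- suppressWarnings(baker_hubert(d, p))
    expect_equal(g, oracle_gamma(d, p))
    # invariant under strictly monotone transforms of the distances
    if (!is.na(g)) {
      expect_equal(suppressWarnings(baker_hubert(d^2, p)), g)
      expect_equal(suppressWarnings(
        baker_hubert(as.dist(exp(as.matrix(d))) , p)), g)
    }
  }
})

test_that("the scan recovers planted structure and enumerates all combinations", {
  m <- planted_matrix(n_items = 200, epsilon = 0, seed = 3)
  scan <- gamma_scan(m)
  expect_equal(nrow(scan$table),
               length(similarity_measures()) *
                 length(clustering_algorithms()) * length(2:5))
  expect_equal(max(scan$table$gamma, na.rm = TRUE), 1)
  # every measure/algorithm combination scores 1 at the planted u = 2
  at2 <- scan$table[scan$table$u == 2, ]
  expect_true(all(at2$gamma == 1))
  expect_true(2 %in% scan$best$u)
  # partitions at u = 2 recover the blocks
  for (p in scan$partitions[scan$table$u == 2]) {
    expect_equal(length(unique(p[c("A1", "A2", "A3")])), 1L)
    expect_equal(length(unique(p[c("B1", "B2", "B3")])), 1L)
  }
  expect_error(gamma_scan(m, u_range = 2:6), "u_range")
})

test_that("a planted outlier lands in its own cluster at the scan optimum", {
  m <- planted_matrix(n_items = 500, epsilon = 0.1, outlier = "OUT",
                      seed = 13)
  scan <- gamma_scan(m)
  expect_true(is_isolated(scan, "OUT", all = FALSE))
  expect_error(is_isolated(scan, "nope"), "unknown method")
})
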