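# Resampled consensus matrices, merging across algorithms, consensus
# partitions and robustness statistics.

test_that("noise-free planted blocks give an exact 0/1 consensus matrix", {
  m <- planted_matrix(n_items = 150, epsilon = 0, seed = 2)
  for (alg in c("average", "kmedoids")) {
    cm <- consensus_matrix(m, alg, u = 2, B = 10, seed = 5)
    blockA <- c("A1", "A2", "A3"); blockB <- c("B1", "B2", "B3")
    expect_true(all(cm$values[blockA, blockA] == 1))
    expect_true(all(cm$values[blockB, blockB] == 1))
    expect_true(all(cm$values[blockA, blockB] == 0))
  }
})

test_that("consensus matrices are symmetric with unit diagonal, any seed", {
  m <- planted_matrix(n_items = 100, epsilon = 0.2, seed = 4)
  for (seed in c(1, 99, 12345)) {
    cm <- consensus_matrix(m, "complete", u = 3, B = 8, seed = seed)
    expect_true(isSymmetric(cm$values))
    expect_true(all(diag(cm$values) == 1))
    expect_true(all(cm$values >= 0 & cm$values <= 1))
    expect_identical(cm$values,
                     consensus_matrix(m, "complete", u = 3, B = 8,
                                      seed = seed)$values)
  }
  # B = 1, rate = 1: the indicator of a single clustering
  cm1 <- consensus_matrix(m, "average", u = 2, B = 1, rate = 1, seed = 1)
  expect_true(all(cm1$values %in% c(0, 1)))
})

test_that("method resampling skips unevaluable resamples and can exhaust", {
  m <- planted_matrix(n_items = 100, epsilon = 0.1, seed = 6)
  cm <- suppressMessages(
    consensus_matrix(m, "average", u = 2, B = 30, rate = 0.5,
                     resample_unit = "methods", seed = 3))
  expect_true(isSymmetric(cm$values))
  # u larger than any retained subpanel: every resample skipped
  expect_error(
    suppressMessages(
      consensus_matrix(m, "average", u = 4, B = 5, rate = 0.5,
                       resample_unit = "methods", seed = 3)),
    "skipped")
})

test_that("merging consensus matrices is the unweighted element mean", {
  m <- planted_matrix(n_items = 120, epsilon = 0.15, seed = 8)
  algs <- c("average", "complete", "ward", "kmedoids", "diana")
  cms <- lapply(algs, function(a)
    consensus_matrix(m, a, u = 2, B = 10, seed = 21))
  merged <- merge_consensus(cms)
  hand <- (cms[[1]]$values + cms[[2]]$values + cms[[3]]$values +
             cms[[4]]$values + cms[[5]]$values) / 5
  expect_equal(merged$values, hand)
  # merging a single matrix is the identity
  expect_equal(merge_consensus(cms[1])$values, cms[[1]]$values)
  # mismatched ids are rejected
  m2 <- planted_matrix(n_items = 120, epsilon = 0.15, seed = 8)
  cm2 <- consensus_matrix(m2, "average", u = 2, B = 5, seed = 1)
  cm2$method_ids <- rev(cm2$method_ids)
  expect_error(merge_consensus(list(cms[[1]], cm2)), "mismatched")
})

test_that("block-structured consensus matrices recover their blocks", {
  ids <- paste0("M", 1:6)
  M <- matrix(0, 6, 6, dimnames = list(ids, ids))
  M[1:3, 1:3] <- 1; M[4:6, 4:6] <- 1
  cm <- structure(list(values = M, counts = M * 0 + 10, skipped = 0L,
                       method_ids = ids, algorithm = "average", u = 2,
                       B = 10, rate = 0.8, measure = "sokal_michener",
                       resample_unit = "items", seed = 1),
                  class = "consensus_matrix")
  p <- cluster_from_consensus(cm, 2)
  expect_equal(length(unique(p[1:3])), 1L)
  expect_equal(length(unique(p[4:6])), 1L)
  expect_false(p[[1]] == p[[4]])
})

test_that("robustness statistics follow their definitions", {
  ids <- c("X", "Y", "Z", "Q")
  M <- matrix(1, 4, 4, dimnames = list(ids, ids))
  M["X", "Y"] <- M["Y", "X"] <- 0.8
  M["X", "Z"] <- M["Z", "X"] <- 0.6
  M["Y", "Z"] <- M["Z", "Y"] <- 1.0
  M["Q", c("X", "Y", "Z")] <- M[c("X", "Y", "Z"), "Q"] <- 0.1
  cm <- structure(list(values = M, counts = M * 0 + 10, skipped = 0L,
                       method_ids = ids, algorithm = "merged", u = 2,
                       B = 10, rate = 0.8, measure = "sokal_michener",
                       resample_unit = "items", seed = 1),
                  class = "consensus_matrix")
  rob <- consensus_robustness(cm, stats::setNames(c(1, 1, 1, 2), ids))
  # member touching the 0.8 and 0.6 links averages to 0.7
  expect_equal(rob$membership[["X"]], 0.7)
  expect_equal(rob$membership[["Y"]], 0.9)
  # cluster robustness averages the three within pairs
  expect_equal(rob$cluster[["cluster1"]], mean(c(0.8, 0.6, 1.0)))
  # the singleton is flagged and scored by whole-panel connectivity
  expect_true(rob$singleton[["Q"]])
  expect_equal(rob$membership[["Q"]], 0.1)
  expect_equal(rob$cluster[["cluster2"]], 1)
  # perfect within-cluster consensus gives membership 1
  rob2 <- consensus_robustness(cm, stats::setNames(c(1, 2, 2, 1), ids))
  expect_equal(rob2$membership[["Y"]], 1)
  expect_equal(rob2$membership[["Z"]], 1)
})

test_that("consensus estimates converge as the number of resamples grows", {
  m <- planted_matrix(n_items = 200, epsilon = 0.25, seed = 10)
  Ms <- lapply(c(25, 50, 100, 200), function(B)
    consensus_matrix(m, "average", u = 2, B = B, seed = 50)$values)
  gaps <- c(max(abs(Ms[[1]] - Ms[[2]])), max(abs(Ms[[2]] - Ms[[3]])),
            max(abs(Ms[[3]] - Ms[[4]])))
  expect_lte(gaps[3], gaps[1])
})

test_that("the planted outlier has the minimum membership robustness", {
  m <- planted_matrix(n_items = 400, epsilon = 0.05, outlier = "OUT",
                      seed = 14)
  algs <- c("average", "kmedoids", "complete", "ward", "diana")
  merged <- merge_consensus(lapply(algs, function(a)
    consensus_matrix(m, a, u = 2, B = 40, seed = 60)))
  p <- cluster_from_consensus(merged, 2)
  rob <- consensus_robustness(merged, p)
  expect_equal(names(which.min(rob$membership)), "OUT")
})
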