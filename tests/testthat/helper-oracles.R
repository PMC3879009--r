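# Independent oracles and random-instance generators shared by the tests.
# The oracles deliberately use naive element-by-element enumeration so they
# stay independent of the package's vectorised implementations.

# contingency counts by explicit loop
oracle_contingency <- function(x, y) {
  a <- b <- cc <- d <- 0L
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) a <- a + 1L
    else if (x[i] == 1 && y[i] == 0) b <- b + 1L
    else if (x[i] == 0 && y[i] == 1) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# the three similarity formulas, evaluated directly on scalar counts
oracle_similarity <- function(t, measure) {
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  if (measure == "sokal_michener") {
    (a + d) / (a + b + cc + d)
  } else if (measure == "rogers_tanimoto") {
    (a + d) / (a + 2 * (b + cc) + d)
  } else {
    if (b == 0 && cc == 0) return(1)
    den <- sqrt((a + b) * (a + cc) * (b + d) * (cc + d))
    if (den == 0) 0 else a * d / den
  }
}

# Baker-Hubert Gamma by brute-force enumeration of every
# (within-pair, between-pair) comparison
oracle_gamma <- function(dmat, labels) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  within <- c(); between <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) within <- c(within, dmat[i, j])
    else between <- c(between, dmat[i, j])
  }
  sp <- sm <- 0L
  for (w in within) for (b in between) {
    if (b > w) sp <- sp + 1L
    if (b < w) sm <- sm + 1L
  }
  if (sp + sm == 0) return(NA_real_)
  (sp - sm) / (sp + sm)
}

random_binary_vector <- function(n) sample(0:1, n, replace = TRUE)

random_peptides <- function(n, L = 6L) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  apply(matrix(sample(aas, n * L, replace = TRUE), n, L), 1, paste,
        collapse = "")
}

# random symmetric distance matrix as a dist object with n objects
random_dist <- function(n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  as.dist(m + t(m))
}

# random partition of n objects with >= 2 clusters and >= 1 within pair
random_partition <- function(n) {
  repeat {
    k <- sample(2:(n - 1), 1)
    p <- sample(rep(seq_len(k), length.out = n))
    if (length(unique(p)) >= 2 && any(table(p) >= 2)) return(p)
  }
}

# small planted classification matrix: two blocks, optional outlier
planted_matrix <- function(n_items = 300, epsilon = 0, outlier = NULL,
                           seed = 1) {
  simulate_classifications(matrix_sim_spec(
    n_items = n_items,
    blocks = c(A1 = 1L, A2 = 1L, A3 = 1L, B1 = 2L, B2 = 2L, B3 = 2L),
    outlier = outlier, epsilon = epsilon, seed = seed))
}
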