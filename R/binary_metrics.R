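# 2x2 contingency tables for pairs of binary decision vectors and the three
# binary similarity measures used to compare classifier panels. All three
# count negative matches (d) as well as positive ones (a): two methods that
# both call a peptide non-amyloid agree just as much as two that both call
# it amyloid.

#' 2x2 contingency table for a pair of binary vectors
#'
#' Counts `a` = both positive (n11), `b` = first positive / second negative
#' (n10), `c` = first negative / second positive (n01), `d` = both negative
#' (n00).
#'
#' @param x,y binary vectors (0/1) of equal length.
#' @return An object of class `contingency_table`: a named integer vector
#'   `c(a, b, c, d)`.
#' @examples
#' contingency(c(1, 0, 1, 1), c(1, 1, 0, 1))  # a=2 b=1 c=1 d=0
#' @export
contingency <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y))
    stop("vectors differ in length (", length(x), " vs ", length(y), ")")
  if (length(x) < 1L) stop("vectors must have length >= 1")
  if (!all(x %in% c(0L, 1L)) || !all(y %in% c(0L, 1L)))
    stop("vectors must be binary (0/1)")
  structure(c(a = sum(x == 1L & y == 1L),
              b = sum(x == 1L & y == 0L),
              c = sum(x == 0L & y == 1L),
              d = sum(x == 0L & y == 0L)),
            class = "contingency_table")
}

# vectorised similarity kernels over contingency counts; each returns values
# in [0,1] and treats a+d agreement symmetrically in 0s and 1s
.sim_sokal_michener <- function(a, b, c, d) (a + d) / (a + b + c + d)

.sim_rogers_tanimoto <- function(a, b, c, d) (a + d) / (a + 2 * (b + c) + d)

.sim_sokal_sneath <- function(a, b, c, d) {
  # Sokal-Sneath V: ad / sqrt((a+b)(a+c)(b+d)(c+d)).
  # b=c=0 means identical vectors -> 1 even when a marginal is 0 (all-0 or
  # all-1 vectors); otherwise a zero marginal factor yields 0.
  denom <- sqrt((a + b) * (a + c) * (b + d) * (c + d))
  out <- ifelse(b + c == 0, 1, ifelse(denom == 0, 0, a * d / denom))
  # guard the ifelse branch that still evaluated a*d/denom with denom 0
  out[is.nan(out)] <- 0
  out
}

.SIMILARITY_MEASURES <- list(
  sokal_michener = .sim_sokal_michener,
  rogers_tanimoto = .sim_rogers_tanimoto,
  sokal_sneath = .sim_sokal_sneath
)

#' Names of the available binary similarity measures
#' @return Character vector of measure names accepted by
#'   [binary_similarity()] and [distance_matrix()].
#' @export
similarity_measures <- function() names(.SIMILARITY_MEASURES)

#' Binary similarity of a contingency table
#'
#' * `sokal_michener`: (a+d) / (a+b+c+d) — the simple matching coefficient.
#' * `rogers_tanimoto`: (a+d) / (a+2(b+c)+d) — mismatches weighted double.
#' * `sokal_sneath`: ad / sqrt((a+b)(a+c)(b+d)(c+d)) — geometric mean of the
#'   four conditional agreement probabilities. Degenerate marginals: if
#'   b = c = 0 the vectors are identical and the similarity is 1; otherwise
#'   a zero marginal factor yields 0.
#'
#' @param t a [contingency()] table (or named vector with a, b, c, d).
#' @param measure one of [similarity_measures()].
#' @return Similarity in `[0, 1]`.
#' @examples
#' t <- contingency(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' binary_similarity(t, "sokal_michener")  # 0.5
#' @export
binary_similarity <- function(t, measure = similarity_measures()) {
  measure <- match.arg(measure)
  a <- t[["a"]]; b <- t[["b"]]; c <- t[["c"]]; d <- t[["d"]]
  if (any(c(a, b, c, d) < 0)) stop("contingency counts must be >= 0")
  if (a + b + c + d == 0) stop("empty contingency table")
  unname(.SIMILARITY_MEASURES[[measure]](a, b, c, d))
}

#' Pairwise method distance matrix from a classification matrix
#'
#' Computes the chosen binary similarity between every pair of method
#' columns and returns the dissimilarity `d = 1 - s` as a `"dist"` object
#' (symmetric, zero diagonal, entries in `[0, 1]`), ready for
#' [agglomerate()], [divisive()] and [kmedoids()].
#'
#' @param m a [classification_matrix()].
#' @param measure one of [similarity_measures()].
#' @return A `stats::dist` object over the methods, with attribute `measure`.
#' @export
distance_matrix <- function(m, measure = similarity_measures()) {
  stopifnot(inherits(m, "classification_matrix"))
  measure <- match.arg(measure)
  X <- m$values
  storage.mode(X) <- "double"
  A <- crossprod(X)                 # n11 for every column pair
  B <- crossprod(X, 1 - X)          # n10 (rows = first method)
  D <- crossprod(1 - X)             # n00
  S <- .SIMILARITY_MEASURES[[measure]](A, B, t(B), D)
  dm <- as.dist(1 - S)
  attr(dm, "Labels") <- m$method_ids
  attr(dm, "measure") <- measure
  dm
}

#' Write a distance matrix as a labelled square TSV
#'
#' @param d a `dist` object as returned by [distance_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  out <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
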