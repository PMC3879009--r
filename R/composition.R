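# Position-specific composition audit: frequency profiles, ratios against a
# background distribution, sequence-logo information content, and
# exact-sequence overlap between datasets.

#' Position-specific residue frequencies
#'
#' Counts, per position 1..L, how many peptides carry each residue, and
#' converts counts to proportions. Duplicate peptides contribute each time
#' they occur.
#'
#' @param dataset a [peptide_dataset()].
#' @return An object of class `composition_profile` with elements `counts`
#'   and `freqs` (L x 20 matrices, rows = positions, columns = residues in
#'   alphabetical one-letter order), `n` (number of peptides) and `length`.
#' @examples
#' d <- peptide_dataset(c("STVIIE", "STVIIE"), c(1, 1))
#' position_frequencies(d)$freqs["pos2", "T"]  # 1
#' @export
position_frequencies <- function(dataset) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  n <- length(dataset$peptides)
  L <- dataset$length
  chars <- matrix(unlist(strsplit(dataset$peptides, "", fixed = TRUE)),
                  nrow = n, ncol = L, byrow = TRUE)
  counts <- t(apply(chars, 2L, function(col)
    table(factor(col, levels = AA_ALPHABET))))
  counts <- matrix(as.integer(counts), nrow = L,
                   dimnames = list(paste0("pos", seq_len(L)), AA_ALPHABET))
  structure(list(counts = counts, freqs = counts / n, n = n, length = L),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("Composition profile: ", x$n, " peptides of length ", x$length, "\n",
      sep = "")
  print(round(x$freqs, 3))
  invisible(x)
}

#' Over/under-representation ratios against a background
#'
#' For every (residue, position) cell the ratio
#' `r(aa, pos) = f_dataset(aa, pos) / f_background(aa)` is computed against a
#' position-independent background. Values above 1 indicate
#' over-representation at that position; a cell with zero dataset count has
#' ratio exactly 0. Values are kept at full precision; use
#' [format_ratio_table()] for the 1-decimal report layout.
#'
#' @param profile a [position_frequencies()] profile.
#' @param background a [background_frequencies()]; defaults to the shipped
#'   Swiss-Prot snapshot.
#' @return An object of class `ratio_table`: element `ratios` is an L x 20
#'   matrix (positions x residues), `source` records the background
#'   provenance.
#' @export
background_ratio <- function(profile, background = default_background()) {
  stopifnot(inherits(profile, "composition_profile"),
            inherits(background, "background_frequencies"))
  ratios <- sweep(profile$freqs, 2L, background$freq[colnames(profile$freqs)],
                  "/")
  structure(list(ratios = ratios, source = background$source),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat("Residue representation ratios vs background (", x$source, ")\n",
      sep = "")
  print(format_ratio_table(x))
  invisible(x)
}

#' Report-shaped ratio table
#'
#' Lays the ratio matrix out as residues (rows, in the conventional report
#' order) by positions (columns), rounded to 1 decimal. Zero-count cells
#' print as `0.0`.
#'
#' @param x a [background_ratio()] table.
#' @param digits decimals in the report (default 1).
#' @return A numeric matrix, residues x positions.
#' @export
format_ratio_table <- function(x, digits = 1L) {
  stopifnot(inherits(x, "ratio_table"))
  round(t(x$ratios)[AA_REPORT_ORDER, , drop = FALSE], digits)
}

#' Sequence-logo information content
#'
#' Per-position information content in bits,
#' `R_p = log2(20) - H_p (- e_n)`, where `H_p` is the Shannon entropy of the
#' position's residue frequencies (terms with zero frequency contribute 0)
#' and `e_n = 19 / (2 ln(2) n)` is the optional small-sample correction.
#' `R_p` is clipped below at 0. Per-residue logo stack heights are
#' `f(r, p) * R_p`.
#'
#' @param profile a [position_frequencies()] profile.
#' @param small_sample_correction apply the small-sample correction
#'   (default `FALSE`; the audit's typical n is in the thousands).
#' @return A list with `bits` (per-position vector), `stack_heights`
#'   (L x 20 matrix) and `correction` (the `e_n` applied, 0 if off).
#' @export
information_content <- function(profile, small_sample_correction = FALSE) {
  stopifnot(inherits(profile, "composition_profile"))
  H <- apply(profile$freqs, 1L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  e_n <- if (small_sample_correction) 19 / (2 * log(2) * profile$n) else 0
  bits <- pmax(log2(20) - H - e_n, 0)
  list(bits = bits, stack_heights = profile$freqs * bits, correction = e_n)
}

#' Exact-sequence overlap between two peptide datasets
#'
#' Counts distinct peptide strings occurring in both sets. The reported
#' fraction divides by the query's size: raw (with duplicates; the default,
#' matching how dataset-contribution percentages are conventionally quoted)
#' or distinct.
#'
#' @param query,reference [peptide_dataset()]s of the same peptide length.
#' @param denominator `"raw"` (query size including duplicates) or
#'   `"distinct"` (number of distinct query strings).
#' @return An object of class `overlap_report` with `n_shared`, `fraction`,
#'   `shared` (the matching strings) and the sizes used.
#' @examples
#' q <- peptide_dataset(c("STVIIE", "AAAAAA"), c(1, 1))
#' r <- peptide_dataset(c("STVIIE", "CCCCCC"), c(1, 1))
#' dataset_overlap(q, r)$n_shared  # 1
#' @export
dataset_overlap <- function(query, reference,
                            denominator = c("raw", "distinct")) {
  stopifnot(inherits(query, "peptide_dataset"),
            inherits(reference, "peptide_dataset"))
  denominator <- match.arg(denominator)
  if (query$length != reference$length)
    stop("peptide length mismatch: query L=", query$length,
         ", reference L=", reference$length)
  shared <- intersect(unique(query$peptides), unique(reference$peptides))
  denom <- if (denominator == "raw") length(query$peptides)
           else length(unique(query$peptides))
  structure(list(n_shared = length(shared),
                 fraction = length(shared) / denom,
                 shared = shared,
                 query_size = length(query$peptides),
                 denominator = denominator,
                 query = query$name, reference = reference$name),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Overlap of \"", x$query, "\" with \"", x$reference, "\": ",
      x$n_shared, " shared peptides (",
      sprintf("%.1f%%", 100 * x$fraction), " of ", x$denominator,
      " query size)\n", sep = "")
  invisible(x)
}
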