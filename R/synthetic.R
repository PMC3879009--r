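# Synthetic data with the statistical structure the audit detects:
# peptide sets with a planted position-specific motif bias over a background
# composition, and classification matrices with planted method blocks plus
# one outlier method and per-method flip noise.

#' Specification for simulating peptide datasets
#'
#' Describes a positive set carrying a planted motif bias and a matched
#' unbiased negative set. Defaults mirror the scale of a hexapeptide
#' training-set audit: 1226 positives and 1226 negatives of length 6, with
#' 5.4% of the positives carrying the STVIIE motif (the contribution an
#' experimental hexapeptide set makes when folded into a windowed training
#' set).
#'
#' @param n_pos,n_neg set sizes.
#' @param background a [background_frequencies()] the residues are drawn
#'   from.
#' @param motif planted residue string; its length fixes the peptide length.
#' @param injection_rate fraction q of positives carrying the motif.
#' @param blend `"replace"` (an injected peptide is the motif verbatim) or
#'   `"per-position"` (each position of an injected peptide takes the motif
#'   residue with probability `bias`, else a background draw — diffuse
#'   enrichment rather than whole-motif duplication).
#' @param bias per-position motif probability for `blend = "per-position"`.
#' @param seed RNG seed.
#' @return An object of class `peptide_sim_spec`.
#' @export
peptide_sim_spec <- function(n_pos = 1226L, n_neg = 1226L,
                             background = default_background(),
                             motif = "STVIIE", injection_rate = 0.054,
                             blend = c("replace", "per-position"),
                             bias = 0.8, seed = 1L) {
  blend <- match.arg(blend)
  stopifnot(inherits(background, "background_frequencies"),
            n_pos >= 1L, n_neg >= 1L,
            injection_rate >= 0, injection_rate <= 1,
            bias >= 0, bias <= 1, nchar(motif) >= 1L)
  if (!grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), motif))
    stop("motif contains a non-canonical residue")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 background = background, motif = motif,
                 injection_rate = injection_rate, blend = blend,
                 bias = bias, seed = as.integer(seed)),
            class = "peptide_sim_spec")
}

# n peptides of length L drawn i.i.d. per position from the background
.draw_background_peptides <- function(n, L, background) {
  chars <- sample(names(background$freq), n * L, replace = TRUE,
                  prob = background$freq)
  apply(matrix(chars, nrow = n, ncol = L), 1L, paste, collapse = "")
}

#' Simulate a positive/negative peptide dataset pair
#'
#' Negatives are drawn i.i.d. per position from the background; positives
#' likewise, except a fraction `injection_rate` of them carries the motif
#' according to the blend mode. Byte-identical output for a given spec.
#'
#' @param spec a [peptide_sim_spec()].
#' @return A list with elements `positive` and `negative`, each a
#'   [peptide_dataset()].
#' @examples
#' sets <- simulate_peptides(peptide_sim_spec(n_pos = 50, n_neg = 50))
#' @export
simulate_peptides <- function(spec) {
  stopifnot(inherits(spec, "peptide_sim_spec"))
  set.seed(spec$seed)
  L <- nchar(spec$motif)
  pos <- .draw_background_peptides(spec$n_pos, L, spec$background)
  neg <- .draw_background_peptides(spec$n_neg, L, spec$background)
  n_inject <- round(spec$injection_rate * spec$n_pos)
  if (n_inject > 0L) {
    idx <- sample.int(spec$n_pos, n_inject)
    if (spec$blend == "replace") {
      pos[idx] <- spec$motif
    } else {
      motif_chars <- strsplit(spec$motif, "")[[1L]]
      for (i in idx) {
        chars <- strsplit(pos[i], "")[[1L]]
        take <- runif(L) < spec$bias
        chars[take] <- motif_chars[take]
        pos[i] <- paste(chars, collapse = "")
      }
    }
  }
  list(positive = peptide_dataset(pos, rep(1L, spec$n_pos),
                                  name = "sim_positive"),
       negative = peptide_dataset(neg, rep(0L, spec$n_neg),
                                  name = "sim_negative"))
}

#' Specification for simulating classification matrices
#'
#' Describes a panel with planted method blocks (ground-truth clusters) and
#' one outlier method. Per item, each block draws a latent binary call
#' (probability `pi` of a positive); each non-outlier method reports its
#' block's call flipped independently with probability `epsilon`; the
#' outlier reports an independent coin with rate `pi_out`. Defaults mirror
#' the audited panel's shape: 2452 items and 12 methods — a 5-method block
#' (FoldAmyloid-like variants), a 6-method block (Waltz-like variants plus a
#' consensus method) and the outlier `P`.
#'
#' @param n_items number of items (peptides).
#' @param blocks named integer vector mapping each non-outlier method id to
#'   its block id.
#' @param outlier outlier method id, or `NULL` for no outlier.
#' @param pi latent positive rate per block call (amyloid calls are the
#'   minority for a typical panel).
#' @param epsilon per-method flip noise in `[0, 0.5)`.
#' @param pi_out outlier positive rate; 0.5 is a pure coin flip.
#' @param seed RNG seed.
#' @return An object of class `matrix_sim_spec`.
#' @export
matrix_sim_spec <- function(n_items = 2452L,
                            blocks = c(FAEC = 1L, FABBD = 1L, FABBA = 1L,
                                       FAH = 1L, FATH = 1L,
                                       W2679 = 2L, W779 = 2L, W2692 = 2L,
                                       W792 = 2L, W797 = 2L, AP = 2L),
                            outlier = "P", pi = 0.2, epsilon = 0.05,
                            pi_out = 0.5, seed = 1L) {
  stopifnot(n_items >= 3L, length(blocks) >= 2L,
            pi > 0, pi < 1, epsilon >= 0, epsilon < 0.5,
            pi_out > 0, pi_out < 1)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    stop("blocks must be a named vector (method id -> block id)")
  if (!is.null(outlier) && outlier %in% names(blocks))
    stop("outlier id collides with a block method id")
  structure(list(n_items = as.integer(n_items),
                 blocks = setNames(as.integer(blocks), names(blocks)),
                 outlier = outlier, pi = pi, epsilon = epsilon,
                 pi_out = pi_out, seed = as.integer(seed)),
            class = "matrix_sim_spec")
}

#' Simulate a classification matrix with planted blocks and an outlier
#'
#' @param spec a [matrix_sim_spec()].
#' @return A [classification_matrix()] whose columns are the outlier (if
#'   any) followed by the block methods, items named `pep<i>`.
#' @examples
#' m <- simulate_classifications(matrix_sim_spec(n_items = 100))
#' @export
simulate_classifications <- function(spec) {
  stopifnot(inherits(spec, "matrix_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_items
  block_ids <- sort(unique(spec$blocks))
  latent <- sapply(block_ids, function(b) rbinom(n, 1L, spec$pi))
  colnames(latent) <- as.character(block_ids)
  cols <- list()
  if (!is.null(spec$outlier))
    cols[[spec$outlier]] <- rbinom(n, 1L, spec$pi_out)
  for (method in names(spec$blocks)) {
    base <- latent[, as.character(spec$blocks[[method]])]
    flips <- rbinom(n, 1L, spec$epsilon)
    cols[[method]] <- as.integer(xor(base, flips))
  }
  values <- do.call(cbind, cols)
  rownames(values) <- paste0("pep", seq_len(n))
  classification_matrix(values)
}
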