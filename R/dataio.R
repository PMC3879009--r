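# Domain containers and readers/writers for the three external formats:
# peptide sets (plain / FASTA / labelled TSV), classification matrices
# (CSV/TSV), and background amino-acid frequency tables.

#' Construct a fixed-length peptide dataset
#'
#' A `peptide_dataset` holds fixed-length peptides over the 20-letter
#' amino-acid alphabet together with binary amyloid labels
#' (1 = amylopositive, 0 = amylonegative). Duplicate peptide strings are
#' permitted; the composition and overlap audits count them.
#'
#' @param peptides character vector of peptides, all of the same length.
#' @param labels binary labels (0/1, or a logical vector), one per peptide.
#' @param name free-text identifier carried into reports.
#' @return An object of class `peptide_dataset` with elements `peptides`,
#'   `labels` (integer 0/1), `length` (the common peptide length) and `name`.
#' @examples
#' peptide_dataset(c("STVIIE", "AAAAAA"), labels = c(1, 1), name = "toy")
#' @export
peptide_dataset <- function(peptides, labels, name = "dataset") {
  peptides <- as.character(peptides)
  if (length(peptides) == 0L)
    stop("peptide dataset must contain at least one peptide")
  if (length(labels) != length(peptides))
    stop("labels must have the same length as peptides (",
         length(labels), " vs ", length(peptides), ")")
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary (0/1)")
  nc <- nchar(peptides)
  L <- nc[1L]
  if (L < 1L) stop("peptides must have length >= 1")
  if (any(nc != L)) {
    bad <- which(nc != L)[1L]
    stop("ragged peptide lengths: peptide ", bad, " (\"", peptides[bad],
         "\") has length ", nc[bad], ", expected ", L)
  }
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), peptides)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("non-canonical residue in peptide ", bad, " (\"", peptides[bad], "\")")
  }
  structure(list(peptides = peptides, labels = labels, length = L,
                 name = as.character(name)[1L]),
            class = "peptide_dataset")
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cat("Peptide dataset \"", x$name, "\": ", length(x$peptides),
      " peptides of length ", x$length, " (", sum(x$labels == 1L),
      " positive, ", sum(x$labels == 0L), " negative)\n", sep = "")
  invisible(x)
}

#' Subset a peptide dataset by label
#'
#' @param dataset a [peptide_dataset()].
#' @param subset one of `"positive"`, `"negative"`, `"all"`.
#' @return A `peptide_dataset` restricted to the requested label class.
#' @export
subset_peptides <- function(dataset, subset = c("all", "positive", "negative")) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  subset <- match.arg(subset)
  keep <- switch(subset,
                 all = rep(TRUE, length(dataset$peptides)),
                 positive = dataset$labels == 1L,
                 negative = dataset$labels == 0L)
  if (!any(keep)) stop("no peptides with subset = \"", subset, "\"")
  peptide_dataset(dataset$peptides[keep], dataset$labels[keep],
                  name = paste0(dataset$name, "(", subset, ")"))
}

#' Construct a classification matrix
#'
#' A `classification_matrix` stores the binary decisions of a panel of
#' classification methods (columns) over a set of items (rows, typically
#' peptides). This is the object the whole clustering analysis runs on.
#'
#' @param values numeric/integer matrix of 0/1 decisions, items x methods.
#' @param item_ids row identifiers; defaults to existing rownames or `item<i>`.
#' @param method_ids ordered method names; defaults to existing colnames.
#' @return An object of class `classification_matrix` with elements `values`
#'   (integer matrix with dimnames), `item_ids` and `method_ids`.
#' @examples
#' m <- classification_matrix(cbind(A = c(1, 0, 1), B = c(1, 1, 0)))
#' @export
classification_matrix <- function(values, item_ids = NULL, method_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(method_ids)) method_ids <- colnames(values)
  if (is.null(method_ids))
    stop("method_ids must be supplied (or values must have colnames)")
  method_ids <- as.character(method_ids)
  if (anyDuplicated(method_ids))
    stop("duplicate method name: \"",
         method_ids[duplicated(method_ids)][1L], "\"")
  if (is.null(item_ids)) item_ids <- rownames(values)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(nrow(values)))
  item_ids <- as.character(item_ids)
  if (ncol(values) < 2L) stop("need at least 2 methods")
  if (nrow(values) < 3L) stop("need at least 3 items")
  if (length(item_ids) != nrow(values) || length(method_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  bad <- which(is.na(values) | !(values %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop("cell outside {0,1} at row ", i, " (", item_ids[i],
         "), column ", method_ids[j])
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(item_ids, method_ids)
  structure(list(values = values, item_ids = item_ids,
                 method_ids = method_ids),
            class = "classification_matrix")
}

#' @export
print.classification_matrix <- function(x, ...) {
  cat("Classification matrix: ", length(x$item_ids), " items x ",
      length(x$method_ids), " methods (",
      paste(x$method_ids, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Construct a background amino-acid frequency table
#'
#' @param freq named numeric vector mapping each of the 20 canonical residues
#'   to its background proportion; must be strictly positive and sum to 1
#'   (tolerance 1e-9).
#' @param source free-text provenance, e.g. a database release identifier.
#' @return An object of class `background_frequencies`.
#' @seealso [default_background()] for the shipped Swiss-Prot snapshot.
#' @export
background_frequencies <- function(freq, source = "unspecified") {
  freq <- unlist(freq)
  missing <- setdiff(AA_ALPHABET, names(freq))
  if (length(missing))
    stop("missing residue ", paste(missing, collapse = ", "),
         " in background table")
  extra <- setdiff(names(freq), AA_ALPHABET)
  if (length(extra))
    stop("unknown residue ", paste(extra, collapse = ", "),
         " in background table")
  freq <- freq[AA_ALPHABET]
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop("all background frequencies must be finite and > 0")
  if (abs(sum(freq) - 1) > 1e-9)
    stop("background frequencies sum to ", format(sum(freq), digits = 12),
         ", not 1 (tolerance 1e-9)")
  structure(list(freq = freq, source = as.character(source)[1L]),
            class = "background_frequencies")
}

#' @export
print.background_frequencies <- function(x, ...) {
  cat("Background amino-acid frequencies (source: ", x$source, ")\n", sep = "")
  print(round(x$freq, 4))
  invisible(x)
}

#' Read a peptide dataset
#'
#' Supported dialects: `plain` (one peptide per line), `fasta` (sequence =
#' peptide), and `tsv` (labelled: `peptide<TAB>label`, label 0/1). For
#' `plain` and `fasta` a single `label` for the whole file is required; for
#' `tsv` the second column supplies per-peptide labels.
#'
#' @param path file path.
#' @param format one of `"plain"`, `"fasta"`, `"tsv"`.
#' @param label whole-file label (0/1 or "positive"/"negative"); required for
#'   `plain` and `fasta`, ignored for `tsv`.
#' @param name dataset identifier; defaults to the file name.
#' @return A [peptide_dataset()].
#' @export
read_peptides <- function(path, format = c("plain", "fasta", "tsv"),
                          label = NULL, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- basename(path)
  lab1 <- function(label) {
    if (is.null(label))
      stop("format \"", format, "\" requires an explicit whole-file label")
    if (is.character(label))
      label <- switch(label, positive = 1L, negative = 0L,
                      stop("label must be 0/1 or \"positive\"/\"negative\""))
    as.integer(label)
  }
  if (format == "plain") {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    peptide_dataset(lines, rep(lab1(label), length(lines)), name = name)
  } else if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    peptide_dataset(as.character(seqs), rep(lab1(label), length(seqs)),
                    name = name)
  } else {
    tab <- read.delim(path, header = FALSE, sep = "\t",
                      colClasses = "character", comment.char = "#")
    if (ncol(tab) < 2L)
      stop("labelled TSV must have at least 2 columns (peptide, label)")
    labs <- suppressWarnings(as.integer(tab[[2L]]))
    badlab <- which(is.na(labs) | !(labs %in% c(0L, 1L)))
    if (length(badlab))
      stop("non-binary label at row ", badlab[1L], " (\"",
           tab[[2L]][badlab[1L]], "\")")
    peptide_dataset(trimws(tab[[1L]]), labs, name = name)
  }
}

#' Write a peptide dataset
#'
#' @inheritParams read_peptides
#' @param dataset a [peptide_dataset()].
#' @return `path`, invisibly.
#' @export
write_peptides <- function(dataset, path, format = c("plain", "fasta", "tsv")) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  format <- match.arg(format)
  if (format == "plain") {
    writeLines(dataset$peptides, path)
  } else if (format == "fasta") {
    seqs <- Biostrings::AAStringSet(dataset$peptides)
    names(seqs) <- paste0("pep", seq_along(dataset$peptides),
                          "|label=", dataset$labels)
    Biostrings::writeXStringSet(seqs, path, width = 80L)
  } else {
    writeLines(paste(dataset$peptides, dataset$labels, sep = "\t"), path)
  }
  invisible(path)
}

# sniff comma vs tab from the header line
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a classification matrix
#'
#' Expects delimited text (comma or tab, auto-detected from the header line)
#' with a header row of method names, the first column holding item
#' identifiers and the remaining cells 0/1.
#'
#' @param path file path.
#' @return A [classification_matrix()] with methods in file order.
#' @export
read_classification_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 3L)
    stop("classification matrix needs an item-id column and >= 2 methods")
  method_ids <- colnames(tab)[-1L]
  if (anyDuplicated(method_ids))
    stop("duplicate method name: \"",
         method_ids[duplicated(method_ids)][1L], "\"")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(num)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(num)) + 1L
    stop("cell \"", vals[bad[1L]], "\" outside {0,1} at row ", i,
         ", column ", method_ids[j])
  }
  m <- classification_matrix(num, item_ids = tab[[1L]],
                             method_ids = method_ids)
  message("read classification matrix: ", length(m$item_ids), " items x ",
          length(m$method_ids), " methods from ", path)
  m
}

#' Write a classification matrix
#'
#' @param m a [classification_matrix()].
#' @param path output file path.
#' @param sep field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_classification_matrix <- function(m, path, sep = "\t") {
  stopifnot(inherits(m, "classification_matrix"))
  out <- data.frame(id = m$item_ids, m$values, check.names = FALSE)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a background frequency table
#'
#' Expects a two-column table `residue<TAB>frequency` covering all 20
#' canonical residues, frequencies summing to 1 (tolerance 1e-9). A comment
#' line `# source: <text>` records provenance.
#'
#' @param path file path.
#' @return A [background_frequencies()].
#' @export
read_background <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  src <- sub("^#\\s*source:\\s*", "", grep("^#\\s*source:", lines, value = TRUE))
  if (length(src) == 0L) src <- "unspecified"
  tab <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                    col.names = c("residue", "freq"),
                    colClasses = c("character", "numeric"))
  background_frequencies(setNames(tab$freq, tab$residue), source = src[1L])
}

#' Write a background frequency table
#'
#' @param background a [background_frequencies()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_background <- function(background, path) {
  stopifnot(inherits(background, "background_frequencies"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# source: ", background$source), con)
  writeLines(paste(names(background$freq),
                   format(background$freq, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' The shipped default background table
#'
#' A frozen snapshot of UniProtKB/Swiss-Prot global residue frequencies
#' (circa 2013 releases), normalised to sum exactly to 1. Used as the default
#' reference for [background_ratio()]; override by reading your own table
#' with [read_background()].
#'
#' @return A [background_frequencies()].
#' @export
default_background <- function() {
  read_background(system.file("extdata", "swissprot_background.tsv",
                              package = "amylaudit", mustWork = TRUE))
}
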