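# Unanimous-voting ensemble audit: how often does a focal classifier agree
# with the items on which every other method in the panel votes the same way?

# half-up rounding to integer percent (round() in R rounds half to even)
.percent_half_up <- function(frac) {
  if (is.na(frac)) return(NA_real_)
  floor(frac * 100 + 0.5)
}

#' Agreement of a focal method with the panel's unanimous vote
#'
#' All methods except the focal one form the base panel. Items on which
#' every base method votes 0 are the unanimous negatives; items on which
#' every base method votes 1 are the unanimous positives (the two sets are
#' disjoint). For each set, the agreement is the fraction of its items on
#' which the focal method casts the same vote. A focal method whose
#' negative-set agreement is close to 50% behaves like a coin flip relative
#' to the panel consensus.
#'
#' @param m a [classification_matrix()].
#' @param focal method id to audit.
#' @return An object of class `vote_report` with counts
#'   (`n_unanimous_negative`, `n_unanimous_positive`), full-precision
#'   agreements (`agreement_negative`, `agreement_positive`; `NA` when the
#'   corresponding unanimous set is empty), half-up integer percents
#'   (`agreement_negative_pct`, `agreement_positive_pct`), and the item id
#'   lists (`negative_items`, `positive_items`).
#' @examples
#' m <- classification_matrix(
#'   cbind(A = c(0, 0, 1, 0), B = c(0, 0, 1, 1), P = c(0, 1, 1, 1)))
#' unanimous_vote(m, focal = "P")$agreement_negative  # 0.5
#' @export
unanimous_vote <- function(m, focal) {
  stopifnot(inherits(m, "classification_matrix"))
  if (!focal %in% m$method_ids)
    stop("focal method \"", focal, "\" not in the matrix (methods: ",
         paste(m$method_ids, collapse = ", "), ")")
  base_ids <- setdiff(m$method_ids, focal)
  if (length(base_ids) < 1L)
    stop("need at least one base method besides the focal one")
  base <- m$values[, base_ids, drop = FALSE]
  fv <- m$values[, focal]
  neg <- rowSums(base) == 0L
  pos <- rowSums(base) == length(base_ids)
  agree <- function(idx, vote) {
    if (!any(idx)) return(NA_real_)
    mean(fv[idx] == vote)
  }
  a_neg <- agree(neg, 0L)
  a_pos <- agree(pos, 1L)
  structure(list(focal = focal, base_ids = base_ids,
                 n_unanimous_negative = sum(neg),
                 n_unanimous_positive = sum(pos),
                 agreement_negative = a_neg,
                 agreement_positive = a_pos,
                 agreement_negative_pct = .percent_half_up(a_neg),
                 agreement_positive_pct = .percent_half_up(a_pos),
                 negative_items = m$item_ids[neg],
                 positive_items = m$item_ids[pos]),
            class = "vote_report")
}

#' @export
print.vote_report <- function(x, ...) {
  fmt <- function(n, pct) {
    if (n == 0L) paste0(n, " items (agreement undefined)")
    else paste0(n, " items, focal agreement ", pct, "%")
  }
  cat("Unanimous-voting audit of \"", x$focal, "\" against ",
      length(x$base_ids), " base methods\n",
      "  unanimous negatives: ",
      fmt(x$n_unanimous_negative, x$agreement_negative_pct), "\n",
      "  unanimous positives: ",
      fmt(x$n_unanimous_positive, x$agreement_positive_pct), "\n", sep = "")
  invisible(x)
}

#' Write a vote report and its item lists
#'
#' Writes a one-row summary TSV plus two item-list files (`<prefix>` with
#' suffixes `_non_amyloids.txt` and `_amyloids.txt`) holding the unanimous
#' negative and positive item ids.
#'
#' @param report a [unanimous_vote()] report.
#' @param prefix output path prefix.
#' @return The summary path, invisibly.
#' @export
write_vote_report <- function(report, prefix) {
  stopifnot(inherits(report, "vote_report"))
  summary_path <- paste0(prefix, "_vote_report.tsv")
  out <- data.frame(focal = report$focal,
                    n_unanimous_negative = report$n_unanimous_negative,
                    agreement_negative = report$agreement_negative,
                    agreement_negative_pct = report$agreement_negative_pct,
                    n_unanimous_positive = report$n_unanimous_positive,
                    agreement_positive = report$agreement_positive,
                    agreement_positive_pct = report$agreement_positive_pct)
  write.table(out, summary_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(report$negative_items, paste0(prefix, "_non_amyloids.txt"))
  writeLines(report$positive_items, paste0(prefix, "_amyloids.txt"))
  invisible(summary_path)
}
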