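#' Weighted sum-of-pairs score of an alignment
#'
#' The fitness the genetic algorithm maximises. For every unordered row pair
#' (i, j) the two rows are projected by deleting their gap-gap columns (a
#' gap-gap column costs 0 and neither creates nor extends a gap run).
#' Residue-residue columns contribute `W_ij * m(a, b)` to the score of their
#' original column; every maximal gap run of length `n` in either projected
#' row contributes the affine penalty `W_ij * (g + n*x)`. `W_ij = w_i * w_j`
#' is the product of the CLUSTAL W sequence weights.
#'
#' @param aln An [msa].
#' @param w Sequence weight vector (defaults to unit weights).
#' @param m A substitution matrix.
#' @param gaps A [gap_model()].
#' @return An object of class `score_breakdown`: list with `total`,
#'   `per_column` (substitution part per column) and `gap_total` (summed
#'   affine penalties); `total = sum(per_column) + gap_total`.
#' @export
wspm <- function(aln, w = NULL, m = pam250(), gaps = gap_model()) {
  stopifnot(inherits(aln, "msa"))
  n <- aln_nrow(aln)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("weights do not match alignment rows")
  res <- cpp_wspm(msa_codes(aln), as.numeric(w), matrix_codes(m),
                  gaps$g, gaps$x)
  structure(res, class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("WSPM total ", format(x$total), " (substitution ",
      format(sum(x$per_column)), ", gaps ", format(x$gap_total), ")\n",
      sep = "")
  invisible(x)
}

#' Score a column range as a standalone sub-alignment
#'
#' Used by the multiple-point crossover to compare the leading/trailing 25%
#' of columns of two parents. The slice is cut out, canonicalised (all-gap
#' columns dropped) and scored with [wspm()]; gap runs therefore truncate at
#' the slice boundaries and re-charge an opening on each side.
#'
#' @param aln An [msa].
#' @param col_from,col_to 1-based inclusive column range.
#' @inheritParams wspm
#' @return A `score_breakdown` for the slice.
#' @export
wspm_range <- function(aln, col_from, col_to, w = NULL, m = pam250(),
                       gaps = gap_model()) {
  stopifnot(inherits(aln, "msa"))
  L <- aln_length(aln)
  if (!(col_from >= 1L && col_from <= col_to && col_to <= L))
    stop("empty or invalid column range")
  slice <- msa(substr(aln$rows, col_from, col_to), aln$ids)
  wspm(canonicalise(slice), w, m, gaps)
}

# residue-ordinal matrix: entry [i, l] is the ordinal of the residue of
# sequence i at column l, or NA for a gap
ordinal_matrix <- function(aln) {
  ch <- msa_chars(aln)
  out <- matrix(NA_integer_, nrow(ch), ncol(ch))
  for (i in seq_len(nrow(ch))) {
    res <- ch[i, ] != GAP_CHAR
    out[i, res] <- seq_len(sum(res))
  }
  out
}

check_comparable <- function(test, ref) {
  stopifnot(inherits(test, "msa"), inherits(ref, "msa"))
  ord <- match(ref$ids, test$ids)
  if (anyNA(ord)) stop("test and reference have different sequence ids")
  test <- msa(test$rows[ord], test$ids[ord])
  if (!identical(unname(ungap(test)), unname(ungap(ref))))
    stop("test and reference disagree on the ungapped sequences")
  test
}

#' Sum-of-pairs accuracy against a reference alignment
#'
#' The BAliBase-style SPS score: the fraction of aligned residue pairs of
#' the reference (two residues of different sequences sharing a column,
#' optionally restricted to core columns) that are also placed in a common
#' column of the test alignment. 1 means every reference pair is recovered,
#' 0 means none is.
#'
#' @param test,ref [msa] objects over the same sequences.
#' @param core_columns Optional integer vector of reference columns to score
#'   (BAliBase core-block style); default all columns.
#' @return Fraction in \[0, 1\].
#' @export
sps <- function(test, ref, core_columns = NULL) {
  test <- check_comparable(test, ref)
  cols <- if (is.null(core_columns)) seq_len(aln_length(ref)) else core_columns
  ord_ref <- ordinal_matrix(ref)
  ord_test <- ordinal_matrix(test)
  n <- aln_nrow(ref)
  # column index in test of residue (i, ordinal)
  col_of <- lapply(seq_len(n), function(i) {
    idx <- which(!is.na(ord_test[i, ]))
    idx[order(ord_test[i, idx])]
  })
  total <- 0
  matched <- 0
  for (l in cols) {
    rows <- which(!is.na(ord_ref[, l]))
    k <- length(rows)
    if (k < 2L) next
    total <- total + choose(k, 2L)
    tc <- vapply(rows, function(i) col_of[[i]][ord_ref[i, l]], integer(1L))
    matched <- matched + sum(choose(table(tc), 2L))
  }
  if (total == 0) stop("reference contains no aligned residue pairs")
  matched / total
}

#' Column-score accuracy against a reference alignment
#'
#' The fraction of (core) reference columns whose full residue content —
#' including which sequences are gapped — is reproduced as a column of the
#' test alignment.
#'
#' @inheritParams sps
#' @return Fraction in \[0, 1\].
#' @export
cs <- function(test, ref, core_columns = NULL) {
  test <- check_comparable(test, ref)
  cols <- if (is.null(core_columns)) seq_len(aln_length(ref)) else core_columns
  ord_ref <- ordinal_matrix(ref)
  ord_test <- ordinal_matrix(test)
  n <- aln_nrow(ref)
  col_of <- lapply(seq_len(n), function(i) {
    idx <- which(!is.na(ord_test[i, ]))
    idx[order(ord_test[i, idx])]
  })
  if (length(cols) == 0L) stop("reference contains no columns to score")
  hit <- vapply(cols, function(l) {
    rows <- which(!is.na(ord_ref[, l]))
    if (length(rows) == 0L) return(FALSE)
    tc <- vapply(rows, function(i) col_of[[i]][ord_ref[i, l]], integer(1L))
    if (length(unique(tc)) != 1L) return(FALSE)
    # gapped reference rows must also be gapped in that test column
    all(is.na(ord_test[setdiff(seq_len(n), rows), tc[1L]]))
  }, logical(1L))
  mean(hit)
}
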