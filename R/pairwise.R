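#' Global pairwise alignment with affine gaps
#'
#' Needleman–Wunsch/Gotoh global alignment maximising the sum of
#' substitution scores over residue-residue columns plus, for every maximal
#' gap run of length `n`, the affine penalty `G = g + n*x`. Terminal gaps
#' are penalised like internal ones. Traceback ties are broken
#' deterministically: diagonal, then gap in `b`, then gap in `a`.
#'
#' @param a,b Ungapped residue strings (optionally named by id).
#' @param m A [substitution_matrix][read_substitution_matrix].
#' @param gaps A [gap_model()].
#' @return An object of class `pairwise_alignment`: list with `row_a`,
#'   `row_b` (equal-length gapped strings), `score`, `align_length` and
#'   `mismatch_count` (columns that are not exact residue matches, counting
#'   residue-vs-gap columns).
#' @export
#' @examples
#' pw <- global_align("AAA", "AAA", pam250())
#' pw$score  # 6: three times m(A, A) = 2
global_align <- function(a, b, m = pam250(), gaps = gap_model()) {
  stopifnot(inherits(m, "substitution_matrix"), inherits(gaps, "gap_model"))
  av <- as.character(a)[[1L]]
  bv <- as.character(b)[[1L]]
  if (!nzchar(av) || !nzchar(bv)) stop("empty sequence")
  A <- chars_codes(matrix(strsplit(toupper(av), "")[[1L]], nrow = 1L))
  B <- chars_codes(matrix(strsplit(toupper(bv), "")[[1L]], nrow = 1L))
  res <- cpp_profile_align(A, B, matrix_codes(m), gaps$g, gaps$x)
  out <- codes_msa(res$codes, c("a", "b"))
  ca <- strsplit(out$rows[[1L]], "")[[1L]]
  cb <- strsplit(out$rows[[2L]], "")[[1L]]
  structure(list(
    row_a = out$rows[[1L]], row_b = out$rows[[2L]],
    ids = c(if (is.null(names(a))) "a" else names(a)[[1L]],
            if (is.null(names(b))) "b" else names(b)[[1L]]),
    score = res$score,
    align_length = length(ca),
    mismatch_count = sum(ca != cb | ca == GAP_CHAR)),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise alignment (", x$ids[1], ", ", x$ids[2], "): score ",
      format(x$score), ", length ", x$align_length, ", ",
      x$mismatch_count, " mismatches\n", sep = "")
  cat(x$row_a, x$row_b, sep = "\n")
  invisible(x)
}

#' Dynamic-programming distance of a sequence pair
#'
#' The observed distance `mismatch / align_length` of a global pairwise
#' alignment, in \[0, 1\]. Residue-vs-gap columns count as mismatches.
#'
#' @param pw A [global_align()] result.
#' @return Distance in \[0, 1\].
#' @export
dp_distance <- function(pw) {
  stopifnot(inherits(pw, "pairwise_alignment"), pw$align_length >= 1L)
  pw$mismatch_count / pw$align_length
}

#' Kimura protein distance of two aligned rows
#'
#' From the fraction of exact matches `S` over positions where both rows
#' carry a residue (gap positions are ignored), `D = 1 - S`, the corrected
#' distance is `-ln(1 - D - 0.2 D^2)`. Outside the valid domain (log
#' argument <= 1e-9, i.e. `D` beyond about 0.8541) the distance is capped at
#' 10 with a warning, so downstream neighbour joining always receives finite
#' input. Ambiguity codes count as matches only when the characters are
#' identical.
#'
#' @param row_a,row_b Equal-length gapped strings.
#' @return Nonnegative distance.
#' @export
kimura_distance <- function(row_a, row_b) {
  ca <- strsplit(toupper(row_a), "")[[1L]]
  cb <- strsplit(toupper(row_b), "")[[1L]]
  if (length(ca) != length(cb)) stop("rows differ in length")
  scored <- ca != GAP_CHAR & cb != GAP_CHAR
  n_scored <- sum(scored)
  if (n_scored == 0L) stop("no scored positions")
  s_frac <- sum(ca[scored] == cb[scored]) / n_scored
  d <- 1 - s_frac
  arg <- 1 - d - 0.2 * d^2
  if (arg <= 1e-9) {
    warning("Kimura distance out of domain (D = ", format(d),
            "); capped at 10")
    return(10)
  }
  -log(arg)
}

#' Pairwise distance matrices
#'
#' `distance_matrix_dp()` aligns every unordered sequence pair globally and
#' applies [dp_distance()]; `distance_matrix_kimura()` applies
#' [kimura_distance()] to every row pair of an existing alignment. Both
#' return a symmetric matrix with zero diagonal and sequence-id dimnames,
#' carrying the method name in attribute `"method"`.
#'
#' @param seqs Named character vector of >= 2 ungapped sequences.
#' @param m A substitution matrix.
#' @param gaps A [gap_model()].
#' @return Symmetric numeric distance matrix.
#' @export
distance_matrix_dp <- function(seqs, m = pam250(), gaps = gap_model()) {
  validate_sequences(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- dp_distance(
        global_align(seqs[[i]], seqs[[j]], m, gaps))
    }
  }
  attr(d, "method") <- "dp"
  d
}

#' Write a distance matrix as PHYLIP square text
#'
#' @param d A distance matrix with id dimnames (from
#'   [distance_matrix_dp()] or [distance_matrix_kimura()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  w <- max(nchar(rownames(d)), 10L)
  lines <- c(format(nrow(d), width = 5L),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(rownames(d)[i], width = -w),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  "))
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname distance_matrix_dp
#' @param aln An [msa] with >= 2 rows.
#' @export
distance_matrix_kimura <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  n <- aln_nrow(aln)
  if (n < 2L) stop("need at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- tryCatch(
        kimura_distance(aln$rows[[i]], aln$rows[[j]]),
        error = function(e) stop("pair (", aln$ids[i], ", ", aln$ids[j],
                                 "): ", conditionMessage(e), call. = FALSE))
    }
  }
  attr(d, "method") <- "kimura"
  d
}
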