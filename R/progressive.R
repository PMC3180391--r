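#' Profile-profile alignment
#'
#' Aligns two aligned groups by global affine-gap dynamic programming over
#' their columns. A column-column score is the mean over all cross pairs of
#' the substitution score, pairs involving an existing gap contributing 0.
#' A new gap run of length `n` inserted into a profile costs `g + n*x` once
#' per run, regardless of profile size. Gaps already present in either
#' profile are never removed.
#'
#' @param pa,pb [msa] objects (a single-row `msa` is a single sequence).
#' @param m A substitution matrix.
#' @param gaps A [gap_model()].
#' @return An `msa` containing all rows of `pa` followed by all rows of
#'   `pb`, with the DP objective in attribute `"score"`.
#' @export
align_profiles <- function(pa, pb, m = pam250(), gaps = gap_model()) {
  stopifnot(inherits(pa, "msa"), inherits(pb, "msa"),
            inherits(m, "substitution_matrix"), inherits(gaps, "gap_model"))
  res <- cpp_profile_align(msa_codes(pa), msa_codes(pb),
                           matrix_codes(m), gaps$g, gaps$x)
  out <- codes_msa(res$codes, c(pa$ids, pb$ids))
  attr(out, "score") <- res$score
  out
}

#' Progressive multiple alignment along a guide tree
#'
#' Post-order traversal of the guide tree: leaves become single-row
#' profiles, and every internal node aligns its two children with
#' [align_profiles()] ("once a gap, always a gap"). Rows of the result are
#' reordered to the input sequence order and the alignment is canonicalised.
#'
#' @param seqs Named character vector of ungapped sequences.
#' @param t A [guide_tree][build_guide_tree] whose leaves index `seqs`.
#' @param m A substitution matrix.
#' @param gaps A [gap_model()].
#' @return An [msa] whose rows gap-strip to `seqs`.
#' @export
progressive_align <- function(seqs, t, m = pam250(), gaps = gap_model()) {
  validate_sequences(seqs)
  stopifnot(inherits(t, "guide_tree"))
  if (!identical(sort(tree_leaves(t)), seq_along(seqs)))
    stop("tree leaves do not index the sequences")
  leaves <- lapply(seqs, seq_codes)
  codes <- prog_codes(leaves, t, matrix_codes(m), gaps)
  codes_msa(codes, names(seqs))
}

# ungapped residue string -> integer code vector
seq_codes <- function(s) {
  out <- match(strsplit(s, "", fixed = TRUE)[[1L]], MATRIX_LETTERS)
  if (anyNA(out)) stop("invalid residue character")
  out
}

# post-order merge plan of a guide tree: row k merges nodes plan[k, 1:2],
# where entries 1..n are leaves and n + j is the result of row j
tree_plan <- function(t) {
  n <- t$n
  a_col <- integer(n - 1L)
  b_col <- integer(n - 1L)
  k <- 0L
  walk <- function(node) {
    if (is_leaf(node)) return(node$leaf)
    a <- walk(node$children[[1L]])
    b <- walk(node$children[[2L]])
    k <<- k + 1L
    a_col[k] <<- a
    b_col[k] <<- b
    n + k
  }
  walk(t$root)
  cbind(a_col, b_col, deparse.level = 0L)
}

# fast path: leaf code vectors + tree -> alignment code matrix in input order
prog_codes <- function(leaves, t, M, gaps) {
  if (length(leaves) == 1L)
    return(matrix(leaves[[1L]], nrow = 1L))
  cpp_progressive_align(leaves, tree_plan(t), M, gaps$g, gaps$x)
}
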