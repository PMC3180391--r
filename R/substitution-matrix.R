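# Residue alphabet shared across the package. Code 0 is the gap '-';
# codes 1..24 index the rows of a substitution matrix in this fixed order.
MATRIX_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z",
                    "X", "*")

# Letters legal in an input protein sequence: the 20 amino acids plus the
# ambiguity codes B, Z and X (no gap, no stop).
SEQ_LETTERS <- setdiff(MATRIX_LETTERS, "*")

GAP_CHAR <- "-"

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-delimited matrix layout used by NCBI tools (a header
#' row of residue letters followed by one labelled row per residue; lines
#' starting with `#` are comments). The matrix must be symmetric and must
#' define every residue letter used by the package, including the ambiguity
#' codes B, Z and X.
#'
#' @param path Path to the matrix file.
#' @param name Matrix name to record (defaults to the file name).
#' @return An object of class `substitution_matrix`: a list with elements
#'   `name` and `score`, a symmetric numeric matrix with residue-letter
#'   dimnames.
#' @seealso [pam250()] for the matrix shipped with the package.
#' @export
read_substitution_matrix <- function(path, name = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  row_letters <- vapply(rows, `[`, character(1L), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(row_letters, header)
  if (!identical(row_letters, header))
    vals <- vals[header, header, drop = FALSE]
  if (max(abs(vals - t(vals))) > 0)
    stop("substitution matrix is not symmetric: ", path)
  missing <- setdiff(SEQ_LETTERS, header)
  if (length(missing))
    stop("matrix does not define residue letters: ",
         paste(missing, collapse = ", "))
  structure(list(name = if (is.null(name)) basename(path) else name,
                 score = vals),
            class = "substitution_matrix")
}

#' The PAM250 substitution matrix
#'
#' Loads the PAM250 log-odds matrix shipped with the package (NCBI layout,
#' 24 letters including B, Z, X and `*`). PAM250 is the default residue-pair
#' cost for both the pairwise distance alignments and the weighted
#' sum-of-pairs fitness.
#'
#' @return A `substitution_matrix`.
#' @export
#' @examples
#' m <- pam250()
#' sub_score(m, "A", "A")  # 2
pam250 <- function() {
  read_substitution_matrix(
    system.file("extdata", "PAM250.txt", package = "vdga", mustWork = TRUE),
    name = "PAM250")
}

#' Look up a residue-pair score
#'
#' @param m A `substitution_matrix`.
#' @param a,b Single residue letters.
#' @return The (symmetric) score `m(a, b)`.
#' @export
sub_score <- function(m, a, b) {
  stopifnot(inherits(m, "substitution_matrix"))
  m$score[a, b]
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("Substitution matrix", x$name, "over",
      paste(colnames(x$score), collapse = ""), "\n")
  invisible(x)
}

# Matrix in the package's fixed code order, for the C++ kernels. Letters the
# file does not define (only possible for '*') score the file's minimum.
matrix_codes <- function(m) {
  out <- matrix(min(m$score), length(MATRIX_LETTERS), length(MATRIX_LETTERS))
  present <- intersect(MATRIX_LETTERS, colnames(m$score))
  idx <- match(present, MATRIX_LETTERS)
  out[idx, idx] <- m$score[present, present]
  out
}

#' Affine gap model
#'
#' Holds the gap-opening penalty `g` and per-position extension penalty `x`
#' of the affine model in which a gap run of length `n` costs `G = g + n*x`.
#' Defaults are the CLUSTAL W defaults used throughout the method:
#' `g = -10`, `x = -0.20`.
#'
#' @param g Gap-opening penalty (must be <= 0).
#' @param x Gap-extension penalty per position (must be <= 0).
#' @return An object of class `gap_model`.
#' @export
gap_model <- function(g = -10, x = -0.2) {
  stopifnot(is.numeric(g), length(g) == 1L, g <= 0,
            is.numeric(x), length(x) == 1L, x <= 0)
  structure(list(g = g, x = x), class = "gap_model")
}

#' Affine gap penalty for a run
#'
#' `G = g + n * x` for a maximal gap run of length `n`.
#'
#' @param n Gap run length (>= 1).
#' @param gaps A [gap_model()].
#' @return The penalty `G` (non-positive under the defaults).
#' @export
#' @examples
#' gap_penalty(5, gap_model())  # -11
gap_penalty <- function(n, gaps = gap_model()) {
  stopifnot(inherits(gaps, "gap_model"))
  if (any(n < 1)) stop("gap run length must be >= 1")
  gaps$g + n * gaps$x
}
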