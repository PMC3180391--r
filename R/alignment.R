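#' Construct a multiple sequence alignment object
#'
#' An `msa` is a rectangular gapped residue matrix stored as one string per
#' row plus a parallel vector of sequence ids. The gap character is `-`
#' internally; the MSF dialect characters `.` and `~` are normalised on read.
#'
#' @param rows Character vector of equal-length gapped strings.
#' @param ids Character vector of unique sequence ids (one per row).
#' @return An object of class `msa` with elements `rows` and `ids`.
#' @export
msa <- function(rows, ids = paste0("seq", seq_along(rows))) {
  rows <- toupper(as.character(rows))
  ids <- as.character(ids)
  if (length(rows) < 1L) stop("empty alignment")
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("not a rectangular alignment")
  if (L < 1L) stop("empty alignment")
  ok <- paste0("^[", paste(SEQ_LETTERS, collapse = ""), "-]+$")
  if (any(!grepl(ok, rows)))
    stop("invalid characters in alignment rows")
  structure(list(rows = unname(rows), ids = unname(ids)), class = "msa")
}

#' @rdname msa
#' @param aln An `msa`.
#' @export
aln_length <- function(aln) nchar(aln$rows[[1L]])

#' @rdname msa
#' @export
aln_nrow <- function(aln) length(aln$rows)

#' @export
print.msa <- function(x, ...) {
  cat("Alignment of", aln_nrow(x), "sequences,", aln_length(x), "columns\n")
  w <- max(nchar(x$ids))
  show <- if (aln_length(x) > 70) paste0(substr(x$rows, 1, 67), "...") else x$rows
  cat(sprintf(paste0("%-", w, "s  %s"), x$ids, show), sep = "\n")
  invisible(x)
}

#' Strip gaps from alignment rows
#'
#' @param aln An `msa`.
#' @return Named character vector of the ungapped sequences, in row order.
#' @export
ungap <- function(aln) {
  out <- gsub("-", "", aln$rows, fixed = TRUE)
  names(out) <- aln$ids
  out
}

#' Remove all-gap columns
#'
#' The canonical form used after every operator: columns consisting only of
#' gaps contribute nothing to the fitness but perturb affine run counting,
#' so they are dropped. Everything else is untouched.
#'
#' @param aln An `msa`.
#' @return A canonical `msa`.
#' @export
canonicalise <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  m <- msa_chars(aln)
  keep <- colSums(m != GAP_CHAR) > 0L
  if (!any(keep)) stop("empty alignment")
  if (all(keep)) return(aln)
  msa(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""), aln$ids)
}

# character matrix view of an msa
msa_chars <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

# integer code matrix view (0 = gap) for the C++ kernels
msa_codes <- function(aln) {
  chars_codes(msa_chars(aln))
}

chars_codes <- function(m) {
  out <- match(m, MATRIX_LETTERS)
  out[m == GAP_CHAR] <- 0L
  if (anyNA(out)) stop("invalid residue character in alignment")
  matrix(out, nrow = nrow(m))
}

codes_msa <- function(codes, ids) {
  chars <- matrix(GAP_CHAR, nrow(codes), ncol(codes))
  chars[codes > 0L] <- MATRIX_LETTERS[codes[codes > 0L]]
  msa(apply(chars, 1L, paste, collapse = ""), ids)
}

#' Read a multiple alignment from file
#'
#' Supports aligned FASTA and MSF (parsed via \pkg{seqinr}) and CLUSTAL
#' (parsed via \pkg{Biostrings}). The MSF/CLUSTAL gap dialect characters
#' `.` and `~` are normalised to `-`.
#'
#' @param path Path to the alignment file.
#' @param format One of `"fasta"`, `"clustal"`, `"msf"`.
#' @return An `msa`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal", "msf")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "clustal") {
    a <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    rows <- as.character(Biostrings::unmasked(a))
    ids <- names(rows)
  } else {
    a <- seqinr::read.alignment(path, format = format)
    rows <- vapply(a$seq, `[[`, character(1L), 1L)
    ids <- a$nam
  }
  rows <- toupper(rows)
  rows <- gsub("[.~]", "-", rows)
  rows <- gsub("\\s", "", rows)
  if (length(unique(nchar(rows))) != 1L)
    stop("not a rectangular alignment: ", path)
  msa(rows, ids)
}

#' Write a multiple alignment to file
#'
#' Emits standard-conformant aligned FASTA, CLUSTAL or MSF text with
#' deterministic byte output for a fixed input.
#'
#' @param aln An `msa`.
#' @param path Output path.
#' @param format One of `"fasta"`, `"clustal"`, `"msf"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal", "msf")) {
  stopifnot(inherits(aln, "msa"))
  format <- match.arg(format)
  lines <- switch(format,
                  fasta = {
                    s <- aln$rows
                    names(s) <- aln$ids
                    fasta_text(s)
                  },
                  clustal = clustal_text(aln),
                  msf = msf_text(aln))
  writeLines(lines, path)
  invisible(path)
}

clustal_text <- function(aln, width = 60L) {
  L <- aln_length(aln)
  w <- max(nchar(aln$ids)) + 3L
  out <- c("CLUSTAL W multiple sequence alignment", "", "")
  for (start in seq(1L, L, by = width)) {
    end <- min(start + width - 1L, L)
    block <- sprintf(paste0("%-", w, "s%s"), aln$ids,
                     substr(aln$rows, start, end))
    out <- c(out, block, "")
  }
  out
}

# GCG checksum: sum over positions of ((pos - 1) mod 57 + 1) * ascii, mod 10000
gcg_checksum <- function(s) {
  codes <- utf8ToInt(toupper(s))
  pos <- seq_along(codes)
  sum(((pos - 1L) %% 57L + 1L) * codes) %% 10000L
}

msf_text <- function(aln, width = 50L) {
  rows_msf <- gsub("-", ".", aln$rows, fixed = TRUE)
  L <- aln_length(aln)
  checks <- vapply(rows_msf, gcg_checksum, numeric(1L))
  out <- c("PileUp", "",
           sprintf(" MSA_FILE  MSF: %d  Type: P  Check: %d  ..",
                   L, sum(checks) %% 10000),
           "")
  w <- max(nchar(aln$ids))
  out <- c(out,
           sprintf(paste0(" Name: %-", w, "s  Len: %5d  Check: %5d  Weight: 1.00"),
                   aln$ids, L, checks),
           "", "//", "")
  for (start in seq(1L, L, by = width)) {
    end <- min(start + width - 1L, L)
    chunk <- substr(rows_msf, start, end)
    # space every 10 columns inside a block, GCG style
    spaced <- vapply(chunk, function(s) {
      n <- nchar(s)
      paste(substring(s, seq(1L, n, 10L), pmin(seq(1L, n, 10L) + 9L, n)),
            collapse = " ")
    }, character(1L), USE.NAMES = FALSE)
    out <- c(out, sprintf(paste0("%-", w, "s  %s"), aln$ids, spaced), "")
  }
  out
}
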