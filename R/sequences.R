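#' Validate a set of unaligned protein sequences
#'
#' Sequences are represented throughout the package as a named character
#' vector: names are the (unique) sequence ids, values are ungapped residue
#' strings over the 20 amino-acid letters plus the ambiguity codes B, Z, X.
#'
#' @param seqs Named character vector of residue strings.
#' @return `seqs`, invisibly, after validation.
#' @export
validate_sequences <- function(seqs) {
  if (!is.character(seqs) || length(seqs) < 1L)
    stop("no sequences")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("sequences must be named by id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("gap character in unaligned sequence: ",
         paste(ids[grepl("-", seqs, fixed = TRUE)], collapse = ", "))
  bad <- !grepl(paste0("^[", paste(SEQ_LETTERS, collapse = ""), "]+$"), seqs)
  if (any(bad))
    stop("non-amino-acid characters in: ", paste(ids[bad], collapse = ", "))
  invisible(seqs)
}

#' Read unaligned protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase residue strings (see
#'   [validate_sequences()] for the representation contract). Record order is
#'   preserved; lowercase input is uppercased; gapped records are rejected.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE),
    error = function(e) stop("no sequences in ", path, call. = FALSE))
  if (length(recs) == 0L) stop("no sequences in ", path)
  seqs <- toupper(vapply(recs, `[[`, character(1L), 1L))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1L))
  validate_sequences(seqs)
  seqs
}

#' Write unaligned protein sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  validate_sequences(seqs)
  writeLines(fasta_text(seqs, width), path)
  invisible(path)
}

fasta_text <- function(seqs, width = 60L) {
  unlist(lapply(seq_along(seqs), function(i) {
    c(paste0(">", names(seqs)[i]), wrap_seq(seqs[[i]], width))
  }), use.names = FALSE)
}

wrap_seq <- function(s, width) {
  n <- nchar(s)
  starts <- seq(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}
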