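#' Simulate a family of homologous protein sequences
#'
#' Evolves a random ancestor down a random rooted binary tree (built by
#' repeated random joins, coalescent style). Along every edge each site is
#' substituted independently with probability `substitution_rate`, and indel
#' events strike with per-site probability `indel_rate`; event lengths are
#' geometric with mean `mean_indel_length`, and insertions and deletions are
#' equally likely. Insertion coordinates are tracked against a global column
#' registry, so the true alignment of the leaves is known exactly.
#'
#' The generator is a pure function of its arguments: the same call yields a
#' byte-identical family, and the caller's RNG state is left untouched.
#'
#' @param n_sequences Number of descendant sequences (>= 2).
#' @param length Ancestor length in residues (>= 10).
#' @param substitution_rate Per-site substitution probability per tree edge,
#'   in \[0, 1\].
#' @param indel_rate Per-site indel-event probability per tree edge, in
#'   \[0, 1\].
#' @param mean_indel_length Mean indel length in residues (>= 1).
#' @param seed Integer seed.
#' @return An object of class `synthetic_family`: a list with `ancestor`
#'   (named length-1 character), `descendants` (named character vector),
#'   `true_alignment` (an [msa]) and `params`.
#' @export
#' @examples
#' fam <- generate_family(4, 60, substitution_rate = 0.1, indel_rate = 0.02,
#'                        seed = 1)
#' identical(ungap(fam$true_alignment), fam$descendants)  # TRUE
generate_family <- function(n_sequences = 8L, length = 150L,
                            substitution_rate = 0.1, indel_rate = 0.02,
                            mean_indel_length = 3, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1)
    stop("rates must be in [0, 1]")
  stopifnot(n_sequences >= 2L, length >= 10L, mean_indel_length >= 1)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  aa20 <- MATRIX_LETTERS[1:20]
  # master column registry: a total order over all columns ever created
  env <- new.env(parent = emptyenv())
  env$master <- seq_len(length)
  env$next_id <- length + 1L

  ancestor <- list(res = sample(aa20, length, replace = TRUE),
                   col = seq_len(length))

  evolve <- function(node) {
    res <- node$res
    col <- node$col
    # substitutions
    hit <- stats::runif(length(res)) < substitution_rate
    if (any(hit))
      res[hit] <- vapply(res[hit],
                         function(r) sample(setdiff(aa20, r), 1L),
                         character(1L), USE.NAMES = FALSE)
    # indel events (count drawn site-wise, applied sequentially)
    n_events <- stats::rbinom(1L, length(res), indel_rate)
    for (e in seq_len(n_events)) {
      len <- stats::rgeom(1L, 1 / mean_indel_length) + 1L
      if (stats::runif(1L) < 0.5 && length(res) > len) {  # deletion
        start <- sample(length(res) - len + 1L, 1L)
        drop <- start:(start + len - 1L)
        res <- res[-drop]
        col <- col[-drop]
      } else {                                            # insertion
        at <- sample(length(res) + 1L, 1L) - 1L  # insert after position `at`
        new_ids <- env$next_id:(env$next_id + len - 1L)
        env$next_id <- env$next_id + len
        anchor <- if (at == 0L) 0L else match(col[at], env$master)
        env$master <- append(env$master, new_ids, after = anchor)
        res <- append(res, sample(aa20, len, replace = TRUE), after = at)
        col <- append(col, new_ids, after = at)
      }
    }
    list(res = res, col = col)
  }

  # random rooted binary join order over n leaves; evolve along each edge
  nodes <- list(ancestor)
  while (length(nodes) < n_sequences) {
    i <- sample(length(nodes), 1L)
    parent <- nodes[[i]]
    nodes[[i]] <- evolve(parent)
    nodes[[length(nodes) + 1L]] <- evolve(parent)
  }

  ids <- sprintf("seq%02d", seq_len(n_sequences))
  descendants <- vapply(nodes, function(n) paste(n$res, collapse = ""),
                        character(1L))
  names(descendants) <- ids

  used <- unique(unlist(lapply(nodes, `[[`, "col")))
  mu <- env$master[env$master %in% used]  # used columns, in registry order
  index <- integer(max(mu))
  index[mu] <- seq_along(mu)
  rows <- vapply(nodes, function(n) {
    r <- rep(GAP_CHAR, length(mu))
    r[index[n$col]] <- n$res
    paste(r, collapse = "")
  }, character(1L))

  structure(list(
    ancestor = c(ancestor0 = paste(ancestor$res, collapse = "")),
    descendants = descendants,
    true_alignment = msa(rows, ids),
    params = list(n_sequences = n_sequences, length = length,
                  substitution_rate = substitution_rate,
                  indel_rate = indel_rate,
                  mean_indel_length = mean_indel_length, seed = seed)),
    class = "synthetic_family")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("Synthetic protein family:", length(x$descendants), "descendants,",
      "true alignment", aln_length(x$true_alignment), "columns\n")
  invisible(x)
}
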