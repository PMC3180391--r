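# Independent oracles and random-case generators for the test suite. These
# deliberately avoid the package's DP/scoring code paths: scores are
# recomputed from first principles (exhaustive enumeration, per-pair string
# projection, direct pair counting) so that agreement is evidence, not
# circularity.

ORACLE_PAM <- pam250()

# score an explicit pairwise alignment (two gapped strings) from scratch:
# substitution scores over residue-residue columns plus g + n*x for every
# maximal gap run in either row
score_pair_alignment <- function(row_a, row_b, m = ORACLE_PAM,
                                 gaps = gap_model()) {
  ca <- strsplit(row_a, "")[[1]]
  cb <- strsplit(row_b, "")[[1]]
  res <- sum(vapply(which(ca != "-" & cb != "-"),
                    function(l) m$score[ca[l], cb[l]], numeric(1)))
  run_score <- function(ch) {
    r <- rle(ch == "-")
    sum(gaps$g + r$lengths[r$values] * gaps$x)
  }
  res + run_score(ca) + run_score(cb)
}

# brute-force optimal global affine alignment score by exhaustive recursion
# over all monotone paths (no DP tables, no memoisation); gap-run bookkeeping
# is carried in the recursion state
brute_align_score <- function(a, b, m = ORACLE_PAM, gaps = gap_model()) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  g <- gaps$g
  x <- gaps$x
  rec <- function(i, j, last) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1, 0L) + m$score[ca[i], cb[j]])
    if (i > 0)
      best <- max(best, rec(i - 1, j, 1L) + if (last == 1L) x else g + x)
    if (j > 0)
      best <- max(best, rec(i, j - 1, 2L) + if (last == 2L) x else g + x)
    best
  }
  rec(length(ca), length(cb), 0L)
}

# brute-force weighted sum-of-pairs: per pair, delete gap-gap columns, score
# residue-residue columns and charge every maximal gap run, all in R strings
wspm_oracle <- function(aln, w = rep(1, length(aln$rows)), m = ORACLE_PAM,
                        gaps = gap_model()) {
  n <- length(aln$rows)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ca <- strsplit(aln$rows[i], "")[[1]]
      cb <- strsplit(aln$rows[j], "")[[1]]
      keep <- !(ca == "-" & cb == "-")
      total <- total + w[i] * w[j] *
        score_pair_alignment(paste(ca[keep], collapse = ""),
                             paste(cb[keep], collapse = ""), m, gaps)
    }
  }
  total
}

# brute-force SPS/CS by direct enumeration of reference residue pairs and
# columns, using residue coordinates (sequence, ordinal)
sps_oracle <- function(test, ref, core_columns = NULL) {
  coord <- function(aln) {
    ch <- do.call(rbind, strsplit(aln$rows, ""))
    t(apply(ch, 1, function(r) {
      o <- rep(NA_integer_, length(r))
      o[r != "-"] <- seq_len(sum(r != "-"))
      o
    }))
  }
  oref <- coord(ref)
  otest <- coord(test)
  cols <- if (is.null(core_columns)) seq_len(ncol(oref)) else core_columns
  total <- matched <- 0
  for (l in cols) {
    rows <- which(!is.na(oref[, l]))
    if (length(rows) < 2) next
    for (ii in seq_along(rows)) {
      for (jj in seq_along(rows)) {
        if (jj <= ii) next
        i <- rows[ii]; j <- rows[jj]
        total <- total + 1
        ci <- which(otest[i, ] == oref[i, l])
        cj <- which(otest[j, ] == oref[j, l])
        if (length(ci) == 1 && length(cj) == 1 && ci == cj)
          matched <- matched + 1
      }
    }
  }
  matched / total
}

cs_oracle <- function(test, ref, core_columns = NULL) {
  chr <- do.call(rbind, strsplit(ref$rows, ""))
  cht <- do.call(rbind, strsplit(test$rows, ""))
  ord <- function(ch) {
    t(apply(ch, 1, function(r) {
      o <- rep(NA_integer_, length(r))
      o[r != "-"] <- seq_len(sum(r != "-"))
      o
    }))
  }
  oref <- ord(chr)
  otest <- ord(cht)
  cols <- if (is.null(core_columns)) seq_len(ncol(chr)) else core_columns
  hits <- vapply(cols, function(l) {
    any(vapply(seq_len(ncol(cht)), function(tc)
      identical(oref[, l], otest[, tc]), logical(1)))
  }, logical(1))
  mean(hits)
}

# random rectangular alignment with no all-gap column and no all-gap row
random_alignment <- function(n = 4, L = 20, gap_prob = 0.25) {
  letters20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  repeat {
    ch <- matrix(ifelse(runif(n * L) < gap_prob, "-",
                        sample(letters20, n * L, replace = TRUE)), n, L)
    rows <- apply(ch, 1, paste, collapse = "")
    ok_col <- all(colSums(ch != "-") > 0)
    ok_row <- all(grepl("[A-Z]", rows))
    if (ok_col && ok_row) return(msa(rows))
  }
}

random_sequences <- function(n = 5, len_range = c(20, 40)) {
  letters20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  out <- vapply(seq_len(n), function(i) {
    paste(sample(letters20, sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
  names(out) <- paste0("s", seq_len(n))
  out
}

# --- additive-tree machinery for the neighbour-joining recovery oracle ---

# random rooted binary topology over n leaves as nested lists, with random
# positive branch lengths; returns the tree and its pairwise path-length
# distance matrix
random_additive_case <- function(n) {
  nodes <- lapply(seq_len(n), function(i) list(leaf = i))
  while (length(nodes) > 1) {
    k <- sample(length(nodes), 2)
    nodes <- c(nodes[-k],
               list(list(children = nodes[k],
                         lengths = runif(2, 0.1, 2))))
  }
  tree <- nodes[[1]]
  # pairwise distance = sum of branch lengths on the connecting path
  d <- matrix(0, n, n)
  fill <- function(node) {
    if (!is.null(node$leaf)) return(list(list(leaf = node$leaf, d = 0)))
    l <- fill(node$children[[1]])
    r <- fill(node$children[[2]])
    l <- lapply(l, function(e) { e$d <- e$d + node$lengths[1]; e })
    r <- lapply(r, function(e) { e$d <- e$d + node$lengths[2]; e })
    for (ei in l) for (ej in r) {
      d[ei$leaf, ej$leaf] <<- d[ej$leaf, ei$leaf] <<- ei$d + ej$d
    }
    c(l, r)
  }
  fill(tree)
  rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  list(tree = tree, d = d)
}

# nontrivial bipartitions (splits) of a nested-list tree, as canonical strings
oracle_splits <- function(node, n) {
  out <- character(0)
  leaves_below <- function(nd) {
    if (!is.null(nd$leaf)) return(nd$leaf)
    c(leaves_below(nd$children[[1]]), leaves_below(nd$children[[2]]))
  }
  walk <- function(nd) {
    if (!is.null(nd$leaf)) return(invisible())
    for (k in 1:2) {
      below <- sort(leaves_below(nd$children[[k]]))
      if (length(below) >= 2 && length(below) <= n - 2) {
        side <- if (1 %in% below) below else sort(setdiff(seq_len(n), below))
        out <<- c(out, paste(side, collapse = ","))
      }
      walk(nd$children[[k]])
    }
  }
  walk(node)
  sort(unique(out))
}

# splits of a package guide_tree, same canonical form
guide_tree_splits <- function(t) {
  n <- t$n
  out <- character(0)
  leaves_below <- function(nd) {
    if (!is.null(nd$leaf)) return(nd$leaf)
    c(leaves_below(nd$children[[1]]), leaves_below(nd$children[[2]]))
  }
  walk <- function(nd) {
    if (!is.null(nd$leaf)) return(invisible())
    for (k in 1:2) {
      below <- sort(leaves_below(nd$children[[k]]))
      if (length(below) >= 2 && length(below) <= n - 2) {
        side <- if (1 %in% below) below else sort(setdiff(seq_len(n), below))
        out <<- c(out, paste(side, collapse = ","))
      }
      walk(nd$children[[k]])
    }
  }
  walk(t$root)
  sort(unique(out))
}
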