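# Guide trees are rooted binary trees over sequence indices. Nodes are
# nested lists: a leaf is list(leaf = i); an internal node is
# list(children = list(l, r), lengths = c(bl_l, bl_r)). The tree object
# wraps the root together with the leaf count and optional labels.

new_guide_tree <- function(root, n, labels = NULL) {
  structure(list(root = root, n = n, labels = labels), class = "guide_tree")
}

is_leaf <- function(node) !is.null(node$leaf)

#' Build a neighbour-joining guide tree
#'
#' Classical neighbour joining on a symmetric distance matrix. The two nodes
#' of the final join become the children of the root, the remaining distance
#' split equally between them. Negative branch-length estimates are clamped
#' to zero, and ties in the Q criterion are broken towards the smallest
#' (i, j) node pair, so the construction is deterministic.
#'
#' @param d Symmetric distance matrix with zero diagonal (as produced by
#'   [distance_matrix_dp()] or [distance_matrix_kimura()]).
#' @return A `guide_tree` whose leaves carry the row indices of `d`.
#' @export
build_guide_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  labels <- rownames(d)
  nodes <- lapply(seq_len(n), function(i) list(leaf = i))
  dm <- unname(d)
  while (length(nodes) > 2L) {
    m <- length(nodes)
    r <- rowSums(dm)
    q <- (m - 2) * dm - outer(r, r, `+`)
    diag(q) <- Inf
    idx <- which(q == min(q)) - 1L
    bi <- idx %% m + 1L
    bj <- idx %/% m + 1L
    lo <- pmin(bi, bj)
    hi <- pmax(bi, bj)
    pick <- order(lo, hi)[1L]
    i <- lo[pick]; j <- hi[pick]
    bl_i <- 0.5 * dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bl_j <- dm[i, j] - bl_i
    node <- list(children = list(nodes[[i]], nodes[[j]]),
                 lengths = pmax(c(bl_i, bl_j), 0))
    dnew <- 0.5 * (dm[i, ] + dm[j, ] - dm[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    nodes <- c(nodes[keep], list(node))
    dm <- dm2
  }
  half <- max(dm[1L, 2L], 0) / 2
  root <- list(children = nodes, lengths = c(half, half))
  new_guide_tree(root, n, labels)
}

#' Leaf indices of a guide tree
#'
#' @param t A `guide_tree`.
#' @return Integer vector of leaf labels in left-to-right traversal order.
#' @export
tree_leaves <- function(t) {
  walk <- function(node) {
    if (is_leaf(node)) return(node$leaf)
    c(walk(node$children[[1L]]), walk(node$children[[2L]]))
  }
  walk(t$root)
}

#' Canonical serialisation of a guide tree
#'
#' Order-invariant topology string (children sorted lexicographically at
#' every node; branch lengths excluded) used for duplicate detection and
#' equality tests.
#'
#' @param t A `guide_tree`.
#' @return A single string.
#' @export
tree_canonical <- function(t) {
  walk <- function(node) {
    if (is_leaf(node)) return(paste0("L", node$leaf))
    kids <- sort(vapply(node$children, walk, character(1L)))
    paste0("(", kids[1L], ",", kids[2L], ")")
  }
  walk(t$root)
}

#' Newick serialisation of a guide tree
#'
#' @param t A `guide_tree`.
#' @param digits Branch-length precision.
#' @return A single Newick string (with branch lengths, semicolon-terminated).
#' @export
tree_newick <- function(t, digits = 6L) {
  labs <- if (is.null(t$labels)) as.character(seq_len(t$n)) else t$labels
  walk <- function(node) {
    if (is_leaf(node)) return(labs[[node$leaf]])
    paste0("(",
           walk(node$children[[1L]]), ":",
           format(node$lengths[[1L]], digits = digits), ",",
           walk(node$children[[2L]]), ":",
           format(node$lengths[[2L]], digits = digits), ")")
  }
  paste0(walk(t$root), ";")
}

#' CLUSTAL W sequence weights from a guide tree
#'
#' The weight of a sequence is the sum, over the edges on its root-to-leaf
#' path, of the edge length divided by the number of leaves below that edge;
#' weights are then rescaled to mean 1. A degenerate tree in which all raw
#' weights are zero (e.g. all branch lengths zero) yields unit weights. The
#' pair weight used by the fitness is the product `w_i * w_j`.
#'
#' @param t A `guide_tree`.
#' @return Numeric weight vector ordered by sequence index, mean 1.
#' @export
clustalw_weights <- function(t) {
  w <- numeric(t$n)
  count_leaves <- function(node) {
    if (is_leaf(node)) 1L
    else sum(vapply(node$children, count_leaves, integer(1L)))
  }
  walk <- function(node, acc) {
    if (is_leaf(node)) {
      w[[node$leaf]] <<- acc
      return(invisible())
    }
    for (k in 1:2) {
      child <- node$children[[k]]
      share <- node$lengths[[k]] / count_leaves(child)
      walk(child, acc + share)
    }
  }
  walk(t$root, 0)
  if (sum(w) <= 0) return(rep(1, t$n))
  w * t$n / sum(w)
}

# Prune a tree to a subset of leaves, preserving relative branching order.
# Collapsed unary nodes add their edge length onto the surviving child.
prune_tree <- function(node, keep) {
  if (is_leaf(node)) {
    if (node$leaf %in% keep) return(list(node = node, extra = 0))
    return(NULL)
  }
  l <- prune_tree(node$children[[1L]], keep)
  r <- prune_tree(node$children[[2L]], keep)
  if (is.null(l) && is.null(r)) return(NULL)
  if (is.null(r))
    return(list(node = l$node, extra = node$lengths[[1L]] + l$extra))
  if (is.null(l))
    return(list(node = r$node, extra = node$lengths[[2L]] + r$extra))
  list(node = list(children = list(l$node, r$node),
                   lengths = c(node$lengths[[1L]] + l$extra,
                               node$lengths[[2L]] + r$extra)),
       extra = 0)
}

#' Population-seeding mechanism 1: random split and rejoin
#'
#' Each leaf is selected independently with probability 0.5 (redrawing if
#' the selected set is empty or complete). The selected leaves are pruned
#' into one subtree that preserves the base tree's relative branching order,
#' the complement into another, and the two subtrees are joined under a new
#' root whose two branches get the mean root-child branch length of the base
#' tree. If the result equals the input in canonical form the draw is
#' repeated (bounded), and the last draw is returned with a warning if no
#' differing tree is found.
#'
#' @param t A `guide_tree` with >= 3 leaves.
#' @param mask Optional logical vector fixing the selection (for testing).
#' @param max_tries Bounded number of redraws.
#' @return A new `guide_tree` over the same leaves.
#' @export
mechanism1_split <- function(t, mask = NULL, max_tries = 25L) {
  if (t$n < 3L) stop("mechanism 1 needs at least 3 leaves")
  base_len <- mean(t$root$lengths)
  out <- t
  for (try in seq_len(max_tries)) {
    sel <- if (is.null(mask)) stats::runif(t$n) < 0.5 else mask
    if (all(sel) || !any(sel)) {
      if (!is.null(mask)) stop("mask must select a proper nonempty subset")
      next
    }
    keep <- which(sel)
    sub1 <- prune_tree(t$root, keep)$node
    sub2 <- prune_tree(t$root, setdiff(seq_len(t$n), keep))$node
    out <- new_guide_tree(list(children = list(sub1, sub2),
                               lengths = c(base_len, base_len)),
                          t$n, t$labels)
    if (!is.null(mask) || tree_canonical(out) != tree_canonical(t))
      return(out)
  }
  warning("mechanism 1 could not produce a distinct tree; returning last draw")
  out
}

#' Population-seeding mechanism 2: leaf shuffle
#'
#' Two distinct leaves are chosen uniformly and their labels exchanged;
#' topology and branch lengths are otherwise unchanged. Applying the same
#' swap twice restores the original tree.
#'
#' @param t A `guide_tree` with >= 2 leaves.
#' @param pair Optional length-2 integer vector fixing the swapped labels.
#' @return A new `guide_tree`.
#' @export
mechanism2_swap <- function(t, pair = NULL) {
  if (t$n < 2L) stop("need at least 2 leaves")
  if (is.null(pair)) pair <- sample(t$n, 2L)
  pair <- as.integer(pair)
  stopifnot(length(pair) == 2L, pair[1L] != pair[2L])
  walk <- function(node) {
    if (is_leaf(node)) {
      if (node$leaf == pair[1L]) node$leaf <- pair[2L]
      else if (node$leaf == pair[2L]) node$leaf <- pair[1L]
      return(node)
    }
    node$children <- lapply(node$children, walk)
    node
  }
  new_guide_tree(walk(t$root), t$n, t$labels)
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("Guide tree over", x$n, "sequences:", tree_newick(x), "\n")
  invisible(x)
}
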