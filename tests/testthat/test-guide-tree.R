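test_that("two-taxon tree splits the distance equally at the root", {
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t <- build_guide_tree(d)
  expect_equal(t$n, 2)
  expect_true(all(vapply(t$root$children, vdga:::is_leaf, logical(1))))
  expect_equal(t$root$lengths, c(1.5, 1.5))
  expect_error(build_guide_tree(d[1, 1, drop = FALSE]), "at least 2")
})

test_that("neighbour joining recovers the {A,B}|{C,D} split of an additive
           4-taxon matrix", {
  d <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 2,
                6, 6, 2, 0), 4, 4)
  rownames(d) <- colnames(d) <- c("A", "B", "C", "D")
  t <- build_guide_tree(d)
  expect_identical(guide_tree_splits(t), "1,2")
})

test_that("neighbour joining recovers additive 4- and 5-taxon topologies", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(4:5, 1)
    case <- random_additive_case(n)
    t <- build_guide_tree(case$d)
    expect_identical(guide_tree_splits(t), oracle_splits(case$tree, n))
  }
})

test_that("neighbour joining agrees with ape on additive matrices", {
  skip_if_not_installed("ape")
  set.seed(32)
  for (rep in 1:10) {
    case <- random_additive_case(5)
    ours <- build_guide_tree(case$d)
    ref <- ape::nj(case$d)
    # compare unrooted splits via ape's bipartitions
    bp <- ape::prop.part(ape::unroot(ref))
    labs <- attr(bp, "labels")
    ape_splits <- sort(unique(vapply(bp, function(p) {
      p <- sort(match(labs[p], paste0("t", 1:5)))
      if (length(p) < 2 || length(p) > 3) return(NA_character_)
      side <- if (1 %in% p) p else sort(setdiff(1:5, p))
      paste(side, collapse = ",")
    }, character(1))))
    ape_splits <- ape_splits[!is.na(ape_splits)]
    expect_identical(guide_tree_splits(ours), ape_splits)
  }
})

test_that("CLUSTAL W weights follow the path-sharing rule", {
  # two leaves at equal depth share nothing: equal weights, mean 1
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(NULL, NULL))
  expect_equal(clustalw_weights(build_guide_tree(d)), c(1, 1))

  # all branch lengths zero: unit-weight fallback
  d0 <- matrix(0, 4, 4)
  expect_equal(clustalw_weights(build_guide_tree(d0)), rep(1, 4))

  # hand trace on a fixed caterpillar ((1:1, 2:1):0.5, 3:2) plus leaf 4:
  # built directly as a nested tree to pin the branch lengths
  leaf <- function(i) list(leaf = i)
  tr <- vdga:::new_guide_tree(
    list(children = list(
      list(children = list(
        list(children = list(leaf(1), leaf(2)), lengths = c(1, 1)),
        leaf(3)), lengths = c(0.5, 2)),
      leaf(4)), lengths = c(0.25, 3)),
    n = 4)
  raw <- c(1 + 0.5 / 2 + 0.25 / 3,  # leaf 1: own branch + shared thirds
           1 + 0.5 / 2 + 0.25 / 3,
           2 + 0.25 / 3,
           3)
  expect_equal(clustalw_weights(tr), raw * 4 / sum(raw))
})

test_that("weights are invariant to child-order permutations", {
  set.seed(33)
  case <- random_additive_case(6)
  t <- build_guide_tree(case$d)
  flip <- function(node) {
    if (!is.null(node$leaf)) return(node)
    node$children <- lapply(rev(node$children), flip)
    node$lengths <- rev(node$lengths)
    node
  }
  t2 <- vdga:::new_guide_tree(flip(t$root), t$n)
  expect_equal(clustalw_weights(t), clustalw_weights(t2))
  expect_identical(tree_canonical(t), tree_canonical(t2))
})

test_that("mechanism 1 splits leaves into two order-preserving subtrees", {
  set.seed(34)
  case <- random_additive_case(8)
  t <- build_guide_tree(case$d)
  # fixed selection mask: chosen and unchosen sets form the two subtrees
  mask <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  out <- mechanism1_split(t, mask = mask)
  kids <- out$root$children
  left <- sort(vdga:::new_guide_tree(kids[[1]], 8) |> tree_leaves())
  right <- sort(vdga:::new_guide_tree(kids[[2]], 8) |> tree_leaves())
  expect_identical(left, which(mask))
  expect_identical(right, which(!mask))

  # pruning preserves the relative traversal order of retained leaves
  base_order <- tree_leaves(t)
  keep <- which(mask)
  pruned <- vdga:::prune_tree(t$root, keep)$node
  pruned_order <- tree_leaves(vdga:::new_guide_tree(pruned, 8))
  expect_identical(pruned_order, base_order[base_order %in% keep])

  # leaf multiset is preserved over random draws
  for (rep in 1:100) {
    expect_identical(sort(tree_leaves(mechanism1_split(t))), 1:8)
  }
  expect_error(mechanism1_split(build_guide_tree(matrix(c(0, 1, 1, 0), 2))),
               "3 leaves")
})

test_that("mechanism 2 swaps exactly two leaf labels and is an involution", {
  set.seed(35)
  case <- random_additive_case(8)
  t <- build_guide_tree(case$d)
  s <- mechanism2_swap(t, pair = c(8, 3))
  expect_identical(tree_newick(s),
                   tree_newick(mechanism2_swap(t, pair = c(3, 8))))
  # same shape: canonical form with 3 and 8 relabelled
  back <- mechanism2_swap(s, pair = c(8, 3))
  expect_identical(tree_newick(back), tree_newick(t))
  # only the two labels moved
  o1 <- tree_leaves(t)
  o2 <- tree_leaves(s)
  moved <- which(o1 != o2)
  expect_identical(sort(o1[moved]), sort(o2[moved]))
  expect_true(all(sort(o1[moved]) == c(3, 8)))

  for (rep in 1:100) {
    expect_identical(sort(tree_leaves(mechanism2_swap(t))), 1:8)
  }
})

test_that("guide trees serialise to parseable Newick", {
  skip_if_not_installed("ape")
  set.seed(36)
  case <- random_additive_case(5)
  t <- build_guide_tree(case$d)
  ph <- ape::read.tree(text = tree_newick(t))
  expect_equal(ape::Ntip(ph), 5)
  expect_equal(sort(ph$tip.label), paste0("t", 1:5))
})
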