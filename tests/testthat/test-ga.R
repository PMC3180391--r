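# small shared fixtures: a family and a seeded population
make_pop <- function(pop_size = 10, seed = 61, n = 5, L = 60) {
  fam <- generate_family(n, L, 0.15, 0.04, seed = seed)
  cfg <- vdga_config(pop_size = pop_size, termination_patience = 5,
                     mutation_patience = 10, seed = seed)
  set.seed(seed)
  list(fam = fam, cfg = cfg, pop = init_population(fam$descendants, cfg))
}

test_that("the initial population is seeded from TR1/TR2 and is reproducible", {
  fx <- make_pop()
  pop <- fx$pop
  expect_length(pop$individuals, 10)
  fit <- vapply(pop$individuals, `[[`, numeric(1), "fitness")
  expect_true(all(diff(fit) <= 0))  # sorted descending
  for (ind in pop$individuals) {
    expect_identical(ungap(ind$aln), fx$fam$descendants)
  }
  # frozen weights come from the DP-distance tree
  tr1 <- build_guide_tree(distance_matrix_dp(fx$fam$descendants))
  expect_equal(pop$weights, clustalw_weights(tr1))
  # MSA1's fitness is the WSPM of the TR1 progressive alignment
  msa1 <- progressive_align(fx$fam$descendants, tr1)
  key1 <- paste(msa1$rows, collapse = "\n")
  keys <- vapply(pop$individuals, function(i) paste(i$aln$rows, collapse = "\n"),
                 character(1))
  expect_true(key1 %in% keys)
  expect_equal(pop$individuals[[which(keys == key1)[1]]]$fitness,
               wspm(msa1, pop$weights)$total)

  fx2 <- make_pop()
  expect_identical(lapply(fx$pop$individuals, `[[`, "aln"),
                   lapply(fx2$pop$individuals, `[[`, "aln"))
  expect_error(init_population(fx$fam$descendants[1:2], fx$cfg), "3")
})

test_that("parent selection draws from the top and bottom halves", {
  fx <- make_pop()
  set.seed(62)
  for (rep in 1:50) {
    p <- select_parents(fx$pop)
    expect_gte(p$pa$fitness, p$pb$fitness)
  }
  # population of 2: always (best, worst)
  tiny <- fx$pop
  tiny$individuals <- tiny$individuals[c(1, 10)]
  p <- select_parents(tiny)
  expect_identical(p$pa, fx$pop$individuals[[1]])
  expect_identical(p$pb, fx$pop$individuals[[10]])

  # draws are uniform within each half (chi-square sanity at alpha = 1e-6)
  key_of <- function(ind) paste(ind$aln$rows, collapse = "\n")
  top_keys <- vapply(fx$pop$individuals[1:5], key_of, character(1))
  set.seed(63)
  draws <- replicate(4000, key_of(select_parents(fx$pop)$pa))
  counts <- table(factor(draws, levels = top_keys))
  expect_equal(sum(counts), 4000)
  expect_gt(chisq.test(counts)$p.value, 1e-6)
})

test_that("single-point crossover preserves content and improves on neither
           parent being degenerate", {
  fx <- make_pop()
  set.seed(64)
  # identical parents reproduce themselves for any cut
  ind <- fx$pop$individuals[[1]]
  child <- single_point_crossover(ind, ind, fx$pop$weights, fx$cfg)
  expect_identical(child$aln$rows, canonicalise(ind$aln)$rows)

  for (rep in 1:100) {
    p <- select_parents(fx$pop)
    ch <- single_point_crossover(p$pa, p$pb, fx$pop$weights, fx$cfg)
    expect_identical(ungap(ch$aln), fx$fam$descendants)
    expect_equal(ch$fitness, wspm(ch$aln, fx$pop$weights)$total)
  }
})

test_that("single-point crossover returns the better of the two recombinants", {
  fx <- make_pop()
  p <- select_parents(fx$pop)
  # enumerate both recombinants by hand at a fixed cut and compare
  for (cut in c(5, 20, 40)) {
    child <- vdga:::recombine_at(p$pa$aln, p$pb$aln, cut, fx$pop$weights,
                                 fx$cfg)
    la <- substr(p$pa$aln$rows, 1, cut)
    ra <- substr(p$pa$aln$rows, cut + 1, aln_length(p$pa$aln))
    tb <- vdga:::tailor_split(p$pb$aln, vdga:::residue_counts(la))
    c1 <- canonicalise(msa(paste0(vdga:::pad_block(la, "right"),
                                  vdga:::pad_block(tb$right, "left")),
                           p$pa$aln$ids))
    c2 <- canonicalise(msa(paste0(vdga:::pad_block(tb$left, "right"),
                                  vdga:::pad_block(ra, "left")),
                           p$pa$aln$ids))
    best <- max(wspm(c1, fx$pop$weights)$total, wspm(c2, fx$pop$weights)$total)
    expect_equal(child$fitness, best)
  }
})

test_that("multi-point crossover preserves content and handles degenerate
           parents", {
  fx <- make_pop()
  ind <- fx$pop$individuals[[1]]
  child <- multi_point_crossover(ind, ind, fx$pop$weights, fx$cfg)
  expect_identical(ungap(child$aln), fx$fam$descendants)

  set.seed(65)
  for (rep in 1:100) {
    p <- select_parents(fx$pop)
    ch <- suppressWarnings(
      multi_point_crossover(p$pa, p$pb, fx$pop$weights, fx$cfg))
    expect_identical(ungap(ch$aln), fx$fam$descendants)
  }
  short <- ind
  short$aln <- msa(substr(ind$aln$rows, 1, 5), ind$aln$ids)
  expect_error(multi_point_crossover(short, short, fx$pop$weights, fx$cfg),
               "8 columns")
})

test_that("mutation returns strictly better children or nothing, and is
           deterministic", {
  fx <- make_pop()
  set.seed(66)
  for (rep in 1:10) {
    fit_before <- vapply(fx$pop$individuals, `[[`, numeric(1), "fitness")
    ch <- mutation_op(fx$pop, fx$pop$weights, fx$cfg)
    if (!is.null(ch)) {
      expect_identical(ungap(ch$aln), fx$fam$descendants)
      expect_true(ch$fitness > min(fit_before))
    }
  }
  set.seed(67)
  a <- mutation_op(fx$pop, fx$pop$weights, fx$cfg)
  set.seed(67)
  b <- mutation_op(fx$pop, fx$pop$weights, fx$cfg)
  expect_identical(a, b)
})

test_that("a three-sequence individual optimal over all leaf swaps mutates to
           nothing", {
  # three identical sequences: every tree aligns them gap-free at the same
  # fitness, so no swap can improve and the mutation must return NULL
  seqs <- setNames(rep("MKVLATGE", 3), paste0("s", 1:3))
  cfg <- vdga_config(pop_size = 4, seed = 1)
  aln <- msa(unname(seqs), names(seqs))
  ind <- vdga:::new_individual(aln, wspm(aln)$total, "init")
  pop <- vdga:::new_population(list(ind), rep(1, 3), 4)
  set.seed(68)
  expect_null(mutation_op(pop, rep(1, 3), cfg))
})

test_that("vertical division never decreases fitness and preserves content", {
  fx <- make_pop()
  set.seed(69)
  for (k in c(1, 2, 3, 5)) {
    for (i in seq_len(5)) {
      ind <- fx$pop$individuals[[i]]
      out <- vertical_division(ind, k, fx$pop$weights, fx$cfg)
      expect_gte(out$fitness, ind$fitness)
      expect_identical(ungap(out$aln), fx$fam$descendants)
      # reported fitness is the true WSPM of the alignment
      expect_equal(out$fitness, wspm(out$aln, fx$pop$weights)$total)
    }
  }
  ind <- fx$pop$individuals[[1]]
  expect_error(vertical_division(ind, aln_length(ind$aln) + 1,
                                 fx$pop$weights, fx$cfg), "divisions")
})

test_that("survivor selection is elitist and deduplicating", {
  fx <- make_pop()
  pop <- fx$pop
  best <- pop$individuals[[1]]
  # no children: population unchanged
  np <- next_generation(pop, list())
  expect_identical(lapply(np$individuals, `[[`, "aln"),
                   lapply(pop$individuals, `[[`, "aln"))
  # an exact duplicate of the best appears only once
  dup <- vdga:::new_individual(best$aln, best$fitness, "crossover")
  np2 <- next_generation(pop, list(dup))
  keys <- vapply(np2$individuals, function(i) paste(i$aln$rows, collapse = "\n"),
                 character(1))
  expect_equal(sum(keys == paste(best$aln$rows, collapse = "\n")), 1)
  expect_equal(np2$individuals[[1]]$fitness, best$fitness)
})

test_that("full runs terminate on the stall rule with monotone best fitness", {
  fam <- generate_family(5, 40, 0.1, 0.03, seed = 70)
  cfg <- vdga_config(pop_size = 8, decomp_k = 2, termination_patience = 4,
                     mutation_patience = 5, seed = 5, max_generations = 60)
  res <- run_vdga(fam$descendants, cfg)
  expect_true(all(diff(res$trace$best_wspm) >= 0))
  expect_identical(ungap(res$best$aln), fam$descendants)
  # stall rule: the last `patience` generations show no improvement, and the
  # generation before them does (unless the cap was hit)
  tb <- res$trace$best_wspm
  if (res$generations < cfg$max_generations) {
    expect_equal(tb[length(tb)], tb[length(tb) - cfg$termination_patience])
    if (length(tb) > cfg$termination_patience + 1) {
      expect_gt(tb[length(tb) - cfg$termination_patience],
                tb[length(tb) - cfg$termination_patience - 1])
    }
  }
})

test_that("identical-sequence families converge to the gap-free alignment", {
  seqs <- setNames(rep("MKVLATGEHW", 4), paste0("s", 1:4))
  cfg <- vdga_config(pop_size = 6, termination_patience = 2,
                     mutation_patience = 3, seed = 2)
  res <- suppressWarnings(run_vdga(seqs, cfg))
  expect_identical(res$best$aln$rows, unname(seqs))
  truth <- msa(unname(seqs), names(seqs))
  expect_equal(sps(res$best$aln, truth), 1)
})
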