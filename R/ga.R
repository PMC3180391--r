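#' GA configuration
#'
#' Bundles the run parameters of the vertical-decomposition GA. Defaults are
#' the method's published settings: population 100; half the children from
#' crossover (split evenly between single- and multiple-point) and half from
#' mutation; three vertical divisions; 50 consecutive unsuccessful swaps
#' ending a mutation; termination after 100 generations without improvement
#' of the best fitness.
#'
#' @param pop_size Population size.
#' @param crossover_fraction Fraction of children from crossover (split
#'   evenly between single-point and multiple-point).
#' @param mutation_fraction Fraction of children attempted by mutation.
#' @param decomp_k Number of vertical divisions (>= 1).
#' @param mutation_patience Consecutive failed swaps ending a mutation loop.
#' @param termination_patience Stalled generations before termination.
#' @param max_generations Hard cap on generations.
#' @param seed RNG seed for the run.
#' @param m Substitution matrix.
#' @param gaps Gap model.
#' @return An object of class `vdga_config`.
#' @export
vdga_config <- function(pop_size = 100L, crossover_fraction = 0.5,
                        mutation_fraction = 0.5, decomp_k = 3L,
                        mutation_patience = 50L, termination_patience = 100L,
                        max_generations = 1000L, seed = 1L,
                        m = pam250(), gaps = gap_model()) {
  stopifnot(pop_size >= 4L, decomp_k >= 1L, mutation_patience >= 1L,
            termination_patience >= 1L, max_generations >= 1L,
            inherits(m, "substitution_matrix"), inherits(gaps, "gap_model"))
  if (abs(crossover_fraction + mutation_fraction - 1) > 1e-12)
    stop("crossover and mutation fractions must sum to 1")
  structure(list(pop_size = as.integer(pop_size),
                 crossover_fraction = crossover_fraction,
                 mutation_fraction = mutation_fraction,
                 decomp_k = as.integer(decomp_k),
                 mutation_patience = as.integer(mutation_patience),
                 termination_patience = as.integer(termination_patience),
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed), m = m, gaps = gaps),
            class = "vdga_config")
}

new_individual <- function(aln, fitness, lineage) {
  structure(list(aln = aln, fitness = fitness, lineage = lineage),
            class = "vdga_individual")
}

score_individual <- function(aln, w, cfg, lineage) {
  new_individual(aln, wspm(aln, w, cfg$m, cfg$gaps)$total, lineage)
}

aln_key <- function(aln) paste(aln$rows, collapse = "\n")

new_population <- function(individuals, weights, pop_size) {
  fit <- vapply(individuals, `[[`, numeric(1L), "fitness")
  structure(list(individuals = individuals[order(-fit)],
                 weights = weights, pop_size = pop_size),
            class = "vdga_population")
}

pop_fitness <- function(pop)
  vapply(pop$individuals, `[[`, numeric(1L), "fitness")

#' @export
print.vdga_population <- function(x, ...) {
  f <- pop_fitness(x)
  cat("VDGA population:", length(x$individuals), "individuals, best WSPM",
      format(max(f)), ", mean", format(mean(f)), "\n")
  invisible(x)
}

#' Seed the initial population
#'
#' Stage 1 builds TR1 by neighbour joining on DP distances and aligns MSA1;
#' stage 2 builds TR2 from the Kimura distances of MSA1 and aligns MSA2;
#' stage 3 fills the population with trees obtained by applying
#' [mechanism1_split()] and [mechanism2_swap()] to TR1 and TR2 (spread
#' evenly over the four mechanism-by-tree combinations), each progressively
#' aligned. Duplicate trees or alignments are redrawn a bounded number of
#' times and then admitted with a warning. The CLUSTAL W weight vector is
#' computed once from TR1 and frozen for the whole run, so fitness values
#' are comparable across the population.
#'
#' @param seqs Named character vector of >= 3 ungapped sequences.
#' @param cfg A [vdga_config()].
#' @return A `vdga_population` (sorted by fitness, weights attached).
#' @export
init_population <- function(seqs, cfg = vdga_config()) {
  validate_sequences(seqs)
  if (length(seqs) < 3L) stop("need at least 3 sequences")
  d1 <- distance_matrix_dp(seqs, cfg$m, cfg$gaps)
  tr1 <- build_guide_tree(d1)
  w <- clustalw_weights(tr1)
  msa1 <- progressive_align(seqs, tr1, cfg$m, cfg$gaps)
  tr2 <- build_guide_tree(distance_matrix_kimura(msa1))
  msa2 <- progressive_align(seqs, tr2, cfg$m, cfg$gaps)

  inds <- list(score_individual(msa1, w, cfg, "init"),
               score_individual(msa2, w, cfg, "init"))
  seen_tree <- c(tree_canonical(tr1), tree_canonical(tr2))
  seen_aln <- vapply(inds, function(i) aln_key(i$aln), character(1L))

  p2 <- cfg$pop_size - 2L
  combos <- list(list(mech = 1L, tree = tr1), list(mech = 1L, tree = tr2),
                 list(mech = 2L, tree = tr1), list(mech = 2L, tree = tr2))
  counts <- rep(p2 %/% 4L, 4L)
  counts[3L] <- counts[3L] + p2 %% 4L  # remainder to mechanism 2 on TR1
  for (ci in seq_along(combos)) {
    for (k in seq_len(counts[ci])) {
      admitted <- FALSE
      for (try in 1:20) {
        tr <- if (combos[[ci]]$mech == 1L)
          suppressWarnings(mechanism1_split(combos[[ci]]$tree))
        else mechanism2_swap(combos[[ci]]$tree)
        key_t <- tree_canonical(tr)
        if (key_t %in% seen_tree && try < 20L) next
        aln <- progressive_align(seqs, tr, cfg$m, cfg$gaps)
        key_a <- aln_key(aln)
        if (key_a %in% seen_aln && try < 20L) next
        if (key_t %in% seen_tree || key_a %in% seen_aln)
          warning("admitting duplicate individual into initial population")
        seen_tree <- c(seen_tree, key_t)
        seen_aln <- c(seen_aln, key_a)
        inds[[length(inds) + 1L]] <- score_individual(aln, w, cfg, "init")
        admitted <- TRUE
        break
      }
      if (!admitted) stop("could not seed population slot")  # unreachable
    }
  }
  new_population(inds, w, cfg$pop_size)
}

#' Select crossover parents
#'
#' One parent uniform over the top half of the population by fitness, the
#' other uniform over the bottom half.
#'
#' @param pop A `vdga_population` (sorted by fitness).
#' @return List with elements `pa` (from the top half) and `pb`.
#' @export
select_parents <- function(pop) {
  n <- length(pop$individuals)
  if (n < 2L) stop("population too small")
  half <- ceiling(n / 2)
  ia <- sample.int(half, 1L)
  ib <- half + sample.int(n - half, 1L)
  list(pa = pop$individuals[[ia]], pb = pop$individuals[[ib]])
}

# split every row of an alignment so the left part of row k carries
# `counts[k]` residues; returns left/right character vectors (ragged)
tailor_split <- function(aln, counts) {
  ch <- msa_chars(aln)
  left <- character(nrow(ch))
  right <- character(nrow(ch))
  for (k in seq_len(nrow(ch))) {
    cum <- cumsum(ch[k, ] != GAP_CHAR)
    pos <- if (counts[k] == 0L) 0L else match(counts[k], cum)
    left[k] <- paste(ch[k, seq_len(pos)], collapse = "")
    right[k] <- if (pos < ncol(ch))
      paste(ch[k, (pos + 1L):ncol(ch)], collapse = "") else ""
  }
  list(left = left, right = right)
}

residue_counts <- function(rows) nchar(gsub("-", "", rows, fixed = TRUE))

# pad ragged rows with gaps to a rectangle; side = where gaps go
pad_block <- function(rows, side = c("right", "left")) {
  side <- match.arg(side)
  w <- max(nchar(rows))
  pad <- strrep(GAP_CHAR, w - nchar(rows))
  if (side == "right") paste0(rows, pad) else paste0(pad, rows)
}

#' Single-point crossover
#'
#' A cut column is drawn uniformly on the interior of the better-scoring
#' parent, which is split there; the other parent is split row-wise so each
#' row's left piece carries the same residue count. Pieces are padded into
#' rectangles (left pieces on the right, right pieces on the left), the two
#' recombinants are canonicalised and scored, and the better one is
#' returned.
#'
#' @param pa,pb `vdga_individual` parents over the same sequences.
#' @param weights Frozen sequence weight vector.
#' @param cfg A [vdga_config()] (matrix and gap model).
#' @return A `vdga_individual` child.
#' @export
single_point_crossover <- function(pa, pb, weights, cfg = vdga_config()) {
  if (pb$fitness > pa$fitness) { tmp <- pa; pa <- pb; pb <- tmp }
  stopifnot(identical(pa$aln$ids, pb$aln$ids))
  L <- aln_length(pa$aln)
  if (L < 2L) stop("better parent has fewer than 2 columns")
  for (try in 1:20) {
    cut <- sample.int(L - 1L, 1L)
    child <- tryCatch(
      recombine_at(pa$aln, pb$aln, cut, weights, cfg),
      error = function(e) NULL)
    if (!is.null(child)) return(child)
  }
  stop("degenerate cut: no valid recombinant found")
}

recombine_at <- function(aa, ab, cut, weights, cfg) {
  left_a <- substr(aa$rows, 1L, cut)
  right_a <- substr(aa$rows, cut + 1L, aln_length(aa))
  tb <- tailor_split(ab, residue_counts(left_a))
  c1 <- msa(paste0(pad_block(c(left_a), "right"),
                   pad_block(c(tb$right), "left")), aa$ids)
  c2 <- msa(paste0(pad_block(c(tb$left), "right"),
                   pad_block(c(right_a), "left")), aa$ids)
  best_of(list(canonicalise(c1), canonicalise(c2)), weights, cfg, "crossover")
}

best_of <- function(alns, weights, cfg, lineage) {
  inds <- lapply(alns, score_individual, w = weights, cfg = cfg,
                 lineage = lineage)
  fit <- vapply(inds, `[[`, numeric(1L), "fitness")
  inds[[which.max(fit)]]
}

#' Multiple-point crossover
#'
#' Each parent is cut into three pieces and the middle pieces are exchanged.
#' Step 1 compares the leading `ceiling(L/4)` columns of the two parents
#' (scored as standalone slices with [wspm_range()]); the better parent is
#' cut at its 25% boundary and the other is tailored row-wise by residue
#' counts. Step 2 repeats this from the right on the trailing quarter of the
#' remaining right pieces. The two recombinants (`a1+b2'+a3` and
#' `b1+a2'+b3`) are scored and the better returned. If tailoring leaves an
#' empty middle piece the better parent is returned unchanged with a
#' warning.
#'
#' @inheritParams single_point_crossover
#' @return A `vdga_individual` child.
#' @export
multi_point_crossover <- function(pa, pb, weights, cfg = vdga_config()) {
  stopifnot(identical(pa$aln$ids, pb$aln$ids))
  La <- aln_length(pa$aln)
  Lb <- aln_length(pb$aln)
  if (La < 8L || Lb < 8L) stop("parents must have at least 8 columns")
  better_parent <- if (pa$fitness >= pb$fitness) pa else pb

  # Step 1: leading quarter
  qa <- ceiling(La / 4)
  qb <- ceiling(Lb / 4)
  sa <- wspm_range(pa$aln, 1L, qa, weights, cfg$m, cfg$gaps)$total
  sb <- wspm_range(pb$aln, 1L, qb, weights, cfg$m, cfg$gaps)$total
  if (sa >= sb) {
    a1 <- substr(pa$aln$rows, 1L, qa)
    a2 <- substr(pa$aln$rows, qa + 1L, La)
    tb <- tailor_split(pb$aln, residue_counts(a1))
    b1 <- tb$left; b2 <- tb$right
  } else {
    b1 <- substr(pb$aln$rows, 1L, qb)
    b2 <- substr(pb$aln$rows, qb + 1L, Lb)
    ta <- tailor_split(pa$aln, residue_counts(b1))
    a1 <- ta$left; a2 <- ta$right
  }

  # Step 2: trailing quarter of the right pieces (rectangularised first)
  a2 <- pad_block(a2, "left")
  b2 <- pad_block(b2, "left")
  La2 <- nchar(a2[[1L]])
  Lb2 <- nchar(b2[[1L]])
  if (La2 < 1L || Lb2 < 1L) {
    warning("crossover produced an empty piece; returning better parent")
    return(new_individual(better_parent$aln, better_parent$fitness,
                          "crossover"))
  }
  ka <- ceiling(La2 / 4)
  kb <- ceiling(Lb2 / 4)
  msa_a2 <- msa(a2, pa$aln$ids)
  msa_b2 <- msa(b2, pb$aln$ids)
  sa2 <- tryCatch(
    wspm_range(msa_a2, La2 - ka + 1L, La2, weights, cfg$m, cfg$gaps)$total,
    error = function(e) -Inf)
  sb2 <- tryCatch(
    wspm_range(msa_b2, Lb2 - kb + 1L, Lb2, weights, cfg$m, cfg$gaps)$total,
    error = function(e) -Inf)
  if (sa2 >= sb2) {
    a3 <- substr(a2, La2 - ka + 1L, La2)
    a2p <- substr(a2, 1L, La2 - ka)
    tb <- tailor_split_right(msa_b2, residue_counts(a3))
    b2p <- tb$left; b3 <- tb$right
  } else {
    b3 <- substr(b2, Lb2 - kb + 1L, Lb2)
    b2p <- substr(b2, 1L, Lb2 - kb)
    ta <- tailor_split_right(msa_a2, residue_counts(b3))
    a2p <- ta$left; a3 <- ta$right
  }
  if (max(nchar(a2p)) == 0L || max(nchar(b2p)) == 0L) {
    warning("crossover produced an empty middle piece; returning better parent")
    return(new_individual(better_parent$aln, better_parent$fitness,
                          "crossover"))
  }

  glue <- function(p1, p2, p3)
    msa(paste0(pad_block(p1, "right"), pad_block(p2, "right"),
               pad_block(p3, "left")), pa$aln$ids)
  child1 <- tryCatch(canonicalise(glue(a1, b2p, a3)),
                     error = function(e) NULL)
  child2 <- tryCatch(canonicalise(glue(b1, a2p, b3)),
                     error = function(e) NULL)
  kids <- Filter(Negate(is.null), list(child1, child2))
  if (length(kids) == 0L) {
    warning("crossover produced no valid recombinant; returning better parent")
    return(new_individual(better_parent$aln, better_parent$fitness,
                          "crossover"))
  }
  best_of(kids, weights, cfg, "crossover")
}

# split so the RIGHT part of row k carries `counts[k]` residues
tailor_split_right <- function(aln, counts) {
  total <- residue_counts(aln$rows)
  tailor_split(aln, total - counts)
}

#' Mutation operator
#'
#' One individual is drawn uniformly from the population. Its Kimura
#' distance table is computed, a guide tree built and progressively aligned;
#' the tree's leaves are then repeatedly shuffled with [mechanism2_swap()],
#' each shuffle re-aligned, a swap being accepted when its WSPM beats the
#' best alignment seen in the loop (which resets the failure counter). The
#' loop stops after `cfg$mutation_patience` consecutive failures. The best
#' loop alignment is returned as a child only if it beats the fitness of the
#' source individual; otherwise the mutation has no effect and `NULL` is
#' returned.
#'
#' @param pop A `vdga_population`.
#' @param weights Frozen sequence weight vector.
#' @param cfg A [vdga_config()].
#' @return A `vdga_individual`, or `NULL` for an unsuccessful mutation.
#' @export
mutation_op <- function(pop, weights, cfg = vdga_config()) {
  src <- pop$individuals[[sample.int(length(pop$individuals), 1L)]]
  d <- tryCatch(distance_matrix_kimura(src$aln), error = function(e) NULL)
  if (is.null(d)) return(NULL)
  tr <- build_guide_tree(d)
  M <- matrix_codes(cfg$m)
  codes <- msa_codes(src$aln)
  leaves <- lapply(seq_len(nrow(codes)), function(i) {
    v <- codes[i, ]
    v[v > 0L]
  })
  res <- cpp_mutation_search(leaves, tree_plan(tr), M, cfg$gaps$g,
                             cfg$gaps$x, as.numeric(weights),
                             cfg$mutation_patience)
  if (res$fitness > src$fitness)
    new_individual(codes_msa(res$codes, src$aln$ids), res$fitness, "mutation")
  else NULL
}

#' Vertical division: decompose, re-align, keep if better
#'
#' The defining operator of the method. The alignment's columns are split
#' into `k` contiguous blocks of near-equal width (the first `L mod k`
#' blocks one column wider). In each block the gaps are stripped from every
#' row; rows emptied by stripping are set aside and re-inserted as all-gap
#' rows. Blocks with at least two non-empty rows are re-aligned from scratch
#' with the guide-tree method (DP distances, neighbour joining, progressive
#' alignment). The re-aligned blocks are concatenated, canonicalised and
#' scored; the reassembly replaces the individual only if its fitness
#' strictly improves, so the operator never decreases fitness.
#'
#' @param ind A `vdga_individual`.
#' @param k Number of vertical divisions (>= 1, <= alignment length).
#' @param weights Frozen sequence weight vector.
#' @param cfg A [vdga_config()].
#' @return A `vdga_individual` with fitness >= `ind$fitness`.
#' @export
vertical_division <- function(ind, k = 3L, weights = NULL,
                              cfg = vdga_config()) {
  stopifnot(inherits(ind, "vdga_individual"), k >= 1L)
  aln <- ind$aln
  L <- aln_length(aln)
  if (k > L) stop("more divisions than columns")
  widths <- rep(L %/% k, k) + (seq_len(k) <= L %% k)
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  n <- aln_nrow(aln)
  if (is.null(weights)) weights <- rep(1, n)
  M <- matrix_codes(cfg$m)
  codes <- msa_codes(aln)

  blocks <- vector("list", k)
  for (b in seq_len(k)) {
    piece <- codes[, starts[b]:ends[b], drop = FALSE]
    stripped <- lapply(seq_len(n), function(i) {
      v <- piece[i, ]
      v[v > 0L]
    })
    nonempty <- which(lengths(stripped) > 0L)
    if (length(nonempty) >= 2L) {
      sub <- stripped[nonempty]
      nd <- length(sub)
      d <- matrix(0, nd, nd)
      for (i in seq_len(nd - 1L)) {
        for (j in (i + 1L):nd) {
          d[i, j] <- d[j, i] <- cpp_dp_distance(sub[[i]], sub[[j]], M,
                                                cfg$gaps$g, cfg$gaps$x)
        }
      }
      baln <- prog_codes(sub, build_guide_tree(d), M, cfg$gaps)
      block <- matrix(0L, n, ncol(baln))
      block[nonempty, ] <- baln
    } else if (length(nonempty) == 1L) {
      block <- matrix(0L, n, length(stripped[[nonempty]]))
      block[nonempty, ] <- stripped[[nonempty]]
    } else {
      block <- NULL  # block was entirely gaps; contributes no columns
    }
    blocks[[b]] <- block
  }
  new_codes <- do.call(cbind, blocks)
  new_codes <- new_codes[, colSums(new_codes > 0L) > 0L, drop = FALSE]
  new_fit <- cpp_wspm(new_codes, as.numeric(weights), M,
                      cfg$gaps$g, cfg$gaps$x)$total
  if (new_fit > ind$fitness)
    new_individual(codes_msa(new_codes, aln$ids), new_fit, "decomposition")
  else ind
}

#' Form the next generation
#'
#' Parents and children are pooled, exact duplicates (by canonical alignment
#' text) removed keeping the first seen, the pool stably sorted by fitness
#' descending, and the best `pop_size` retained. The previous best
#' individual is always present, so elitism holds by construction. If the
#' deduplicated pool is smaller than `pop_size` the whole pool is kept with
#' a warning.
#'
#' @param pop Parent `vdga_population`.
#' @param children List of `vdga_individual` children (possibly empty).
#' @return A `vdga_population`.
#' @export
next_generation <- function(pop, children) {
  pool <- c(pop$individuals, children)
  keys <- vapply(pool, function(i) aln_key(i$aln), character(1L))
  pool <- pool[!duplicated(keys)]
  fit <- vapply(pool, `[[`, numeric(1L), "fitness")
  pool <- pool[order(-fit)]  # stable: ties keep parents-first insertion order
  if (length(pool) < pop$pop_size)
    warning("population shrank to ", length(pool), " after deduplication")
  pool <- pool[seq_len(min(pop$pop_size, length(pool)))]
  structure(list(individuals = pool, weights = pop$weights,
                 pop_size = pop$pop_size), class = "vdga_population")
}

#' Run the vertical-decomposition genetic algorithm
#'
#' Full optimisation loop: seed the population ([init_population()]), apply
#' [vertical_division()] to every individual, then iterate generations of
#' single-point and multiple-point crossover children plus mutation
#' attempts, vertical division on every child, and 50-50 survivor selection
#' ([next_generation()]), until the best fitness has not improved for
#' `termination_patience` consecutive generations (or `max_generations` is
#' reached). The whole run is a deterministic function of the config seed.
#'
#' @param seqs Named character vector of >= 3 ungapped protein sequences.
#' @param cfg A [vdga_config()].
#' @return An object of class `vdga_result`: list with `best` (the best
#'   `vdga_individual`), `population`, `weights`, `generations`, and `trace`
#'   (a data frame with one row per generation: `generation`, `best_wspm`,
#'   `mean_wspm`, `children_produced`, `mutations_failed`).
#' @export
run_vdga <- function(seqs, cfg = vdga_config()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(cfg$seed)

  pop <- init_population(seqs, cfg)
  pop$individuals <- lapply(pop$individuals, vertical_division,
                            k = cfg$decomp_k, weights = pop$weights,
                            cfg = cfg)
  pop <- new_population(pop$individuals, pop$weights, cfg$pop_size)

  n_single <- floor(cfg$pop_size * cfg$crossover_fraction / 2)
  n_multi <- n_single
  n_mut <- floor(cfg$pop_size * cfg$mutation_fraction)

  trace <- data.frame(generation = 0L,
                      best_wspm = pop$individuals[[1L]]$fitness,
                      mean_wspm = mean(pop_fitness(pop)),
                      children_produced = 0L, mutations_failed = 0L)
  best_fit <- pop$individuals[[1L]]$fitness
  stall <- 0L
  gen <- 0L
  while (stall < cfg$termination_patience && gen < cfg$max_generations) {
    gen <- gen + 1L
    children <- list()
    mutations_failed <- 0L
    can_cross <- length(pop$individuals) >= 2L
    for (i in seq_len(if (can_cross) n_single else 0L)) {
      p <- select_parents(pop)
      child <- tryCatch(
        single_point_crossover(p$pa, p$pb, pop$weights, cfg),
        error = function(e) NULL)
      if (!is.null(child)) children[[length(children) + 1L]] <- child
    }
    for (i in seq_len(if (can_cross) n_multi else 0L)) {
      p <- select_parents(pop)
      child <- tryCatch(
        if (aln_length(p$pa$aln) >= 8L && aln_length(p$pb$aln) >= 8L)
          suppressWarnings(multi_point_crossover(p$pa, p$pb, pop$weights, cfg))
        else single_point_crossover(p$pa, p$pb, pop$weights, cfg),
        error = function(e) NULL)
      if (!is.null(child)) children[[length(children) + 1L]] <- child
    }
    for (i in seq_len(n_mut)) {
      child <- mutation_op(pop, pop$weights, cfg)
      if (is.null(child)) mutations_failed <- mutations_failed + 1L
      else children[[length(children) + 1L]] <- child
    }
    children <- lapply(children, vertical_division, k = cfg$decomp_k,
                       weights = pop$weights, cfg = cfg)
    pop <- suppressWarnings(next_generation(pop, children))
    new_best <- pop$individuals[[1L]]$fitness
    if (new_best > best_fit) {
      best_fit <- new_best
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- rbind(trace, data.frame(
      generation = gen, best_wspm = new_best,
      mean_wspm = mean(pop_fitness(pop)),
      children_produced = length(children),
      mutations_failed = mutations_failed))
  }
  structure(list(best = pop$individuals[[1L]], population = pop,
                 weights = pop$weights, generations = gen, trace = trace),
            class = "vdga_result")
}

#' @export
print.vdga_result <- function(x, ...) {
  cat("VDGA run:", x$generations, "generations, best WSPM",
      format(x$best$fitness), "\n")
  invisible(x)
}
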