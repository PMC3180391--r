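test_that("affine gap penalty is g + n*x", {
  expect_equal(gap_penalty(5), -11)     # -10 + 5 * (-0.2)
  expect_equal(gap_penalty(1), -10.2)
  expect_equal(gap_penalty(3, gap_model(0, 0)), 0)
  expect_error(gap_penalty(0), ">= 1")
})

test_that("weighted sum-of-pairs matches hand computation on small cases", {
  a <- msa(c("AA", "AA"), c("s1", "s2"))
  sb <- wspm(a)
  expect_equal(sb$total, 4)  # two columns of m(A, A) = 2
  expect_equal(sb$per_column, c(2, 2))
  expect_equal(sb$gap_total, 0)
  expect_equal(sb$total, sum(sb$per_column) + sb$gap_total)

  # a gap-gap column contributes 0 and does not interrupt a gap run:
  # projecting row pair (1, 2) turns A--A / AC-A into A-A / ACA, one run
  b <- msa(c("A--A", "AC-A"), c("s1", "s2"))
  sbb <- wspm(b)
  expect_equal(sbb$gap_total, gap_penalty(1))
  expect_equal(sum(sbb$per_column), 2 * sub_score(pam250(), "A", "A"))

  # weights scale pair contributions multiplicatively
  w <- c(2, 0.5)
  expect_equal(wspm(a, w)$total, 2 * 0.5 * 4)
})

test_that("wspm equals the brute-force projection oracle on random alignments", {
  set.seed(51)
  for (rep in 1:40) {
    a <- random_alignment(n = sample(2:6, 1), L = sample(5:30, 1),
                          gap_prob = 0.3)
    w <- runif(aln_nrow(a), 0.5, 2)
    got <- wspm(a, w)
    expect_equal(got$total, wspm_oracle(a, w), tolerance = 1e-9)
    expect_equal(got$total, sum(got$per_column) + got$gap_total,
                 tolerance = 1e-9)
  }
})

test_that("wspm is invariant under all-gap columns and row permutation", {
  set.seed(52)
  a <- random_alignment(4, 20)
  w <- runif(4, 0.5, 2)
  base <- wspm(a, w)$total
  # splice an all-gap column in the middle
  padded <- msa(paste0(substr(a$rows, 1, 10), "-", substr(a$rows, 11, 20)),
                a$ids)
  expect_equal(wspm(padded, w)$total, base, tolerance = 1e-9)
  p <- sample(4)
  perm <- msa(a$rows[p], a$ids[p])
  expect_equal(wspm(perm, w[p])$total, base, tolerance = 1e-9)
})

test_that("range scoring slices behave as standalone sub-alignments", {
  set.seed(53)
  a <- random_alignment(4, 24)
  w <- runif(4, 0.5, 2)
  expect_equal(wspm_range(a, 1, 24, w)$total, wspm(a, w)$total)

  # additivity for a gap-free alignment split in two
  b <- msa(c("MKVLATMKVL", "MKVLGTMKVL", "MRVLATMKIL"))
  expect_equal(wspm_range(b, 1, 5)$total + wspm_range(b, 6, 10)$total,
               wspm(b)$total, tolerance = 1e-9)

  # a gap run straddling the cut is charged one opening on each side:
  # rows AAAA / A--A cut at column 2 -> slices (AA / A-) and (AA / -A)
  d <- msa(c("AAAA", "A--A"))
  whole <- wspm(d)$total
  lft <- wspm_range(d, 1, 2)$total
  rgt <- wspm_range(d, 3, 4)$total
  expect_equal(whole, 2 * sub_score(pam250(), "A", "A") + gap_penalty(2))
  expect_equal(lft + rgt,
               2 * sub_score(pam250(), "A", "A") + 2 * gap_penalty(1))
  expect_error(wspm_range(d, 3, 2), "range")
})

test_that("SPS and CS are exact on the boundary cases", {
  ref <- msa(c("AC-DE", "ACGD-", "A-GDE"), c("s1", "s2", "s3"))
  expect_equal(sps(ref, ref), 1)
  expect_equal(cs(ref, ref), 1)

  # fully staggered test: every residue in its own column
  stagger <- function(aln) {
    seqs <- ungap(aln)
    tot <- sum(nchar(seqs))
    off <- c(0, cumsum(head(nchar(seqs), -1)))
    rows <- vapply(seq_along(seqs), function(i) {
      paste0(strrep("-", off[i]), seqs[[i]],
             strrep("-", tot - off[i] - nchar(seqs[[i]])))
    }, character(1))
    msa(rows, aln$ids)
  }
  st <- stagger(ref)
  expect_equal(sps(st, ref), 0)
  expect_equal(cs(st, ref), 0)

  other <- msa(c("ACDE", "ACGD"), c("s1", "s2"))
  expect_error(sps(other, ref), "ids")
})

test_that("SPS and CS agree with brute-force enumeration, with and without
           core columns", {
  set.seed(54)
  for (rep in 1:25) {
    fam <- generate_family(4, 20, 0.2, 0.1, seed = rep)
    ref <- fam$true_alignment
    tr <- build_guide_tree(distance_matrix_dp(fam$descendants))
    test <- progressive_align(fam$descendants, tr)
    expect_equal(sps(test, ref), sps_oracle(test, ref), tolerance = 1e-12)
    expect_equal(cs(test, ref), cs_oracle(test, ref), tolerance = 1e-12)
    core <- sort(sample(aln_length(ref), max(2, aln_length(ref) %/% 2)))
    if (sum(!is.na(colSums(vdga:::ordinal_matrix(ref)[, core]))) > 0) {
      got <- tryCatch(sps(test, ref, core), error = function(e) NULL)
      if (!is.null(got))
        expect_equal(got, sps_oracle(test, ref, core), tolerance = 1e-12)
      expect_equal(cs(test, ref, core), cs_oracle(test, ref, core),
                   tolerance = 1e-12)
    }
  }
})

test_that("staggering perturbations never increase SPS or CS", {
  set.seed(55)
  fam <- generate_family(4, 30, 0.1, 0.05, seed = 3)
  ref <- fam$true_alignment
  # progressively push the first row rightwards with leading gaps
  prev_sps <- 1
  prev_cs <- 1
  for (k in 1:4) {
    rows <- ref$rows
    rows[1] <- paste0(strrep("-", k), rows[1])
    rows[-1] <- paste0(rows[-1], strrep("-", k))
    test <- msa(rows, ref$ids)
    cur_sps <- sps(test, ref)
    cur_cs <- cs(test, ref)
    expect_lte(cur_sps, prev_sps)
    expect_lte(cur_cs, prev_cs)
    prev_sps <- cur_sps
    prev_cs <- cur_cs
  }
})
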