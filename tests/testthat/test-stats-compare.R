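test_that("G statistic matches direct likelihood-ratio evaluation", {
  set.seed(202)
  for (r in 1:50) {
    m <- matrix(rpois(12, lambda = 30) + 1, nrow = 2)
    expect_equal(g_test(m)$G, g_oracle(m), tolerance = 1e-12)
  }
  gt <- g_test(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(gt$G, 20.93, tolerance = 1e-3)
  expect_equal(gt$df, 1L)
})

test_that("G-test degenerate and scaling behaviour", {
  m0 <- matrix(10, 2, 2)
  expect_equal(g_test(m0)$G, 0)
  expect_equal(g_test(m0)$p_value, 1)
  m <- matrix(c(12, 5, 9, 20), 2)
  expect_equal(g_test(2 * m)$G, 2 * g_test(m)$G, tolerance = 1e-12)
  expect_error(g_test(matrix(c(0, 0, 5, 5), 2)), "zero")
  expect_error(g_test(matrix(c(-1, 2, 3, 4), 2)), "negative")
  expect_error(g_test(matrix(1:3, 1)), "2x2")
})

test_that("rank-sum test switches between exact enumeration and normal approximation", {
  r <- mww_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact_enumeration")
  # identical multisets: U = n^2/2, p about 1 under the tie-corrected normal
  ri <- mww_test(1:10, 1:10)
  expect_equal(ri$U, 50)
  expect_equal(ri$method, "normal_approx")
  expect_gt(ri$p_value, 0.9)
  # large tie-free samples switch to the normal approximation
  big <- mww_test(seq(1, 60, by = 2) + 0.1, seq(2, 61, by = 2))
  expect_equal(big$method, "normal_approx")
  expect_error(mww_test(numeric(0), 1:3), "empty")
})

test_that("exact rank-sum p equals brute-force permutation enumeration", {
  set.seed(203)
  for (r in 1:12) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    repeat {
      x <- round(runif(n1, 0, 100), 3)
      y <- round(runif(n2, 0, 100), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    res <- mww_test(x, y)
    expect_equal(res$method, "exact_enumeration")
    expect_equal(res$p_value, mww_perm_p(x, y), tolerance = 1e-12)
  }
})

test_that("normal approximation agrees with exact enumeration for moderate n", {
  set.seed(204)
  for (r in 1:5) {
    x <- round(rnorm(15, 0, 1), 4)
    y <- round(rnorm(15, 0.8, 1), 4)
    if (anyDuplicated(c(x, y))) next
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    p_norm <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("annotation matching applies the contiguous-coverage and identity rules", {
  ref <- tx("r1", c(1, 301, 601), c(200, 500, 800), gene = "ref1")
  refs <- list(ref1 = locus_of(ref))
  # identical exon chain: coverage 1, identity 1
  asm_same <- list(a1 = gene_locus("a1", list(
    tx("a1.t", c(1, 301, 601), c(200, 500, 800), gene = "a1"))))
  expect_true(match_to_annotation(asm_same, refs)$per_gene$matched)
  # contiguous 70% of the reference mRNA (600 nt): exons 1-2 only = 400/600
  asm_partial <- list(a2 = gene_locus("a2", list(
    tx("a2.t", c(1, 301), c(200, 500), gene = "a2"))))
  expect_false(match_to_annotation(asm_partial, refs)$per_gene$matched)
  # 5/6 of the mRNA contiguously, structurally identical where present
  asm_most <- list(a3 = gene_locus("a3", list(
    tx("a3.t", c(1, 301, 601), c(200, 500, 700), gene = "a3"))))
  expect_true(match_to_annotation(asm_most, refs)$per_gene$matched)
  # non-overlapping locus never matches
  asm_far <- list(a4 = gene_locus("a4", list(
    tx("a4.t", 5001, 6000, gene = "a4"))))
  expect_false(match_to_annotation(asm_far, refs)$per_gene$matched)
})

test_that("generator loci match themselves; strong truncations never match", {
  ds <- simulate_dataset(small_spec(seed = 91L), coverage = FALSE)
  self <- match_to_annotation(ds$loci, ds$loci)
  expect_equal(self$fraction, 1)
  # restrict to single-isoform reference loci: a planted (itself truncated)
  # alternative isoform can legitimately be matched by a truncated query
  singles <- Filter(function(l) length(l$transcripts) == 1L, ds$loci)
  truncated <- lapply(singles, function(l) {
    t <- l$transcripts[[1L]]
    L <- spliced_length(t)
    # keep only leading exons until < 60% of the mRNA remains
    keep <- which(cumsum(exon_lengths(t)) <= 0.6 * L)
    if (length(keep) == 0L) keep <- 1L
    t$exon_start <- t$exon_start[keep]
    t$exon_end <- t$exon_end[keep]
    t$cds_span <- NULL
    gene_locus(l$gene_id, list(t))
  })
  frac <- match_to_annotation(truncated, ds$loci)$per_gene
  lens_ok <- vapply(names(truncated), function(g) {
    spliced_length(truncated[[g]]$transcripts[[1L]]) /
      spliced_length(ds$loci[[g]]$transcripts[[1L]]) < 0.8
  }, TRUE)
  expect_true(all(!frac$matched[lens_ok]))
})

test_that("two-sample report is internally consistent and deterministic", {
  ds <- simulate_dataset(small_spec(seed = 92L), coverage = FALSE)
  s <- list(loci = ds$loci, abundance = ds$abundance, genome = ds$genome)
  rep1 <- compare_samples(s, s)
  expect_equal(rep1$category_table[1, ], rep1$category_table[2, ])
  expect_equal(sum(rep1$category_table[1, ]), rep1$a$summary$n_events)
  expect_equal(rep1$a$filter_report$n_kept + rep1$a$filter_report$n_dropped,
               rep1$a$filter_report$n_input)
  expect_equal(sum(unlist(rep1$a$filter_report$per_criterion)),
               rep1$a$filter_report$n_dropped)
  rep2 <- compare_samples(s, s)
  expect_identical(rep1, rep2)
})
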