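test_that("ORF finding returns the longest AUG-initiated frame with 5'-most ties", {
  o <- find_orf("ATGAAATAA")
  expect_equal(o$start_pos, 1L)
  expect_equal(o$stop_pos, 7L)
  expect_equal(o$length_nt, 9L)
  expect_null(find_orf("CCCCCC"))
  expect_null(find_orf("ATGCCCCCC")) # no in-frame stop
  # 60-nt ORF beats a 30-nt ORF regardless of order in the sequence
  short_orf <- paste0("ATG", strrep("GCC", 8), "TAA")   # 30 nt
  long_orf <- paste0("ATG", strrep("GCC", 18), "TAA")   # 60 nt
  for (s in c(paste0(short_orf, "CC", long_orf),
              paste0(long_orf, "CC", short_orf))) {
    o <- find_orf(s)
    expect_equal(o$length_nt, 60L)
  }
  # exact tie: the 5'-most start wins
  s <- paste0(short_orf, "C", short_orf)
  expect_equal(find_orf(s)$start_pos, 1L)
})

test_that("last junction position is strand-aware and absent for single exons", {
  expect_equal(last_junction_position(tx("p", c(1, 201), c(100, 300))), 100L)
  expect_equal(last_junction_position(tx("m", c(1, 201), c(100, 300),
                                         strand = "-")), 100L)
  expect_true(is.na(last_junction_position(tx("s", 1, 500))))
})

test_that("the 55-nt rule boundary is strict and monotone in distance", {
  flags <- vapply(c(10L, 54L, 55L, 56L, 200L), function(d) {
    f <- make_ptc_tx(d)
    a <- assess_nmd(f$t, f$genome)
    expect_equal(a$stop_to_junction_nt, d)
    expect_true(a$is_ptc)
    a$is_nmd_candidate
  }, TRUE)
  expect_equal(flags, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # monotone: once a candidate, always a candidate at larger distances
  ds <- vapply(seq(10L, 300L, by = 10L), function(d)
    assess_nmd(make_ptc_tx(d)$t, make_ptc_tx(d)$genome)$is_nmd_candidate, TRUE)
  expect_true(all(diff(as.integer(ds)) >= 0))
})

test_that("a stop in the last exon is neither PTC nor NMD candidate", {
  f <- make_ptc_tx(-30L)
  a <- assess_nmd(f$t, f$genome)
  expect_false(a$is_ptc)
  expect_false(a$is_nmd_candidate)
  # single exon transcripts are never candidates
  g <- c(chr1 = paste0("ATG", strrep("GCC", 50), "TAA",
                       paste(rep("C", 30), collapse = "")))
  a1 <- assess_nmd(tx("se", 1, nchar(g[[1]])), g)
  expect_false(a1$is_nmd_candidate)
  # no ORF at all: flags false, orf absent
  g2 <- c(chr1 = strrep("C", 200))
  a2 <- assess_nmd(tx("no", c(1, 101), c(80, 200)), g2)
  expect_null(a2$orf)
  expect_false(a2$is_ptc)
})

test_that("generator-planted NMD flags are recovered exactly", {
  ds <- simulate_dataset(small_spec(), coverage = FALSE)
  pn <- ds$truth$planted_nmd
  expect_gte(nrow(pn), 5L)
  for (i in seq_len(nrow(pn))) {
    t <- ds$loci[[pn$gene_id[i]]]$transcripts[[pn$transcript_id[i]]]
    a <- assess_nmd(t, ds$genome)
    expect_equal(a$stop_to_junction_nt, pn$distance_nt[i])
    expect_equal(a$is_nmd_candidate, pn$expected_candidate_flag[i])
  }
})

test_that("retained-intron stop scan agrees with a brute-force codon walk", {
  set.seed(404)
  any_stop <- FALSE; any_clean <- FALSE
  for (r in 1:40) {
    f <- make_ri_case(c(60L, 99L, 150L)[1L + r %% 3L])
    res <- intron_stop_scan(f$event, f$retaining, f$genome)
    expect_false(res$not_applicable)
    seq <- spliced_sequence(f$retaining, f$genome)
    orf <- find_orf(seq)
    want <- codon_walk_has_stop(seq, orf$start_pos, f$event$start, f$event$end)
    expect_equal(res$contains_inframe_stop, want)
    expect_equal(res$frame_preserved,
                 (f$event$end - f$event$start + 1L) %% 3L == 0L)
    if (want) any_stop <- TRUE else any_clean <- TRUE
  }
  expect_true(any_stop)
})

test_that("stop scan handles engineered stop-free and stop-bearing introns", {
  set.seed(405)
  # intron of 99 Gs: frame preserved, no stop
  f <- make_ri_case(99L)
  f$genome <- c(chr1 = paste0(substr(f$genome[[1]], 1, 900), strrep("G", 99),
                              substr(f$genome[[1]], 1000, nchar(f$genome[[1]]))))
  res <- intron_stop_scan(f$event, f$retaining, f$genome)
  expect_false(res$contains_inframe_stop)
  expect_true(res$frame_preserved)
  # planted in-frame TAA
  g2 <- c(chr1 = paste0(substr(f$genome[[1]], 1, 900), strrep("G", 48), "TAA",
                        strrep("G", 48),
                        substr(f$genome[[1]], 1000, nchar(f$genome[[1]]))))
  res2 <- intron_stop_scan(f$event, f$retaining, g2)
  expect_true(res2$contains_inframe_stop)
  # non-RI events are rejected
  bad <- f$event; bad$category6 <- "AA"
  expect_error(intron_stop_scan(bad, f$retaining, f$genome), "RI_SI")
})
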