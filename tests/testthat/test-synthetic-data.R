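test_that("every artifact is byte-identical across runs with the same seed", {
  s <- small_spec(seed = 303L)
  g1 <- simulate_genome(s)
  g2 <- simulate_genome(s)
  expect_identical(as.character(g1), as.character(g2))
  d1 <- simulate_dataset(s, coverage = TRUE)
  d2 <- simulate_dataset(s, coverage = TRUE)
  expect_identical(as.character(d1$genome), as.character(d2$genome))
  expect_identical(d1$abundance, d2$abundance)
  expect_identical(d1$truth, d2$truth)
  expect_identical(unclass(d1$coverage), unclass(d2$coverage))
})

test_that("the genome is large enough to host all genes with spacing", {
  s <- simulation_spec(seed = 1, n_genes = 50L,
                       events_per_class = c(RI_SI = 0L),
                       n_low_abundance_isoforms = 0L, n_ptc_isoforms = 0L)
  g <- simulate_genome(s)
  expect_gte(sum(Biostrings::width(g)), 50 * 3500)
  expect_silent(simulate_gene_models(s, g))
})

test_that("raw genome base composition is uniform", {
  s <- simulation_spec(seed = 5, n_genes = 90L, n_chrom = 1L,
                       events_per_class = c(RI_SI = 0L),
                       n_low_abundance_isoforms = 0L, n_ptc_isoforms = 0L)
  g <- simulate_genome(s)
  expect_gte(sum(Biostrings::width(g)), 1e6)
  counts <- colSums(Biostrings::alphabetFrequency(g)[, c("A", "C", "G", "T"),
                                                     drop = FALSE])
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("emitted gene models respect intron bounds, splice motifs and ORF design", {
  ds <- simulate_dataset(small_spec(seed = 77L), coverage = FALSE)
  g <- ds$genome
  for (l in ds$loci) {
    for (t in l$transcripts) {
      d <- derive_introns(t)
      if (nrow(d) == 0L) next
      lens <- d$end - d$start + 1L
      if (t$transcript_id == paste0(l$gene_id, ".t1"))
        expect_true(all(lens >= 60 & lens <= 6000))
      # canonical GT..AG on the mRNA strand at every intron
      chr <- g[[t$chrom]]
      don <- vapply(seq_len(nrow(d)), function(i) {
        s <- as.character(Biostrings::subseq(chr, d$start[i], d$start[i] + 1L))
        e <- as.character(Biostrings::subseq(chr, d$end[i] - 1L, d$end[i]))
        if (t$strand == "+") paste0(s, "|", e) else
          paste0(revcomp(e), "|", revcomp(s))
      }, "")
      expect_true(all(don == "GT|AG"))
    }
    # reference isoform: ORF found; unless the gene hosts a planted PTC,
    # the ORF spans >= 60% of the mRNA and terminates in the last exon
    ref <- l$transcripts[[paste0(l$gene_id, ".t1")]]
    orf <- find_orf(spliced_sequence(ref, g))
    expect_false(is.null(orf))
    if (!ref$transcript_id %in% ds$truth$planted_nmd$transcript_id) {
      expect_gte(orf$length_nt, 0.6 * spliced_length(ref))
      a <- assess_nmd(ref, g)
      expect_false(a$is_nmd_candidate)
      expect_false(a$is_ptc)
    }
  }
})

test_that("intron lengths follow the log-uniform target distribution", {
  s <- simulation_spec(seed = 9L, n_genes = 600L,
                       events_per_class = c(RI_SI = 0L),
                       n_low_abundance_isoforms = 0L, n_ptc_isoforms = 0L)
  ds <- simulate_dataset(s, coverage = FALSE)
  lens <- all_intron_sizes(ds$loci)$lengths
  expect_gte(length(lens), 2000L)
  u <- (log(lens) - log(60)) / (log(6000) - log(60))
  d_stat <- max(abs(sort(u) - seq_along(u) / length(u)))
  expect_lt(d_stat, 0.05)
})

test_that("planting zero events leaves loci unchanged and bookkeeping is exact", {
  s0 <- simulation_spec(seed = 21L, n_genes = 30L,
                        events_per_class = c(RI_SI = 0L),
                        n_low_abundance_isoforms = 0L, n_ptc_isoforms = 0L)
  g <- simulate_genome(s0)
  m <- simulate_gene_models(s0, g)
  pl <- plant_as_isoforms(m$loci, m$genome, s0)
  expect_identical(pl$loci, m$loci)
  expect_equal(nrow(pl$planted_events), 0L)
  ds <- simulate_dataset(small_spec(), coverage = FALSE)
  expect_equal(nrow(ds$truth$planted_events), 18L)
  expect_equal(unname(table(ds$truth$planted_events$category6)[c(
    "AA", "AD", "ATE", "RI_SI", "SE_RE", "IWI_TWI")]),
    rep(3L, 6), ignore_attr = TRUE)
  expect_error(
    simulate_dataset(simulation_spec(seed = 1, n_genes = 4L,
                                     events_per_class = c(AA = 50L)),
                     coverage = FALSE),
    "shortfall")
})

test_that("planted low-abundance bookkeeping records one failing criterion each", {
  ds <- simulate_dataset(small_spec(), coverage = FALSE)
  low <- ds$truth$planted_low_abundance
  expect_equal(nrow(low), 6L)
  ab <- ds$abundance
  totals <- locus_totals(ab, ds$loci)
  for (i in seq_len(nrow(low))) {
    t <- low$transcript_id[i]
    gene <- all_transcripts(ds$loci)[[t]]$gene_id
    v <- ab$fpkm[ab$transcript_id == t]
    frac <- v / totals[[gene]]
    expect_equal(low$criterion[i],
                 if (v < 1 && frac < 0.03) "both_fail"
                 else if (v < 1) "fpkm_fail" else "fraction_fail")
  }
})

test_that("simulated coverage conserves fragment mass and respects abundance", {
  # single 1 kb single-exon transcript: flat interior depth at the analytic
  # expectation n_fragments * fragment_len / n_start_positions
  t1 <- tx("s1", 1, 1000, gene = "gs")
  t0 <- tx("s0", 2001, 3000, gene = "gz")
  loci <- list(gs = locus_of(t1), gz = locus_of(t0))
  ab <- data.frame(transcript_id = c("s1", "s0"), fpkm = c(10, 0),
                   stringsAsFactors = FALSE)
  s <- simulation_spec(seed = 3L, n_genes = 2L, n_fragments = 1000L,
                       events_per_class = c(RI_SI = 0L),
                       n_low_abundance_isoforms = 0L, n_ptc_isoforms = 0L)
  cov <- simulate_coverage(loci, ab, s, c(chr1 = 4000L))
  expect_equal(sum(cov$chr1), 1000 * 101)
  expect_true(all(cov$chr1[2001:3000] == 0))
  interior <- cov$chr1[101:900]
  expected <- 1000 * 101 / (1000 - 101 + 1)
  expect_lt(abs(mean(interior) - expected) / expected, 0.05)
  expect_lt(abs(mean(interior) - 101) / 101, 0.2)
})
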