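test_that("retained introns are detected with the intron as affected interval", {
  a <- tx("a", c(1, 201), c(100, 300))
  b <- tx("b", 1, 300)
  ev <- classify_pair(a, b)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$category6, "RI_SI")
  expect_equal(c(ev$start, ev$end), c(101L, 200L))
  expect_equal(ev$isoform_a, "b") # the retaining isoform
})

test_that("skipped internal exons are detected with the exon as affected interval", {
  a <- tx("a", c(1, 201, 401), c(100, 300, 500))
  b <- tx("b", c(1, 401), c(100, 500))
  ev <- classify_pair(a, b)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$category6, "SE_RE")
  expect_equal(c(ev$start, ev$end), c(201L, 300L))
  expect_equal(ev$isoform_a, "a") # the exon-retaining isoform
})

test_that("donor/acceptor assignment is strand-aware", {
  # shared boundary at 101, alternate boundary at 200 vs 250
  a_p <- tx("a", c(1, 201), c(100, 330), strand = "+")
  b_p <- tx("b", c(1, 251), c(100, 330), strand = "+")
  ev <- classify_pair(a_p, b_p)
  expect_equal(ev$category6, "AA") # + strand: intron start is the donor
  expect_equal(c(ev$start, ev$end), c(200L, 250L))
  a_m <- tx("a", c(1, 201), c(100, 330), strand = "-")
  b_m <- tx("b", c(1, 251), c(100, 330), strand = "-")
  ev_m <- classify_pair(a_m, b_m)
  expect_equal(ev_m$category6, "AD") # same structure read on - strand
})

test_that("UTR-only terminal length differences produce no event", {
  a <- tx("a", c(1, 201), c(100, 300))
  b <- tx("b", c(21, 201), c(100, 350))
  expect_equal(nrow(classify_pair(a, b)), 0L)
})

test_that("intron pairs differing at both ends fall into the complex bucket", {
  a <- tx("a", c(1, 201), c(100, 330))
  b <- tx("b", c(1, 251), c(110, 330))
  ev <- classify_pair(a, b)
  expect_equal(ev$category6, "complex")
  loci <- list(g = locus_of(a, b))
  cls <- classify_transcriptome(loci)
  expect_equal(nrow(cls$events), 0L)
  expect_equal(nrow(cls$complex_events), 1L)
})

test_that("classification rejects mismatched inputs", {
  a <- tx("a", 1, 100)
  b <- tx("b", 1, 100, strand = "-")
  expect_error(classify_pair(a, b), "strand")
  b2 <- tx("b", 1, 100, gene = "other")
  expect_error(classify_pair(a, b2), "gene")
})

test_that("the nine-to-six merge map is total and surjective", {
  nine <- c("AA", "AD", "ATE", "SE", "RE", "IWI", "TWI", "RI", "SI")
  six <- merge_category(nine)
  expect_setequal(unique(six), c("AA", "AD", "ATE", "SE_RE", "IWI_TWI", "RI_SI"))
  expect_equal(merge_category(c("RI", "SI")), c("RI_SI", "RI_SI"))
  expect_error(merge_category("XX"), "unknown")
})

test_that("pair classification is reciprocal and transcriptome output is order-invariant", {
  ds <- simulate_dataset(small_spec(seed = 55L), coverage = FALSE)
  multi <- Filter(function(l) length(l$transcripts) == 2L, ds$loci)
  for (l in multi) {
    e1 <- classify_pair(l$transcripts[[1]], l$transcripts[[2]])
    e2 <- classify_pair(l$transcripts[[2]], l$transcripts[[1]])
    rownames(e1) <- rownames(e2) <- NULL
    expect_identical(e1[order(e1$start), ], e2[order(e2$start), ])
  }
  cls <- classify_transcriptome(ds$loci)
  shuffled <- lapply(ds$loci, function(l) {
    l$transcripts <- rev(l$transcripts)
    l
  })
  cls2 <- classify_transcriptome(shuffled[rev(names(shuffled))])
  expect_identical(cls$events, cls2$events)
})

test_that("events match an independent predicate enumeration on small isoform pairs", {
  # brute-force checker coded from the category definitions, evaluated
  # predicate by predicate on interval arithmetic
  oracle6 <- function(a, b) {
    ia <- derive_introns(a); ib <- derive_introns(b)
    out <- character(0)
    contains <- function(s1, e1, s2, e2) s1 <= s2 & e1 >= e2
    for (d in list(list(r = a, s = b, ri = ia, si = ib),
                   list(r = b, s = a, ri = ib, si = ia))) {
      if (nrow(d$si)) for (i in seq_len(nrow(d$si)))
        if (any(d$r$exon_start < d$si$start[i] & d$r$exon_end > d$si$end[i]) &&
            !any(d$ri$start == d$si$start[i] & d$ri$end == d$si$end[i]))
          out <- c(out, "RI_SI")
      n <- n_exons(d$r)
      if (n >= 3L && nrow(d$si)) for (k in 2:(n - 1L))
        if (any(contains(d$si$start, d$si$end,
                         d$r$exon_start[k], d$r$exon_end[k])))
          out <- c(out, "SE_RE")
    }
    # alternate splice sites: one shared intron boundary, flanking exons of
    # the differing boundary overlapping the other isoform, and neither
    # intron explained by retention/skipping/termini
    explained <- function(d, i) {
      # consumed by RI (intron inside an exon of the other) or by SE
      # (intron holding an internal exon of the other) or terminal introns
      other <- if (identical(d, a)) b else a
      s <- derive_introns(d)$start[i]; e <- derive_introns(d)$end[i]
      if (any(other$exon_start < s & other$exon_end > e)) return(TRUE)
      n_o <- n_exons(other)
      if (n_o >= 3L &&
          any(s <= other$exon_start[2:(n_o - 1L)] &
              e >= other$exon_end[2:(n_o - 1L)])) return(TRUE)
      FALSE
    }
    if (nrow(ia) && nrow(ib)) {
      plus <- a$strand == "+"
      for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
        sA <- ia$start[i]; eA <- ia$end[i]; sB <- ib$start[j]; eB <- ib$end[j]
        if (sA == sB && eA == eB) next
        if (explained(a, i) || explained(b, j)) next
        ovl <- function(xs, xe, t) any(t$exon_start <= xe & t$exon_end >= xs)
        if (sA == sB && eA != eB) {
          fa <- i + 1L; fb <- j + 1L
          if (ovl(a$exon_start[fa], a$exon_end[fa], b) &&
              ovl(b$exon_start[fb], b$exon_end[fb], a))
            out <- c(out, if (plus) "AA" else "AD")
        } else if (eA == eB && sA != sB) {
          fa <- i; fb <- j
          if (ovl(a$exon_start[fa], a$exon_end[fa], b) &&
              ovl(b$exon_start[fb], b$exon_end[fb], a))
            out <- c(out, if (plus) "AD" else "AA")
        }
      }
    }
    # termini: truncation into an intron vs displaced terminal exons
    for (side in c("l", "r")) {
      bnd <- function(t) if (side == "r") max(t$exon_end) else min(t$exon_start)
      if (bnd(a) == bnd(b)) next
      inner <- if ((side == "r") == (bnd(a) < bnd(b))) a else b
      outer_ <- if (identical(inner, a)) b else a
      ty <- bnd(inner)
      io <- derive_introns(outer_)
      in_exon <- any(outer_$exon_start <= ty & outer_$exon_end >= ty)
      k <- if (side == "r") n_exons(inner) else 1L
      eyS <- inner$exon_start[k]; eyE <- inner$exon_end[k]
      ey_overlaps <- any(outer_$exon_start <= eyE & outer_$exon_end >= eyS)
      ko <- if (side == "r") n_exons(outer_) else 1L
      exS <- outer_$exon_start[ko]; exE <- outer_$exon_end[ko]
      ex_overlaps <- any(inner$exon_start <= exE & inner$exon_end >= exS)
      if (in_exon) next
      if (nrow(io) && any(io$start < ty & io$end > ty) && ey_overlaps)
        out <- c(out, "IWI_TWI")
      else if (!ey_overlaps && !ex_overlaps)
        out <- c(out, "ATE")
    }
    out
  }
  ds <- simulate_dataset(
    simulation_spec(seed = 71L, n_genes = 80L, exons_per_gene = c(3L, 3L),
                    events_per_class = c(AA = 6L, AD = 6L, ATE = 6L,
                                         RI_SI = 6L, SE_RE = 6L, IWI_TWI = 6L),
                    n_low_abundance_isoforms = 0L, n_ptc_isoforms = 0L),
    coverage = FALSE)
  checked <- 0L
  for (l in Filter(function(l) length(l$transcripts) == 2L, ds$loci)) {
    got <- classify_pair(l$transcripts[[1]], l$transcripts[[2]])
    want <- oracle6(l$transcripts[[1]], l$transcripts[[2]])
    expect_equal(sort(got$category6[got$category6 != "complex"]), sort(want),
                 info = l$gene_id)
    checked <- checked + 1L
  }
  expect_gte(checked, 30L)
})

test_that("AS rate follows the gene-ratio definition", {
  t1 <- tx("t1", c(1, 201), c(100, 300), gene = "g1")
  t2 <- tx("t2", 1, 300, gene = "g1")
  u1 <- tx("u1", c(401, 601), c(500, 700), gene = "g2")
  loci <- list(g1 = locus_of(t1, t2), g2 = locus_of(u1))
  cls <- classify_transcriptome(loci)
  expect_equal(cls$summary$n_intron_containing_genes, 2L)
  expect_equal(cls$summary$n_as_genes, 1L)
  expect_equal(cls$summary$as_rate, 50)
  # single-isoform transcriptome: zero events, rate 0
  cls1 <- classify_transcriptome(loci["g2"])
  expect_equal(cls1$summary$n_events, 0L)
  expect_equal(cls1$summary$as_rate, 0)
  # no intron-containing genes: rate undefined
  v1 <- tx("v1", 1, 300, gene = "g3")
  cls0 <- classify_transcriptome(list(g3 = locus_of(v1)))
  expect_true(is.na(cls0$summary$as_rate))
  # formula check at the published scale: 2090 AS genes of 11967
  expect_equal(round(100 * 2090 / 11967, 1), 17.5)
})
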