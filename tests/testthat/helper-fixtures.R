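# Shared fixture builders and independent oracles. Oracles are coded from
# first principles (direct formula evaluation, exhaustive enumeration,
# brute-force codon walks) and never call the implementation they check.

tx <- function(id, starts, ends, strand = "+", gene = "g", chrom = "chr1",
               cds = NULL) {
  transcript_model(id, gene, chrom, strand, starts, ends, cds_span = cds)
}

locus_of <- function(...) {
  tl <- list(...)
  gene_locus(tl[[1L]]$gene_id, tl)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

filler_seq <- function(n) paste(sample(c("C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# independent likelihood-ratio evaluation for the G statistic
g_oracle <- function(m) {
  n <- sum(m)
  g <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    o <- m[i, j]
    if (o > 0) g <- g + o * log(o / (sum(m[i, ]) * sum(m[, j]) / n))
  }
  2 * g
}

# exhaustive permutation two-sided p-value for the Mann-Whitney U statistic
# (tie-free inputs)
u_stat <- function(x, y) sum(outer(x, y, ">"))
mww_perm_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2L, function(i) u_stat(pool[i], pool[-i]))
  u <- u_stat(x, y)
  min(1, 2 * min(mean(us <= u), mean(us >= u)))
}

# a transcript retaining an intron of length L (a multiple of 3, inserted at
# a codon boundary of a long host ORF), its spliced reference, and the RI
# event row — the scaffold for retained-intron stop-codon analyses
make_ri_case <- function(L) {
  ex1 <- paste0("ATG", filler_seq(897))                  # 900 nt, ORF from 1
  ex2 <- paste0(filler_seq(99), "TAA", filler_seq(30))   # 132 nt
  intron <- rand_seq(L)
  chrseq <- paste0(ex1, intron, ex2)
  genome <- c(chr1 = chrseq)
  ref <- tx("t.ref", c(1L, 901L + L), c(900L, 900L + L + 132L))
  ret <- tx("t.ret", 1L, 900L + L + 132L)
  event <- data.frame(gene_id = "g", category9 = "RI", category6 = "RI_SI",
                      chrom = "chr1", start = 901L, end = 900L + L,
                      isoform_a = "t.ret", isoform_b = "t.ref",
                      stringsAsFactors = FALSE)
  list(event = event, retaining = ret, reference = ref, genome = genome,
       intron_seq = intron)
}

# independent brute-force codon walk: does any stop codon sit wholly inside
# [i_start, i_end] of seq, walking in frame from orf_start?
codon_walk_has_stop <- function(seq, orf_start, i_start, i_end) {
  q <- orf_start
  while (q + 2L <= nchar(seq)) {
    if (q >= i_start && q + 2L <= i_end &&
        substr(seq, q, q + 2L) %in% c("TAA", "TAG", "TGA"))
      return(TRUE)
    q <- q + 3L
  }
  FALSE
}

# two-exon plus-strand transcript whose ORF stop starts exactly d nt
# upstream of the last exon-exon junction (d may be negative: stop in the
# last exon)
make_ptc_tx <- function(d) {
  L <- 720L; j <- 600L; intron_len <- 80L
  p <- j - d
  a <- 1L + ((p - 1L) %% 3L)
  spl <- strsplit(filler_seq(L), "")[[1L]]
  spl[a:(a + 2L)] <- c("A", "T", "G")
  spl[p:(p + 2L)] <- c("T", "A", "A")
  spl <- paste(spl, collapse = "")
  chrseq <- paste0(substr(spl, 1L, j), rand_seq(intron_len),
                   substr(spl, j + 1L, L))
  t <- tx("t.ptc", c(1L, j + intron_len + 1L), c(j, j + intron_len + L - j))
  list(t = t, genome = c(chr1 = chrseq))
}

# small seed-pinned synthetic dataset shared across tests
small_spec <- function(seed = 101L, ...) {
  simulation_spec(seed = seed, n_genes = 60L,
                  events_per_class = c(AA = 3L, AD = 3L, ATE = 3L,
                                       RI_SI = 3L, SE_RE = 3L, IWI_TWI = 3L),
                  n_low_abundance_isoforms = 6L, n_fragments = 40000L, ...)
}
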