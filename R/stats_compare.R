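#' Likelihood-ratio G-test of independence
#'
#' `G = 2 * sum(O * ln(O / E))` with expectations
#' `E = row_total * col_total / grand_total`; zero cells contribute 0. The
#' p-value comes from the chi-square upper tail with
#' `(rows - 1) * (cols - 1)` degrees of freedom. No Williams or continuity
#' correction is applied (set `williams = TRUE` for the Williams-corrected
#' variant).
#'
#' @param counts Numeric matrix or table of non-negative counts, at least
#'   2 x 2. A zero row or column total is an error (the expectation is
#'   undefined).
#' @param williams Apply the Williams correction to G.
#' @return List of class `g_test` with `G`, `df`, `p_value`.
#' @export
g_test <- function(counts, williams = FALSE) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("g_test needs at least a 2x2 table")
  if (any(m < 0)) stop("g_test: negative counts")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0))
    stop("g_test: zero row or column total (expected counts undefined)")
  E <- outer(rs, cs) / n
  term <- ifelse(m > 0, m * log(m / E), 0)
  G <- 2 * sum(term)
  if (williams) {
    q <- 1 + (n * sum(1 / rs) - 1) * (n * sum(1 / cs) - 1) /
      (6 * n * (nrow(m) - 1) * (ncol(m) - 1))
    G <- G / q
  }
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(list(G = G, df = df,
                 p_value = stats::pchisq(G, df, lower.tail = FALSE)),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test: G = %.4g, df = %d, p = %.4g\n", x$G, x$df, x$p_value))
  invisible(x)
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Wraps the standard rank-sum machinery with a fixed method-selection rule:
#' exact enumeration of the U distribution when `n1 * n2 <= 400` and the
#' pooled sample is tie-free, otherwise the normal approximation with
#' midranks, tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List of class `rank_test` with `U` (the Mann-Whitney statistic
#'   for `x` vs `y`), `p_value`, and `method` (`"exact_enumeration"` or
#'   `"normal_approx"`).
#' @export
mww_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("mww_test: empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400L) && !ties
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  structure(list(U = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact_enumeration" else "normal_approx"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney-Wilcoxon: U = %.1f, p = %.4g (%s)\n",
              x$U, x$p_value, x$method))
  invisible(x)
}

.exon_ranges <- function(t) IRanges::IRanges(t$exon_start, t$exon_end)

# structural identity and contiguous coverage of one (assembled, reference)
# transcript pair; both genome-anchored, so identity is computed on shared
# genomic bases rather than by sequence alignment
.pair_match_stats <- function(ta, tr) {
  ra <- .exon_ranges(ta); rr <- .exon_ranges(tr)
  shared <- IRanges::intersect(ra, rr)
  span_r <- IRanges::IRanges(min(tr$exon_start), max(tr$exon_end))
  denom <- sum(IRanges::width(IRanges::intersect(ra, span_r)))
  identity <- if (denom > 0) sum(IRanges::width(shared)) / denom else 0
  coverage <- 0
  if (length(shared) > 0L) {
    # project covered reference-exon segments into reference mRNA coordinates
    ts <- genomic_to_transcript(tr, IRanges::start(shared))
    te <- genomic_to_transcript(tr, IRanges::end(shared))
    seg <- IRanges::reduce(IRanges::IRanges(pmin(ts, te), pmax(ts, te)))
    coverage <- max(IRanges::width(seg)) / spliced_length(tr)
  }
  c(coverage = coverage, identity = identity)
}

#' Match assembled gene models to a reference annotation
#'
#' A gene of the assembled set matches the reference when at least one of its
#' isoforms resembles some reference isoform of an overlapping locus:
#' contiguous coverage of at least `config$match_coverage` of the reference
#' mRNA length and structural identity of at least `config$match_identity`
#' (shared exonic genomic bases over the assembled exonic bases that fall in
#' the reference locus span).
#'
#' @param assembled,reference Named lists of `gene_locus` objects on the
#'   same genome.
#' @param config An [analysis_config()].
#' @return List with `per_gene` (data.frame: `gene_id`, `matched`) and
#'   `fraction` (of assembled genes matching).
#' @export
match_to_annotation <- function(assembled, reference,
                                config = analysis_config()) {
  ref_chrom <- vapply(reference, `[[`, "", "chrom")
  ref_start <- vapply(reference, function(l) l$span[1L], 1L)
  ref_end <- vapply(reference, function(l) l$span[2L], 1L)
  matched <- vapply(assembled, function(la) {
    hits <- which(ref_chrom == la$chrom & ref_start <= la$span[2L] &
                    ref_end >= la$span[1L])
    for (h in hits) {
      lr <- reference[[h]]
      for (ta in la$transcripts) for (tr in lr$transcripts) {
        if (ta$strand != tr$strand) next
        st <- .pair_match_stats(ta, tr)
        if (st[["coverage"]] >= config$match_coverage &&
            st[["identity"]] >= config$match_identity)
          return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  list(per_gene = data.frame(gene_id = names(assembled),
                             matched = unname(matched),
                             stringsAsFactors = FALSE),
       fraction = if (length(matched)) mean(matched) else NA_real_)
}

# full single-sample pipeline: filter -> classify -> NMD -> intron metrics
.analyze_sample <- function(s, config) {
  fl <- filter_isoforms(s$abundance, s$loci, config)
  kept_loci <- subset_loci(s$loci, fl$kept)
  cls <- classify_transcriptome(kept_loci)
  nmd <- assess_nmd_all(kept_loci, s$genome, config)
  as_genes <- names(kept_loci)[vapply(kept_loci, function(l)
    length(l$transcripts) >= 2L, TRUE)]
  nmd_as <- nmd[nmd$gene_id %in% as_genes, , drop = FALSE]
  ri <- cls$events[cls$events$category6 == "RI_SI", , drop = FALSE]
  scans <- lapply(seq_len(nrow(ri)), function(i) {
    ret <- kept_loci[[ri$gene_id[i]]]$transcripts[[ri$isoform_a[i]]]
    intron_stop_scan(ri[i, ], ret, s$genome)
  })
  applicable <- vapply(scans, function(x) !x$not_applicable, TRUE)
  with_stop <- vapply(scans, function(x) isTRUE(x$contains_inframe_stop), TRUE)
  list(filter_report = fl$report, kept = fl$kept, events = cls$events,
       complex_events = cls$complex_events, summary = cls$summary,
       nmd = nmd,
       nmd_candidate_pct = if (nrow(nmd_as) > 0)
         100 * mean(nmd_as$is_nmd_candidate) else NA_real_,
       intron_stop = list(n_scanned = sum(applicable),
                          n_with_stop = sum(with_stop[applicable]),
                          pct = if (sum(applicable) > 0)
                            100 * sum(with_stop[applicable]) / sum(applicable)
                          else NA_real_),
       retained_introns = retained_intron_sizes(ri),
       all_introns = all_intron_sizes(kept_loci)$stats)
}

#' Compare two samples end to end
#'
#' Runs the full per-sample pipeline (low-abundance filter, AS
#' classification, NMD assessment, retained-intron stop scan, intron size
#' statistics) on both inputs, then builds the 2 x 6 category count table
#' with its G-test (plus the 2 x 2 retained-intron-vs-rest G-test, since the
#' headline contrast concerns intron retention) and the
#' Mann-Whitney-Wilcoxon test on retained-intron sizes. Category columns
#' with zero counts in both samples are dropped before the G-test (their
#' expectations are undefined).
#'
#' @param sample_a,sample_b Lists with elements `loci`, `abundance`,
#'   `genome` (and optionally `name`).
#' @param config An [analysis_config()].
#' @return List of class `comparison_report` with per-sample results (`a`,
#'   `b`), `category_table`, `g_category` (2 x 6), `g_ri_vs_rest` (2 x 2),
#'   and `mww_retained_size`.
#' @export
compare_samples <- function(sample_a, sample_b, config = analysis_config()) {
  name_a <- if (!is.null(sample_a$name)) sample_a$name else "sample_a"
  name_b <- if (!is.null(sample_b$name)) sample_b$name else "sample_b"
  A <- .analyze_sample(sample_a, config)
  B <- .analyze_sample(sample_b, config)
  tab <- rbind(A$summary$per_category6$count, B$summary$per_category6$count)
  dimnames(tab) <- list(c(name_a, name_b), .AS_CATEGORIES6)
  nz <- colSums(tab) > 0
  g_cat <- if (sum(nz) >= 2L) g_test(tab[, nz, drop = FALSE]) else NULL
  ri <- tab[, "RI_SI"]
  rest <- rowSums(tab) - ri
  tab22 <- cbind(RI_SI = ri, rest = rest)
  g_ri <- if (all(colSums(tab22) > 0) && all(rowSums(tab22) > 0))
    g_test(tab22) else NULL
  mww <- if (A$retained_introns$stats$n > 0 && B$retained_introns$stats$n > 0)
    mww_test(A$retained_introns$lengths, B$retained_introns$lengths) else NULL
  structure(list(a = A, b = B, names = c(name_a, name_b),
                 category_table = tab, g_category = g_cat,
                 g_ri_vs_rest = g_ri, mww_retained_size = mww,
                 config = config),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Two-sample alternative-splicing comparison\n")
  cat("Category counts:\n")
  print(x$category_table)
  for (i in 1:2) {
    s <- if (i == 1) x$a else x$b
    cat(sprintf(
      "%s: %d/%d isoforms kept (%.1f%% dropped); %d events; AS rate %.1f%%; NMD candidates %.1f%%; retained introns with stop %.1f%%\n",
      x$names[i], s$filter_report$n_kept, s$filter_report$n_input,
      s$filter_report$pct_dropped, s$summary$n_events, s$summary$as_rate,
      s$nmd_candidate_pct, s$intron_stop$pct))
  }
  if (!is.null(x$g_category)) {
    cat("2x6 category G-test: "); print(x$g_category)
  }
  if (!is.null(x$g_ri_vs_rest)) {
    cat("RI/SI vs rest G-test: "); print(x$g_ri_vs_rest)
  }
  if (!is.null(x$mww_retained_size)) {
    cat("Retained-intron sizes: "); print(x$mww_retained_size)
  }
  invisible(x)
}
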