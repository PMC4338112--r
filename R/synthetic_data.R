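#' Specification of a synthetic transcriptome simulation
#'
#' The generator emulates the structure of the study data: multi-exon gene
#' models with introns in the admissible 60-6000 nt range (drawn log-uniform
#' so that both the sub-200-nt mass and long introns are exercised), planted
#' alternative isoforms of each of the six merged AS categories, a
#' subpopulation of low-abundance isoforms that violate exactly one recorded
#' filter criterion, PTC-bearing isoforms at controlled stop-to-junction
#' distances, log-normal expression and uniform 101-nt fragment coverage.
#' Every artifact is fully deterministic under `seed`.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_genes Number of gene loci.
#' @param n_chrom Number of chromosomes the genes are spread over.
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param exon_len_nt Integer range of exon lengths.
#' @param intron_len_nt Integer range of intron lengths (log-uniform draw).
#' @param events_per_class Named integer vector over
#'   `{AA, AD, ATE, RI_SI, SE_RE, IWI_TWI}`: alternative isoforms to plant,
#'   one structural edit each.
#' @param n_low_abundance_isoforms Number of planted alternative isoforms
#'   assigned abundances that fail the filter (criteria cycle through
#'   fpkm-only, fraction-only, both).
#' @param ptc_distances_nt Stop-to-last-junction distances (nt) for planted
#'   PTC transcripts.
#' @param n_ptc_isoforms Number of PTC transcripts (distances recycled).
#' @param expression_meanlog,expression_sdlog Log-normal FPKM parameters.
#' @param fragment_len_nt Fragment length for coverage simulation (101 nt,
#'   the read length of the emulated libraries).
#' @param n_fragments Total fragments for coverage simulation.
#' @param intergenic_nt Minimum intergenic spacing.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, n_genes = 300L, n_chrom = 2L,
                            exons_per_gene = c(3L, 7L),
                            exon_len_nt = c(90L, 300L),
                            intron_len_nt = c(60L, 6000L),
                            events_per_class = c(AA = 10L, AD = 10L, ATE = 10L,
                                                 RI_SI = 10L, SE_RE = 10L,
                                                 IWI_TWI = 10L),
                            n_low_abundance_isoforms = 25L,
                            ptc_distances_nt = c(10L, 54L, 55L, 56L, 200L),
                            n_ptc_isoforms = length(ptc_distances_nt),
                            expression_meanlog = 3, expression_sdlog = 1,
                            fragment_len_nt = 101L, n_fragments = 200000L,
                            intergenic_nt = 500L) {
  ev <- stats::setNames(rep(0L, length(.AS_CATEGORIES6)), .AS_CATEGORIES6)
  if (length(events_per_class)) {
    if (is.null(names(events_per_class)) ||
        !all(names(events_per_class) %in% .AS_CATEGORIES6))
      stop("events_per_class must be named with categories among: ",
           paste(.AS_CATEGORIES6, collapse = ", "))
    ev[names(events_per_class)] <- as.integer(events_per_class)
  }
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_chrom = as.integer(n_chrom),
               exons_per_gene = as.integer(exons_per_gene),
               exon_len_nt = as.integer(exon_len_nt),
               intron_len_nt = as.integer(intron_len_nt),
               events_per_class = ev,
               n_low_abundance_isoforms = as.integer(n_low_abundance_isoforms),
               ptc_distances_nt = as.integer(ptc_distances_nt),
               n_ptc_isoforms = as.integer(n_ptc_isoforms),
               expression_meanlog = expression_meanlog,
               expression_sdlog = expression_sdlog,
               fragment_len_nt = as.integer(fragment_len_nt),
               n_fragments = as.integer(n_fragments),
               intergenic_nt = as.integer(intergenic_nt))
  stopifnot(spec$n_genes >= 1L, spec$n_chrom >= 1L,
            length(spec$exons_per_gene) == 2L,
            spec$exons_per_gene[1L] >= 2L,
            spec$exons_per_gene[1L] <= spec$exons_per_gene[2L],
            spec$exon_len_nt[1L] >= 30L,
            spec$exon_len_nt[1L] <= spec$exon_len_nt[2L],
            spec$intron_len_nt[1L] >= 4L,
            spec$intron_len_nt[1L] <= spec$intron_len_nt[2L],
            all(spec$events_per_class >= 0L),
            spec$n_low_abundance_isoforms >= 0L, spec$n_ptc_isoforms >= 0L,
            spec$fragment_len_nt >= 1L, spec$n_fragments >= 0L,
            spec$intergenic_nt >= 300L)
  structure(spec, class = "simulation_spec")
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.dss_to_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
}

.chars_to_dss <- function(chars) {
  Biostrings::DNAStringSet(vapply(chars, paste0, "", collapse = ""))
}

.mean_intron_len <- function(rng) {
  a <- rng[1L]; b <- rng[2L]
  if (a == b) a else (b - a) / log(b / a)
}

# genome editor: chromosome letter vectors plus a queue of pending edits.
# Edits are batched and applied once per chromosome (a naive subassignment
# per gene would copy the multi-megabase vector every time); within the
# queue, later edits override earlier ones at the same position.
.new_gen <- function(chars) {
  gen <- new.env(parent = emptyenv())
  gen$chars <- chars
  gen$qi <- stats::setNames(vector("list", length(chars)), names(chars))
  gen$qv <- gen$qi
  gen
}

.queue_write <- function(gen, chrom, idx, val) {
  k <- length(gen$qi[[chrom]]) + 1L
  gen$qi[[chrom]][[k]] <- as.integer(idx)
  gen$qv[[chrom]][[k]] <- val
  invisible(NULL)
}

.apply_queue <- function(gen) {
  for (cn in names(gen$chars)) {
    if (length(gen$qi[[cn]]) == 0L) next
    gen$chars[[cn]][unlist(gen$qi[[cn]], use.names = FALSE)] <-
      unlist(gen$qv[[cn]], use.names = FALSE)
    gen$qi[[cn]] <- list()
    gen$qv[[cn]] <- list()
  }
  invisible(NULL)
}

.final_chars <- function(gen) {
  .apply_queue(gen)
  gen$chars
}

# queue the spliced (mRNA) letters of transcript t into the genome
.write_tx_seq <- function(gen, t, spliced) {
  lens <- exon_lengths(t)
  cum <- cumsum(lens)
  L <- cum[length(cum)]
  for (k in seq_along(lens)) {
    if (t$strand == "+") {
      seg <- spliced[(c(0L, cum)[k] + 1L):cum[k]]
    } else {
      tr <- (L - cum[k] + 1L):(L - c(0L, cum)[k])
      seg <- rev(unname(.COMP[spliced[tr]]))
    }
    .queue_write(gen, t$chrom, t$exon_start[k]:t$exon_end[k], seg)
  }
  invisible(NULL)
}

# canonical splice dinucleotides at one intron, strand-aware (plus-strand
# letters; a minus-strand intron reads GT..AG on the minus strand)
.write_splice_sites <- function(gen, chrom, strand, istart, iend) {
  if (strand == "+") {
    .queue_write(gen, chrom, c(istart, istart + 1L, iend - 1L, iend),
                 c("G", "T", "A", "G"))
  } else {
    .queue_write(gen, chrom, c(istart, istart + 1L, iend - 1L, iend),
                 c("C", "T", "A", "C"))
  }
  invisible(NULL)
}

.sim_genome_chars <- function(spec) {
  set.seed(spec$seed)
  mean_ex <- mean(spec$exon_len_nt)
  mean_n <- mean(spec$exons_per_gene)
  est_span <- mean_n * mean_ex + (mean_n - 1) * .mean_intron_len(spec$intron_len_nt)
  len <- ceiling(1.7 * spec$n_genes * (est_span + spec$intergenic_nt) /
                   spec$n_chrom) + 20000L
  chars <- lapply(seq_len(spec$n_chrom), function(i)
    sample(c("A", "C", "G", "T"), len, replace = TRUE))
  names(chars) <- paste0("chr", seq_len(spec$n_chrom))
  chars
}

#' Simulate a random genome
#'
#' Uniform i.i.d. A/C/G/T chromosomes sized to host `n_genes` gene models
#' (estimated from the spec's exon/intron ranges, with head room) with at
#' least `intergenic_nt` spacing. Byte-identical across runs with the same
#' seed.
#'
#' @param spec A [simulation_spec()].
#' @return Named `DNAStringSet`.
#' @export
simulate_genome <- function(spec) .chars_to_dss(.sim_genome_chars(spec))

# one reference isoform per gene: random exon/intron structure, canonical
# GT..AG intron boundaries, and an embedded ATG..stop ORF covering >= 60% of
# the spliced length with the stop in the last mRNA exon. The coding filler
# uses only C/G/T so the designed ATG..stop is provably the unique (and
# therefore longest) AUG-initiated ORF of the reference mRNA.
.plant_reference_orf <- function(gen, t) {
  lens <- exon_lengths(t)
  L <- sum(lens)
  J <- last_junction_position(t)
  p <- L - 12L
  a <- 4L + ((p - 4L) %% 3L)
  spliced <- sample(c("C", "G", "T"), L, replace = TRUE)
  spliced[a:(a + 2L)] <- c("A", "T", "G")
  spliced[p:(p + 2L)] <- c("T", "A", "A")
  .write_tx_seq(gen, t, spliced)
  c(a, p + 2L)
}

.sim_models <- function(spec, gen) {
  set.seed(spec$seed + 1L)
  chrom_names <- names(gen$chars)
  chrom_len <- lengths(gen$chars)
  cursor <- stats::setNames(rep(2000L, length(chrom_names)), chrom_names)
  loci <- vector("list", spec$n_genes)
  ids <- character(spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    chrom <- chrom_names[(g - 1L) %% spec$n_chrom + 1L]
    n_ex <- .runif_int(spec$exons_per_gene[1L], spec$exons_per_gene[2L], 1L)
    ex_lens <- .runif_int(spec$exon_len_nt[1L], spec$exon_len_nt[2L], n_ex)
    il <- spec$intron_len_nt
    in_lens <- if (n_ex > 1L)
      pmin(pmax(as.integer(round(exp(stats::runif(n_ex - 1L, log(il[1L]),
                                                  log(il[2L]))))),
                il[1L]), il[2L])
    else integer(0)
    strand <- sample(c("+", "-"), 1L)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- cursor[[chrom]]
    for (k in seq_len(n_ex)) {
      starts[k] <- pos
      ends[k] <- pos + ex_lens[k] - 1L
      pos <- ends[k] + (if (k < n_ex) in_lens[k] else 0L) + 1L
    }
    span_end <- ends[n_ex]
    if (span_end + spec$intergenic_nt + 200L > chrom_len[[chrom]])
      stop("genome too small to host ", spec$n_genes,
           " genes; enlarge the genome or reduce n_genes")
    cursor[[chrom]] <- span_end + spec$intergenic_nt
    gid <- paste0("g", g)
    t <- transcript_model(paste0(gid, ".t1"), gid, chrom, strand, starts, ends)
    t$cds_span <- .plant_reference_orf(gen, t)
    for (k in seq_len(n_ex - 1L))
      .write_splice_sites(gen, chrom, strand, ends[k] + 1L, starts[k + 1L] - 1L)
    loci[[g]] <- gene_locus(gid, list(t))
    ids[g] <- gid
  }
  names(loci) <- ids
  # canonical order: chromosome, then span start (matches the GFF3 reader)
  key_chr <- vapply(loci, `[[`, "", "chrom")
  key_pos <- vapply(loci, function(l) l$span[1L], 1L)
  loci[order(key_chr, key_pos, names(loci))]
}

#' Simulate gene models on a genome
#'
#' Places one reference isoform per gene with intron lengths inside the
#' spec's range, canonical GT..AG splice dinucleotides, and an embedded
#' ATG..stop ORF spanning at least 60% of the spliced length whose stop lies
#' in the last mRNA exon (so reference isoforms are never NMD candidates).
#' The genome is modified in place and returned alongside the models.
#'
#' @param spec A [simulation_spec()].
#' @param genome `DNAStringSet` from [simulate_genome()].
#' @return List with `loci` (named list of `gene_locus`) and the modified
#'   `genome`.
#' @export
simulate_gene_models <- function(spec, genome) {
  gen <- .new_gen(.dss_to_chars(genome))
  loci <- .sim_models(spec, gen)
  list(loci = loci, genome = .chars_to_dss(.final_chars(gen)))
}

.pick <- function(v) v[sample.int(length(v), 1L)]

# uniform integers on [lo, hi]; safe when lo == hi (unlike sample(seq(...)))
.runif_int <- function(lo, hi, n) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

# per-category structural edit builders ------------------------------------

.plant_one_event <- function(gen, locus, category) {
  ref <- locus$transcripts[[1L]]
  n <- n_exons(ref)
  ins <- derive_introns(ref)
  chrom <- ref$chrom
  alt_id <- paste0(locus$gene_id, ".t2")
  mk <- function(starts, ends)
    transcript_model(alt_id, locus$gene_id, chrom, ref$strand, starts, ends)
  row <- function(cat9, s, e, iso_a, iso_b)
    .as_event_row(locus$gene_id, cat9, chrom, s, e, iso_a, iso_b)

  if (category == "RI_SI") {
    j <- .pick(seq_len(n - 1L))
    alt <- mk(ref$exon_start[-(j + 1L)], ref$exon_end[-j])
    return(list(alt = alt, truth = row("RI", ins$start[j], ins$end[j],
                                       alt_id, ref$transcript_id)))
  }
  if (category == "SE_RE") {
    j <- .pick(2:(n - 1L))
    alt <- mk(ref$exon_start[-j], ref$exon_end[-j])
    return(list(alt = alt, truth = row("SE", ref$exon_start[j], ref$exon_end[j],
                                       ref$transcript_id, alt_id)))
  }
  if (category %in% c("AA", "AD")) {
    lens <- ins$end - ins$start + 1L
    j <- .pick(which(lens >= 100L))
    k <- .pick(10:min(40L, lens[j] - 60L))
    s <- ins$start[j]; e <- ins$end[j]
    starts <- ref$exon_start; ends <- ref$exon_end
    plus <- ref$strand == "+"
    shrink_at_end <- (category == "AA") == plus  # move the genomic-end boundary
    if (shrink_at_end) {
      starts[j + 1L] <- e - k + 1L                # downstream exon grows left
      din <- if (plus) c("A", "G") else c("A", "C")
      .queue_write(gen, chrom, (e - k - 1L):(e - k), din)
      aff <- c(e - k, e)
    } else {
      ends[j] <- s + k - 1L                       # upstream exon grows right
      din <- if (plus) c("G", "T") else c("C", "T")
      .queue_write(gen, chrom, (s + k):(s + k + 1L), din)
      aff <- c(s, s + k)
    }
    alt <- mk(starts, ends)
    iso <- sort(c(ref$transcript_id, alt_id))
    return(list(alt = alt, truth = row(category, aff[1L], aff[2L],
                                       iso[1L], iso[2L])))
  }
  if (category == "ATE") {
    ns <- ref$exon_end[n] + 60L
    ne <- ns + 79L
    alt <- mk(c(ref$exon_start[seq_len(n - 1L)], ns),
              c(ref$exon_end[seq_len(n - 1L)], ne))
    din <- if (ref$strand == "+") c("A", "G") else c("A", "C")
    .queue_write(gen, chrom, (ns - 2L):(ns - 1L), din)
    return(list(alt = alt, truth = row("ATE", ns, ne, alt_id,
                                       ref$transcript_id)))
  }
  if (category == "IWI_TWI") {
    lens <- ins$end - ins$start + 1L
    k <- .pick(intersect(2:(n - 1L), which(lens >= 30L)))
    term <- .pick((ins$start[k] + 5L):(ins$end[k] - 5L))
    alt <- mk(ref$exon_start[seq_len(k)],
              c(ref$exon_end[seq_len(k - 1L)], term))
    cat9 <- if (ref$strand == "+") "TWI" else "IWI"
    return(list(alt = alt, truth = row(cat9, ins$start[k], ins$end[k],
                                       ref$transcript_id, alt_id)))
  }
  stop("unknown category: ", category)
}

.event_host_ok <- function(locus, category) {
  ref <- locus$transcripts[[1L]]
  n <- n_exons(ref)
  if (n < 3L) return(FALSE)
  ins <- derive_introns(ref)
  lens <- ins$end - ins$start + 1L
  switch(category,
         RI_SI = TRUE, SE_RE = TRUE, ATE = TRUE,
         AA = any(lens >= 100L), AD = any(lens >= 100L),
         IWI_TWI = any(lens[2:(n - 1L)] >= 30L),
         FALSE)
}

.plant_as <- function(loci, gen, spec) {
  set.seed(spec$seed + 2L)
  order_ids <- sample(names(loci))
  used <- character(0)
  truth <- list()
  shortfall <- c()
  for (cat in .AS_CATEGORIES6) {
    need <- spec$events_per_class[[cat]]
    if (need == 0L) next
    got <- 0L
    for (gid in order_ids) {
      if (got >= need) break
      if (gid %in% used) next
      if (!.event_host_ok(loci[[gid]], cat)) next
      pl <- .plant_one_event(gen, loci[[gid]], cat)
      tx <- c(loci[[gid]]$transcripts, list(pl$alt))
      loci[[gid]] <- gene_locus(gid, tx)
      truth[[length(truth) + 1L]] <- pl$truth
      used <- c(used, gid)
      got <- got + 1L
    }
    if (got < need) shortfall[cat] <- need - got
  }
  if (length(shortfall))
    stop("insufficient host genes for planted events; shortfall: ",
         paste(names(shortfall), shortfall, sep = "=", collapse = ", "))
  planted <- if (length(truth)) do.call(rbind, truth) else .empty_events()
  rownames(planted) <- NULL
  list(loci = loci, planted_events = planted, used = used)
}

#' Plant alternative-splicing isoforms with known ground truth
#'
#' Adds, for each requested event, one alternative isoform differing from the
#' host gene's reference isoform by exactly one structural edit of the
#' requested category: intron retention (two exons merged across an intron),
#' exon skipping (an internal exon dropped), alternate acceptor/donor (one
#' splice site shifted into the intron by 10-40 nt, with the new GT/AG
#' written into the genome), alternate terminal exon (the last genomic exon
#' replaced by a non-overlapping exon in the intergenic buffer), and
#' initiation/termination within an intron (the transcript truncated so its
#' terminus lies inside a reference intron). Each host gene carries at most
#' one planted isoform, so the planted multiset is exactly countable.
#'
#' @param loci Named list of `gene_locus` objects (reference isoforms).
#' @param genome `DNAStringSet` (modified where new splice sites are needed).
#' @param spec A [simulation_spec()].
#' @return List with modified `loci`, `genome`, and `planted_events` — a
#'   data.frame in the same layout as [classify_transcriptome()] events.
#' @export
plant_as_isoforms <- function(loci, genome, spec) {
  gen <- .new_gen(.dss_to_chars(genome))
  res <- .plant_as(loci, gen, spec)
  list(loci = res$loci, genome = .chars_to_dss(.final_chars(gen)),
       planted_events = res$planted_events)
}

.plant_ptc <- function(loci, gen, spec, skip_genes = character(0)) {
  set.seed(spec$seed + 3L)
  if (spec$n_ptc_isoforms == 0L)
    return(list(loci = loci,
                planted_nmd = data.frame(transcript_id = character(0),
                                         gene_id = character(0),
                                         distance_nt = integer(0),
                                         ptc_present = logical(0),
                                         expected_candidate_flag = logical(0),
                                         stringsAsFactors = FALSE)))
  dists <- rep(spec$ptc_distances_nt, length.out = spec$n_ptc_isoforms)
  free <- setdiff(names(loci), skip_genes)
  free <- free[vapply(free, function(g)
    length(loci[[g]]$transcripts) == 1L && n_exons(loci[[g]]$transcripts[[1L]]) >= 2L,
    TRUE)]
  free <- sample(free)
  rows <- list()
  for (d in dists) {
    host <- NULL
    for (g in free) {
      t <- loci[[g]]$transcripts[[1L]]
      if (!is.na(last_junction_position(t)) && last_junction_position(t) - d >= 10L) {
        host <- g; break
      }
    }
    if (is.null(host))
      stop("requested PTC distance ", d,
           " nt exceeds every available transcript's junction position")
    free <- setdiff(free, host)
    t <- loci[[host]]$transcripts[[1L]]
    L <- spliced_length(t)
    J <- last_junction_position(t)
    p <- J - d
    a <- 4L + ((p - 4L) %% 3L)
    spliced <- sample(c("C", "G", "T"), L, replace = TRUE)
    spliced[a:(a + 2L)] <- c("A", "T", "G")
    spliced[p:(p + 2L)] <- c("T", "A", "A")
    .write_tx_seq(gen, t, spliced)
    t$cds_span <- c(a, p + 2L)
    loci[[host]]$transcripts[[t$transcript_id]] <- t
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = t$transcript_id, gene_id = host,
      distance_nt = as.integer(d), ptc_present = TRUE,
      expected_candidate_flag = d > 55L, stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, rows)
  rownames(planted) <- NULL
  list(loci = loci, planted_nmd = planted)
}

#' Plant PTC-bearing transcripts at controlled junction distances
#'
#' For each requested distance `d`, rewrites the ORF of the reference
#' isoform of a dedicated (single-isoform, multi-exon) host gene so that the
#' first base of its stop codon lies exactly `d` nt upstream of the last
#' exon-exon junction in mRNA coordinates. The expected NMD-candidate flag is
#' `d > 55` (strict). Using dedicated hosts keeps the AS-event ground truth
#' exactly countable.
#'
#' @param loci Named list of `gene_locus` objects.
#' @param genome `DNAStringSet` (modified in the rewritten exons).
#' @param spec A [simulation_spec()].
#' @return List with modified `loci`, `genome`, and `planted_nmd`
#'   (data.frame: `transcript_id`, `gene_id`, `distance_nt`, `ptc_present`,
#'   `expected_candidate_flag`).
#' @export
plant_ptc_isoforms <- function(loci, genome, spec) {
  gen <- .new_gen(.dss_to_chars(genome))
  multi <- names(loci)[vapply(loci, function(l) length(l$transcripts) > 1L, TRUE)]
  res <- .plant_ptc(loci, gen, spec, skip_genes = multi)
  list(loci = res$loci, genome = .chars_to_dss(.final_chars(gen)),
       planted_nmd = res$planted_nmd)
}

.assign_expr <- function(loci, spec, ptc_genes = character(0)) {
  set.seed(spec$seed + 4L)
  alt_ids <- unlist(lapply(loci, function(l)
    setdiff(names(l$transcripts),
            paste0(l$gene_id, ".t1"))), use.names = FALSE)
  n_low <- spec$n_low_abundance_isoforms
  if (n_low > length(alt_ids))
    stop("n_low_abundance_isoforms (", n_low,
         ") exceeds the number of alternative isoforms (", length(alt_ids), ")")
  low_ids <- if (n_low > 0L) sample(alt_ids, n_low) else character(0)
  low_crit <- stats::setNames(rep(c("fpkm_fail", "fraction_fail", "both_fail"),
                                  length.out = n_low), low_ids)
  ids <- character(0); fpkm <- numeric(0)
  for (l in loci) {
    ref_id <- paste0(l$gene_id, ".t1")
    alts <- setdiff(names(l$transcripts), ref_id)
    draw <- stats::rlnorm(1L, spec$expression_meanlog, spec$expression_sdlog)
    if (length(alts) == 0L) {
      ids <- c(ids, ref_id); fpkm <- c(fpkm, max(draw, 2.5))
    } else if (alts[1L] %in% low_ids) {
      v <- switch(low_crit[[alts[1L]]],
                  fpkm_fail = c(ref = 6, alt = 0.5),
                  fraction_fail = c(ref = 150, alt = 2),
                  both_fail = c(ref = 60, alt = 0.4))
      ids <- c(ids, ref_id, alts[1L]); fpkm <- c(fpkm, v[["ref"]], v[["alt"]])
    } else {
      ref_v <- max(draw, 7)
      alt_v <- ref_v * stats::runif(1L, 0.3, 0.6)
      ids <- c(ids, ref_id, alts[1L]); fpkm <- c(fpkm, ref_v, alt_v)
    }
  }
  abundance <- data.frame(transcript_id = ids, fpkm = fpkm,
                          stringsAsFactors = FALSE)
  low <- data.frame(transcript_id = low_ids,
                    criterion = unname(low_crit[low_ids]),
                    stringsAsFactors = FALSE)
  list(abundance = abundance, planted_low_abundance = low)
}

#' Assign expression with planted low-abundance isoforms
#'
#' Reference isoforms draw log-normal FPKMs (floored so that references and
#' ordinary alternatives pass both filter thresholds with at least a 2x
#' margin); the designated low-abundance isoforms receive values violating
#' exactly the recorded criterion: FPKM 0.5 at a fraction above 6%
#' (fpkm_fail), FPKM 2 at a fraction of 1.3% (fraction_fail), or FPKM 0.4 at
#' 0.7% (both_fail).
#'
#' @param loci Named list of `gene_locus` objects (after planting).
#' @param spec A [simulation_spec()].
#' @return List with `abundance` (data.frame) and `planted_low_abundance`
#'   (data.frame: `transcript_id`, `criterion`).
#' @export
assign_expression <- function(loci, spec) .assign_expr(loci, spec)

.sim_coverage <- function(loci, abundance, spec, chrom_len) {
  set.seed(spec$seed + 5L)
  depth <- lapply(chrom_len, function(n) numeric(n))
  tx <- all_transcripts(loci)
  if (spec$n_fragments > 0L && length(tx) > 0L) {
    v <- suppressWarnings(fpkm_of(abundance, names(tx)))
    L <- vapply(tx, spliced_length, 1L)
    w <- v * L
    if (sum(w) > 0) {
      counts <- as.vector(stats::rmultinom(1L, spec$n_fragments, prob = w))
      flen <- spec$fragment_len_nt
      for (i in seq_along(tx)) {
        if (counts[i] == 0L) next
        t <- tx[[i]]
        Li <- L[i]
        fl <- min(flen, Li)
        smax <- Li - fl + 1L
        starts <- sample.int(smax, counts[i], replace = TRUE)
        cnt <- tabulate(starts, nbins = Li)
        S <- cumsum(cnt)
        depth_t <- S - c(rep(0, fl), S)[seq_len(Li)]
        lens <- exon_lengths(t)
        cum <- cumsum(lens)
        for (k in seq_along(lens)) {
          if (t$strand == "+") {
            tr <- (c(0L, cum)[k] + 1L):cum[k]
            gidx <- t$exon_start[k]:t$exon_end[k]
          } else {
            tr <- (Li - cum[k] + 1L):(Li - c(0L, cum)[k])
            gidx <- t$exon_end[k]:t$exon_start[k]
          }
          depth[[t$chrom]][gidx] <- depth[[t$chrom]][gidx] + depth_t[tr]
        }
      }
    }
  }
  coverage_track(depth)
}

#' Simulate uniform fragment coverage
#'
#' Fragments of `fragment_len_nt` are allocated to transcripts with
#' probability proportional to FPKM times length, placed uniformly along the
#' mRNA (so every fragment fits), and projected through the exon chain onto
#' genomic per-base depth. Deterministic under the spec seed.
#'
#' @param loci Named list of `gene_locus` objects.
#' @param abundance Abundance data.frame.
#' @param spec A [simulation_spec()].
#' @param genome `DNAStringSet` (or named lengths) defining chromosomes.
#' @return A [coverage_track()].
#' @export
simulate_coverage <- function(loci, abundance, spec, genome) {
  chrom_len <- if (methods::is(genome, "DNAStringSet"))
    stats::setNames(Biostrings::width(genome), names(genome))
  else if (is.character(genome)) vapply(genome, nchar, 1L)
  else unlist(genome)
  .sim_coverage(loci, abundance, spec, chrom_len)
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Runs the full generator: genome, reference gene models, planted AS
#' isoforms, planted PTC transcripts, expression with planted low-abundance
#' isoforms, and (optionally) fragment coverage. The `truth` element is the
#' oracle for every downstream recovery test.
#'
#' @param spec A [simulation_spec()].
#' @param coverage Simulate the coverage track too (slower)?
#' @return List with `genome` (`DNAStringSet`), `loci`, `abundance`,
#'   `coverage` (or `NULL`), `truth` (list: `planted_events`,
#'   `planted_low_abundance`, `planted_nmd`, `true_fpkm`), and `spec`.
#' @export
simulate_dataset <- function(spec, coverage = TRUE) {
  gen <- .new_gen(.sim_genome_chars(spec))
  loci <- .sim_models(spec, gen)
  as_res <- .plant_as(loci, gen, spec)
  ptc_res <- .plant_ptc(as_res$loci, gen, spec, skip_genes = as_res$used)
  expr <- .assign_expr(ptc_res$loci, spec)
  chrom_len <- lengths(gen$chars)
  cov <- if (coverage)
    .sim_coverage(ptc_res$loci, expr$abundance, spec, chrom_len) else NULL
  list(genome = .chars_to_dss(.final_chars(gen)), loci = ptc_res$loci,
       abundance = expr$abundance, coverage = cov,
       truth = list(planted_events = as_res$planted_events,
                    planted_low_abundance = expr$planted_low_abundance,
                    planted_nmd = ptc_res$planted_nmd,
                    true_fpkm = expr$abundance),
       spec = spec)
}

#' Write a simulated dataset to standard-format files
#'
#' Emits `genome.fa`, `models.gff3`, `abundance.tsv`, `coverage.bedgraph`
#' (when present) and `ground_truth.json` under `dir`.
#'
#' @param ds Result of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(ds$genome, file.path(dir, "genome.fa"))
  write_gff3(ds$loci, file.path(dir, "models.gff3"))
  write_abundance(ds$abundance, file.path(dir, "abundance.tsv"))
  if (!is.null(ds$coverage))
    write_bedgraph(ds$coverage, file.path(dir, "coverage.bedgraph"))
  write_ground_truth(ds$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Simulation spec for the two-sample total vs polyribosomal scenario
#'
#' Encodes the study conditions the package's comparative analysis emulates:
#' the total-RNA sample carries many retained-intron isoforms and a large
#' planted low-abundance subpopulation; the polyribosomal sample carries
#' fewer events overall, proportionally fewer retained introns, and almost
#' no low-abundance isoforms.
#'
#' @param sample `"total"` or `"polysomal"`.
#' @param seed Base seed; the two samples use disjoint derived seeds.
#' @return A [simulation_spec()].
#' @export
scenario_spec <- function(sample = c("total", "polysomal"), seed = 1L) {
  sample <- match.arg(sample)
  if (sample == "total") {
    simulation_spec(seed = seed, n_genes = 700L,
                    events_per_class = c(AA = 108L, AD = 60L, ATE = 30L,
                                         RI_SI = 232L, SE_RE = 20L,
                                         IWI_TWI = 50L),
                    n_low_abundance_isoforms = 225L,
                    n_fragments = 300000L)
  } else {
    simulation_spec(seed = seed + 7919L, n_genes = 700L,
                    events_per_class = c(AA = 72L, AD = 45L, ATE = 20L,
                                         RI_SI = 59L, SE_RE = 15L,
                                         IWI_TWI = 39L),
                    n_low_abundance_isoforms = 1L,
                    n_fragments = 300000L)
  }
}
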