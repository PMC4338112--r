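#' Construct a transcript model
#'
#' A transcript model is a strand-aware ordered exon chain on one chromosome,
#' with introns derived as the gaps between consecutive exons. Coordinates are
#' 1-based and fully closed (GFF3 convention) throughout the package.
#'
#' @param transcript_id Character scalar, unique transcript identifier.
#' @param gene_id Character scalar, identifier of the parent gene/locus.
#' @param chrom Character scalar, chromosome name.
#' @param strand `"+"` or `"-"`. Unstranded features are rejected because
#'   splice-site polarity (donor vs acceptor) is strand-dependent.
#' @param exon_start,exon_end Integer vectors of equal length: exon bounds in
#'   ascending genomic order. Exons must be non-overlapping with a gap of at
#'   least 1 nt between consecutive exons.
#' @param cds_span Optional length-2 integer vector: CDS start and end in
#'   *transcript* (spliced mRNA) coordinates, 1-based inclusive, including the
#'   stop codon.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_start, exon_end, cds_span = NULL) {
  exon_start <- as.integer(exon_start)
  exon_end <- as.integer(exon_end)
  if (length(exon_start) != length(exon_end) || length(exon_start) < 1L)
    stop("transcript ", transcript_id, ": exon start/end vectors must be non-empty and equal length")
  if (!strand %in% c("+", "-"))
    stop("transcript ", transcript_id, ": strand must be '+' or '-' (unstranded features are rejected)")
  if (any(exon_end < exon_start))
    stop("transcript ", transcript_id, ": exon with end < start")
  if (is.unsorted(exon_start, strictly = TRUE) && length(exon_start) > 1L)
    stop("transcript ", transcript_id, ": exons must be in ascending genomic order")
  if (length(exon_start) > 1L &&
      any(exon_start[-1L] <= exon_end[-length(exon_end)] + 1L))
    stop("transcript ", transcript_id,
         ": exons overlap or are adjacent (gap >= 1 nt required)")
  if (!is.null(cds_span)) {
    cds_span <- as.integer(cds_span)
    if (length(cds_span) != 2L || cds_span[1L] > cds_span[2L] ||
        cds_span[1L] < 1L || cds_span[2L] > sum(exon_end - exon_start + 1L))
      stop("transcript ", transcript_id, ": invalid cds_span")
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom), strand = strand,
         exon_start = exon_start, exon_end = exon_end, cds_span = cds_span),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%d-%d [%s], %d exon(s)%s\n",
              x$transcript_id, x$gene_id, x$chrom,
              min(x$exon_start), max(x$exon_end), x$strand,
              length(x$exon_start),
              if (is.null(x$cds_span)) "" else
                sprintf(", CDS %d-%d (mRNA)", x$cds_span[1], x$cds_span[2])))
  invisible(x)
}

#' Number of exons of a transcript
#' @param t A `transcript_model`.
#' @return Integer scalar.
#' @export
n_exons <- function(t) length(t$exon_start)

#' Exon lengths of a transcript, in ascending genomic order
#' @param t A `transcript_model`.
#' @return Integer vector.
#' @export
exon_lengths <- function(t) t$exon_end - t$exon_start + 1L

#' Spliced (mRNA) length of a transcript
#' @param t A `transcript_model`.
#' @return Integer scalar: the sum of exon lengths.
#' @export
spliced_length <- function(t) sum(exon_lengths(t))

#' Genomic span of a transcript
#' @param t A `transcript_model`.
#' @return Length-2 integer vector `c(start, end)`.
#' @export
transcript_span <- function(t) c(min(t$exon_start), max(t$exon_end))

#' Derive introns from a transcript's exon chain
#'
#' Intron *i* is the gap between exon *i* and exon *i + 1*:
#' `(exon_end[i] + 1, exon_start[i + 1] - 1)`.
#'
#' @param t A `transcript_model`.
#' @return A data.frame with columns `start`, `end` (0 rows for single-exon
#'   transcripts). Row order follows ascending genomic order.
#' @export
derive_introns <- function(t) {
  n <- n_exons(t)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = t$exon_end[-n] + 1L, end = t$exon_start[-1L] - 1L)
}

#' Construct a gene locus
#'
#' @param gene_id Character scalar.
#' @param transcripts List of `transcript_model` objects, all with
#'   `gene_id` equal to `gene_id` and on the same chromosome.
#' @return An object of class `gene_locus` with a `span` covering all exons.
#' @export
gene_locus <- function(gene_id, transcripts) {
  if (length(transcripts) < 1L) stop("locus ", gene_id, ": needs >= 1 transcript")
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  if (length(chroms) != 1L) stop("locus ", gene_id, ": transcripts on multiple chromosomes")
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stop("locus ", gene_id, ": duplicated transcript ids")
  names(transcripts) <- ids
  span <- c(min(vapply(transcripts, function(t) min(t$exon_start), 1L)),
            max(vapply(transcripts, function(t) max(t$exon_end), 1L)))
  structure(list(gene_id = as.character(gene_id), chrom = chroms,
                 transcripts = transcripts, span = span),
            class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s %s:%d-%d, %d transcript(s)\n",
              x$gene_id, x$chrom, x$span[1], x$span[2], length(x$transcripts)))
  invisible(x)
}

#' All transcripts of a locus set as a flat named list
#' @param loci Named list of `gene_locus` objects.
#' @return Named list of `transcript_model` objects.
#' @export
all_transcripts <- function(loci) {
  out <- unlist(lapply(loci, `[[`, "transcripts"), recursive = FALSE, use.names = FALSE)
  names(out) <- vapply(out, `[[`, "", "transcript_id")
  out
}

#' Subset a locus set to a set of transcript ids
#'
#' Loci left with no transcript are dropped.
#'
#' @param loci Named list of `gene_locus` objects.
#' @param keep_ids Character vector of transcript ids to retain.
#' @return Named list of `gene_locus` objects.
#' @export
subset_loci <- function(loci, keep_ids) {
  out <- lapply(loci, function(l) {
    tx <- l$transcripts[names(l$transcripts) %in% keep_ids]
    if (length(tx) == 0L) return(NULL)
    gene_locus(l$gene_id, tx)
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' the two-part low-abundance isoform filter (FPKM at least `fpkm_min`,
#' isoform fraction of locus expression at least `isoform_fraction_min`),
#' the NMD distance rule (a premature stop more than `nmd_distance_nt`
#' upstream of the last exon-exon junction flags an NMD candidate), the
#' admissible intron length range, the annotation-matching thresholds, and
#' the coverage-profile resolutions.
#'
#' @param fpkm_min Minimum FPKM to keep an isoform (default 1).
#' @param isoform_fraction_min Minimum fraction of locus FPKM (default 0.03).
#' @param nmd_distance_nt Strict distance threshold, nt (default 55).
#' @param min_intron_nt,max_intron_nt Admissible intron lengths (60, 6000).
#' @param match_coverage Minimum contiguous fraction of the reference mRNA a
#'   matching assembly must cover (default 0.80).
#' @param match_identity Minimum structural identity (default 0.95).
#' @param chrom_bin_nt Bin width for chromosome density profiles (default 1e5).
#' @param metagene_bins Number of relative positions in the metagene profile
#'   (default 101).
#' @param use_annotated_cds If `TRUE`, NMD assessment uses an annotated CDS
#'   when present instead of the longest AUG-initiated ORF.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(fpkm_min = 1.0, isoform_fraction_min = 0.03,
                            nmd_distance_nt = 55L, min_intron_nt = 60L,
                            max_intron_nt = 6000L, match_coverage = 0.80,
                            match_identity = 0.95, chrom_bin_nt = 100000L,
                            metagene_bins = 101L, use_annotated_cds = FALSE) {
  cfg <- list(fpkm_min = fpkm_min, isoform_fraction_min = isoform_fraction_min,
              nmd_distance_nt = as.integer(nmd_distance_nt),
              min_intron_nt = as.integer(min_intron_nt),
              max_intron_nt = as.integer(max_intron_nt),
              match_coverage = match_coverage, match_identity = match_identity,
              chrom_bin_nt = as.integer(chrom_bin_nt),
              metagene_bins = as.integer(metagene_bins),
              use_annotated_cds = isTRUE(use_annotated_cds))
  stopifnot(cfg$fpkm_min > 0, cfg$nmd_distance_nt > 0,
            cfg$min_intron_nt > 0, cfg$max_intron_nt >= cfg$min_intron_nt,
            cfg$chrom_bin_nt >= 1L, cfg$metagene_bins >= 2L,
            cfg$isoform_fraction_min > 0, cfg$isoform_fraction_min <= 1,
            cfg$match_coverage > 0, cfg$match_coverage <= 1,
            cfg$match_identity > 0, cfg$match_identity <= 1)
  structure(cfg, class = "analysis_config")
}

#' Spliced mRNA sequence of a transcript
#'
#' Concatenates the exon sequences in transcript (5' to 3') order;
#' minus-strand transcripts are reverse-complemented.
#'
#' @param t A `transcript_model`.
#' @param genome A named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @return Character scalar of length `spliced_length(t)`.
#' @export
spliced_sequence <- function(t, genome) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!t$chrom %in% names(genome)) stop("chromosome not in genome: ", t$chrom)
    chr <- genome[[t$chrom]]
    if (max(t$exon_end) > length(chr))
      stop("transcript ", t$transcript_id, ": exon beyond end of chromosome ", t$chrom)
    parts <- Biostrings::extractAt(chr, IRanges::IRanges(t$exon_start, t$exon_end))
    s <- paste0(as.character(parts), collapse = "")
  } else {
    chrseq <- .chrom_seq(genome, t$chrom)
    if (max(t$exon_end) > nchar(chrseq))
      stop("transcript ", t$transcript_id, ": exon beyond end of chromosome ", t$chrom)
    s <- paste0(substring(chrseq, t$exon_start, t$exon_end), collapse = "")
  }
  if (t$strand == "-") s <- revcomp(s)
  s
}

.chrom_seq <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    return(as.character(genome[[chrom]]))
  }
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    return(genome[[chrom]])
  }
  stop("genome must be a DNAStringSet or a named character vector")
}

#' Reverse complement of a DNA string
#' @param s Character scalar over A/C/G/T/N.
#' @return Character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Map genomic positions to transcript (mRNA) coordinates
#'
#' Position 1 is the 5' end of the spliced mRNA, so the mapping is
#' strand-aware. Positions falling in introns or outside the transcript span
#' raise an error.
#'
#' @param t A `transcript_model`.
#' @param gpos Integer vector of genomic positions, each inside an exon of `t`.
#' @return Integer vector of 1-based transcript positions.
#' @export
genomic_to_transcript <- function(t, gpos) {
  gpos <- as.integer(gpos)
  idx <- findInterval(gpos, t$exon_start)
  bad <- idx < 1L | gpos > t$exon_end[pmax(idx, 1L)]
  if (any(bad))
    stop("position(s) ", paste(gpos[bad], collapse = ","),
         " not exonic in transcript ", t$transcript_id)
  lens <- exon_lengths(t)
  cum <- cumsum(lens)
  if (t$strand == "+") {
    c(0L, cum)[idx] + (gpos - t$exon_start[idx] + 1L)
  } else {
    total <- cum[length(cum)]
    (total - cum[idx]) + (t$exon_end[idx] - gpos + 1L)
  }
}

#' Map transcript (mRNA) coordinates to genomic positions
#'
#' Inverse of [genomic_to_transcript()].
#'
#' @param t A `transcript_model`.
#' @param tpos Integer vector of positions in `1..spliced_length(t)`.
#' @return Integer vector of genomic positions.
#' @export
transcript_to_genomic <- function(t, tpos) {
  tpos <- as.integer(tpos)
  L <- spliced_length(t)
  if (any(tpos < 1L | tpos > L))
    stop("transcript position out of range 1..", L, " for ", t$transcript_id)
  lens <- exon_lengths(t)
  n <- length(lens)
  if (t$strand == "+") {
    cum <- cumsum(lens)
    k <- findInterval(tpos - 1L, c(0L, cum[-n])) # exon index
    off <- tpos - c(0L, cum)[k]
    t$exon_start[k] + off - 1L
  } else {
    mlens <- rev(lens)                    # mRNA order = descending genomic
    mcum <- cumsum(mlens)
    j <- findInterval(tpos - 1L, c(0L, mcum[-n]))
    off <- tpos - c(0L, mcum)[j]
    k <- n - j + 1L
    t$exon_end[k] - off + 1L
  }
}

#' Choose the representative isoform of a locus
#'
#' The transcript with the longest CDS; when no transcript carries a CDS, the
#' longest spliced transcript. Ties break to the lexicographically smallest
#' transcript id, making the choice deterministic.
#'
#' @param locus A `gene_locus`.
#' @return A `transcript_model`.
#' @export
select_representative <- function(locus) {
  tx <- locus$transcripts
  cds_len <- vapply(tx, function(t)
    if (is.null(t$cds_span)) NA_integer_ else t$cds_span[2L] - t$cds_span[1L] + 1L,
    1L)
  key <- if (all(is.na(cds_len))) {
    vapply(tx, spliced_length, 1L)
  } else {
    ifelse(is.na(cds_len), -1L, cds_len)
  }
  ids <- vapply(tx, `[[`, "", "transcript_id")
  ord <- order(-key, ids)
  tx[[ord[1L]]]
}
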