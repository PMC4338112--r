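.STOP_CODONS <- c("TAA", "TAG", "TGA")

.find_all <- function(seq, pat) {
  m <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Longest AUG-initiated open reading frame of a spliced sequence
#'
#' Scans every ATG and pairs it with the first in-frame stop codon at or
#' after it. Returns the longest such ORF (length includes the stop codon);
#' ties break to the 5'-most start. Assembled isoforms usually carry no CDS
#' annotation, so ORF finding works from sequence alone.
#'
#' @param seq Character scalar over A/C/G/T (case-insensitive).
#' @return `NULL` when no ATG..stop pair exists, otherwise a list with
#'   `start_pos` (position of the A of AUG), `stop_pos` (first base of the
#'   stop codon), `frame` (0/1/2) and `length_nt` (a multiple of 3).
#' @export
find_orf <- function(seq) {
  seq <- toupper(seq)
  atg <- .find_all(seq, "ATG")
  if (length(atg) == 0L) return(NULL)
  stops <- sort(unique(c(.find_all(seq, "TAA"), .find_all(seq, "TAG"),
                         .find_all(seq, "TGA"))))
  if (length(stops) == 0L) return(NULL)
  best <- NULL
  for (a in atg) {
    cand <- stops[stops >= a + 3L & (stops - a) %% 3L == 0L]
    if (length(cand) == 0L) next
    st <- cand[1L]
    len <- st - a + 3L
    if (is.null(best) || len > best$length_nt) # ties keep the 5'-most start
      best <- list(start_pos = a, stop_pos = st,
                   frame = (a - 1L) %% 3L, length_nt = len)
  }
  best
}

#' Transcript coordinate of the last exon-exon junction
#'
#' The position of the last base of the penultimate exon on the spliced mRNA
#' (the 5' side of the 3'-most junction), strand-aware.
#'
#' @param t A `transcript_model`.
#' @return Integer position, or `NA` for single-exon transcripts.
#' @export
last_junction_position <- function(t) {
  n <- n_exons(t)
  if (n < 2L) return(NA_integer_)
  lens <- exon_lengths(t)
  L <- sum(lens)
  last_mrna_exon_len <- if (t$strand == "+") lens[n] else lens[1L]
  L - last_mrna_exon_len
}

#' Assess a transcript for a premature termination codon and NMD candidacy
#'
#' Finds the transcript's ORF (longest AUG-initiated by default; the
#' annotated CDS when `config$use_annotated_cds` is set and one is present),
#' measures the distance from the first base of the stop codon to the last
#' exon-exon junction in mRNA coordinates, and applies the 55-nt rule: a stop
#' more than `config$nmd_distance_nt` nucleotides upstream of the last
#' junction (strict inequality) marks a likely NMD substrate. Single-exon
#' transcripts and transcripts without an ORF are never candidates.
#'
#' @param t A `transcript_model`.
#' @param genome Named `DNAStringSet` or character vector.
#' @param config An [analysis_config()].
#' @return List with `transcript_id`, `orf` (or `NULL`),
#'   `last_junction_pos`, `stop_to_junction_nt`, `is_ptc`,
#'   `is_nmd_candidate`.
#' @export
assess_nmd <- function(t, genome, config = analysis_config()) {
  orf <- NULL
  if (config$use_annotated_cds && !is.null(t$cds_span)) {
    orf <- list(start_pos = t$cds_span[1L], stop_pos = t$cds_span[2L] - 2L,
                frame = (t$cds_span[1L] - 1L) %% 3L,
                length_nt = t$cds_span[2L] - t$cds_span[1L] + 1L)
  } else {
    orf <- find_orf(spliced_sequence(t, genome))
  }
  lj <- last_junction_position(t)
  if (is.null(orf) || is.na(lj)) {
    return(list(transcript_id = t$transcript_id, orf = orf,
                last_junction_pos = lj, stop_to_junction_nt = NA_integer_,
                is_ptc = FALSE, is_nmd_candidate = FALSE))
  }
  d <- lj - orf$stop_pos
  list(transcript_id = t$transcript_id, orf = orf, last_junction_pos = lj,
       stop_to_junction_nt = d, is_ptc = d > 0L,
       is_nmd_candidate = d > config$nmd_distance_nt)
}

#' NMD assessment for every transcript of a locus set
#'
#' @param loci Named list of `gene_locus` objects.
#' @param genome Named `DNAStringSet` or character vector.
#' @param config An [analysis_config()].
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `orf_start`, `orf_stop`, `last_junction`, `distance`,
#'   `is_ptc`, `is_nmd_candidate`.
#' @export
assess_nmd_all <- function(loci, genome, config = analysis_config()) {
  tx <- all_transcripts(loci)
  rows <- lapply(tx, function(t) {
    a <- assess_nmd(t, genome, config)
    data.frame(transcript_id = t$transcript_id, gene_id = t$gene_id,
               orf_start = if (is.null(a$orf)) NA_integer_ else a$orf$start_pos,
               orf_stop = if (is.null(a$orf)) NA_integer_ else a$orf$stop_pos,
               last_junction = a$last_junction_pos,
               distance = a$stop_to_junction_nt,
               is_ptc = a$is_ptc, is_nmd_candidate = a$is_nmd_candidate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan a retained intron for in-frame stop codons
#'
#' For a retained-intron (RI/SI) event, takes the reading frame from the
#' retaining transcript's ORF and reports whether any stop codon lies wholly
#' within the retained intron in that frame — the readthrough question: can
#' translation traverse the unspliced intron? `frame_preserved` records
#' whether the intron length is a multiple of 3. The scan is not applicable
#' when the retaining transcript has no ORF or the intron begins outside the
#' translated span.
#'
#' @param event One row of an RI/SI event data.frame (from
#'   [classify_transcriptome()]); `start`/`end` is the retained intron.
#' @param retaining `transcript_model` that contains the intron exonically
#'   (the event's `isoform_a`).
#' @param genome Named `DNAStringSet` or character vector.
#' @return List with logicals `contains_inframe_stop` (NA when not
#'   applicable), `frame_preserved`, `not_applicable`.
#' @export
intron_stop_scan <- function(event, retaining, genome) {
  if (event$category6 != "RI_SI")
    stop("intron_stop_scan applies to RI_SI events only, got ", event$category6)
  ti <- sort(genomic_to_transcript(retaining, c(event$start, event$end)))
  ilen <- ti[2L] - ti[1L] + 1L
  frame_preserved <- ilen %% 3L == 0L
  seq <- spliced_sequence(retaining, genome)
  orf <- find_orf(seq)
  if (is.null(orf) || ti[1L] < orf$start_pos || ti[1L] > orf$stop_pos + 2L) {
    return(list(contains_inframe_stop = NA, frame_preserved = frame_preserved,
                not_applicable = TRUE))
  }
  q0 <- orf$start_pos + 3L * ceiling((ti[1L] - orf$start_pos) / 3L)
  contains <- FALSE
  if (q0 + 2L <= ti[2L]) {
    qs <- seq.int(q0, ti[2L] - 2L, by = 3L)
    codons <- substring(seq, qs, qs + 2L)
    contains <- any(codons %in% .STOP_CODONS)
  }
  list(contains_inframe_stop = contains, frame_preserved = frame_preserved,
       not_applicable = FALSE)
}
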