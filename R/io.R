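#' Read gene models from GFF3 or GTF
#'
#' Accepts both dialects on read (the attribute style is auto-detected).
#' Every mRNA/transcript feature becomes a [transcript_model()] grouped under
#' its gene; exon order is normalised to ascending genomic start; CDS
#' features, when present, are converted to transcript coordinates.
#'
#' Hard errors: a record with `end < start` (reported with its line number),
#' an exon without a resolvable parent transcript, unstranded (`.`) features,
#' and overlapping exons within one transcript.
#'
#' @param path Path to a GFF3 or GTF file.
#' @return Named list of `gene_locus` objects (names are gene ids), sorted by
#'   chromosome and span start.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path, warn = FALSE)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(body) == 0L) stop("no feature lines in ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L))
    stop("malformed GFF/GTF record at line ",
         which(!startsWith(raw, "#") & nzchar(raw))[which(nf < 8L)[1L]])
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  bad <- which(is.na(starts) | is.na(ends) | starts > ends)
  if (length(bad)) {
    lineno <- which(!startsWith(raw, "#") & nzchar(raw))[bad[1L]]
    stop("malformed coordinates (start > end or non-numeric) at line ", lineno,
         " of ", path, ": ", body[bad[1L]])
  }
  is_gtf <- any(grepl("(gene_id|transcript_id) \"", vapply(fields, `[[`, "", 9L), fixed = FALSE))
  gr <- rtracklayer::import(path, format = if (is_gtf) "gtf" else "gff3")

  type <- as.character(gr$type)
  strand <- as.character(GenomicRanges::strand(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)

  if (is_gtf) {
    tx_parent <- as.character(gr$transcript_id)
    gene_of_feat <- as.character(gr$gene_id)
    feat_id <- tx_parent
  } else {
    feat_id <- as.character(gr$ID)
    par <- gr$Parent
    tx_parent <- vapply(seq_along(gr), function(i) {
      p <- par[[i]]
      if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
    }, "")
    gene_of_feat <- tx_parent # for mRNA rows the Parent is the gene
  }

  sel_tx <- type %in% c("mRNA", "transcript")
  sel_ex <- type == "exon"
  sel_cds <- type == "CDS"
  if (!any(sel_ex)) stop("no exon features in ", path)

  # transcript -> gene map
  if (is_gtf) {
    tx_ids <- unique(tx_parent[sel_ex | sel_tx])
    tx_ids <- tx_ids[!is.na(tx_ids)]
    gene_of_tx <- vapply(tx_ids, function(id) {
      g <- unique(gene_of_feat[(sel_ex | sel_tx) & tx_parent == id])
      g[!is.na(g)][1L]
    }, "")
  } else {
    tx_ids <- feat_id[sel_tx]
    gene_of_tx <- stats::setNames(tx_parent[sel_tx], tx_ids)
    gene_of_tx[is.na(gene_of_tx)] <- tx_ids[is.na(gene_of_tx)]
  }

  exon_parent <- tx_parent[sel_ex]
  if (any(is.na(exon_parent) | !nzchar(exon_parent)))
    stop("exon without a parent transcript in ", path)
  orphan <- setdiff(unique(exon_parent), tx_ids)
  if (length(orphan) > 0L && !is_gtf)
    stop("exon parent(s) not declared as mRNA/transcript: ",
         paste(utils::head(orphan, 3L), collapse = ", "))

  ex_df <- data.frame(tx = exon_parent, chrom = chrom[sel_ex],
                      start = st[sel_ex], end = en[sel_ex],
                      strand = strand[sel_ex], stringsAsFactors = FALSE)
  cds_df <- data.frame(tx = tx_parent[sel_cds], start = st[sel_cds],
                       end = en[sel_cds], stringsAsFactors = FALSE)

  transcripts <- lapply(split(ex_df, ex_df$tx), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    strd <- unique(d$strand)
    if (length(strd) != 1L)
      stop("transcript ", d$tx[1L], ": exons on multiple strands")
    if (strd == "*")
      stop("transcript ", d$tx[1L],
           ": unstranded features are rejected (AS classification is strand-dependent)")
    t <- transcript_model(d$tx[1L],
                          gene_id = unname(gene_of_tx[d$tx[1L]]),
                          chrom = d$chrom[1L], strand = strd,
                          exon_start = d$start, exon_end = d$end)
    cd <- cds_df[cds_df$tx == t$transcript_id, , drop = FALSE]
    if (nrow(cd) > 0L) {
      g1 <- min(cd$start); g2 <- max(cd$end)
      tpos <- sort(genomic_to_transcript(t, c(g1, g2)))
      t$cds_span <- tpos
    }
    t
  })
  genes <- vapply(transcripts, `[[`, "", "gene_id")
  loci <- lapply(split(unname(transcripts), genes), function(tx)
    gene_locus(tx[[1L]]$gene_id, tx))
  # deterministic order: chromosome then span start then gene id
  key_chr <- vapply(loci, `[[`, "", "chrom")
  key_pos <- vapply(loci, function(l) l$span[1L], 1L)
  loci[order(key_chr, key_pos, names(loci))]
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and (when a `cds_span` is present) CDS features.
#' `read_gff3(write_gff3(loci))` reproduces the object graph.
#'
#' @param loci Named list of `gene_locus` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path) {
  rows <- list()
  for (l in loci) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = l$chrom, start = l$span[1L], end = l$span[2L],
      strand = l$transcripts[[1L]]$strand, type = "gene",
      ID = l$gene_id, Parent = NA_character_, phase = NA_integer_,
      stringsAsFactors = FALSE)
    for (t in l$transcripts) {
      sp <- transcript_span(t)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = t$chrom, start = sp[1L], end = sp[2L], strand = t$strand,
        type = "mRNA", ID = t$transcript_id, Parent = l$gene_id,
        phase = NA_integer_, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = t$chrom, start = t$exon_start, end = t$exon_end,
        strand = t$strand, type = "exon", ID = NA_character_,
        Parent = t$transcript_id, phase = NA_integer_,
        stringsAsFactors = FALSE)
      if (!is.null(t$cds_span)) {
        g <- sort(transcript_to_genomic(t, t$cds_span))
        cds_rng <- IRanges::IRanges(g[1L], g[2L])
        ex_rng <- IRanges::IRanges(t$exon_start, t$exon_end)
        seg <- IRanges::intersect(ex_rng, cds_rng)
        w <- IRanges::width(seg)
        # phase per segment in translation (mRNA) order
        mrna_ord <- if (t$strand == "+") seq_along(w) else rev(seq_along(w))
        prior <- cumsum(c(0L, w[mrna_ord]))[seq_along(w)]
        phase_mrna <- (3L - prior %% 3L) %% 3L
        phase <- integer(length(w))
        phase[mrna_ord] <- phase_mrna
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = t$chrom, start = IRanges::start(seg), end = IRanges::end(seg),
          strand = t$strand, type = "CDS", ID = NA_character_,
          Parent = t$transcript_id, phase = phase, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$source <- "polysomeAS"
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file path.
#' @return A `DNAStringSet`; names are truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome Named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a per-transcript abundance table
#'
#' Expects a TSV with header `transcript_id<TAB>fpkm`.
#'
#' @param path TSV file path.
#' @return data.frame with character `transcript_id` and numeric `fpkm`.
#' @export
read_abundance <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "fpkm") %in% names(d)))
    stop("abundance table must have header: transcript_id<TAB>fpkm")
  d$fpkm <- as.numeric(d$fpkm)
  if (any(is.na(d$fpkm) | d$fpkm < 0)) stop("FPKM values must be non-negative numbers")
  if (anyDuplicated(d$transcript_id)) stop("duplicated transcript_id in abundance table")
  d[, c("transcript_id", "fpkm")]
}

#' Write a per-transcript abundance table
#' @param abundance data.frame with `transcript_id` and `fpkm` columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(abundance, path) {
  utils::write.table(abundance[, c("transcript_id", "fpkm")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' FPKM lookup with missing ids treated as zero
#'
#' Transcripts absent from the table get FPKM 0 with a warning (id drift
#' between assembler and quantifier output is common and should not abort an
#' analysis).
#'
#' @param abundance Abundance data.frame.
#' @param ids Character vector of transcript ids.
#' @return Named numeric vector of FPKMs in the order of `ids`.
#' @export
fpkm_of <- function(abundance, ids) {
  v <- abundance$fpkm[match(ids, abundance$transcript_id)]
  if (anyNA(v)) {
    warning(sum(is.na(v)), " transcript(s) missing from abundance table; treated as FPKM 0")
    v[is.na(v)] <- 0
  }
  stats::setNames(v, ids)
}

#' Write simulation ground truth as JSON
#' @param truth Ground-truth list from [simulate_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' Read simulation ground truth from JSON
#' @param path JSON path written by [write_ground_truth()].
#' @return List with the ground-truth components as data.frames.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(names(x), c("planted_events", "planted_low_abundance",
                                   "planted_nmd", "true_fpkm")))
    x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  x
}
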