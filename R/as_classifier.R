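#' @keywords internal
.AS_CATEGORIES6 <- c("AA", "AD", "ATE", "RI_SI", "SE_RE", "IWI_TWI")

#' Merge the nine AS classes into six categories
#'
#' Reciprocal/cognate classes collapse: RI and SI (retained vs spliced
#' intron), SE and RE (skipped vs retained exon), IWI and TWI (initiation or
#' termination within an intron); AA, AD and ATE map to themselves.
#'
#' @param category9 Character vector over
#'   `{AA, AD, ATE, SE, RE, IWI, TWI, RI, SI, complex}`.
#' @return Character vector of merged categories.
#' @export
merge_category <- function(category9) {
  map <- c(AA = "AA", AD = "AD", ATE = "ATE", SE = "SE_RE", RE = "SE_RE",
           RI = "RI_SI", SI = "RI_SI", IWI = "IWI_TWI", TWI = "IWI_TWI",
           complex = "complex")
  out <- unname(map[category9])
  if (anyNA(out)) stop("unknown AS class: ",
                       paste(unique(category9[is.na(out)]), collapse = ","))
  out
}

.as_event_row <- function(gene_id, cat9, chrom, start, end, iso_a, iso_b) {
  data.frame(gene_id = gene_id, category9 = cat9,
             category6 = merge_category(cat9), chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             isoform_a = iso_a, isoform_b = iso_b, stringsAsFactors = FALSE)
}

.empty_events <- function() {
  data.frame(gene_id = character(0), category9 = character(0),
             category6 = character(0), chrom = character(0),
             start = integer(0), end = integer(0),
             isoform_a = character(0), isoform_b = character(0),
             stringsAsFactors = FALSE)
}

# does interval (s, e) overlap any exon of t?
.overlaps_any_exon <- function(s, e, t) any(t$exon_start <= e & t$exon_end >= s)

# terminal-end comparison on one genomic side ("left"/"right").
# Returns NULL or a list describing one event. The two mRNA ends are handled
# jointly per side: UTR-only length differences produce no event; a terminus
# falling strictly inside an intron of the other isoform, with its terminal
# exon overlapping a shared exon (contiguous readthrough), is IWI/TWI; two
# mutually non-overlapping terminal exons are a single ATE event.
.terminal_side_event <- function(a, b, side) {
  bound <- function(t) if (side == "right") max(t$exon_end) else min(t$exon_start)
  ba <- bound(a); bb <- bound(b)
  if (ba == bb) return(NULL)
  inner_is_a <- if (side == "right") ba < bb else ba > bb
  y <- if (inner_is_a) a else b   # terminus ends first (inner)
  x <- if (inner_is_a) b else a   # extends further
  ty <- bound(y)
  term_idx <- function(t) if (side == "right") n_exons(t) else 1L
  ey <- c(y$exon_start[term_idx(y)], y$exon_end[term_idx(y)])
  ex <- c(x$exon_start[term_idx(x)], x$exon_end[term_idx(x)])
  if (any(x$exon_start <= ty & x$exon_end >= ty)) return(NULL) # terminus in an exon of x
  ix <- derive_introns(x)
  w <- which(ix$start < ty & ix$end > ty)
  term_intron_idx <- function(t)
    if (side == "right") n_exons(t) - 1L else 1L # may be 0 -> no intron
  if (length(w) == 1L && .overlaps_any_exon(ey[1L], ey[2L], x)) {
    five_prime <- (side == "left") == (a$strand == "+")
    cat9 <- if (five_prime) "IWI" else "TWI"
    return(list(cat9 = cat9, start = ix$start[w], end = ix$end[w],
                iso_a = x$transcript_id, iso_b = y$transcript_id,
                consume = list(c(x$transcript_id, w),
                               c(y$transcript_id, term_intron_idx(y)))))
  }
  if (!.overlaps_any_exon(ey[1L], ey[2L], x) && !.overlaps_any_exon(ex[1L], ex[2L], y)) {
    return(list(cat9 = "ATE", start = ex[1L], end = ex[2L],
                iso_a = x$transcript_id, iso_b = y$transcript_id,
                consume = list(c(x$transcript_id, term_intron_idx(x)),
                               c(y$transcript_id, term_intron_idx(y)))))
  }
  NULL
}

#' Classify the alternative-splicing events between two isoforms
#'
#' Compares two transcript models of the same gene and strand and emits one
#' row per detected event. Classes follow the nine-way PASA-style taxonomy
#' (RI/SI, SE/RE, AA, AD, IWI/TWI, ATE) merged into six categories; an
#' intron pair that differs at both the donor and the acceptor is reported as
#' `complex` and excluded from the six-category tables.
#'
#' Detection order (each intron is consumed by at most one class):
#' intron retention (an intron of one isoform lying inside a single exon of
#' the other), exon skipping (an internal exon inside a single intron of the
#' other), the two mRNA termini (IWI/TWI and ATE, handled jointly per side),
#' then alternate acceptor/donor among the remaining introns. AA/AD
#' additionally requires the exon flanking the differing splice site in each
#' isoform to overlap an exon of the other isoform, so terminal-exon
#' rearrangements are never binned as splice-site shifts. Terminal-exon
#' length differences confined to UTRs produce no event.
#'
#' Roles are structure-determined so that `classify_pair(a, b)` and
#' `classify_pair(b, a)` return identical tables: for RI/SI `isoform_a` is
#' the retaining isoform, for SE/RE the exon-retaining one, for IWI/TWI and
#' ATE the further-extending one; for AA/AD and complex the lexicographically
#' smaller id.
#'
#' @param a,b `transcript_model` objects of the same gene and strand whose
#'   genomic spans overlap.
#' @return data.frame with columns `gene_id`, `category9`, `category6`,
#'   `chrom`, `start`, `end` (the affected genomic interval), `isoform_a`,
#'   `isoform_b`.
#' @export
classify_pair <- function(a, b) {
  if (a$gene_id != b$gene_id) stop("isoforms belong to different genes")
  if (a$strand != b$strand) stop("isoforms on different strands")
  if (a$transcript_id == b$transcript_id) stop("cannot classify a transcript against itself")
  sa <- transcript_span(a); sb <- transcript_span(b)
  if (sa[1L] > sb[2L] || sb[1L] > sa[2L]) return(.empty_events())

  ia <- derive_introns(a); ib <- derive_introns(b)
  consumed <- list(rep(FALSE, nrow(ia)), rep(FALSE, nrow(ib)))
  names(consumed) <- c(a$transcript_id, b$transcript_id)
  rows <- list()
  gene <- a$gene_id; chrom <- a$chrom
  same_intron <- function(s, e, d) any(d$start == s & d$end == e)

  # --- intron retention (RI/SI) ---
  for (dir in 1:2) {
    ret <- if (dir == 1L) a else b    # candidate retainer
    spl <- if (dir == 1L) b else a    # candidate splicer
    di <- if (dir == 1L) ib else ia
    dr <- if (dir == 1L) ia else ib
    if (nrow(di) == 0L) next
    for (i in seq_len(nrow(di))) {
      s <- di$start[i]; e <- di$end[i]
      inside <- any(ret$exon_start < s & ret$exon_end > e)
      if (inside && !same_intron(s, e, dr)) {
        rows[[length(rows) + 1L]] <- .as_event_row(
          gene, "RI", chrom, s, e, ret$transcript_id, spl$transcript_id)
        consumed[[spl$transcript_id]][i] <- TRUE
      }
    }
  }

  # --- exon skipping (SE/RE) ---
  for (dir in 1:2) {
    keep <- if (dir == 1L) a else b   # isoform retaining the exon (RE side)
    skip <- if (dir == 1L) b else a   # isoform skipping it (SE side)
    dkeep <- if (dir == 1L) ia else ib
    dskip <- if (dir == 1L) ib else ia
    n <- n_exons(keep)
    if (n < 3L || nrow(dskip) == 0L) next
    for (k in 2:(n - 1L)) {
      es <- keep$exon_start[k]; ee <- keep$exon_end[k]
      j <- which(dskip$start <= es & dskip$end >= ee)
      if (length(j) == 1L) {
        rows[[length(rows) + 1L]] <- .as_event_row(
          gene, "SE", chrom, es, ee, keep$transcript_id, skip$transcript_id)
        consumed[[skip$transcript_id]][j] <- TRUE
        consumed[[keep$transcript_id]][c(k - 1L, k)] <- TRUE
      }
    }
  }

  # --- transcript termini (IWI/TWI and ATE), one joint decision per side ---
  for (side in c("left", "right")) {
    ev <- .terminal_side_event(a, b, side)
    if (!is.null(ev)) {
      rows[[length(rows) + 1L]] <- .as_event_row(
        gene, ev$cat9, chrom, ev$start, ev$end, ev$iso_a, ev$iso_b)
      for (cn in ev$consume) {
        idx <- as.integer(cn[2L])
        if (idx >= 1L && idx <= length(consumed[[cn[1L]]]))
          consumed[[cn[1L]]][idx] <- TRUE
      }
    }
  }

  # --- alternate acceptor / donor among unconsumed introns ---
  plus <- a$strand == "+"
  iso_lo <- min(a$transcript_id, b$transcript_id)
  iso_hi <- max(a$transcript_id, b$transcript_id)
  if (nrow(ia) > 0L && nrow(ib) > 0L) {
    for (i in seq_len(nrow(ia))) {
      if (consumed[[a$transcript_id]][i]) next
      for (j in seq_len(nrow(ib))) {
        if (consumed[[b$transcript_id]][j]) next
        sA <- ia$start[i]; eA <- ia$end[i]; sB <- ib$start[j]; eB <- ib$end[j]
        if (sA == sB && eA == eB) next
        dA <- if (plus) sA else eA; dB <- if (plus) sB else eB
        aA <- if (plus) eA else sA; aB <- if (plus) eB else sB
        if (dA == dB && aA != aB) {
          # alternate acceptor; guard on the acceptor-flanking exons
          fa <- if (plus) i + 1L else i
          fb <- if (plus) j + 1L else j
          okA <- .overlaps_any_exon(a$exon_start[fa], a$exon_end[fa], b)
          okB <- .overlaps_any_exon(b$exon_start[fb], b$exon_end[fb], a)
          if (okA && okB)
            rows[[length(rows) + 1L]] <- .as_event_row(
              gene, "AA", chrom, min(aA, aB), max(aA, aB), iso_lo, iso_hi)
        } else if (aA == aB && dA != dB) {
          fa <- if (plus) i else i + 1L
          fb <- if (plus) j else j + 1L
          okA <- .overlaps_any_exon(a$exon_start[fa], a$exon_end[fa], b)
          okB <- .overlaps_any_exon(b$exon_start[fb], b$exon_end[fb], a)
          if (okA && okB)
            rows[[length(rows) + 1L]] <- .as_event_row(
              gene, "AD", chrom, min(dA, dB), max(dA, dB), iso_lo, iso_hi)
        } else if (sA <= eB && sB <= eA) {
          # overlapping introns differing at both ends: outside the taxonomy
          rows[[length(rows) + 1L]] <- .as_event_row(
            gene, "complex", chrom, min(sA, sB), max(eA, eB), iso_lo, iso_hi)
        }
      }
    }
  }

  if (length(rows) == 0L) return(.empty_events())
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("category6", "start", "end")]), , drop = FALSE]
}

#' Classify all alternative-splicing events of a transcriptome
#'
#' Classifies every unordered isoform pair of every locus, deduplicates
#' events by (gene, merged category, affected interval), and computes the
#' per-category summary. `complex` intron pairs are returned separately and
#' excluded from the six-category table and event count.
#'
#' @param loci Named list of `gene_locus` objects.
#' @return List with elements `events` (deduplicated, deterministically
#'   sorted data.frame), `complex_events`, and `summary` (see [as_rate()]).
#' @export
classify_transcriptome <- function(loci) {
  evs <- list()
  for (l in loci) {
    tx <- l$transcripts
    n <- length(tx)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      e <- classify_pair(tx[[i]], tx[[j]])
      if (nrow(e)) evs[[length(evs) + 1L]] <- e
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else .empty_events()
  dedup_key <- paste(events$gene_id, events$category6, events$chrom,
                     events$start, events$end)
  events <- events[!duplicated(dedup_key), , drop = FALSE]
  ord <- order(events$chrom, events$start, events$category6, events$end,
               events$gene_id)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  cplx <- events[events$category6 == "complex", , drop = FALSE]
  events <- events[events$category6 != "complex", , drop = FALSE]
  rownames(events) <- rownames(cplx) <- NULL
  list(events = events, complex_events = cplx,
       summary = as_rate(loci, events))
}

#' Per-category event counts and the AS-gene rate
#'
#' The AS rate follows the ratio definition used for annotation summaries:
#' genes with more than one isoform divided by intron-containing genes
#' (genes any of whose isoforms has at least one intron), as a percent.
#' With no intron-containing genes the rate is undefined (`NA`).
#'
#' @param loci Named list of `gene_locus` objects.
#' @param events Event data.frame from [classify_transcriptome()].
#' @return List with `n_events`, `per_category6` (data.frame of count and
#'   percent per category), `n_genes_detected`, `n_intron_containing_genes`,
#'   `n_as_genes`, `as_rate` (percent or `NA`).
#' @export
as_rate <- function(loci, events) {
  counts <- table(factor(events$category6, levels = .AS_CATEGORIES6))
  n_events <- nrow(events)
  per_cat <- data.frame(category6 = .AS_CATEGORIES6,
                        count = as.integer(counts),
                        percent = if (n_events > 0)
                          100 * as.integer(counts) / n_events else
                          rep(NA_real_, length(.AS_CATEGORIES6)),
                        stringsAsFactors = FALSE)
  n_intronic <- sum(vapply(loci, function(l)
    any(vapply(l$transcripts, n_exons, 1L) >= 2L), TRUE))
  n_as <- sum(vapply(loci, function(l) length(l$transcripts) >= 2L, TRUE))
  list(n_events = n_events, per_category6 = per_cat,
       n_genes_detected = length(loci),
       n_intron_containing_genes = n_intronic, n_as_genes = n_as,
       as_rate = if (n_intronic > 0) 100 * n_as / n_intronic else NA_real_)
}
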