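#' Summary statistics for a pool of intron sizes
#'
#' @param lengths Integer vector of intron lengths (nt).
#' @return List with `n`, `mean_nt`, `median_nt` (midpoint rule for even n),
#'   `fraction_below_200nt` (strict `< 200`); the stats are `NA` for an
#'   empty pool.
#' @export
size_stats <- function(lengths) {
  n <- length(lengths)
  if (n == 0L)
    return(list(n = 0L, mean_nt = NA_real_, median_nt = NA_real_,
                fraction_below_200nt = NA_real_))
  list(n = n, mean_nt = mean(lengths), median_nt = stats::median(lengths),
       fraction_below_200nt = mean(lengths < 200))
}

#' Intron sizes pooled over a whole annotation
#'
#' Pools the intron lengths of every transcript of every locus, without
#' deduplicating identical introns shared between isoforms (set
#' `deduplicate = TRUE` for the deduplicated variant, or
#' `representative_only = TRUE` to restrict to one representative model per
#' gene).
#'
#' @param loci Named list of `gene_locus` objects.
#' @param representative_only Use only [select_representative()] per gene.
#' @param deduplicate Count each distinct genomic intron once per gene.
#' @return List with `lengths` (integer vector) and `stats`
#'   (see [size_stats()]).
#' @export
all_intron_sizes <- function(loci, representative_only = FALSE,
                             deduplicate = FALSE) {
  lens <- integer(0)
  for (l in loci) {
    tx <- if (representative_only) list(select_representative(l)) else l$transcripts
    ins <- lapply(tx, derive_introns)
    d <- do.call(rbind, ins)
    if (is.null(d) || nrow(d) == 0L) next
    if (deduplicate) d <- d[!duplicated(d), , drop = FALSE]
    lens <- c(lens, d$end - d$start + 1L)
  }
  list(lengths = lens, stats = size_stats(lens))
}

#' Sizes of retained introns from deduplicated RI/SI events
#'
#' One length per deduplicated retained-intron event (the affected genomic
#' interval).
#'
#' @param events Event data.frame containing only RI_SI rows.
#' @return List with `lengths` and `stats` (see [size_stats()]).
#' @export
retained_intron_sizes <- function(events) {
  if (nrow(events) > 0L && any(events$category6 != "RI_SI"))
    stop("retained_intron_sizes expects RI_SI events only")
  lens <- as.integer(events$end - events$start + 1L)
  list(lengths = lens, stats = size_stats(lens))
}
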