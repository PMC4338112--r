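#' Total FPKM per locus
#'
#' Locus expression is the sum of the FPKMs of all member transcripts on the
#' *input* membership. Transcripts missing from the abundance table count as
#' 0 (with a warning from [fpkm_of()]).
#'
#' @param abundance Abundance data.frame (`transcript_id`, `fpkm`).
#' @param loci Named list of `gene_locus` objects.
#' @return Named numeric vector, one total per gene id.
#' @export
locus_totals <- function(abundance, loci) {
  vapply(loci, function(l)
    sum(fpkm_of(abundance, names(l$transcripts))), 1.0)
}

#' Two-part low-abundance isoform filter
#'
#' Keeps a transcript iff its FPKM is at least `fpkm_min` *and* it represents
#' at least `isoform_fraction_min` of the total expression of its locus
#' (candidate included in the denominator). Locus totals are computed once on
#' the pre-filter membership — a single pass, so the filter is idempotent.
#' A locus with zero total expression drops all members (the fraction is
#' undefined, which counts as a fraction failure).
#'
#' @param abundance Abundance data.frame.
#' @param loci Named list of `gene_locus` objects.
#' @param config An [analysis_config()].
#' @return List with `kept` (character vector of transcript ids) and
#'   `report`: `n_input`, `n_kept`, `n_dropped`, `pct_dropped`, and
#'   `per_criterion` counts (`fpkm_fail`, `fraction_fail`, `both_fail`).
#' @export
filter_isoforms <- function(abundance, loci, config = analysis_config()) {
  totals <- locus_totals(abundance, loci)
  kept <- character(0)
  crit <- c(fpkm_fail = 0L, fraction_fail = 0L, both_fail = 0L)
  dropped <- character(0)
  drop_crit <- character(0)
  for (l in loci) {
    ids <- names(l$transcripts)
    v <- suppressWarnings(fpkm_of(abundance, ids))
    tot <- totals[[l$gene_id]]
    frac_ok <- if (tot > 0) (v / tot) >= config$isoform_fraction_min else rep(FALSE, length(v))
    fpkm_ok <- v >= config$fpkm_min
    keep <- fpkm_ok & frac_ok
    kept <- c(kept, ids[keep])
    if (any(!keep)) {
      f_fail <- !fpkm_ok[!keep]
      r_fail <- !frac_ok[!keep]
      lab <- ifelse(f_fail & r_fail, "both_fail",
                    ifelse(f_fail, "fpkm_fail", "fraction_fail"))
      dropped <- c(dropped, ids[!keep])
      drop_crit <- c(drop_crit, lab)
    }
  }
  tab <- table(factor(drop_crit, levels = names(crit)))
  crit[names(tab)] <- as.integer(tab)
  n_input <- sum(vapply(loci, function(l) length(l$transcripts), 1L))
  report <- list(n_input = n_input, n_kept = length(kept),
                 n_dropped = length(dropped),
                 pct_dropped = if (n_input > 0) 100 * length(dropped) / n_input else 0,
                 per_criterion = as.list(crit),
                 dropped = data.frame(transcript_id = dropped,
                                      criterion = drop_crit,
                                      stringsAsFactors = FALSE))
  list(kept = kept, report = report)
}
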