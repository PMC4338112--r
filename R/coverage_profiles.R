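#' Construct a per-base coverage track
#'
#' @param depth Named list of non-negative numeric vectors, one per
#'   chromosome, with one entry per base.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(depth) {
  if (is.null(names(depth)) || any(!nzchar(names(depth))))
    stop("coverage track chromosomes must be named")
  if (any(vapply(depth, function(v) any(v < 0), TRUE)))
    stop("coverage depths must be non-negative")
  structure(depth, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), %.0f covered bases\n",
              length(x), sum(vapply(x, function(v) sum(v > 0), 1.0))))
  invisible(x)
}

.chrom_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    return(stats::setNames(Biostrings::width(genome), names(genome)))
  if (is.character(genome)) return(vapply(genome, nchar, 1L))
  unlist(genome)
}

#' Read a bedGraph file into a dense per-base coverage track
#'
#' bedGraph intervals are 0-based half-open; they are converted to the
#' package's 1-based closed convention at this boundary. Bases absent from
#' the file get depth 0. Intervals beyond the chromosome end, or overlapping
#' intervals (which bedGraph forbids), raise hard errors.
#'
#' @param path bedGraph file path.
#' @param genome `DNAStringSet`, named character vector of sequences, or
#'   named vector/list of chromosome lengths.
#' @return A [coverage_track()] covering every chromosome of `genome`.
#' @export
read_bedgraph <- function(path, genome) {
  lens <- .chrom_lengths(genome)
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chrom), names(lens))
  if (length(unknown))
    stop("bedGraph chromosome(s) not in genome: ", paste(unknown, collapse = ","))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  if (any(en > lens[chrom]))
    stop("bedGraph interval beyond chromosome end in ", path)
  depth <- lapply(lens, numeric)
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    s <- st[sel]; e <- en[sel]; v <- gr$score[sel]
    o <- order(s)
    s <- s[o]; e <- e[o]; v <- v[o]
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      stop("overlapping bedGraph intervals on ", cn, " (bedGraph forbids overlap)")
    for (i in seq_along(s)) depth[[cn]][s[i]:e[i]] <- v[i]
  }
  coverage_track(depth)
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted (they are implicit on read).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  chroms <- character(0); starts <- integer(0); ends <- integer(0)
  scores <- numeric(0)
  for (cn in names(track)) {
    r <- rle(track[[cn]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- r$values != 0
    chroms <- c(chroms, rep(cn, sum(keep)))
    starts <- c(starts, s[keep]); ends <- c(ends, e[keep])
    scores <- c(scores, r$values[keep])
  }
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, ends),
                               score = scores)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Binned chromosome read-density profile
#'
#' Splits each chromosome into fixed non-overlapping bins of `bin_nt` bases
#' (final partial bin included) and reports `log2(median per-base depth + 1)`
#' per bin — the +1 pseudocount keeps zero-coverage bins finite while
#' preserving ordering.
#'
#' @param track A [coverage_track()].
#' @param bin_nt Bin width in bases (>= 1).
#' @return data.frame with `chrom`, `bin`, `start`, `end`, `value`.
#' @export
chromosome_density <- function(track, bin_nt = 100000L) {
  stopifnot(bin_nt >= 1L)
  rows <- lapply(names(track), function(cn) {
    v <- track[[cn]]
    n <- length(v)
    nb <- ceiling(n / bin_nt)
    s <- (seq_len(nb) - 1L) * bin_nt + 1L
    e <- pmin(seq_len(nb) * bin_nt, n)
    val <- vapply(seq_len(nb), function(b)
      log2(stats::median(v[s[b]:e[b]]) + 1), 1.0)
    data.frame(chrom = cn, bin = seq_len(nb), start = s, end = e,
               value = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# exonic depth of a transcript in mRNA (5'->3') order
.tx_depth <- function(track, t) {
  v <- unlist(lapply(seq_len(n_exons(t)), function(k)
    track[[t$chrom]][t$exon_start[k]:t$exon_end[k]]), use.names = FALSE)
  if (t$strand == "-") rev(v) else v
}

#' Normalised transcription-unit (metagene) coverage profile
#'
#' For each gene's representative transcript (longest CDS, see
#' [select_representative()]), the exonic per-base depths are read 5' to 3'
#' on the mRNA and sampled at `metagene_bins` evenly spaced relative
#' positions (0% to 100%, nearest-base lookup). The profile value at each
#' relative position is `log2(median across genes + 1)`.
#'
#' @param track A [coverage_track()].
#' @param loci Named list of `gene_locus` objects.
#' @param config An [analysis_config()].
#' @return Numeric vector of length `config$metagene_bins`.
#' @export
metagene_profile <- function(track, loci, config = analysis_config()) {
  bins <- config$metagene_bins
  mat <- vapply(loci, function(l) {
    t <- select_representative(l)
    v <- .tx_depth(track, t)
    v[round(seq(1, length(v), length.out = bins))]
  }, numeric(bins))
  log2(apply(matrix(mat, nrow = bins), 1L, stats::median) + 1)
}

#' Fraction of each cDNA covered by reads
#'
#' Per transcript, the fraction of exonic bases with depth >= 1; the summary
#' reports the quartiles of that distribution (the headline statistic being
#' the median: half the cDNAs have at least that fraction of their length
#' represented).
#'
#' @param track A [coverage_track()].
#' @param loci Named list of `gene_locus` objects.
#' @return List with `per_transcript` (data.frame: `transcript_id`,
#'   `fraction`) and `summary` (named quartile vector `q25`, `median`,
#'   `q75`).
#' @export
cdna_coverage_fractions <- function(track, loci) {
  tx <- all_transcripts(loci)
  frac <- vapply(tx, function(t) mean(.tx_depth(track, t) >= 1), 1.0)
  q <- stats::quantile(frac, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_transcript = data.frame(transcript_id = names(tx),
                                   fraction = unname(frac),
                                   stringsAsFactors = FALSE),
       summary = c(q25 = q[1L], median = q[2L], q75 = q[3L]))
}
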