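#!/usr/bin/env Rscript
# Step 4 — PTC/NMD assessment and retained-intron analyses.
#
# For each filtered transcriptome: find each transcript's ORF, apply the
# 55-nt rule against the last exon-exon junction, scan retained introns for
# in-frame stop codons (the readthrough question), and summarise intron
# sizes overall and for retained introns.

suppressPackageStartupMessages(library(polysomeAS))

for (which in c("total", "polysomal")) {
  kept <- file.path("results", paste0("kept_", which, ".gff3"))
  evp <- file.path("results", paste0("events_", which, ".tsv"))
  if (!file.exists(evp)) stop("run analysis/03_classify.R first")
  loci <- read_gff3(kept)
  genome <- read_genome_fasta(file.path("results", "data", which, "genome.fa"))
  events <- utils::read.delim(evp, stringsAsFactors = FALSE)

  nmd <- assess_nmd_all(loci, genome)
  as_genes <- names(loci)[vapply(loci, function(l)
    length(l$transcripts) >= 2L, TRUE)]
  nmd_as <- nmd[nmd$gene_id %in% as_genes, ]
  message(sprintf("%s: %.1f%% of isoforms at AS loci are NMD candidates (>55 nt rule)",
                  which, 100 * mean(nmd_as$is_nmd_candidate)))
  utils::write.table(nmd, file.path("results", paste0("nmd_", which, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ri <- events[events$category6 == "RI_SI", ]
  scans <- lapply(seq_len(nrow(ri)), function(i)
    intron_stop_scan(ri[i, ], loci[[ri$gene_id[i]]]$transcripts[[ri$isoform_a[i]]],
                     genome))
  ok <- !vapply(scans, `[[`, TRUE, "not_applicable")
  with_stop <- vapply(scans, function(x) isTRUE(x$contains_inframe_stop), TRUE)
  message(sprintf("  %d/%d scanned retained introns contain an in-frame stop (%.0f%%)",
                  sum(with_stop[ok]), sum(ok), 100 * mean(with_stop[ok])))

  sizes <- list(all_introns = all_intron_sizes(loci)$stats,
                retained_introns = retained_intron_sizes(ri)$stats,
                retained_with_inframe_stop = list(
                  n_scanned = sum(ok), n_with_stop = sum(with_stop[ok]),
                  pct = 100 * mean(with_stop[ok])))
  message(sprintf("  retained introns: mean %.0f nt, median %.0f nt, %.0f%% below 200 nt",
                  sizes$retained_introns$mean_nt,
                  sizes$retained_introns$median_nt,
                  100 * sizes$retained_introns$fraction_below_200nt))
  jsonlite::write_json(sizes,
                       file.path("results", paste0("introns_", which, ".json")),
                       auto_unbox = TRUE, digits = NA)
}
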