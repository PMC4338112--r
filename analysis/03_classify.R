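#!/usr/bin/env Rscript
# Step 3 — alternative-splicing event classification.
#
# Classifies every isoform pair of the filtered transcriptomes into the six
# merged AS categories and writes the per-sample event tables and category
# summaries (the inputs to the two-sample proportion test in step 6).

suppressPackageStartupMessages(library(polysomeAS))

for (which in c("total", "polysomal")) {
  kept <- file.path("results", paste0("kept_", which, ".gff3"))
  if (!file.exists(kept)) stop("run analysis/02_filter.R first")
  loci <- read_gff3(kept)
  cls <- classify_transcriptome(loci)
  s <- cls$summary
  message(sprintf("%s: %d events over %d AS genes (AS rate %.1f%% of %d intron-containing genes)",
                  which, s$n_events, s$n_as_genes, s$as_rate,
                  s$n_intron_containing_genes))
  pc <- s$per_category6
  message("  ", paste(sprintf("%s %.1f%%", pc$category6, pc$percent),
                      collapse = ", "))
  utils::write.table(cls$events,
                     file.path("results", paste0("events_", which, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_events = s$n_events, per_category6 = s$per_category6,
         n_genes_detected = s$n_genes_detected,
         n_intron_containing_genes = s$n_intron_containing_genes,
         n_as_genes = s$n_as_genes, as_rate = s$as_rate),
    file.path("results", paste0("as_summary_", which, ".json")),
    auto_unbox = TRUE, digits = NA)
}
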