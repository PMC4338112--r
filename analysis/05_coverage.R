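#!/usr/bin/env Rscript
# Step 5 — coverage profiles.
#
# Three views of the per-base coverage track for each sample: binned
# chromosome density (log2 of median depth + 1), the normalised
# transcription-unit (metagene) profile over representative models, and the
# per-cDNA covered fraction with its quartiles.

suppressPackageStartupMessages(library(polysomeAS))

for (which in c("total", "polysomal")) {
  dir <- file.path("results", "data", which)
  if (!file.exists(file.path(dir, "coverage.bedgraph")))
    stop("run analysis/01_simulate.R first")
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  loci <- read_gff3(file.path(dir, "models.gff3"))
  cov <- read_bedgraph(file.path(dir, "coverage.bedgraph"), genome)

  dens <- chromosome_density(cov, bin_nt = 100000L)
  utils::write.table(dens,
                     file.path("results", paste0("chrom_density_", which, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prof <- metagene_profile(cov, loci)
  utils::write.table(
    data.frame(relative_pos_pct = seq(0, 100, length.out = length(prof)),
               log2_median_depth = prof),
    file.path("results", paste0("metagene_", which, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  core <- prof[11:91]
  message(sprintf("%s: metagene profile flat within %.1f%% over the 10-90%% span",
                  which, 100 * max(abs(core - prof[51]) / prof[51])))

  cc <- cdna_coverage_fractions(cov, loci)
  message(sprintf("  cDNA coverage quartiles: q25 %.3f, median %.3f, q75 %.3f",
                  cc$summary[["q25"]], cc$summary[["median"]],
                  cc$summary[["q75"]]))
  utils::write.table(cc$per_transcript,
                     file.path("results", paste0("cdna_coverage_", which, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
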