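# polysomeAS

Compare alternative splicing between a **total-RNA transcriptome** and a
**polyribosome-associated transcriptome** (the translatome).

Total cellular RNA contains incompletely spliced nuclear pre-mRNA alongside
mature mRNA, so transcriptome assemblies built from it include splice
isoforms — retained introns above all — that may never reach a ribosome.
Sequencing RNA recovered from immunopurified polysomes samples only mRNAs
engaged in translation. `polysomeAS` takes the end products of assembly and
quantification for two such samples — transcript models (GFF3/GTF) on a
shared genome (FASTA), per-transcript FPKM tables (TSV), optional per-base
coverage (bedGraph) — and runs the comparison:

1. **Low-abundance isoform filter** — keep an isoform iff FPKM ≥ 1 *and*
   it is ≥ 3% of its locus's summed FPKM, with a per-criterion attrition
   report.
2. **AS event classification** — pairwise structural comparison of
   isoforms into the nine classic classes (RI/SI, SE/RE, AA, AD, ATE,
   IWI/TWI) merged into six categories, deduplicated by affected genomic
   interval.
3. **PTC / NMD assessment** — longest-AUG ORF per transcript and the
   *55-nt rule*: a stop codon more than 55 nt (strict) upstream of the last
   exon–exon junction flags a likely nonsense-mediated-decay substrate.
   Retained introns are additionally scanned for in-frame stop codons (can
   translation read through the unspliced intron?).
4. **Intron size statistics** — pooled and retained-intron size
   distributions (mean, median, fraction below 200 nt).
5. **Coverage profiles** — binned chromosome density, a normalised
   0–100% transcription-unit (metagene) profile over representative
   models, per-cDNA covered fractions.
6. **Two-sample statistics** — likelihood-ratio G-test
   `G = 2 Σ O·ln(O/E)` on the 2×6 category table (and on retained-intron
   vs rest), Mann–Whitney–Wilcoxon on retained-intron sizes, and
   structural matching of assemblies against a reference annotation
   (≥80% contiguous mRNA coverage, ≥95% identity).

Because ground truth is unknowable for real libraries, the package includes
a deterministic **synthetic transcriptome generator** that plants AS events
of every category, low-abundance isoforms violating known filter criteria,
and PTC transcripts at controlled stop-to-junction distances — every
pipeline stage is tested by exact recovery of what was planted. See the
methods vignette (`vignettes/translatome-splicing.Rmd`) for the design.

## Worked example

The `analysis/` scripts run the whole study on synthetic data, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # two samples + ground truth (FASTA/GFF3/TSV/bedGraph/JSON)
Rscript analysis/02_filter.R       # low-abundance filtering
Rscript analysis/03_classify.R     # AS event classification
Rscript analysis/04_nmd_introns.R  # 55-nt rule + retained-intron scans
Rscript analysis/05_coverage.R     # coverage profiles
Rscript analysis/06_compare.R      # the two-sample comparison
```

The final step prints (seed 1):

```
Two-sample alternative-splicing comparison
Category counts:
          AA AD ATE RI_SI SE_RE IWI_TWI
total     52 31  18   128    13      33
polysomal 72 45  20    58    15      39
total: 975/1200 isoforms kept (18.8% dropped); 275 events; AS rate 39.3%; NMD candidates 21.8%; retained introns with stop 97.1%
polysomal: 949/950 isoforms kept (0.1% dropped); 249 events; AS rate 35.6%; NMD candidates 17.7%; retained introns with stop 98.1%
2x6 category G-test: G-test: G = 32.3, df = 5, p = 5.191e-06
RI/SI vs rest G-test: G-test: G = 31.46, df = 1, p = 2.038e-08
Retained-intron sizes: Mann-Whitney-Wilcoxon: U = 3467.5, p = 0.4731 (normal_approx)
```

Reading it: the total sample loses 18.8% of its isoforms to the
low-abundance filter while the polysomal sample loses 0.1%; after
filtering, 46.5% of the total sample's AS events are retained introns
against 23.3% in the polysomal sample, a difference the G-test calls highly
significant — the expected signature of pre-mRNA contamination in total
RNA. Nearly all retained introns carry an in-frame stop in this synthetic
scenario because their sequence is random; the retained-intron *size*
distributions do not differ (rank-sum p = 0.47) because none was planted.

Equivalent calls in R, on anything that parses as gene models + FPKMs:

```r
library(polysomeAS)
loci <- read_gff3("models.gff3")
ab   <- read_abundance("abundance.tsv")
kept <- filter_isoforms(ab, loci)
cls  <- classify_transcriptome(subset_loci(loci, kept$kept))
cls$summary$per_category6
```

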