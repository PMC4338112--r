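---
title: "Comparing splicing between a transcriptome and a translatome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing splicing between a transcriptome and a translatome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the approach

RNA-seq libraries made from total cellular RNA contain a mixture of mature
cytoplasmic mRNA and incompletely spliced nuclear pre-mRNA. Transcriptome
assemblies built from such libraries therefore include splice isoforms —
retained introns above all — that may never be translated. Sequencing RNA
recovered from immunopurified polyribosomes (the translatome) samples only
mRNAs engaged by ribosomes, and comparing the two assemblies asks which
isoforms are real substrates of translation.

`polysomeAS` implements that comparison as a reusable pipeline operating on
the *end products* of assembly and quantification: transcript models
(GFF3/GTF anchored on a genome FASTA), a per-transcript FPKM table, and
optionally a per-base coverage track (bedGraph). Read alignment, de novo or
genome-guided assembly, and quantification are upstream tools' jobs and are
out of scope. Because the interesting behaviour of every stage depends on
ground truth that real data cannot supply, the package ships a synthetic
transcriptome generator that plants known events, known low-abundance
isoforms and known premature stop codons, and every stage is tested by exact
recovery of what was planted.

## Pipeline stages

### Low-abundance isoform filter

An isoform is kept iff its FPKM is at least `fpkm_min` (default 1) **and**
it represents at least `isoform_fraction_min` (default 3%) of the summed
FPKM of its locus. Both comparisons are `>=` ("at least"). Two design
points deserve justification:

* **Locus totals are computed once, on the pre-filter membership.** If
  totals were recomputed after dropping isoforms, the 3% denominators would
  shrink and previously passing isoforms could change status, making the
  result depend on iteration order. With a single pass the filter is
  provably idempotent (dropping members only raises survivors' fractions).
* **The candidate is included in its own denominator.** The alternative
  (fraction of the *other* isoforms' expression) is stricter; including the
  candidate is the natural reading of "expression level of that locus" and
  keeps the fraction bounded by 1. A locus with zero total expression drops
  all members — the fraction is undefined, which we count as a fraction
  failure.

The filter report tallies which criterion failed per dropped isoform
(`fpkm_fail`, `fraction_fail`, `both_fail`), and the generator plants
isoforms violating exactly one recorded criterion so the tallies are
testable, not just the kept set.

### AS event classification

Isoform pairs within a locus are compared structurally and events are
assigned to the nine classic classes — retained/spliced intron (RI/SI),
skipped/retained exon (SE/RE), alternate acceptor (AA), alternate donor
(AD), alternate terminal exon (ATE), initiation/termination within an
intron (IWI/TWI) — merged into six categories by collapsing the reciprocal
pairs (an assembly showing SI is the cognate of one showing RI, and so on).
Donor means the 5' splice site of an intron and acceptor the 3' site, so
the AA/AD assignment is strand-aware.

Structural taxonomies are only well-defined with explicit precedence. Ours,
with each intron consumed by at most one category:

1. **RI/SI**: an intron of one isoform lies strictly inside a single exon
   of the other and is absent from the other's intron set. A merged exon
   spanning several introns yields one event per contained intron.
2. **SE/RE**: an *internal* exon of one isoform lies inside a single intron
   of the other. The skipping isoform's bridging intron and the retaining
   isoform's two flanking introns are consumed, since they share boundaries
   by construction and would otherwise masquerade as AA/AD.
3. **Termini**, one joint decision per mRNA end:
   * equal ends, or an end falling inside an exon of the other isoform
     (a pure UTR length difference): no event;
   * the shorter isoform's terminus falls strictly inside an intron of the
     other, and its terminal exon overlaps a shared exon (a contiguous
     read-through into the intron): IWI or TWI depending on which mRNA end,
     with the containing intron as the affected interval;
   * the two terminal exons overlap no exon of the other isoform at all:
     one ATE event, with the further-extending isoform's terminal exon as
     the affected interval.

   The ends must be decided jointly: an alternate terminal exon necessarily
   leaves the other isoform's old terminal exon inside its final intron, so
   testing the IWI/TWI predicate in isolation would double-count every ATE
   pair (and a "terminal exon fully inside an intron" variant of the
   IWI/TWI rule is literally indistinguishable from an ATE pair). The
   exon-overlap requirement — the read-through signature — is what makes
   the two categories disjoint.
4. **AA/AD** among the surviving introns: two introns sharing a donor but
   not an acceptor are AA (shared acceptor, differing donor: AD), *guarded*
   by requiring the exon flanking the differing boundary in each isoform to
   overlap an exon of the other isoform. Without the guard, terminal
   rearrangements whose introns share one boundary with a reference intron
   are mis-binned as splice-site shifts.
5. Overlapping intron pairs differing at **both** ends fit none of the nine
   classes. They are reported in a separate `complex` bucket excluded from
   the six-category table rather than forced into AA or AD, which would
   silently corrupt the proportions the comparison tests.

Events are deduplicated by (gene, merged category, affected genomic
interval) — several isoform pairs supporting the same coordinate-identical
event count once — and roles are structure-determined (the retaining
isoform, the exon-keeping isoform, the further-extending isoform), so the
output is invariant to the order in which isoforms are supplied.

The AS gene rate follows the ratio definition used in annotation summaries:
genes with more than one isoform over intron-containing genes (any isoform
with at least one intron), as a percent; with no intron-containing genes it
is reported as undefined rather than zero.

### ORFs, PTCs and the 55-nt rule

Assembled isoforms typically carry no CDS annotation, so the default ORF is
the longest AUG-initiated open reading frame of the spliced sequence (ties
break to the 5'-most start; the stop codon counts toward the length). When
a CDS *is* annotated, `analysis_config(use_annotated_cds = TRUE)` uses it
instead; the default remains the sequence-derived ORF because mixing the
two regimes within one sample would bias the comparison.

A transcript is PTC-bearing when its stop codon lies upstream of the last
exon–exon junction, and an NMD candidate when the distance from the *first
base of the stop codon* to that junction exceeds 55 nt — a strict
inequality, so 55 nt is not a candidate and 56 nt is. We measure against
the last junction (not "any junction") because a junction downstream of the
terminating ribosome is what deposits the exon-junction complex that
triggers decay; with that choice candidacy is monotone in the distance.
Single-exon transcripts and transcripts without an ORF are never
candidates.

The retained-intron stop scan asks the read-through question for each RI/SI
event: walking in the retaining transcript's ORF frame, does any stop codon
lie wholly within the retained intron? The scan is restricted to that one
frame (not any-frame) because the biological question is whether the
ribosome translating *this* mRNA can traverse the intron. It also records
whether the intron preserves frame (length divisible by 3) and reports
not-applicable when the intron begins outside the translated span. For a
random-sequence intron of length `L` inserted at a codon boundary the
expected hit rate has the closed form `1 - (61/64)^(L/3)`, which the test
suite verifies by simulation at `L` of 60, 150 and 300.

### Intron size statistics

"All introns" pools per-transcript intron lengths across isoforms without
deduplicating introns shared between isoforms (the convention of annotation
summaries; a deduplicated mode and a representative-only mode exist as
flags for sensitivity). Retained-intron sizes take one length per
deduplicated RI/SI event. "Smaller than 200 nt" is a strict `<`. Medians
use the midpoint rule for even counts.

### Coverage profiles

Three views of a per-base coverage track, converted from bedGraph's 0-based
half-open convention at the boundary (all internal arithmetic is 1-based
closed):

* **Chromosome density**: `log2(median depth + 1)` in fixed bins (default
  100 kb, configurable — the binning of published density plots is rarely
  stated). The +1 pseudocount keeps empty bins finite while preserving
  order.
* **Metagene profile**: each gene's representative model (longest CDS,
  ties to the smallest id; longest spliced form when no CDS) contributes
  its exonic depths read 5'→3' on the mRNA, sampled at 101 evenly spaced
  relative positions by nearest-base lookup — deterministic and
  resolution-independent, at the cost of ignoring between-sample-point
  bases. The profile is `log2(median across genes + 1)` per position.
* **Per-cDNA covered fraction**: the fraction of exonic bases with depth at
  least 1, summarised by quartiles.

### Comparative statistics

The category comparison uses the likelihood-ratio G-test,
`G = 2 * sum(O * ln(O/E))` against chi-square, with no Williams or
continuity correction by default (a Williams-corrected variant sits behind
a flag). The test runs on the 2×6 count table — counts are the sufficient
statistic; percentages are derived for display — and additionally on the
2×2 table of retained-intron events versus the rest, since the headline
contrast concerns intron retention specifically and the 2×6 test dilutes
it. Categories empty in both samples are dropped before testing (their
expected counts are undefined).

Retained-intron sizes are compared with the two-sided
Mann–Whitney–Wilcoxon test: exact enumeration when `n1*n2 <= 400` with no
ties, otherwise the normal approximation with midranks, tie correction and
continuity correction. The implementation wraps the standard rank-sum
machinery; the test suite checks the exact branch against an independent
brute-force enumeration of all assignments.

Annotation matching deems an assembled gene confirmed when some isoform
pair (assembled × reference, same strand, overlapping loci) has (a)
contiguous coverage of at least 80% of the reference mRNA length and (b)
structural identity of at least 95%, computed as shared exonic genomic
bases over the assembled exonic bases falling within the reference locus
span. Identity is structural rather than alignment-based on purpose: both
transcript sets are anchored on the same genome, so base-level alignment
would only re-derive the coordinates we already have.

## The synthetic generator

The generator is first-class, tested code, and its defaults are the
conditions under which the package's claims are made:

* **Gene models**: 3–7 exons of 90–300 nt; intron lengths log-uniform on
  [60, 6000] nt — the admissible range of the emulated alignments — which
  exercises both the sub-200-nt mass where most real retained introns live
  and the long tail. Genes are placed with ≥500 nt intergenic spacing on
  uniform-composition chromosomes sized with ~1.7× head room.
* **Reference ORFs**: every intron gets canonical GT..AG dinucleotides (on
  its own strand), and every reference isoform gets an embedded ATG..stop
  ORF covering at least 60% of the mRNA with the stop in the last exon.
  The coding filler is drawn from {C,G,T} only, so the designed ORF is
  provably the unique AUG-initiated ORF — ORF recovery is exact by
  construction, which is what makes the NMD boundary tests sharp. The cost
  is unrealistic base composition inside coding exons; nothing downstream
  reads composition, but this is why the generator's sequences should not
  be used to study codon or GC statistics.
* **Planted AS isoforms**: one structural edit per alternative isoform, at
  most one alternative per host gene, so the planted multiset is exactly
  countable. RI merges two exons across an intron; SE drops an internal
  exon; AA/AD shift one splice site 10–40 nt *into* the intron (writing a
  fresh GT or AG inside intronic sequence, so reference exons are never
  touched and the shrunken intron stays ≥60 nt); ATE replaces the last
  genomic exon with one in the intergenic buffer; IWI/TWI extend an exon
  into the following intron and truncate there. Shifts of ≥3 nt (ours are
  ≥10) keep events unambiguous; compound isoforms are deliberately not
  generated — ground truth must be countable, and the classifier's
  consumption rules are exercised by the single-edit structures already.
* **PTC transcripts**: for each requested stop-to-junction distance `d`,
  the ORF of a dedicated single-isoform host gene is rewritten so the first
  base of its stop lies exactly `d` nt upstream of the last junction. A
  structurally distinct extra isoform would create unplanned AS events, so
  the carrier is the reference isoform itself. Default distances
  {10, 54, 55, 56, 200} bracket the 55-nt boundary from both sides.
* **Abundance**: reference isoforms draw log-normal FPKM (meanlog 3,
  sdlog 1, floored so that every non-designated isoform passes both filter
  thresholds with ≥2× margin); designated low-abundance isoforms get
  values violating exactly one recorded criterion (0.5 FPKM at a passing
  fraction; 2 FPKM at a 1.3% fraction; 0.4 FPKM at 0.7%). The floor means
  the generator does not model genuinely silent reference genes — the
  filter's recovery test needs the planted set to be the exact answer.
* **Coverage**: fragments of 101 nt (the emulated read length) are
  allocated to transcripts in proportion to FPKM × length and placed
  uniformly along the mRNA, then projected through the exon chain to
  genomic depth. Fragments always fit inside the transcript, so total
  covered base count is exactly `n_fragments × fragment_length`; the edges
  of each transcript ramp over one fragment length, which is why flatness
  is asserted over the 10–90% core of the metagene profile only.

Everything is deterministic under the spec seed (each stage derives a fixed
small offset from it), down to byte-identical FASTA/GFF3/TSV/bedGraph/JSON
artifacts.

**What passing tests do and do not show.** Exact recovery on planted data
shows the definitions on both sides of the pipeline agree and the
arithmetic is right. It does not show the classifier reproduces PASA's
behaviour on real assemblies (real data have compound isoforms, soft
boundaries and fragmentary models the generator deliberately omits), nor
that the NMD rule predicts decay — the 55-nt rule is itself a heuristic.
The published headline numbers derive from ~96 million-read libraries plus
full assembly stacks and are not reproducible at desk scale; the package's
two-sample scenario reproduces the *structure* of the comparison (retained
introns enriched in total RNA, low-abundance isoforms almost exclusive to
it) at roughly 700 genes per sample, with the attrition fraction scaled
down by the one-alternative-per-gene design.

## Problem sizes and numerical choices

The test suite runs the recovery conditions at 300 genes with 10 planted
events per category and 25 low-abundance isoforms; the statistical power
check uses two ~1,000-event samples (1,300 genes each) with the
retained-intron class halved and the alternate-acceptor class doubled in
one of them; the stop-codon analytics use 5,000 random introns per length.
The analysis scripts and `scripts/acceptance.R` run the two-sample scenario
at 700 genes per sample with 500 and 250 planted events and 300,000
simulated fragments. These sizes give stable statistics (binomial standard
errors well inside the asserted tolerances) while keeping a full run in the
low minutes on one CPU.

Other numerical choices: G-test cells with zero observed count contribute
zero; the exact rank-sum branch bounds the enumeration at `n1*n2 <= 400`;
metagene resampling uses nearest-base lookup; all coordinates are 1-based
fully closed with conversion only at the bedGraph boundary; unstranded
annotation features are rejected outright because donor/acceptor polarity
is undefined without strand.

## Known limitations

* The classifier assumes assembled isoforms with exact splice boundaries;
  it does not model boundary uncertainty or fragmentary assemblies.
* Events are binary per isoform pair; quantitative splicing (PSI) is out
  of scope, as are differential expression and translation efficiency.
* `complex` intron pairs and multi-intron retentions are reported but not
  sub-classified.
* The generator plants one edit per isoform; classifier behaviour on
  compound isoforms is untested by construction (the consumption rules
  define it, but no ground truth exercises it).
* Annotation matching is structural; it will not detect base-level
  sequence divergence between assembly and reference, which cannot occur
  when both are projections of the same genome but would matter for
  de novo assemblies with indels.
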