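---
title: "Methods: calling, classifying and tracking chromomethylase-induced gene body methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling, classifying and tracking chromomethylase-induced gene body methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Gene body methylation (gbM) — CG-only DNA methylation on the bodies of a
subset of transcribed genes — is widespread in flowering plants, yet species
that have lost the CHG maintenance methyltransferase CMT3 also lack gbM.
Expressing *CMT3* heterologously in such a species lets one watch gbM being
born: expressed genes first acquire de novo CHG methylation (enriched at the
CWG subcontext CMT3 prefers), co-acquire CWA-enriched CHH and a little CG
methylation, and, when the transgene is silenced or segregated away, lose
the CHG/CHH marks quickly while the CG marks persist across generations —
a heritable epimutation.

This package implements the downstream analysis chain of such an experiment
— per-cytosine binomial methylation calls against a non-conversion control,
trinucleotide context partitioning, a differential-methylation stage,
the CHG-gain gene classifier, retention-ratio analysis across a generational
series, the background CG estimator, exact enrichment statistics, and
binned metaplots — together with a synthetic-study generator so that every
stage can be exercised, and its parameter recovery measured, without any
external data.

## Coordinates and formats

All internal coordinates are 1-based and closed, the GRanges/IRanges
convention, and conversions happen only at file boundaries: allc
per-cytosine tables store 1-based positions and pass through unchanged; BED
(0-based, half-open) and GFF3 (1-based, closed) are converted by
rtracklayer at import/export. `read_allc()`/`write_allc()` round-trip
byte-identically, and a BED file re-exported after import is unchanged —
both are tested.

Context labels are always read 5'→3' on the cytosine's own strand.
`classify_context()` recomputes the trinucleotide from the genome;
`annotate_sites()` reconciles file-declared contexts with genome-derived
ones, lets the genome win, and aborts when the mismatch rate exceeds 1% —
in our experience the most common silent failure here is a coordinate
convention off-by-one, and a loud failure beats a quietly wrong context
table. Windows that run off a contig end or contain non-ACGT bases are
UNDETERMINED and excluded from every downstream statistic. The 16
determined `CNN` trinucleotides partition exactly into CG (4), CHG (3; CWG =
CAG/CTG vs CCG) and CHH (9; CWA = CAA/CTA vs the other seven).

## Binomial methylation calls

Bisulfite conversion is imperfect; a fully unmethylated control contig (the
chloroplast in the real study) estimates the non-conversion rate `r` as
pooled methylated reads over pooled total reads. Every cytosine with at
least 3 reads is tested against the upper tail of Binomial(cov, r); the
p-values are Benjamini–Hochberg corrected across all tested cytosines of a
sample, and a site is called methylated at q < 0.01. The source study did
not state its significance threshold or correction; we chose one-sided
tests with BH at q = 0.01 — the stringency typical of methylpy-style
callers — and expose both as arguments. On simulated null data the
genome-wide false methylated-call fraction stays below q (tested).

Weighted methylation levels — used for all region summaries, heatmaps,
metaplots and the gain classifier — are pooled raw counts (sum mc / sum
cov), never calls; binomial calls enter only where individual methylated
cytosines are counted (retention, background). A region with zero pooled
coverage is flagged undefined, never reported as zero. Pooling makes the
value invariant to region partitioning and site order (tested as an
invariant).

## The differential-methylation stand-in

The original analysis delegated region calling to an external
root-mean-square permutation tool. That algorithm is out of scope here; the
package ships a deliberately simple, fully testable stand-in: per-site
two-sided Fisher exact tests on the 2×2 read-count tables of the two
samples (both covered at ≥ 3 reads), BH correction, then chaining of
significant sites at most 250 bp apart (argument) into regions that must
contain at least 5 differential sites. Regions are classified hyper/hypo
relative to wild type at a minimum change of 10 percentage points (CHG,
CHH) or 20 points (CG), read as inclusive thresholds, and annotated by
overlap with precedence gene > repeat > intergenic at ≥ 1 bp, which keeps
the classes mutually exclusive. The heatmap matrix keeps regions with at
least 5 cytosines covered at ≥ 3 reads in every sample and ranks rows by
wild-type weighted %CHG, ascending (the ranking direction was not stated in
the source; ascending is our choice). On synthetic data a planted
hypermethylated block is recovered as a single hyper region covering ≥ 90%
of the planted sites (tested).

The interval-overlap Fisher test builds its 2×2 table from merged interval
counts, with the "neither" cell approximated by genome length over mean
interval length; it is a documented approximation of base-resolution
contingency constructions (different tools build this table differently),
so p-values on real data are comparable within, not across, tools.

## The CHG-gain gene classifier

A gene is a CHG-gain gene in a line when

1. wild type shows < 1% weighted methylation in each of CG, CHG and CHH
   over the gene body (the full annotated span, introns included — the
   source does not restrict to exons);
2. the gene has ≥ 10 informative CHG cytosines (≥ 5 reads) in *every*
   sample of its coverage-harmonization group, so that informativeness is
   never an artifact of one shallow library; and
3. the line's weighted %CHG exceeds wild type by ≥ 5 percentage points —
   "5% increase" is interpreted as 5 absolute points, matching how percent
   methylation is used throughout this analysis style.

A context with no covered cytosines in wild type passes filter 1 (absence
of evidence of methylation, with the informative-site filter guarding
against uncovered genes). The gain set shrinks monotonically as any
threshold tightens (tested). Characterization compares gain vs unmethylated
genes on length, exon count, expression and CHG-site frequency (3-base
window, step 1, both strands, N windows never match) with two-sided
Wilcoxon rank-sum tests — exact via the Wilcoxon null distribution for
combined n ≤ 25 without ties, otherwise the normal approximation with tie
and continuity correction.

## Retention ratios and the background CG floor

The retention analysis is restricted to cytosines inside the analyzed
regions (CHG DMRs over gain genes, or the gain-gene bodies) that are
covered at ≥ 3 reads in every series sample and carry an *unmethylated
binomial call* in wild type — the call, not raw mc > 0, because methylation
status in this analysis chain is defined by the binomial test. Counts of
methylated-called cytosines per context partition (CG/CHG/CHH and
CWG/CCG, CWA/other-CHH) are reported as ratios to the reference generation;
an empty reference partition yields an undefined ratio, never zero.

The background estimator draws five random sets of never-gain unmethylated
genes (count matched to the gain set), takes an equal amount of sequence
per gene — a centered window of ceiling(total_bp/n_genes) bases, truncated
to the gene; the anchoring was unstated in the source, so it is an argument
(`centered` default, `five_prime` alternative) — and reports the percent of
eligible CG cytosines called methylated per sample. With a stringent caller
this floor sits near the non-conversion-driven false-call rate, well below
the retained genic CG signal.

## Exact statistics

The hypergeometric upper tail is a log-gamma sum evaluated with
log-sum-exp, so tails far below double underflow (the ortholog gbM
enrichment sits near 10⁻¹³⁰ on its count table) are exact on the log10
scale; tests compare it with brute-force summation (N ≤ 60) at 1e-12
relative error and with R's log-scale survival function on large instances.
The two-sided Fisher p uses the point-probability convention (sum all
tables with the observed margins whose probability does not exceed the
observed), matching the common exact-test implementation, with a
conditional-MLE odds ratio. Expression fold changes are
log2(line/wild-type) with zero-FPKM genes excluded and a strict ±2 cutoff
("greater than" in the source), and qPCR relative expression is
2^-(mean Ct_target - mean Ct_reference) over technical replicates.
Bonferroni thresholds take the number of tests explicitly from the caller.

## Metaplots and ChIP profiles

Methylation metaplots split 1 kb flanks into 20 bins each and the feature
body into 20 near-equal bins; the remainder of length mod 20 is spread one
base at a time over the *leading* body bins (a deterministic, documented
tie-break). Minus-strand features are mirrored so bin 1 is always the
distal 5' flank; unstranded features default to plus. Bins pool counts
across features, and a bin with no covered site is undefined (a plotting
gap), not zero. Uniform input produces flat profiles to floating-point
tolerance (tested).

ChIP profiles average per-locus window counts over 4 bins (2 kb upstream,
2 kb inward from each end, 2 kb downstream), normalized by library size and
locus count. For loci shorter than 4 kb the two inward windows are
truncated at the locus midpoint so they never overlap — the source is
silent on this; truncation was chosen over overlapping windows to keep the
four bins disjoint. Peak post-processing merges overlapping or book-ended
peaks, sums their reads, and keeps regions whose read density (reads /
length) strictly exceeds 0.05.

## The synthetic study

The generator emulates the study design, not the organism: a main contig
with 120 genes (1–3 kb, 1–8 exons), 60 repeats (0.5–1.5 kb), intergenic
spacers and 36% GC, plus a 20 kb fully unmethylated control contig. Wild
type methylates repeats at CG 0.80 / CHG 0.15 / CHH 0.10 (the CHG default
echoes the ~15% repeat-level CHG methylation typical of a wild type in this
design) and leaves genes at zero. Six generations carry transgene
expression 60/120/180/240 FPKM rising to the fourth generation and 0
afterwards (silencing after generation 4). Longer genes are more likely to
be susceptible to gain (echoing the length bias of gbM genes; about 60% of
genes overall); a susceptible, not-yet-gained gene gains in generation *g*
with probability expr/(expr + 60). Within a gained gene, sites methylate
with probability 0.60 (CWG) vs 0.0667 (CCG) — 9:1 odds — 0.30 (CWA), 0.02
(other CHH) and 0.25 (CG), at true methylated fractions 0.80 (CHG), 0.70
(CHH) and 0.85 (CG). After silencing, each methylated genic site persists per
generation with probability 0.7 (CG) or 0.2 (CHG, CHH). Reads are emitted
as cov ~ Poisson(20) and mc ~ Binomial(cov, f + (1−f)·0.005): partial
methylation is a per-read Bernoulli and non-conversion acts symmetrically
on the unmethylated fraction — a documented simplification with no
conversion-failure asymmetry for methylated reads.

Two generations after silencing the expected surviving fractions are
0.7² = 0.49 (CG) and 0.2² = 0.04 (CHG, CHH); the retention report recovers
these within three binomial standard errors, and planted gain genes are
recovered with sensitivity ≥ 0.9 at FDR ≤ 0.05 under the study thresholds
(both are acceptance-tested at mean coverage 20 with ≥ 10⁴ eligible genic
cytosines). The default scale — a ~0.5 Mb genome, ~150,000 cytosines,
7 samples — keeps a full pipeline run near ten seconds while leaving the
binomial standard errors of the recovery checks a factor of several below
the tested tolerances.

What the generator does *not* emulate: repeats do not gain further CHG
methylation in transgenic samples (real repeats go from ~15% to 30–70%),
intergenic space is unmethylated, there is no RdDM-style patchiness, no
sequence evolution, no chromatin feedback, and coverage is homoscedastic
Poisson rather than the long-tailed empirical coverage of real libraries.
Passing parameter-recovery tests therefore demonstrates correctness of the
analysis chain under its own assumptions — calibration, filters,
arithmetic, bookkeeping — not robustness to the full messiness of real
bisulfite data.

## Numerical and degenerate-input choices

Ties in BH are handled by the standard step-up on stably sorted p-values —
deterministic. Fisher's two-sided sum uses a 1e-7 relative tolerance when
comparing table probabilities, the usual guard against spurious strictness
at ties. The Wilcoxon normal approximation returns p = 1 when the tie
correction removes all variance (all observations identical). The
regression helper refuses constant x and flags constant y (R² = 0, p
undefined). All-zero Fisher tables, empty gene sets, empty region sets,
zero-coverage controls and undersized gene pools are errors, not silent
zeros. Every stochastic entry point takes an explicit seed, and re-running
any stage with the same configuration and seed reproduces its outputs
bit for bit.

## Known limitations

The DMS/DMR stage is a stand-in: its regions are comparable in spirit, not
numerically, to permutation-based callers, and the interval Fisher table is
an approximation (above). The informative-site filter's
coverage-harmonization grouping defaults to "all samples in the provided
list"; the finer per-lineage groupings used on real data are expressed by
passing different sample lists. Orthology and gbM status of a reference
species are consumed as count inputs to the enrichment test, never
computed. GO enrichment is out of scope.
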