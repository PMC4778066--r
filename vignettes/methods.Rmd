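---
title: "Models and methods behind srnamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srnamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnamir)
```

`srnamir` re-creates, as a tested R pipeline, the computational workflow of a
two-library plant small-RNA sequencing study: one pooled library per
condition (treatment vs control, e.g. magnesium-deficient vs sufficient
citrus leaves), no biological replicates, and exact count-based statistics.
This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data tests do and do
not demonstrate.

## Read cleaning and tag collapsing

Raw reads are cleaned in three steps, in this order:

1. **Quality**: reads with mean Phred quality below 20, or containing any
   `N`, are discarded. Published sRNA studies rarely state their exact
   cutoff; 20 is a conventional choice and is a configurable argument, not
   an inference of any particular study's value.
2. **Adapter**: the 3′ adapter is trimmed at the leftmost exact occurrence
   of its first 8 bases. An 8-nt seed makes trimming deterministic and
   essentially unambiguous (a random 8-mer occurs once per ~65 kb); reads
   with no hit are kept whole, since short inserts always retain a full
   adapter suffix in sRNA protocols.
3. **Length**: inserts outside 18–30 nt are discarded. The lower bound
   matches the minimum mature miRNA length used downstream (18 nt); the
   upper bound leaves margin above the 25-nt maximum so that length
   accounting covers the whole small-RNA range.

Counts are conserved by construction: raw = clean + low-quality +
length-filtered, and collapsing preserves per-library totals. Sequences are
held internally in the DNA alphabet; U↔T conversion happens only at
miRNA-reference ingestion and report writing.

## Annotation cascade

Tags are mapped to the genome by perfect match on both strands (the study
design this package follows retains only perfectly mapped reads), then
classified by the first matching stage of a fixed priority:

rRNA > tRNA > snRNA > snoRNA > known miRNA > repeat > exon > intron > unannotated

Published pipelines state the order "rRNA > known miRNA > repeat > exon >
intron" while also reporting tRNA/snRNA/snoRNA categories; here all four
ncRNA classes share the first stage (internal order as listed) because they
are removed together before miRNA identification. ncRNA matching is exact
substring containment of the tag in a reference sequence on either strand —
a deterministic, dependency-free stand-in for a BLASTn search at a stringent
e-value; an external aligner can be substituted behind the same interface.

Known-miRNA assignment is an ungapped same-length comparison against the
mature reference with at most 2 mismatches, ties broken by reference order.
By default an assignment alone suffices (the genome may lack loci for some
conserved families, so such tags count in the miRNA category but not as
mapped-to-genome); a flag requires a genomic hit as well. A tag is counted
in exactly one category regardless of its number of loci, so categories
partition the clean reads — the invariant behind the summary table.

## RNA folding: the default engine

Novel-miRNA prediction needs a secondary-structure engine. The default is an
exact dynamic-programming minimizer over nested structures under a
deliberately simple stacked-pair model:

* a base pair stacked directly inside an adjacent outer pair contributes its
  own pair energy: G:C −3.0, A:U −2.0, G:U −1.0 kcal/mol;
* isolated (unstacked) pairs contribute nothing, so the model rewards
  helices rather than scattered pairs;
* hairpin loops shorter than 3 nt are forbidden; there are no dangling-end,
  loop-size or coaxial terms; no pseudoknots.

For example `GGGGAAAACCCC` folds to `((((....))))` with three stacked G:C
steps, −9.0 kcal/mol. The DP (O(n³), implemented in C++) returns the exact
optimum of this model; the test suite verifies it against brute-force
enumeration of *all* nested structures for hundreds of short random
sequences. Absolute energies are **not** comparable with Turner-parameter
folders such as ViennaRNA — all thresholds in this package refer to this
model, and the synthetic hairpins are designed so that acceptance does not
depend on folding-engine subtleties. Any function honoring the
`fold()` contract (sequence, dot-bracket, MFE) can be plugged in instead.

## Hairpin acceptance (novel miRNAs)

Candidate tags are unannotated, perfectly mapped, 18–25 nt long, with at
most 20 genomic loci (the copy-number cap is interpreted per tag). For each
locus, windows extending up to the maximal miRNA/miRNA\* gap (300 nt) on
either side are folded; the miRNA\* arm is read off the pair table as the
duplex partner with 2-nt 3′ overhangs on both arms — the Dicer-cleavage
signature operationalized from the fold, with the star arm required to be
20–23 nt (the "reference sequence" bounds). The precursor is then
re-extracted as the mature/star span plus 20-nt flanks, re-folded, and
accepted only if:

* precursor MFE ≤ −18 kcal/mol;
* ≥ 16 base pairs in the miRNA/miRNA\* duplex;
* largest bulge on either arm ≤ 4 nt;
* duplex asymmetry ≤ 4 (defined here as the sum over internal loops of the
  absolute left/right size difference — the combination rule is not
  standardized, and the designed test hairpins have perfect stems so the
  choice does not affect them);
* mature–star gap ≤ 300 nt.

Star presence as a *sequenced* tag is not required. A perfect inverted
repeat equals its own reverse complement, so the same hairpin is recovered
from both genome strands; candidates are therefore deduplicated by
overlapping precursor locus, keeping the lowest-MFE representative. The
original study additionally required consensus between three prediction
tools; this package implements a single transparent predictor and exposes
every acceptance diagnostic instead.

## Differential expression

Counts are normalized to tags per million: TPM = count / library clean reads
× 10⁶. miRNAs below 10 TPM in *both* libraries are dropped (kept if ≥ 10 in
at least one). The fold change is log₂(treatment TPM / control TPM) with
zeros replaced by a 0.01 pseudo-TPM, which reproduces the finite extreme
fold changes (≈ ±17.6) that single-library designs report for on/off miRNAs.

Significance uses the exact conditional count test: given x counts among N₁
reads, the probability of y counts among N₂ reads is

$$p(y|x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!}
  \left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

the depth-corrected generalization of the Audic–Claverie statistic;
equivalently, y | x is negative binomial NB(x+1, N₁/(N₁+N₂)), which the test
suite uses as an independent cross-check. Numerically, point masses are
computed in log space via `lgamma`; the lower tail is a direct sum and the
upper tail is summed upward to machine-precision convergence, because the
1 − lower + point complement loses all relative precision for the very
small tails that matter. The reported p-value is the smaller one-sided tail
(no doubling — the source convention pairs the two tail sums without a
combination rule; doubling is available as an option). A miRNA is called
differentially expressed when p < 0.01 **and** |log₂FC| > 1.5; the
fold-change gate is applied on the log₂ scale since that is the scale on
which such studies define and report "fold change" (gating on the raw
ratio is available as an option). No multiple-testing correction is applied,
matching the single-pool design this reproduces. Monte-Carlo calibration in
the test suite shows the min-tail rule at the 0.01 cutoff yields an
empirical null false-positive rate of about 1–2 % (the discrete min-tail
can at most double the nominal level), and > 90 % recovery for |log₂FC| = 3
features at baseline TPM ≥ 50 and 5×10⁵-read depth.

## Target prediction

A duplex aligns the miRNA antiparallel to a candidate transcript window,
position by position from the miRNA 5′ end; G:U wobbles weigh 0.5
mismatches, mismatches and bulges weigh 1. When lengths differ by one, a
single-nucleotide bulge is placed at the score-minimizing position (leftmost
on ties) — one bulge at most, keeping the search deterministic and the
adjacency rules meaningful. The six acceptance rules are:

(a) total score ≤ 4; (b) no more than two adjacent mismatches anywhere;
(c) no adjacent mismatches in positions 2–12; (d) positions 10–11 strictly
Watson–Crick (a wobble is half a mismatch, hence "no mismatches" excludes
it); (e) score over positions 1–12 ≤ 2.5; (f) duplex MFE strictly greater
than 75 % of the MFE of the miRNA bound to its perfect complement. Wobbles
do not count toward adjacency in (b)/(c) — treating a half-mismatch as
adjacency-blocking would contradict common usage of these rules — though a
strictness flag enables it. Duplex energies use the same stacked-pair model
as the folding engine restricted to intermolecular pairs, so the ratio in
(f) is model-independent in the perfect-complement limit (it tends to 1 as
the site approaches the exact complement).

Scanning evaluates every window of miRNA length on every transcript;
overlapping passing windows of one miRNA merge to the best-scoring one (an
option reports all windows, which is also how the exhaustive-window oracle
test compares results exactly).

## qRT-PCR validation and concordance

Relative expression follows the ddCt algorithm: technical replicates are
averaged first, ΔCt = Ct(gene) − Ct(internal standard) per biological
replicate, ΔΔCt subtracts the control-condition mean, and relative
expression is 2^−ΔΔCt with the control at 1 by construction (invariant to
any constant Ct shift). A miRNA/target pair is *reverse* when the target
moves opposite to the miRNA's sequencing fold change (miRNA down and target
ratio > 1, or miRNA up and ratio < 1), *same* otherwise, and *not detected*
when the target gave no signal; a ratio of exactly 1 is logged and counted
as *same*, since no change is not a reverse change. The package bundles a
77-row concordance table (qRT-PCR relative expression for target genes of
23 magnesium-deficiency-responsive citrus miRNAs) whose 56/17/4 partition
(73 % reversal) is a regression test. GO reporting only tallies gene counts
per term and category — no enrichment statistics.

## The synthetic-data generator

The generator builds a single-chromosome toy genome in which every
annotation category is represented by designed features: hairpin precursors
(known and novel), ncRNA loci, two-exon genes (whose spliced transcripts
carry planted perfect target sites for the known miRNAs), repeats, and
deliberately unmappable background tags. Hairpins are perfect inverted
repeats — stem of the 21-nt mature plus a 5-bp extension (26 bp, no
bulges), an AT-rich 8–12-nt loop — so their acceptance under the default
energy model is guaranteed by construction (MFE ≈ −60 to −80 kcal/mol) and
verified by re-folding at build time.

Libraries are simulated as multinomial draws over TPM-derived proportions
(control) and fold-change-adjusted proportions (treatment), one pooled
sample per condition — the sampling noise stands in for the study's pooled
single-library design, not for biological replication. Reads are the
feature tag plus adapter, cut to 36 nt, with per-base substitution errors
and a configurable fraction of uniformly low-quality reads to exercise
cleaning. Default test scales — 20,000-read libraries for pipeline runs,
5×10⁵-read depths and 1000 features for calibration/recovery, 200 random
sequences for the folding oracle — were chosen as the smallest sizes at
which the binomial/multinomial error bands in the assertions are tight;
they are ordinary function arguments.

What passing tests therefore show: the machinery is internally correct
(exact tests against oracles, conservation and partition invariants,
ground-truth recovery). What they do not show: performance on real
Illumina error profiles, PCR duplicates, imperfect hairpins, isomiR
heterogeneity, or thermodynamically marginal precursors — real-data
behavior additionally depends on the folding model and reference quality.

## Reproducibility and degenerate inputs

All randomness flows from a single integer seed through a documented
splitting scheme (`derive_seed(seed, stream)`), so identical configurations
reproduce byte-identical outputs. Degenerate inputs are defined rather than
accidental: empty libraries yield zero-count tables with percentages
reported as absent (not 0/0); an empty tag collection yields an empty
length distribution; unpairable sequences fold to all-dots structures with
MFE 0; ties (equal-energy structures, equal-mismatch references, equal-score
bulge placements) break deterministically toward the first/leftmost option.
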