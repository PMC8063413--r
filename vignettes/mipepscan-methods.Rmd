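---
title: "mipepscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mipepscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mipepscan` implements the computational side of a question that has become
standard in the small-ORF field: do primary microRNA transcripts (pri-miRs)
carry translatable short open reading frames (sORFs), and what can be said
about the micropeptides (miPEPs) they would encode? The package covers five
analysis stages — sORF surveys across RNA classes, ribosome-profiling
peptide matching, candidate-miORF annotation at a pri-miR locus,
dual-condition differential-expression (DE) partitioning, and the cross
genetics / measurement statistics used to score fly phenotypes — plus a
seeded synthetic-data generator that plants known structure in every input
type, so each stage is testable end to end without any external download.

This vignette records the models, the tunable parameters and the design
decisions that were genuinely open, in the package's own words. Every
number quoted here is recomputed by the test suite or by
`scripts/acceptance.R`; nothing is asserted from memory.

# ORF definition and the density survey

An ORF starts at an ATG and runs to the first in-frame stop (TAA/TAG/TGA),
with a peptide of at least `min_aa = 10` residues (stop excluded). Scanning
is forward-strand only, in all three frames; codons containing N never act
as start or stop (conservative on ambiguous bases). Densities are expressed
per transcript as ORFs/kb and compared between RNA classes as
distributions (box-plot semantics), not pooled, via Kruskal-Wallis plus
pairwise Mann-Whitney with Bonferroni correction.

Two counting conventions exist when several in-frame ATGs share a stop.
`mode = "maximal"` (the default) counts one ORF per (frame, stop), anchored
at the 5'-most ATG; `mode = "all"` counts every qualifying ATG and is
provided for sensitivity analysis. The default avoids inflating densities
with ATG runs. ORFs must be complete (end at a stop); `allow_open = TRUE`
admits stop-less 3' ORFs but is off by default, since an ORF that never
reaches a stop is not a coding unit under the definition above.

Degenerate inputs: an all-identical density table returns p = 1 by the
all-ties convention; classes with fewer than two transcripts are excluded
with a warning.

# Three-frame translation and peptide matching

Ribosome-profiling studies yield lists of sORF-encoded peptides. The
matcher translates each transcript in its three forward frames (standard
nuclear code; N-containing codons become X; stops become `*`) and reports
every exact, case-insensitive occurrence of each peptide. Matching is exact
by design — no mismatches, no I/L equivalence — because fuzziness would
change counts in ways that cannot be validated; a peptide that contains no
`*` can never span a stop, so every match lies within one stop-free
segment. The minimum peptide length for matching defaults to 7 residues:
shorter sequences match essentially any transcriptome by chance.

A peptide matching several transcripts is counted once in the global
distinct-peptide total and once per transcript in per-transcript counts;
both numbers are reported to keep the two summaries unambiguous.

# miORF annotation at a pri-miR locus

Given a pri-miR transcript with its pre-miR hairpin interval, the candidate
miORF is the longest ORF lying wholly 5' of the hairpin ("wholly" means
the stop codon ends at or before the hairpin start — processing of the
hairpin separates the regions, so an ORF overlapping it is not a clean
upstream unit). Ties go to the 5'-most ORF, the first one a scanning
ribosome would initiate on. Downstream in-frame ATGs sharing the stop are
reported as alternative starts (ATG2, ...), since they can produce
N-terminally truncated peptide forms.

Start-codon context is scored against a configurable consensus matrix. The
default is a Cavener-style Drosophila consensus over positions −4..−1 and
+4 (A of ATG = +1), with −3 weighted three times the other positions and
A/C as its preferred set; position weights and per-base scores are fully
replaceable. The score is a weight-normalized match in [0, 1], and a
context is "favorable" when the score reaches the threshold (default 0.5)
*and* the −3 base is in the preferred set. Favorability of a natural
context is ultimately an experimental property; this score is a documented
heuristic annotation, and the threshold is a package default, not a
measured constant.

Single-base variants are applied with reference-allele checking and all
annotation is recomputed from the mutated sequence. A variant that keeps
the selected start but shortens the peptide is reported as a truncation of
(original − new) residues; a variant that changes the selected start
reports `start_lost` instead, because a truncation length computed across
different starts would be meaningless.

`surrogate_primir8()` builds a fully synthetic transcript mirroring the
studied locus geometry at desk scale — a 71-codon miORF in a favorable
context, an internal in-frame ATG at codon 15 (57-aa alternative form), a
downstream hairpin interval, and a stop-gain variant at codon 48 that
truncates the peptide to 47 residues (24 lost). It exists so that the
71/47/24 arithmetic is exercised deterministically; it is constructed, not
genomic, and is labelled accordingly.

# Differential expression and the two-condition partition

Counts are normalized with TMM (trimmed mean of M-values): reference
library by upper-quartile closeness to the mean, two-sided trimming of 30%
of M-values and 5% of A-values, inverse-variance weighting, factors
rescaled to geometric mean 1. The trim fractions are the canonical ones.
One test cross-checks the factors against an established implementation
(edgeR) when it is available; the package's own factors are computed
independently.

Testing uses a deliberately simple NB framework rather than a
re-implementation of any specific tool's machinery. Per-gene dispersions
are Pearson-moment estimates with an n/(n − 2) degrees-of-freedom
correction, shrunk toward the abundance-weighted genome-wide estimate with
a fixed weight (`shrink_weight = 0.3` on the gene-wise component). Each
gene is tested by a Wald statistic on the difference of log mean
normalized abundances with NB variance (Var = μ + φμ²) against a
standard-normal reference; the pseudo-mean offset for log fold changes is
0.5 normalized counts, keeping zero-containing genes finite. All-zero
genes get p = 1 and logFC = 0 by convention. The shrink weight and the
normal reference were fixed by calibration: under the generator's null
(five replicates, dispersion 0.1) the type-I error at p < 0.05 stays
within the binomial 3σ band of the nominal level, which is the framework's
stated guarantee — recovery and calibration properties, never
gene-by-gene agreement with another tool.

Regulated genes satisfy q ≤ 0.05 (inclusive) after Benjamini-Hochberg
adjustment, optionally intersected with a strict linear fold-change filter
(|FC| > 1.5 when requested); the boundary semantics (inclusive q, strict
FC) are part of the contract and tested. Two regulated sets over an
identical universe are partitioned into A-specific / B-specific / shared,
with percentages relative to each set and a direction breakdown. Row
standardization for heatmap display uses the sample (n − 1) standard
deviation and maps constant rows to zero.

Low-count filtering is not applied by default; the NB test's zero-gene
convention and the partition percentages make it unnecessary for the
synthetic conditions, and it would otherwise be a silent change of gene
universe.

# Cross genetics and measurement statistics

Expected progeny fractions come from gamete enumeration under equal
segregation and independent assortment, with lethal genotype patterns
(e.g. a balancer homozygote) removed before renormalization. Lethality is
a predicate on genotypes, not a hard-coded balancer rule, so deletion and
knock-in crosses are expressible. The canonical checks: a construct/CyO
intercross with CyO/CyO inviable gives 1/3 homozygotes and 2/3
balancer-carrying progeny; a balanced driver crossed to a homozygous
responder gives 50/50.

Observed class counts are tested against expectation with an exact
binomial test for two classes — exact and conservative at the scale of
tens of crosses — with chi-square goodness of fit for more classes and an
exact multinomial fallback (full enumeration of outcomes no more probable
than the observed one) when expected counts are small and enumeration is
tractable (≤ 2×10⁵ compositions).

Continuous measurements run through a decision battery: per-group
D'Agostino-Pearson normality first (implemented from the published
skewness and kurtosis approximations, as no installed package provides
it; it requires n ≥ 8, and smaller groups force the nonparametric branch
with a note); if all groups pass and Bartlett's test accepts equal
variances, one-way ANOVA (pooled t-test for two groups) with
Bonferroni-corrected pairwise t-tests; otherwise Kruskal-Wallis
(Mann-Whitney for two groups) with Bonferroni-corrected pairwise
Mann-Whitney tests. Bonferroni is used in both branches for symmetry. The
battery records every intermediate p-value and the branch taken, so the
decision path is auditable.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated under.

**Transcriptome.** Five classes, 40 transcripts each, with lengths
(CDS 600–3000, 5'UTR 300–900, 3'UTR 400–1500, lncRNA 600–2500, pri-miR
800–2000 nt) and planted-ORF rates per kb (CDS 1.5, 5'UTR 0.5, 3'UTR 1.0,
lncRNA 2.0, pri-miR 2.0) chosen so the class ordering — pri-miR and lncRNA
comparable and clearly above the 5'UTR — is built in, which is exactly
what the density survey is expected to recover. Background sequence is
blocks of 10 random bases alternating with an 11-nt cassette
(`TAAATAAATAA`) that carries a stop in every frame, capping unplanted ORFs
far below the 10-residue threshold. Planted ORF bodies interleave a
stop-bearing codon triple (CTA-ACT-AAC, i.e. TAA in both shifted frames)
every few codons so shifted-frame read-through across a planted ORF rarely
reaches 10 residues either; residual spurious ORFs are a few percent of
planted ones. Every planted ORF is recoverable by the scanner in `all`
mode — the ground-truth consistency the recall tests rely on. pri-miR
transcripts place the hairpin at 65–80% of their length, plant all ORFs
strictly 5' of it, and plant at least one ORF (their Poisson draw has a
floor of 1, a deliberate bias so every pri-miR has the geometry the
annotation stage needs; Poisson-count calibration tests therefore use a
non-pri-miR class).

**Peptides.** True peptides are 7–17-residue windows of planted ORF
peptides; decoys are drawn from the planted residue pool and rejected
until absent from every three-frame translation, which makes
recall/precision exactly 1/1 for a correct matcher rather than
approximately so.

**Counts.** Genes get log-normal baseline abundances; planted sets
(7.6% miR-specific, 7.6% miPEP-specific, 2.4% shared — i.e. 10% of genes
miPEP-responsive of which 24% are co-regulated, the published overlap
structure) shift by |log2FC| = 1.5 with random sign (same sign in both
conditions for shared genes). Per-sample means are renormalized so each
library's expected total equals its drawn size (0.8–1.2 million), which
turns condition effects into composition effects and gives TMM real work
to do. Counts are NB with genome-wide dispersion 0.1 — a typical
cell-line-replicate value and the simplest model the downstream test
assumes.

**What the generator does not emulate:** raw reads and alignment
artifacts, footprint calling, splicing, gene-length and GC biases,
gene-wise dispersion trends, correlated gene modules, linkage or meiotic
drive. Passing tests therefore demonstrate correctness of the
computations under a clean generative model, not robustness to every
artifact of real libraries; the qualitative recoveries (class ordering,
overlap percentages) are statements about the pipeline, not new evidence
about any organism.

# Problem sizes and numerical choices

The bundled checks run at desk scale: 200 transcripts per survey run (10
seeds), 2,000 genes × 15 samples per DE run (20 seeds for the recovery
average, one run for null calibration), 1,000 random vectors for the BH
step-up oracle, 100 random instances for the matcher oracle, and a few
hundred simulated crosses for the deviation-test null. These sizes give
the stochastic checks comfortable margins while keeping a full run in
tens of seconds.

Numerical conventions collected in one place: 0-based half-open transcript
coordinates internally, converted explicitly to 1-based closed GFF3 on
export; ties in miORF selection go 5'-most; all-ties class comparisons
report p = 1; constant rows standardize to zero; constant samples are
"non-Gaussian" for branching purposes; TMM factors have geometric mean 1
to machine precision; every simulator derives its stream from the single
config seed plus a fixed per-simulator offset, so the same seed never
reuses a stream across generators.

# Known limitations

The NB framework is intentionally minimal: no trended dispersion, no
empirical-Bayes moderation, no GLM design matrices beyond two-group
contrasts — adequate (and calibrated) for the planted conditions, but not
a general-purpose DE engine. The context score annotates rather than
predicts initiation. The exact multinomial fallback enumerates
compositions and is limited to small tables. The ORF survey treats the
pri-miR extent as given input; how a pri-miR's boundaries are called from
upstream data is outside the package's scope.
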