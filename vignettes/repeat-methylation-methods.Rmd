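---
title: "Methods: repeat-element methylation scoring, differential calling, and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-element methylation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repmeth)
```

# The problem

Endogenous retroviruses of the ERVK class — intracisternal A particles
(IAP) above all — are kept transcriptionally silent by dense CpG
methylation. When silencing machinery is impaired, individual elements
can lose methylation in the germ line while the bulk methylome is
untouched. Detecting that pattern from two whole-genome bisulphite
libraries (one wild type, one mutant) is the core task of this package:
a *local* differential signal at annotated repeat elements against a
*globally* unchanged background near 90% methylation.

Two companion analyses accompany the genomic one in this study design:
locus-level validation by Sanger sequencing of cloned bisulphite PCR
products, and phenotypic read-out through metastable epialleles such as
agouti viable yellow, where the coat-colour distribution of a cohort
measures the penetrance of silencing at an IAP insertion.

# The scoring model

## From strand calls to CpG dinucleotides

Bisulphite callers report the two cytosines of a CpG separately: the
plus-strand C at position $p$ and the minus-strand C at $p+1$.
`merge_strands()` sums the two records into one count pair keyed at
$p$, the canonical key for the dinucleotide. Sites seen on one strand
only pass through. Duplicate (chrom, pos, strand) records are rejected
rather than summed: deduplication belongs upstream, and silent summing
would mask double-loaded inputs.

## Library equalization

Sequencing depth differs between libraries. Read-level subsampling of
the larger library is emulated at the count level: every methylated and
unmethylated count is replaced by a Binomial(count, $r$) draw with
$r = N_\text{small}/N_\text{large}$ (`thin_counts()`,
`equalize_libraries()`). The expectation of every per-site methylation
fraction is unchanged, and the draw is seeded — an explicit seed is
required, never the clock. Exact totals differ from read-level
subsampling by at most binomial noise, which the test suite bounds at
three standard deviations.

## CpG qualification

Differential statements at a CpG are only meaningful when both samples
measure it well. A CpG qualifies when (i) both samples cover it with at
least `min_cov = 8` reads, and (ii) coverage is balanced:
$\min(c_1, c_2) \ge 0.6 \cdot \max(c_1, c_2)$. The balance rule has a
second defensible reading — relative deviation
$(\max-\min)/\max \le 0.6$ — which is implemented behind the
`bias_rule = "deviation"` switch; the ratio reading is the default as
the more literal one. Comparisons use a $10^{-9}$ tolerance so that
integer boundary cases such as coverage 6 against $0.6 \times 10$ are
not decided by the binary representation of 0.6.

## Coverage-weighted region scores

For a region with qualifying CpGs $i = 1..n$, methylation percentages
$m_i$ and coverages $c_i$, the score is

$$ M = \frac{\sum_i m_i c_i}{\sum_i c_i}, $$

computed per sample with that sample's own coverages (no pooling across
samples). Repeat elements need at least `min_cpgs = 8` qualifying CpGs;
elements below that are excluded and counted, never imputed. Membership
of a CpG in a region is 0-based half-open containment of the
plus-strand C. The score is invariant to CpG order and to scaling all
coverages by a constant, and the suite checks it against a brute-force
loop at $10^{-9}$ on 1,000 random regions.

Genome windows (default 10 kb, tiled from coordinate 0, short final
window per chromosome) are scored with relaxed filters — every covered
CpG counts, no balance rule — because the global view serves a
different question (is the bulk methylome intact?) and precedes the
repeat-level filtering. Imprinting control regions are scored the same
way; maternally methylated ICRs must be hypomethylated in sperm, so a
maternal ICR under 15% (configurable) sets a purity flag that guards
against somatic contamination of the sample.

## Differential calling and enrichment

An element is called differentially methylated when
$|M_\text{mut} - M_\text{wt}| > 10$ percentage points — strictly
greater, so a delta of exactly 10.0 is not called. Direction is defined
relative to the mutant (hypo = lower in mutant). Subfamily composition
of the calls is tabulated, sorted by total with alphabetical
tie-breaks, and truncated to the top 20. The distribution shift is
tested with a two-sample Mann–Whitney U (mutant scores vs wild-type
scores): midranks for ties, exact distribution when both groups have at
most 20 observations without ties, otherwise the normal approximation
with tie correction and no continuity correction. The test's scope
defaults to the DM subset, with `scope = "all"` available — the study
design does not pin down which set enters the test, so both are
first-class and the choice is always explicit in the output. No
multiple-testing correction is applied anywhere: the design makes one
planned comparison per question, and corrected variants would misstate
what was computed.

TSS proximity counts calls whose minimal interval-to-point distance is
at most 10 kb (inside = 0), read conservatively from the element
boundary rather than its midpoint. Control classes — LINE1, B1, or
`random_regions()` drawing length-proportional uniform 1-kb intervals —
run through *identical* filters, which is what makes their flat results
interpretable.

# Sanger clones and coat colour

`individual_percent()` pools all clones of an individual
(methylated calls / non-missing calls); pooling, rather than averaging
per-clone percentages, weights clones by their informative CpGs and
matches how per-individual percentages are conventionally reported
above clone diagrams. Conversion QC uses non-CpG cytosines with a 97%
threshold. The between-genotype test is Welch's t by default — with 2–3
individuals per genotype, assuming equal variances buys little and
risks anticonservatism — with the pooled-variance variant behind
`var_equal = TRUE`.

Coat colour maps percent-yellow to five categories and pools them to
Y/M/ψ. The published category edges are informally stated (the
mottled/pseudoagouti-mottled boundary mixes yellow and agouti
percentages), and in practice assignment is made by a trained observer;
the package fixes deterministic half-open boundaries
(100 / >95 / >25 / ≥5 / <5 percent yellow) so that simulated cohorts are
reproducible. Group comparisons are plain Pearson chi-squared on the
2×3 table without continuity correction, collapsing columns empty in
both groups (df reported accordingly) and flagging expected counts
below 5; genotype ratios are tested with a chi-squared goodness-of-fit
against Mendelian expectations.

# The synthetic study

The simulator generates everything the pipeline consumes, with a truth
table. Its defaults are the package's statement of realistic study
conditions, chosen once:

* **Genome**: 2 chromosomes × 2 Mb. CpG spacing geometric with mean
  35 bp (minimum 2 bp). This is denser than a mammalian genome average
  because the toy genome stands in for the repeat-rich compartment
  under study: IAP LTRs are CpG-dense, and elements must be able to
  carry ≥ 8 qualifying CpGs.
* **Repeats**: 2,000 ERVK-like elements of 700 bp across four
  subfamilies (IAPEY, RLTRETN, IAPLTR3, RNERVK23-int), plus LINE1-like
  (1,200 bp) and B1-like (400 bp) control classes; non-overlapping
  placement with random gaps.
* **Methylation**: one true level per element drawn from Beta(18, 2)
  (mean 0.90), shared between samples; background CpGs i.i.d. from the
  same Beta; maternal ICRs from Beta(1.5, 28.5) (mean 0.05), paternal
  ICRs high — the sperm imprint pattern.
* **Planted effect**: 100 elements (1/12 of IAPEY and of RLTRETN)
  shifted by −25 pp in the mutant, subtractively and floored at 0, so
  the planted delta is directly comparable to the pipeline's delta.
* **Counts**: coverage per CpG per sample from NB(mean 30, size 15) —
   30-fold nominal depth with realistic overdispersion — and methylated
  counts Binomial(coverage, level). A `coverage_imbalance` switch
  shifts the mutant's coverage mean to exercise the bias filter.

All randomness descends from one root seed through named sub-streams
(`derive_seed()`), so the genome, methylomes, cohorts and clone
matrices can be regenerated independently and every artefact is
byte-reproducible.

What the simulator does *not* emulate — and what green tests therefore
do not show about real data: correlated methylation between neighbouring
elements, sequence-driven coverage bias (GC, mappability),
bisulphite non-conversion in the WGBS counts (conversion error is
modelled only in the clone simulator), cell-type mixtures beyond the
ICR purity construct, and biological between-individual variance (the
two samples share true levels except where an effect is planted). The
null-calibration results in particular say that the *statistics* are
calibrated under the simulator's null, not that real replicate sperm
methylomes would show zero DM elements — with n = 1 per genotype, real
calls at any threshold include biological variability, which is why
threshold-passing counts in real studies are descriptive and validation
falls to independent methods.

# Problem sizes and determinism

The test suite and the acceptance script run the full stack at desk
scale: 2,000-element genomes (≈ 115,000 CpGs) per replicate, 20-seed
recovery and null-calibration batches, a 600-element shift-detection
run, 100 cohort and 50 clone power replicates, and exhaustive
verification of the chi-squared statistic on all 2×3 tables with total
≤ 12 and of the Mann–Whitney U against full enumeration at small n.
These sizes give stable averages (recovery sensitivity ≈ 0.98, FPR
≈ 10⁻⁴ at the default conditions) while keeping a full run in the order
of a minute. The genome-scale numbers a real study reports (tens of
thousands of scored elements, hundreds of thousands of windows) require
the deposited sequencing data and annotation tracks and are outside
what simulation can or should reproduce; the read-level subsampling
step of real pipelines is additionally unseeded in common practice, so
even a re-run on deposited data would reproduce headline counts only
approximately.

Degenerate inputs are handled by stated convention: empty CpG sets have
undefined scores (error, not NA propagation); all-tied Mann–Whitney
inputs give p = 1; zero-variance equal-mean t-tests give p = 1;
all-zero contingency rows are errors; elements below the CpG minimum
are excluded, never imputed.
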