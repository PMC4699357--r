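---
title: "Methods: population twin WGBS analysis with popmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population twin WGBS analysis with popmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`popmeth` implements a population-scale analysis of whole-genome bisulfite
sequencing (WGBS) data in a two-tissue twin design. This vignette explains
the models and procedures, the parameters that matter, what the bundled
simulator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## Data model and coordinates

The atomic observation is one cytosine on one strand with methylated and
unmethylated read counts; the methylation level is the read fraction and is
defined only at positive coverage. All internal coordinates are 0-based and
half-open (BED convention); the 1-based positions of cytosine reports are
converted at the I/O boundary and nowhere else. A CpG unit pairs the
forward-strand cytosine at position *p* with its reverse-strand mate at
*p* + 1 and is anchored at *p*, which matches dinucleotide-based island
annotation. Units covered on only one strand are carried through I/O
flagged as single-stranded — they fail the strand filter later, but I/O
never silently drops data.

## Site-level quality control

Four rules are applied in a fixed order, with per-rule removal counts
reported:

1. **Strand concordance** — keep units with ≥ 2 reads on *each* strand and
   an absolute between-strand level difference ≤ 20 percentage points. The
   20-point boundary is inclusive; the comparison adds a 10⁻⁹ guard so
   that a difference that is mathematically exactly 20 points is never
   rejected through floating-point rounding.
2. **External blacklist** — remove units whose dinucleotide overlaps any
   supplied blacklist interval (either cytosine suffices, since a variant
   or artifact at either position corrupts the unit).
3. **Study-specific high-coverage blacklist** — per sample, compute the
   mean and SD of pooled unit coverage; flag loci exceeding mean + 1.5 SD;
   blacklist loci flagged in ≥ 2 samples. The statistics are computed on
   *unfiltered* samples, because artifact loci must be visible before
   other filters touch them. A sample with fewer than two covered sites
   has no defined SD and is an error, not a silent skip.
4. **SNP removal and autosome restriction** — as rule 2, against annotated
   SNP positions; chromosome names are normalized to the `chr` dialect at
   import and only `chr1`–`chr22` survive when requested.

The chain is idempotent, and both thresholds are monotone (relaxing the
strand-difference bound never removes more sites; raising the per-strand
read floor never keeps more); both properties are under test.

## Merged-tissue segmentation

Samples of one tissue are merged by summing counts at sites detected in
≥ 3 individuals, which together with the two-reads-per-strand filter
guarantees ≥ 12-fold pooled coverage per retained site. Unmethylated
regions (UMRs) and low-methylated regions (LMRs) are then called with an
explicit cutoff method: maximal runs of consecutive retained CpGs below a
50 % level form candidate segments; runs of ≥ 30 CpGs are UMRs, runs of
4–29 CpGs are LMRs, and shorter runs are discarded. The two size cutoffs
were chosen once to reproduce the characteristic size contrast of the two
region classes (UMRs around 120 CpGs and ~2.4 kb, promoter-like; LMRs
around 11 CpGs and ~750 bp, enhancer-like) and are fully configurable.
Runs break at chromosome boundaries and at any retained CpG at or above
the threshold; no gap limit is imposed, since detection gaps in merged
low-pass data carry no methylation information. Partially methylated
domain detection and smoothing/HMM segmentation are deliberately out of
scope.

## Invariable CpGs and pairwise differential CpGs

A site is *invariable* when detected in ≥ *k* individuals (*k* = 2 by
default, with 5 and 10 as stringent variants) and every detected pooled
level is identical. Identity is tested exactly on the count fractions by
integer cross-multiplication (`m₁·c₂ = m₂·c₁`), never on floating-point
levels, so 3/4 and 6/8 are equal but 50 % and 51 % never collide. The
constant level classifies the site as unmethylated (exactly 0),
fully methylated (exactly 1) or other-constant.

A site is a *pDMC* when a two-sided Fisher exact test on pooled counts is
significant at nominal *p* < 0.05 in at least one pairwise comparison
among detecting samples. No multiple-testing correction is applied at this
stage by design — the regional and permutation machinery downstream is
where error control enters. Two open points were settled as follows:
Fisher tests use strand-pooled counts (consistent with the
strand-concordance filter, which makes the two strands redundant
measurements of one state), and the cell-composition flag reads the
correlation threshold as a magnitude (|R| > 0.5 with *p* < 0.05, across
≥ 10 individuals), since a negative association with a cell fraction is
equally a composition artifact.

The Fisher kernel itself is a vectorized sum of hypergeometric point
probabilities not exceeding the observed table's probability (with the
conventional 1 + 10⁻⁷ tie guard). It is cross-checked in the test suite
against `stats::fisher.test` and against an independent `choose()`-based
enumeration over every 2×2 table with margins up to 30.

## The pDMR scan

The population DMR caller combines two signals over 500-bp windows: how
much CpGs vary across individuals, and how *consistent* that variation is
within the window.

- **Per-CpG SD** over individuals, at sites detected in ≥ 3 individuals.
- **Windows** are anchored at every retained CpG and contain all retained
  CpGs within [anchor, anchor + 500); a sliding window over a sparse site
  list is otherwise ill-defined. Singleton windows are discarded, as is
  any window whose CpG set is a subset of another candidate's set.
  Because candidate windows are contiguous runs over the sorted site
  list, subset elimination reduces to comparing each anchor's right edge
  with its predecessor's; the test suite verifies this against a
  quadratic set-containment oracle.
- **Consistency** is the mean Spearman correlation between each
  individual's window profile and the consensus profile (the per-CpG mean
  over individuals detected there). Individuals covering fewer than two
  window CpGs do not contribute; an individual with a constant profile
  has no rank correlation and is excluded; a constant *consensus* profile
  carries no shape information and contributes a neutral zero. Ties take
  average ranks. Windows with fewer than two scorable individuals are
  unscored and dropped.
- **Score and selection**: the default combination is
  `mean SD × max(consistency, 0)` — multiplicative weighting with
  anti-consistent windows truncated to zero, implementing the view that
  inconsistent profiles are likely false positives. The combination rule
  is pluggable (`sd_rank` ranks by SD among windows above a consistency
  floor). Windows are ranked by score with ties broken deterministically
  by genomic coordinate, the top quantile (10/20/25 %) kept, windows with
  fewer than three CpGs removed, and surviving intervals merged with a
  zero-base-pair merge (overlapping or bookended intervals coalesce).
  Calls split at 50 % regional methylation (coverage-weighted, boundary
  value counts as high) into low- and high-methylation strata.

One property of the score deserves explicit statement. Because each
individual contributes to the consensus profile, the correlation of a
signal-free (exchangeable) window does not center at zero but near
1/√m for m individuals. The scan therefore ranks *relative* consistency;
the positive null baseline cancels between equally sized windows. A
`exclude_self` variant compares each individual to the average of the
others and is centered at zero under the null; it is provided for
diagnostic use and the property-test suite verifies both behaviors. The
score detects regions where inter-individual offsets ride on a non-flat
consensus shape; a region with a perfectly flat consensus and pure
offsets has no rank signal, which is a known limitation of
correlation-with-consensus scoring.

## Twin variance decomposition

Per-site intra-class correlations use the one-way random-effects
mean-squares form, (MSB − MSW)/(MSB + MSW) with group size 2, computed
within complete MZ pairs and complete DZ pairs (≥ 5 of each by default).
Heritability and environment follow the Falconer identities
h² = 2(ICC_MZ − ICC_DZ), c² = ICC_MZ − h², e² = 1 − ICC_MZ, under the
additive-genetic assumption that DZ pairs share half the additive
variance. The identity h² + c² + e² = 1 holds exactly (to floating point)
in the raw view. Estimates are reported *unclamped*, because negative h²
or c² estimates are informative about sampling noise; a clamped view
(components truncated to [0, 1] and renormalized) is provided separately,
since threshold summaries such as "fraction of sites with e² > 0.9"
depend on the clamping convention. ICCs are computed on methylation
levels, not rank-transformed levels. Sites with zero total variance have
no defined ICC and are skipped.

## Environmental DMCs, eDMRs and the permutation FDR

Within one MZ pair, per-site Fisher tests on shared covered sites yield
eDMCs at *p* < 0.05 with the direction of the co-twin difference. A
±500-bp window around each eDMC is a candidate region; a candidate
containing ≥ 3 eDMCs, *all* of one direction, becomes an eDMR spanning
its first to last eDMC, and overlapping same-direction eDMRs merge. A
window containing three eDMCs of mixed direction is disqualified — the
unidirectionality clause is read as a property of the region, and the
direction-match requirement extends to merging for coherence.

The FDR is estimated by permutation: the observed eDMCs — count and
direction multiset preserved — are reassigned uniformly at random among
all tested site positions, eDMRs are re-called, and the FDR is the mean
permuted fraction of eDMCs inside eDMRs divided by the observed fraction
(capped at 1). This null was chosen over re-running Fisher tests because
it preserves the tested-site density, which is the dominant driver of
spurious clusters, at a fraction of the cost. Permutation is within
chromosome by default (a genome-wide option exists), and the generator's
seed makes every estimate reproducible.

Within-pair Fisher testing has little power below roughly 20-fold pooled
coverage per co-twin; analyses of environmental differences should be
restricted to moderate-coverage pairs, and the package's own examples do
so.

## Inter-tissue drift

To ask whether genetic influence stabilizes methylation across tissues,
sites covered in all four samples of two MZ pairs in both tissues are
enriched for genetic signal by keeping the top 50 % by the ratio of
between-pair variance (of pair means) to mean within-pair variance in the
reference tissue; eDMCs of either tissue are excluded; reads are pooled
within pair × tissue; pair 1 versus pair 2 is Fisher-tested per tissue;
and among sites significant in both tissues, the count with concordant
direction is tested against 0.5 with a two-sided exact binomial test. The
variance ratio is computed on levels, not counts, so that coverage
differences between pairs do not masquerade as genetic signal.

## Feature annotation and enrichment

CGI classes follow the precedence island > shore (≤ 2 kb) > shelf
(2–4 kb) > open sea, with north/south assigned by the side of the nearest
island; separation is measured in base pairs from the island edge, and a
site equidistant from two islands resolves to the upstream island. Genic
classes follow the precedence TSS1500 (201–1500 bp upstream,
strand-aware), TSS200, 5′UTR, exon 1, other exons, introns, 3′UTR,
intergenic, resolved across overlapping transcripts by the same order.
For the UTR classes to be reachable at all, the exon classes cover the
*coding* portions of exons; exonic sequence outside the CDS belongs to
the UTRs. Regions (as opposed to sites) are classified by ≥ 1 bp overlap
in precedence order.

Histone-mark tracks are consumed as read-interval BED files: the genome
is tiled into 100-bp bins, each read is assigned to the bin holding its
midpoint, counts are normalized to the donor's total read count (fold
ranks are invariant to the per-million versus fraction choice), the
same-donor normalized input is subtracted, and bins are ranked by the
subtracted signal with coordinate tie-breaks. The top 1 % per donor —
restricted to strictly positive signal, so a flat track yields an empty
set — is kept, and the final set requires reproducibility in ≥ 3 donors.
Promoter bins are H3K4me3 top bins within 1 kb of a TSS; enhancer bins
are H3K4me1 top bins not overlapping any H3K4me3 top bin. Enrichment of
a query set against a caller-stated background is the ratio of in-feature
fractions, with a two-sided Fisher probability on the 2×2 membership
table.

## CpH methylation

CpH (CHG/CHH) calls are strand-specific, since CpH methylation is
asymmetric. A site is called methylated at a strict cutoff — level > 50 %
at ≥ 4 reads in ≥ 2 individuals — which suppresses bisulfite-conversion
artifacts; note the deliberate asymmetry with the ≥ 50 % threshold used
on the *CpG* side of the highCpH-lowCpG classification, both implemented
exactly as specified. Conversion efficiency per sample is
100 × (1 − methylated CpH reads / total CpH reads), with the cohort
median reported. Each methylated CpH is linked to its nearest detected
CpG (ties broken downstream; only filter-passing CpGs count as
"detected"); calls whose nearest CpG is below 50 % are flagged
highCpH-lowCpG, and a flagged site is "clustered" when ≥ 3 flagged sites
fall within ±500 bp in the same individual. Trinucleotide classes
(CpHpG/CpHpH) come from the report's context string; records without one
are classed "unknown" and excluded from context ratios.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults define the simulated study: 7 MZ and 6 DZ pairs
plus two singletons, two tissues (adipose and blood), ~1 CpG per 100 bp
on one synthetic chromosome, Poisson stranded coverage at 4 reads per
strand per site (≈ 8-fold pooled, matching low-pass WGBS; a
negative-binomial option supports overdispersion checks), a bimodal
baseline (20 % of sites near 0 %, 80 % near 95 %, giving ~80 % mean
methylation), 5 % of CpGs carrying a C-ablating variant with
genotype-coded apparent methylation (100/50/0 % by variant dosage, shared
within MZ pairs and per-allele with probability ½ within DZ pairs), 0.2 %
of loci with 30-fold inflated coverage in every sample, 0.6 % bisulfite
conversion failure, and blood-only cell-type mixing.

Latent methylation follows a liability-scale ACE model:
`level = plogis(baseline + A + C + E)` with A pair-correlated (1 for MZ,
0.5 for DZ), C pair-shared, E individual- and tissue-specific, and
variances proportional to per-site (a2, c2, e2) triples summing to at
most 1. The logistic link keeps levels in [0, 1] at the price of mild
attenuation of correlations; at the default liability SD of 0.4 the
attenuation is small enough that twin ICCs on latent levels recover
a2 + c2 (MZ) and a2/2 + c2 (DZ) well within the tolerances the test
suite asserts. The per-site distribution of variance components is not
something the study design pins down, so it is an explicit modeling
choice: 20 % of sites are variable, with a2 drawn from {0, 0.3, 0.6}
(probabilities 0.5/0.3/0.2) and c2 = 0.05 — all configurable.

Cell-type-driven sites are modeled as polarized loci: methylated in one
cell class and unmethylated in another (`plogis(±4)` for neutrophils
versus lymphocytes), with per-sample cell fractions drawn from a
Dirichlet around typical blood composition (concentration 35, matching
realistic inter-individual variability of differential counts). The bulk
blood level mixes the cell-type levels by the sample's fractions before
count emission. Genuinely methylated CpH sites default to a fraction of
5 × 10⁻⁴ at level 0.8 — rare relative to the conversion-noise floor, as
in differentiated somatic tissue, so that the conversion-efficiency
estimator remains dominated by the failure rate it is meant to recover.
Planted environmental DMRs shift one co-twin by 2.5 liability units over
runs of 8 consecutive CpGs, two regions per MZ pair, each in one tissue.

Not emulated: read-level artifacts (the simulator emits counts, not
FASTQ), alignment and mapping biases, age effects, chromosome-scale
methylation domains, linkage between neighboring SNPs, and fine-scale
correlation of methylation between adjacent CpGs outside planted
regions. Passing tests on simulated data therefore validate the
statistical machinery and its bookkeeping — recovery of planted truth
under the stated noise model — not robustness to alignment pathology or
to biological autocorrelation structures the generator does not produce.

## Numerical choices and degenerate inputs

- Exact rational equality (integer cross-multiplication) for
  invariability; a 10⁻⁹ guard at the 20-point strand boundary; the
  1 + 10⁻⁷ tie guard in both exact tests, matching the conventional
  two-sided rules.
- The ACE identity is asserted at 10⁻¹² — exact modulo binary floating
  point, since `a + (1 − a)` need not round to 1 for every double.
- Zero-coverage sites, zero-variance correlation inputs, empty interval
  sets, empty truth tables, chromosomes without CpGs, and samples without
  CpH reads all have defined behavior (skip, NA, empty-with-headers, or
  error with a message naming the cause), and each is exercised by a
  test.
- Ranking ties anywhere (window scores, ChIP bins) break by genomic
  coordinate, making every selection deterministic.
- All randomness flows from a single integer seed through fixed derived
  streams; identical configuration and seed reproduce output files
  byte-identically.

## Problem sizes used by the test suite

The suite validates at sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances while keeping a full run fast:
parameter recovery uses 200 MZ + 200 DZ pairs at 2000 sites per scenario;
the Fisher kernel is enumerated over all ~245,000 tables with margins up
to 30; the window scan is checked exactly against a brute-force oracle on
chromosomes of up to 200 CpGs and by 100 seeded plant-versus-decoy
replicates; the permutation FDR runs 1000 permutations on a 50,000-site
map; filter and segmentation recoveries use cohorts of 2000 CpGs and 40
seeded replicates. `scripts/acceptance.R` re-runs the same computations
from scratch against the installed package and writes the resulting
quantities as JSON.

## Known limitations

- The consistency score cannot see offset-only regions with a flat
  consensus profile, and carries a positive null baseline from
  self-inclusion (both discussed above).
- Falconer estimation is moment-based: no likelihood, no confidence
  intervals, no covariates. Full structural-equation twin modeling is out
  of scope.
- The segmentation cutoffs stand in for likelihood-calibrated region
  finding; they reproduce the UMR/LMR size contrast but are not adaptive
  to coverage.
- Measurement noise in read counts attenuates ICCs toward zero and
  inflates e²; decompositions on low-coverage count-derived levels should
  be read as lower bounds on familial components. The simulator's latent
  levels allow this attenuation to be quantified for any design.
- Cell-composition confounding is addressed by flagging correlated sites,
  not by deconvolution or covariate adjustment.
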