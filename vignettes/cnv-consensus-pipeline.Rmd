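---
title: "Consensus CNVRs, tag haplotypes and population structure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus CNVRs, tag haplotypes and population structure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the models and
conventions each stage implements, the parameters that matter and their
defaults, what the synthetic-cohort generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Coordinates and data model

Every interval in the package is 0-based and half-open, `[start, end)`,
the BED convention. VCF positions (1-based) are converted once on read:
a SNP at VCF position $p$ lies inside $[s, e)$ iff $s < p \le e$.
Book-ended intervals share zero bases and never merge or count as
overlapping. Using one convention internally removes the most common
source of off-by-one drift in interval pipelines.

Phased SNPs are held as a sites-by-chromosomes allele matrix (two columns
per sample, phase order preserved, `NA` for missing). Missing genotypes
are flagged and excluded pairwise downstream; they are never imputed.

## Consensus CNVR construction

A CNV region (CNVR) is the maximal union of per-sample call intervals
that overlap by at least 1 bp. The stage order is fixed and logged:

1. merge each caller's calls into CNVRs;
2. flag outlier samples on combined call counts and drop them;
3. re-merge the retained calls;
4. drop singleton CNVRs (carrier count < 2);
5. keep the fine caller's regions with ≥ 1 bp of coarse-caller overlap
   (boundaries always come from the fine caller, whose breakpoint
   resolution is the reason it anchors the consensus).

Conventions where more than one choice was defensible:

* **Copy state per sample.** A sample with several overlapping calls
  inside one CNVR contributes its *longest* call's copy number — the
  longest call carries the most evidence about the locus as merged.
* **Absent calls are reference.** Samples without a call at a CNVR are
  copy 2, not missing. Carrier frequencies are undefined otherwise.
  Calls that themselves assert copy 2 carry no CNV claim and are dropped
  on entry.
* **Outlier rule.** Samples whose call count exceeds median + 5·MAD are
  outliers. A count-based rule is used because excess calls is exactly
  what distinguishes failed samples; MDS coordinates of the per-sample
  call-presence profile are still computed and written so the usual
  visual screen can be drawn. The flagged-versus-retained contrast is
  reported with a Welch t-test.
* **Overlap length semantics.** `total_overlap_length()` sums the *full*
  length of each fine-caller interval confirmed by ≥ 1 bp of
  coarse-caller overlap, not the intersection length. The quantity of
  interest is "how much CNV length is found by both methods", which is
  the total length of the retained set.

## The random-placement overlap null

To ask how much of the confirmed length is expected by chance, the
observed interval lengths are re-placed uniformly at random: a chromosome
is chosen with probability proportional to its number of valid start
positions (`length − L + 1`), then a start is drawn uniformly. Placements
are independent — intervals may collide, since the observed statistic is a
sum over intervals and nothing in the procedure requires disjointness.
The null is summarised as the mean and sample SD (n − 1) of the overlap
across replicates (default 100). For a single placed interval of length
$L$ against one region of length $M$ on a chromosome of length $G$, the
closed form $P(\text{overlap}) = (L + M - 1)/(G - L + 1)$ (clipped to
[0, 1]) is used as a test oracle. The toy layouts contain no assembly
gaps or centromeres, so no placement exclusions are modelled.

## Annotation

* **Novelty** is conservative: a CNVR is novel only if it overlaps no
  known region by even 1 bp, so adding known regions can only shrink the
  novel set.
* **Carrier frequency** is `100 × carriers / denominator`, reported to
  the nearest whole percent in summaries. The denominator is
  configurable and defaults to the retained (post-outlier) sample count.
  Published cohort summaries are ambiguous between the full and retained
  cohort as denominator; both are supported and the choice is recorded in
  the output header.
* **Sharing** uses fixed-origin bins (0, 5000, 10000, …; last partial
  bin kept); a group occupies a bin iff any of its CNVRs overlaps it.
  Venn cells are disjoint and exhaustive over occupied bins.
* **Windowed correlations** between populations use Pearson correlation
  of per-window call counts (default 10 Mb windows); a constant count
  vector has no defined correlation and yields `NA`, never a silent 0.
* **Gene-type ratios** take the background composition as an input
  table rather than assuming any particular annotation release, because
  expected counts depend on the full background including types the
  query set never hits.

## Tag haplotypes

The tagging model assumes that a CNV that arose once sits on an ancestral
haplotype background, so the dosage (0/1/2) of some phased allele
combination near the CNVR predicts copy number linearly.

1. **Candidate window**: the CNVR ± 5 kb flank, clipped to the
   chromosome. Interior SNPs are included by default; an
   `include_interior = FALSE` mode uses flanks only, for the case where
   SNP calls inside deletions are unreliable.
2. **LD clustering**: r² is the squared Pearson correlation of
   per-chromosome allele indicators (phase is known, so no EM); pairs at
   most 50 kb apart with r² > 0.8 are joined, and single-linkage
   components realise "in LD with at least one other SNP" literally.
   Singleton clusters are dropped.
3. **Haplotypes**: each distinct complete allele string over a cluster is
   one haplotype; dosage counts exact chromosome matches. Haplotypes on
   fewer than 2 chromosomes are dropped as noise.
4. **Informative filter**: haplotypes whose carriers all share one
   integer copy number cannot discriminate and are excluded — including
   from the Bonferroni denominator.
5. **Regression**: OLS of *fractional* copy number (the caller's
   continuous estimate; integer copies lose the dosage-response signal)
   on dosage; two-sided t-test on the slope with n − 2 df; per-CNVR
   Bonferroni (`p × m` for m informative haplotypes); tagged iff any
   adjusted p < 0.05.

Tagging is reported cohort-wide and, when a roster is supplied, per
population, since a haplotype may tag only where the CNV's background is
common.

## Selection enrichment

Selection scores are consumed as s = −log10 p of |iHS| with threshold
s > 3 (i.e. p < 10⁻³), matching the score-file definition rather than a
raw-iHS threshold. A CNVR counts as *selected* if at least one SNP above
threshold falls inside its ± 5 kb flanked interval — the same flanks used
for the SNP membership table, so the two analyses agree on region
boundaries. The membership table is tested with a Pearson chi-square
without continuity correction.

CNV-state counts use the complete-count convention: every
(CNVR, sample) pair contributes exactly one count — deletion, wild type
or insertion — with uncalled samples counted as wild type. Published
analogues of this table appear to exclude some pairs by an unstated
criterion; the complete count is the only reproducible convention, and
row totals are reported so any exclusion can be diagnosed.

The joint tagged × selected excess is tested by a Pearson chi-square on
the 2×2 CNVR cross-classification built from the margins and the observed
joint count (Fisher's exact test available by flag); the procedure behind
published joint-excess p-values of this kind is not recoverable, so the
default is the simplest classical test and its calibration is verified by
simulation under independence.

## Population structure

Integer copies are encoded as allele pairs split as evenly as possible
between chromosomes — 0→(1,1), 1→(1,2), 2→(2,2), 3→(2,3), 4→(3,3),
5→(3,4), capping at (4,4) for six or more copies; decoding returns
min(copy, 6). PCA runs on the column-centred copy matrix with
zero-variance loci dropped; the IBS-MDS mode over allele-pair sharing is
provided for parity with identity-by-state pipelines — the two give the
same qualitative structure, and the PCA default is numerically simpler.

F_ST uses the Weir–Cockerham variance components a, b, c per locus,
restricted to bi-allelic deletion CNVRs (all copy states in {0, 1, 2}),
where the deletion-allele dosage 2 − copy is phase-unambiguous — the
reason duplications are excluded. Per-locus estimates are a/(a + b + c);
global and pairwise values are ratios of summed components; negative
estimates are retained (truncation biases averages); monomorphic loci are
undefined and excluded from the sums. High-F_ST CNVRs exceed
mean + 3·SD of the defined per-locus distribution (at least 10 defined
values required for the threshold to mean anything).

## The synthetic cohort

The generator produces everything the pipeline reads, reproducibly from
one seed. What it emulates, and the defaults (all configurable, one named
key each):

* **Genome**: 2 chromosomes × 10 Mb.
* **Cohort**: 3 populations × 20 samples in 2 linguistic groups.
* **True CNVRs**: 300 disjoint intervals, log-normal lengths with median
  5 kb (sdlog 0.6), placed with reserved gaps so tagging windows never
  overlap; a configuration whose CNVRs cannot fit errors before
  generating anything.
* **Frequencies**: a beta base frequency per CNVR (mean 0.08 per
  chromosome, so carrier frequencies centre near 15%), then hierarchical
  Balding–Nichols draws — group-level divergence 0.08, population-level
  0.02 — giving the two-tier structure that PCA and F_ST should and do
  recover.
* **Taggable vs recurrent backgrounds**: 60% of CNVRs are carried by a
  single designated founder haplotype, so copy number is exactly
  determined by that haplotype's dosage; the rest are recurrent, with
  carrier chromosomes drawn independently of SNP background (and for the
  mixed type, a random sign per chromosome).
* **SNPs**: 1 per 500 bp, generated as a founder mosaic — each LD block
  (20 kb, except taggable-CNVR windows which form their own block) has a
  pool of 4 founder haplotypes and each chromosome picks one per block
  with population-specific weights. A small pool gives the strong
  within-block LD the tagging model assumes. Taggable blocks additionally
  carry three variants private to the CNV's founder background,
  emulating the mutations that accumulate on an ancestral haplotype after
  the CNV arises; without them a minority of blocks have no SNP pattern
  that isolates the CNV background at all.
* **Callers**: caller A reports each carried CNVR with Normal(0, 200 bp)
  boundary jitter and fractional copy = copy + Normal(0, 0.15) — an SD
  chosen so rounding recovers the true integer > 99% of the time; caller
  B reports the span of true CNVRs within 20 kb of each other as one
  coarse region with 1 kb jitter. Each caller has its own false-positive
  process (rate 0.02 per true CNVR per sample; coarse-caller FP lengths
  scaled up to its granularity); 3 designated outlier samples get 10×
  that rate in both callers.
* **Selection scores**: −log10 of a uniform p, so P(s > 3) = 10⁻³ in the
  background; inside the 5% of CNVRs designated as selected (± 5 kb) the
  exceedance probability is multiplied by the enrichment ratio
  (default 3).
* **Known regions**: 97% of true CNVRs, with up to 2 kb of random
  padding.
* **Missingness**: 0.2% per genotype.

What it does **not** emulate: coalescent genealogies and recombination
(the mosaic has block-constant ancestry), mutation-rate or mappability
variation, GC-dependent caller bias, caller-specific error modes beyond
jitter/merging/FPs, assembly gaps, and relatedness between samples.
Consequently, passing tests show that the pipeline's logic is correct
under its stated assumptions and recovers known truth in a structured
cohort — not that real callers on real genomes meet those assumptions.

## Problem sizes and numerical choices

Tests and examples run at desk scale by design: toy layouts of
50–100 kb for the exhaustive per-base interval oracles; 1–10 Mb genomes,
15–300 CNVRs and 24–90 samples for cohort-level properties; 50 seeds for
the tagging size experiment; 100 placement replicates for overlap nulls;
1000 replicates for regression-p uniformity. The convergence check for
configured carrier frequencies uses one population of 500 samples and a
3-standard-error band.

Degenerate inputs are handled explicitly rather than silently:
monomorphic SNPs have undefined r² and are excluded from clustering;
constant dosage refuses regression (caught by the informative filter);
constant window counts give `NA` correlations; zero-margin contingency
tables and empty CNVR sets error; chi-square on a table is refused rather
than corrected when a margin is zero. Ties in the copy-state rule are
broken by call length only; no randomness is involved anywhere outside
the seeded generators, which is what makes the end-to-end pipeline
byte-reproducible from its seed.

## Known limitations

* The outlier criterion is a count-based surrogate for a visual screen;
  cohorts whose failed samples have normal call counts but aberrant call
  *profiles* would need the MDS view.
* The informative-haplotype filter follows the literal convention of
  excluding haplotypes whose carriers share one copy number; a perfectly
  tagging haplotype whose carriers are all heterozygous is rescued in
  practice by its complementary haplotypes, but the filter itself is
  deliberately strict.
* F_ST is only computed where CNV phase is unambiguous (bi-allelic
  deletions); duplications contribute to PCA but not to differentiation
  estimates.
* The complete-count convention for CNV-state tables will not reproduce
  published tables that excluded (CNVR, sample) pairs by unstated rules.
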