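# cnvrpipe

Cohort-scale analysis of copy number variant regions (CNVRs) built from the
output of two CNV callers with very different region granularity — a
fine-grained caller that resolves breakpoints well and a coarse read-depth
caller that merges nearby loci. The package is aimed at population
geneticists who have per-sample CNV calls, phased SNP genotypes and
per-SNP selection scores for a structured cohort, and want a reproducible
path from raw calls to a high-confidence consensus CNVR set with
annotation, SNP-haplotype tagging, selection-signature enrichment and
population-structure summaries. A synthetic-cohort generator emulates the
whole data regime, so every stage runs and is testable without any access
to controlled data.

## What it computes

**Consensus CNVRs.** A CNVR is the maximal union of call intervals that
overlap by at least 1 bp across samples (coordinates are 0-based,
half-open throughout). The pipeline order is fixed: per-caller merge →
outlier-sample removal (call count above median + 5·MAD) → re-merge →
singleton filter (carrier count ≥ 2) → consensus intersection, keeping the
fine caller's regions that overlap the coarse caller's regions by ≥ 1 bp.

**Random-placement null.** How much of the retained CNVR length would be
confirmed by chance is estimated by placing the observed interval lengths
uniformly at random on the genome (chromosome chosen with probability
∝ number of valid starts) and recomputing the overlap, reported as
mean ± SD over replicates.

**Tag haplotypes.** Near each CNVR (± 5 kb), SNPs with pairwise LD
r² > 0.8 are clustered by single linkage; every distinct phased allele
string over a cluster is a haplotype with per-sample dosage 0/1/2.
Fractional copy number is regressed on dosage by OLS; the slope's t-test
p-value is Bonferroni-corrected by the number of informative haplotypes at
the CNVR, and the CNVR is *tagged* if any haplotype reaches adjusted
p < 0.05.

**Selection enrichment.** With per-SNP scores s = −log10 p of |iHS| and
threshold s > 3, SNPs are cross-tabulated by region membership
(CNVR ± 5 kb) and significance, and tested with a Pearson chi-square.
CNV states (deletion / wild type / insertion per CNVR–sample pair) are
contrasted between CNVRs with and without selected SNPs, and the joint
excess of tagged × selected CNVRs is tested against the independence
expectation `n_tagged × n_selected / n_total`.

**Population structure.** Integer copies are encoded as even-split allele
pairs (0→1 1, 1→1 2, 2→2 2, 3→2 3, … capped at 4 4); PCA runs on the
column-centred copy matrix (an IBS-MDS mode is also provided). F_ST is the
Weir–Cockerham estimator restricted to bi-allelic deletion loci, where the
deletion-allele dosage 2 − copy is unambiguous; per-locus values more than
3 SD above the mean flag high-differentiation CNVRs.

## Worked example

```r
library(cnvrpipe)
cfg    <- cohort_config(seed = 42)          # 3 populations x 20 samples,
cohort <- generate_cohort(cfg)              # 300 true CNVRs on 2 x 10 Mb

res <- build_consensus(cohort$calls_a, cohort$calls_b, cohort$samples)
res
#> <consensus_result> 237 consensus CNVRs (A: 250, B: 212); 3 outlier samples removed
glance(res)[, 1:6]
#>         set n_cnvr total_cnv mean_cnv_per_cnvr mean_cnvr_per_individual mean_length_kb
#> 1  caller_a    250      2433           9.73200                 42.68421       7.967468
#> 2  caller_b    212      2487          11.73113                 43.63158      42.381481
#> 3 consensus    237      2406          10.15190                 42.21053       7.611557
```

The three configured outlier samples are recovered exactly, and the coarse
caller's mean region length (42.4 kb) versus the fine caller's (8.0 kb)
reproduces the two-granularity regime the pipeline is designed for. The
observed two-caller overlap exceeds its random-placement expectation:

```r
nul <- expected_overlap(res$consensus$regions,
                        merge_calls_to_cnvr(cohort$calls_b)$regions,
                        cohort$layout, n_sims = 100, seed = 42)
nul
#> <overlap_null> observed 1.804 Mb; simulated 1.406 +/- 0.0696 Mb (100 sims)
```

Tagging and population differentiation:

```r
qc   <- snp_qc(cohort$snps)
tags <- tag_cnvrs(res$consensus, qc$snps, cohort$layout)
tags
#> <tag_result> 137 of 237 CNVRs tagged; 2659 haplotype associations

roster <- dplyr::filter(cohort$samples, sample %in% res$retained_samples)
fst_deletions(res$consensus, roster)
#> <cnv_fst> 93 bi-allelic deletion loci; global F_ST = 0.06105
#>        P1     P2     P3
#> P1 0.0000 0.0277 0.0766
#> P2 0.0277 0.0000 0.0782
#> P3 0.0766 0.0782 0.0000
```

58% of consensus CNVRs are tagged (the generator makes 60% of CNVRs arise
on a single taggable haplotype background), and the pairwise F_ST matrix
recovers the configured two-tier structure: P1 and P2 share a linguistic
group and sit close together; P3 is diverged from both.

`run_pipeline(cfg, "out/")` chains every stage
(simulate → consensus → null-overlap → annotate → taghap → selection →
popstruct), writes flat TSV/BED/VCF outputs per stage plus a
`manifest.json` with the seed, resolved parameters and file digests, and
is byte-reproducible from the seed.

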