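# envmeth

Separating environment-associated from genotype-driven differential DNA
methylation in whole-genome bisulfite sequencing (WGBS) cohorts.

`envmeth` re-implements, as a tested and reusable R package, an integrated
epigenome analysis for a two-group exposure design (e.g. smoking-exposed
versus unexposed mother–child pairs, 8 vs 8, sampled at birth and up to
four years later):

* **DMR calling** from per-CpG methylated/unmethylated counts:
  local-likelihood smoothing (coverage-weighted tricube local quadratic
  fit on the logit scale; windows of ≥ 11 CpGs and ≥ 1 kb, broken at CpG
  gaps > 2 kb), candidate segmentation on a per-site group statistic, a
  SAM-style moderated *t* with permutation p-values, and retention at
  pSAM < 0.1 with |Δ methylation| > 0.1 in both raw and smoothed data;
  a permutation FDR scan over Δ thresholds (1–25 %).
* **meQTL classification**: every SNP within ± 5 kb of a DMR is
  correlated (Pearson, dosage 0/1/2 vs per-sample mean raw methylation);
  the |r| threshold is calibrated from a dosage-permutation null at a 10 %
  false-call rate (realized values near 0.6), splitting DMRs into
  genotype-influenced **gDMRs** and non-genetically-influenced **ngDMRs**,
  with CpG-destroying SNPs flagged (a destroyed CpG forces methylation to
  0 in homozygous and 0.5 in heterozygous carriers).
* **Longitudinal stability**: a DMR is *qualitatively* stable when its
  group difference keeps its sign at a later timepoint, *quantitatively*
  stable when additionally |Δ| shrinks by at most 5 percentage points;
  plus hierarchical clustering of samples on ngDMR CpGs (coverage ≥ 10 in
  all samples, Euclidean distance).
* **Chromatin segmentation**: a 16-state Bernoulli-emission hidden Markov
  model over four binarized histone marks (H3K4me1, H3K27ac, H3K27me3,
  H3K9me3) on 200-bp bins, trained by Baum–Welch (≤ 400 iterations)
  across all samples; canonical state labels (Void; active 1–3; bivalent
  4–11; repressed 12–14; Amplification 15), ≥ 2-sample group consensus,
  TSS association with the 400-bp chaining rule, enhancer/promoter
  meta-elements, and base-pair-weighted transition analysis between
  condition consensus paths.
* **Shuffle enrichment** of DMRs in chromatin element classes
  (length-matched uniform placement, 1000 randomizations, fold change
  over the null mean, empirical and normal-approximation upper-tail p).
* **Commuting enhancers**: intragenic enhancers regulating at least one
  gene beyond their host gene ("commuting"), or none of the host's
  ("exclusive commuting"); differentially methylated enhancers (DMEs)
  compared with other enhancers by Mann–Whitney tests of length and
  target count.
* **Methylation–expression coupling**: target assignment by chromatin
  category (nearest TSS for void/promoter, interaction-derived targets
  for enhancer/repressed, union rule for DMEs), Spearman correlation at
  α = 0.05 with sign-split summaries, a moderated genome-wide
  differential-expression test with Benjamini–Hochberg correction at 10 %
  FDR, and hypergeometric gene-set enrichment.

Because raw cohort data of this kind are controlled-access, the package
ships a seeded **synthetic-data generator** (`simulate_dataset()`) that
produces complete inputs with the statistical structure the analysis
assumes — beta-binomial WGBS counts with planted exposure and
genotype-linked DMRs (including CpG-destroying SNPs), four-mark chromatin
tracks with planted group transitions, and expression coupled to element
methylation — so every stage is testable end to end.

## Worked example

```r
library(envmeth)

cfg <- sim_config(genome = c(chr1 = 2e6, chr2 = 1e6),
                  n_exposure_dmrs = 12, n_genotype_dmrs = 10,
                  n_cpg_destroying_snps = 4, n_null_snps = 40,
                  timepoints = c(0, 1), n_enhancer_gene_pairs = 20, seed = 7)
sim <- simulate_dataset(cfg)
sim
#> Synthetic dataset: 3 Mb genome, 24084 CpGs, 16 individuals, 2 timepoint(s)
#>   planted: 12 exposure / 10 genotype DMRs; 4 CpG-destroying SNPs

ms <- sim$methylomes$t0
calls <- call_dmrs(ms)          # smooth -> candidates -> SAM -> filter
calls
#> DMR calls: 14 DMRs from 72 candidates ( 8 hyper / 6 hypo )
head(calls$dmrs[, c("chrom","start","end","n_cpgs","delta_raw","p_sam","direction")], 3)
#>   chrom   start     end n_cpgs  delta_raw        p_sam direction
#> 1  chr1  387508  388886     14 -0.2376572 0.0001388696      hypo
#> 2  chr1 1822545 1824027     15  0.2189218 0.0001388696     hyper
#> 3  chr1  281790  283463     16  0.2054129 0.0001388696     hyper

cls <- classify_dmrs(calls$dmrs, ms, sim$genotypes, r_threshold = 0.6)
cls
#> DMR classification: 2/14 gDMR (|r| > 0.6, target FDR 0.1)

st <- assess_stability(calls$dmrs, sim$methylomes["t1"])
stability_summary(st, setNames(cls$table$dmr_class, cls$table$dmr_id))
#>   timepoint dmr_class  n frac_qualitative frac_quantitative
#> 1        t1      gDMR  2                1         1.0000000
#> 2        t1     ngDMR 12                1         0.9166667
```

All 12 planted exposure DMRs are recovered; the two gDMR calls pick up
genotype-driven regions whose random dosage imbalance between the groups
produced a group methylation difference — the separation the meQTL step
exists for. The stability table reads as: every DMR keeps its direction
one year later (qualitative), and all but one stay within the 5-point
shrinkage bound (quantitative). With 20 or more DMRs,
`classify_dmrs()` calibrates the |r| threshold itself from the
permutation null instead of taking a fixed 0.6.

`run_pipeline(run_config(seed = 1), outdir = "out")` chains every stage
(simulate → DMRs → meQTL → stability → chromatin HMM → transitions →
enrichment → enhancers → expression link) and writes standard-format
outputs plus a `manifest.json` with parameters, summaries and checksums;
reruns with the same seed are byte-identical. A thin command-line wrapper
lives at `inst/scripts/envmeth`.

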