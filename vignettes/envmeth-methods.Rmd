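---
title: "Methods: models, parameters and design choices in envmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in envmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `envmeth`, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made
where more than one reasonable option existed.

## The observable and the smoother

WGBS reduces to a pair of counts per CpG and sample: methylated reads
$M$ and unmethylated reads $U$, with coverage $N = M + U$ and raw
methylation $M/N$. Counts are overdispersed relative to binomial
sampling because molecules within a library share a latent methylation
state; all region-level summaries in the package therefore work on mean
raw methylation across CpGs, and single-CpG inference is avoided.

Smoothing borrows strength across neighbouring CpGs. For each sample and
site, the package fits a weighted quadratic on the logit methylation
scale over the smallest symmetric window that contains at least `ns`
CpGs and spans at least `h` bp on each side, with weights equal to
coverage times a tricube kernel in distance; the fitted value at the
site (inverse-logit transformed) is the smoothed methylation.
Chromosomes are split wherever consecutive CpGs are more than `maxGap`
apart, so no window bridges a large CpG desert; segments shorter than
`ns` CpGs fall back to a flagged coverage-weighted mean. Defaults are
`ns = 11`, `h = 500` (so windows are at least 1 kb wide) and
`maxGap = 2000` — a deliberately small window suited to high-coverage
data, where smoothing should denoise rather than interpolate over
kilobases.

Two numerical details matter. Raw fractions are clamped to
$[0.005, 0.995]$ before the logit, so fully (un)methylated sites remain
finite while interior values are transformed exactly — a constant
methylation profile is then an exact fixed point of the smoother, and
the fit is linear in the transformed response, which makes it verifiable
against an independent least-squares implementation to machine
precision. Second, positions are centred and expressed in kb inside the
normal-equation solve, keeping the 3×3 system well conditioned; if the
quadratic is degenerate the solver falls back to a linear fit, then to a
weighted mean. Zero-coverage sites carry zero weight but still receive
the fitted value — that is the point of smoothing. A known artefact of
local quadratic fits is small opposite-sign side lobes flanking a sharp
methylation step; these never carry a material raw methylation
difference and are removed by the Δ filter.

## DMR calling

A per-site signal-to-noise statistic (smoking minus non-smoking group
mean of smoothed methylation over a pooled SD) is floored at the 75th
percentile of the pooled SDs across sites, which prevents near-constant
stretches from generating huge statistics. Consecutive same-sign sites
above the 97.5th percentile of the absolute statistic (configurable;
this quantile convention assumes differential signal is sparse
genome-wide) and within `maxGap` of each other become candidates;
candidates need at least 3 CpGs.

Candidates are tested with a SAM-style moderated statistic on
per-candidate per-sample mean raw methylation:
$d = (\bar m_1 - \bar m_2) / (s + s_0)$, where $s$ is the two-sample
pooled standard error and the fudge factor $s_0$ is the median of the
per-candidate $s$ values — one standard SAM choice; it damps the
statistic where $s$ is small by chance. P-values come from group-label
permutations pooled over the full candidate set with the +1 correction
(100 permutations by default; an exact mode enumerates all label
assignments when feasible). DMRs are candidates with $p < 0.1$ and an
absolute group difference above the Δ cutoff (default 0.1) **in both raw
and smoothed data**, ranked by p then |Δ|, with coordinate tie-breaks
for determinism. The 10 % Δ cutoff doubles as a guard against whole-blood
cell-composition artefacts, which a promoter-methylation screen over
lineage-marker genes (`lineage_marker_screen()`) shows to stay below
that level.

The permutation FDR scan re-runs candidates → SAM → filter for each
label permutation and reports, per Δ threshold, the median ratio of
permutation to observed DMR counts. Smoothing is per-sample and
label-invariant, so the smoothed matrix is computed once and reused —
an identity, not an approximation. When nothing is observed at a
threshold the FDR is reported missing rather than zero.

## meQTL classification

Each DMR's per-sample mean raw methylation is correlated (Pearson by
default — dosage 0/1/2 is ordinal enough, and a single signed axis is
wanted; Spearman is an option) with every SNP within ± 5 kb,
pairwise-complete over non-missing dosages (no imputation), and the
maximal-|r| SNP retained. The gDMR/ngDMR threshold is calibrated by
permuting dosage vectors across samples (200 rounds), recomputing the
per-DMR max-|r| null, and taking the $(1-\mathrm{fdr})$ quantile of the
pooled null: an uncorrelated genotype then produces a false gDMR call at
exactly the target rate among DMRs that have an in-window SNP. This
operationalization was chosen over a ratio-of-counts FDR estimate
because the latter degenerates on data with no genotype effects (the
ratio is ~1 at every threshold), whereas the quantile rule behaves
sensibly in both the null and the planted regime and reproduces the
familiar near-0.6 realized threshold at 16 samples. A fixed threshold
can be supplied instead (`r_threshold`), which is also the fallback for
small DMR sets (< 20), where calibration is refused as unstable.
CpG-destroying SNPs (the variant removes the CpG dinucleotide on either
strand) are flagged per DMR by the same window rule; flank context is
required — it is never guessed from the alleles alone.

## Longitudinal stability

Stability re-evaluates the group difference of regions called at the
reference timepoint in later methylomes. Qualitative stability keeps the
sign; quantitative stability additionally bounds the *decrease* of |Δ|
at 5 absolute percentage points on the methylation scale (increases
never break stability — the bound is about fading, not growth). Year-4
comparisons default to the birth reference, configurable. Sample
clustering uses CpGs inside the supplied regions with coverage ≥ 10 in
every sample, Euclidean distance and average linkage (fixed for
determinism; only the distance is dictated by the analysis design), and
summarises whether each individual's timepoints are mutual nearest
neighbours.

## Chromatin model

Four binarized histone marks on 200-bp bins admit $2^4 = 16$
presence/absence combinations, so the HMM uses 16 states with
independent Bernoulli emissions per mark, trained by Baum–Welch over all
samples jointly (each chromosome of each sample is an independent
sequence), up to 400 iterations or a log-likelihood gain below $10^{-4}$.
Emissions are initialised at the 16 canonical mark patterns (k-means
centroids for smaller models) plus seeded jitter; after training, states
are greedily matched to the canonical patterns by emission distance and
relabelled, so state 0 is always Void, 1–3 active, 4–11 bivalent
(mixed active and repressive marks), 12–14 repressed and 15
Amplification (all four marks). Decoding is per-bin posterior argmax
with ties to the lower state index (Viterbi available behind a flag);
posterior decoding was preferred because downstream consensus and
transition summaries are per-bin quantities.

Group consensus assigns a bin the state supported by at least 2 samples,
most-support first, ties to the lower index, otherwise Void; the exact
multi-qualifier rule is a documented choice. TSS association covers
elements overlapping a TSS, elements directly abutting those, and
elements within 400 bp of either — the chain deliberately does not
iterate further. Active elements split into promoters (TSS-associated)
and enhancers (not); transition analysis compares the two condition
consensus paths at the meta-state level (base-pair-weighted matrix,
destination fractions, two-sided binomial test of the active-vs-repressed
asymmetry), reports the 16-state matrix alongside, and measures the
enrichment of variable chromatin (any state change) in DMR masks as fold
change over the genomic rate; a within-group label-swap permutation test
for the amount of change is provided as a separate function.

## Enrichment, enhancers, expression

Shuffle enrichment places length-matched regions uniformly on the
genome (chromosome chosen proportional to length among chromosomes that
fit the region) 1000 times; overlap means ≥ 1 bp; fold change is
observed over null mean and the empirical upper-tail p uses the +1
correction so it is never zero — a normal-approximation p from the null
mean and SD is emitted alongside for magnitudes beyond the empirical
resolution. No gap/blacklist masking is applied by default, matching the
plain whole-genome procedure.

Enhancer classification: intragenic means overlapping any gene body,
with the largest-overlap gene as host; targets come from interaction
anchors overlapping the element; commuting requires at least one
non-host target, exclusive commuting additionally no host interaction.
DMR target assignment by chromatin category uses the nearest TSS (from
the DMR midpoint, ties to the lower-coordinate gene) for void and
promoter contexts, interaction-derived targets for enhancer and
repressed contexts, and the union of DMR and element targets for DMEs;
a DMR overlapping several categories contributes one record per
category. Coupling is Spearman (invariant to monotone normalization
choices) at α = 0.05 with sign-split per-category summaries. The
genome-wide differential-expression test is a pooled-variance t with the
gene variance shrunk halfway toward the gene-wise median, BH-corrected
at 10 % FDR — deliberately simple, since normalization and batch
correction happen upstream and the package receives a normalized matrix.
Gene-set enrichment is the hypergeometric upper tail with BH adjustment;
the set-level expression score (permutation p of the mean |t| against
size-matched random sets) is a documented stand-in for an unpublished
original. The odds-ratio extrapolation reports the linear reading
$(\mathrm{OR}-1)\times 100 \times \text{units}$ — an OR of 1.40 per
10 % methylation loss reads as +40 % risk per unit and ~+400 % over full
loss — with the multiplicative alternative $\mathrm{OR}^{\text{units}}$
alongside.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 8 individuals per exposure
group, 30× mean coverage with negative-binomial dispersion 0.05,
beta-binomial methylation dispersion 0.02 (realistic WGBS
overdispersion), CpG density 8 per kb (close to the genome-wide CpG
rate), a 20-Mb two-chromosome toy genome, 50 exposure DMRs of width
1.5 kb with a planted raw difference of 0.2 placed symmetrically around
0.5 (half hyper, half hypo), 30 genotype DMRs with 0.2 methylation per
alternative allele under Hardy–Weinberg dosages at allele frequency 0.3
(so all three dosages occur at n = 16), 10 CpG-destroying SNPs planted
at near-fully-methylated CpGs inside genotype DMRs (carriers forced to
0.5/0 for het/hom), timepoints 0/1/4 years with the exposure delta
shrinking 0.02 per year, 200-bp chromatin bins with emission
probabilities 0.9/0.05 (on/off), a 5 % transition fraction placed at 3×
density inside exposure DMRs with a 2:1 active:repressed destination
bias, and enhancer–gene coupling targeting |Spearman| 0.6 over 100
pairs. Exposure and genotype effects are planted disjointly so
class-recovery tests are unambiguous; mixed planting is not simulated.
Every planted DMR is checked at generation time to contain ≥ 11 CpGs
and span ≥ 1 kb, so it is callable under the default smoothing
parameters. Per-stage seeds are derived deterministically from the
config seed, so the whole dataset — and each stage alone — is exactly
reproducible.

What the generator does *not* emulate: stable between-individual
methylation profiles (real people differ at baseline; the simulated
null is exchangeable across individuals), cell-composition structure in
whole blood, read-level artefacts (bisulfite conversion error, mapping
bias, strand asymmetries), linkage disequilibrium among SNPs,
correlated placement of CpGs (islands/shores), and co-occurring
genotype and exposure effects at the same locus. Consequences worth
knowing: on null simulations the caller produces no DMRs at the 10 % Δ
threshold (real cohorts do, from inter-individual variability), so null
FDR calibration is assessed at a low Δ threshold where the null caller
has counts; and recovery rates on synthetic data are upper bounds on
real-data performance, demonstrating correctness of the machinery
rather than field sensitivity.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` use the full 20-Mb study-scale
configuration for DMR caller recovery, and smaller instances elsewhere
so each property is measured where it is statistically informative: a
1.5-Mb genome over 20 replicate seeds for the null FDR calibration, a
6-Mb genome with 25+25 planted DMRs for meQTL classification, a 1-Mb
genome (5000 bins) for HMM training at emission probabilities 0.95/0.02,
a 2-Mb genome with 10 % ROI coverage and 1000 shuffles for enrichment,
and a 3-Mb dataset with 20 planted pairs for expression coupling. These
are scientific choices of instance size — each large enough that the
tested quantity has a stable expectation, small enough to keep the suite
routine to run.

## Known limitations

* The smoother's least-squares-on-logit formulation is a deliberate,
  testable simplification of iterative local likelihood; the two agree
  closely away from extreme methylation but are not identical there.
* The SAM permutation p is pooled across candidates, which assumes
  candidate statistics are comparable after moderation; with very few
  candidates the resolution of p is limited (+1 correction dominates).
* meQTL calibration treats the per-DMR best |r| as exchangeable across
  DMRs; strong differences in per-window SNP counts are only partially
  absorbed by the max-over-SNPs construction.
* The HMM assumes conditional independence of marks given the state —
  exactly the assumption that makes 16 states "all combinations" — and
  canonical relabelling is greedy, which can mislabel states whose
  emissions sit far from every canonical pattern (visible only at high
  noise).
* Consensus-based transition analysis discards within-group
  heterogeneity beyond the ≥ 2-sample rule; the permutation test over
  label swaps is the guard against over-reading consensus differences.
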