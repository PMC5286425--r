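---
title: "Profiling genomic isolation in structured populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling genomic isolation in structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Human (and more generally diploid) populations that have experienced
geographic or linguistic barriers to gene flow accumulate a recognizable
genomic signature: drift at reduced effective size raises homozygosity,
lengthens runs of homozygosity (RoH), increases identity-by-state (IBS) and
identity-by-descent (IBD) sharing among members, and extends linkage
disequilibrium (LD). `isopop` turns a diploid SNP panel plus a sample
metadata table into a quantitative isolation profile per population, ranks
populations along a principal component of those profiles, estimates each
population's contemporary effective size from LD, and converts observed
inbreeding gains into envelopes of compatible (Ne, time-since-isolation)
combinations. A forward-time simulator with exact ground truth closes the
loop: every statistic in the package can be checked against a cohort whose
demography is known by construction.

# The model and its statistics

## Drift and inbreeding

The package's demographic backbone is the idealized Wright-Fisher
population of constant effective size `Ne`. Under stationarity the
inbreeding coefficient after `t` generations satisfies

    F(t) = 1 - (1 - 1/(2 Ne))^t

and the gain `dF = F_obs - F_0` relative to an assumed inbreeding level
`F_0` at the time of the split can be inverted for either quantity:
`time_since_isolation()` solves for `t`, `ne_given_time()` for `Ne`.
`isolation_envelope()` evaluates the `Ne` bounds over a grid of `t`, using
the lowest and highest inbreeding coefficients observed among open
populations as the bracketing assumptions for `F_0`. Because `dF` alone
cannot identify both parameters, the envelope is the honest summary: any
(Ne, t) between the two curves is compatible with the observed gain.

## Intra-population measures

Seven measures are computed per population on the post-QC genotypes:

* observed homozygosity `hom = 1 - het` (`observed_heterozygosity()`);
* inter-locus dispersion: the standard deviation over loci of per-locus
  heterozygosity (`interlocus_dispersion()`). The phrase "square root of
  the standard deviation" in the field's usage is internally inconsistent;
  we default to the SD and expose the literal reading behind
  `mode = "sqrt_sd"`;
* mean intra-population pairwise IBS (`pairwise_ibs()`), with per-locus
  similarity `(2 - |g_i - g_j|)/2` averaged over jointly observed loci;
* mean RoH count and mean total RoH length per individual (`scan_roh()`);
* W_int, the total length of within-population IBD segments divided by the
  number of individual pairs (`w_int()`), in centimorgans when the segment
  source provides them;
* mean LD-block length (`ld_blocks()`).

RoH lengths are additionally decomposed into classes by a univariate
Gaussian mixture fitted by EM with BIC model selection
(`classify_roh_lengths()`), and the inbreeding coefficient `F_ROH` is the
fraction of the (centromere-masked) genome inside RoH (`froh()`).

## RoH detection

`scan_roh()` implements the conventional SNP-count sliding window: windows
of 50 consecutive SNPs pass when they contain at most one heterozygous and
five missing calls; a SNP is segment-eligible when strictly more than 5% of
the windows covering it pass; maximal runs of eligible SNPs are trimmed to
homozygous end SNPs and kept when at least 0.5 Mb long with at least
25 SNPs. All parameters live in `roh_params()`. The literature around the
underlying tool describes the window both as "5 Mb" and as its default
SNP-count setting; we read it as the 50-SNP default and provide a physical
window via `window_mode = "bp"` for sensitivity analyses. End-SNP trimming
interacts with the hit-ratio rule, so a homozygous stretch can lose a SNP
at either end relative to naive expectations; the test suite pins the
behaviour to an independently coded brute-force reference rather than to
folklore examples.

## LD blocks

`ld_blocks()` implements the D' confidence-interval block definition:
two-locus haplotype frequencies from unphased genotypes by EM, a 90%
interval for |D'| from the profile of the multinomial likelihood on a
0.001 grid (a flat-prior posterior, the classic practice), pairs classed as
strong LD / strong recombination / inconclusive, and maximal spans whose
informative pairs are at least 95% strong LD taken greedily longest-first.
The default maximum pair span is 200 kb, the default of the tool that
popularized the definition; this is also what keeps the pairwise sweep
tractable. The likelihood profile is deterministic, so block calls are
reproducible without a seed.

## Effective size from LD

`burrows_r2()` estimates, for SNP pairs (by default on different
chromosomes, so that physical linkage cannot inflate the signal), the
Burrows composite disequilibrium from unphased genotype counts with the
`S/(S-1)` correction, standardized by per-locus variance terms that absorb
Hardy-Weinberg departures. `ldne_estimate()` subtracts the finite-sample
expectation (`1/S + 3.19/S^2` for harmonic sample size `S >= 30`, the
published small-sample coefficients otherwise) and inverts the drift
expectation `E(r2') ~ 1/(3 Ne) + 0.69/Ne^2`, giving

    Ne = (1/3 + sqrt(1/9 + 2.76 r2')) / (2 r2')

with `Ne = Inf` reported when no drift signal remains — the correct answer
for a very large population at this sample size. Parametric 95% bounds pass
`n_pairs * mean_r2 / chi-square` quantiles through the same transformation;
with physically linked pairs included this interval is anti-conservative,
one reason the inter-chromosome policy is the default. A minor-allele
frequency floor of 0.05 excludes the rare variants that bias the method.

## Multivariate structure

`isolation_pca()` standardizes the per-population measures and
eigen-decomposes their correlation matrix — correlation, not covariance,
because the measures live on incommensurable scales (fractions, base
pairs, centimorgans). Signs are fixed so the total-RoH-length loading on
PC1 is positive, making "more isolated" a consistent direction.
`group_compare()` applies two-sided Mann-Whitney U tests (exact when the
pooled sample is at most 20 without ties) and median-centred
Brown-Forsythe/Levene variance tests, with the Bonferroni-corrected alpha
`0.05/7 = 0.007` reported to three decimals. `classical_mds()` is Torgerson
scaling of the `1 - IBS` matrix; `ibd_distance_regression()` fits genetic
on great-circle geographic distance over open-population pairs only and
reports every pair's deviation from that line, the isolation-by-distance
residual that flags populations more diverged than their geography
predicts; `hierarchical_cluster()` gives the complete-linkage population
tree.

# The simulator and what it does (not) emulate

`simulate_cohort()` is a forward-time founder-mosaic Wright-Fisher
simulator: every founder haplotype is an atomic label, descendants carry
mosaics of founder tiles, and recombination places Poisson(cM/100)
crossovers uniformly per chromosome (uniform 1 cM/Mb by default — the
conventional stand-in when no genetic map is given). Because descent is
tracked exactly, autozygosity (`autozygosity()`) and IBD segments
(`true_ibd_segments()`) are read off the mosaics rather than inferred, and
`emit_dataset()` drops genotypes onto evenly spaced SNPs whose founder
alleles are drawn from a configurable frequency spectrum
(uniform minor-allele frequency 0.05-0.5 by default, a chip-like spectrum).

Mating draws both parents independently with replacement, selfing included.
This is a deliberate choice: it is exactly the random union of gametes
behind `F(t) = 1 - (1 - 1/(2Ne))^t`, so the simulator's expected
autozygosity equals the closed form and calibration tests have a sharp
target. Excluding selfing (available via `allow_selfing = FALSE`) delays
inbreeding by roughly one generation and shifts the effective size by 1/2,
a deterministic bias of about 0.01 at (Ne = 50, t = 30) — larger than the
Monte-Carlo error of the calibration itself. Migration is implemented as
backward parent-source choice (an offspring's parents both come from deme
`d'` with probability `m[d, d']`), which keeps census sizes constant and
reproduces panmixia at symmetric rate 0.5.

What the simulator does **not** emulate: mutation after founding,
selection, non-uniform recombination maps, genotyping error, ascertainment
bias of real SNP chips, and non-constant deme sizes. Passing tests on
synthetic cohorts therefore demonstrate the statistics' correctness and
calibration under the stated demographic model, not robustness to the
technical noise of real array data.

`make_study_fixture()` bundles the study design used throughout the tests
and documentation: 6 open demes (Ne = 2000, splitting 4 generations before
sampling, so essentially undrifted) and 4 isolated demes
(Ne = 100, 200, 400, 800, drifting for 30 generations), 25 samples per
deme, 10,000 SNPs on 4 chromosomes of 100 Mb. At these sizes the whole
suite runs on one CPU in minutes; the SNP spacing (40 kb) keeps expected
autozygous segments (about 1.7 Mb at Ne = 100) comfortably detectable.

# Numerical choices and degenerate inputs

* Positions are 1-based; intervals are half-open, so a segment's length is
  `end_bp - start_bp` and mask subtraction is exact.
* Missing genotypes are excluded pairwise/per-locus everywhere; nothing is
  imputed.
* Minor-allele orientation is recomputed from the sample after QC, with
  frequency ties broken by allele label, making dosage codes reproducible.
* QC order is SNPs first, then individuals, in one pass. Removing an
  individual can push a SNP's call rate to the boundary, so the filter is
  idempotent only when no rate crosses a threshold on the second look; the
  pipeline applies it once, as the analysis it mirrors did.
* Relatedness pruning removes one member of each PI_HAT > 0.185 pair,
  chosen at random under the run seed; visiting pairs in a fixed order
  makes the outcome reproducible. The method-of-moments estimator uses
  count-based unbiased allele-frequency products and clamps the IBD state
  probabilities into [0, 1]; on a few thousand SNPs the clamped estimate
  for truly unrelated pairs scatters a few hundredths above zero, which is
  why the pruning threshold (0.185, third-degree relatives) sits far above
  the null noise.
* The Gaussian-mixture EM restarts 10 times per candidate k from
  k-means++-style draws, stops on a 1e-8 log-likelihood change, rejects
  degenerate components (vanishing variance), and selects k by BIC; ties
  in class labels are resolved by ordering components by mean.
* `estimate_ne()` reports `Inf` rather than a negative or absurd size when
  the drift signal is non-positive; downstream code treats that as "no
  evidence of a finite Ne at this sample size".
* Single global seeds fan out to per-stage child seeds through a fixed
  affine counter, so stages stay independently reproducible.

# Known limitations

* The block finder enumerates candidate spans under the simplified
  fraction rule; it does not require the outermost pair itself to be in
  strong LD, so adjacent true blocks separated by few inconclusive pairs
  can occasionally merge.
* The chi-square parametric CI for Ne ignores the dependence among SNP
  pairs and is therefore narrower than a jackknife would be.
* PI_HAT relatedness is computed against panel-wide allele frequencies; in
  strongly drifted demes it measures recent kinship *and* deme-level
  allele-frequency shift, which is the tool-faithful but occasionally
  aggressive behaviour (small, old isolates can lose many members at the
  default threshold).
* W_int depends on the IBD segment source; ground-truth segments from the
  simulator contain every segment above the length floor, whereas real
  detectors miss short segments, so absolute W_int values are comparable
  only within one segment source.

# Problem sizes used in the packaged checks

The bundled tests and the acceptance script run the simulator at desk
scale, chosen once as the smallest sizes at which every calibration target
is statistically sharp: 20 replicates for the autozygosity calibration
(N = 50, t = 30, four 100 Mb chromosomes), 20 replicates of
(N = 100, S = 50) cohorts with 5,000 SNPs on 20 chromosomes for the Ne
recovery, 100 random fixtures for the W_int oracle, 40 random genotype
vectors plus constructed edge cases for the RoH oracle, and the 10-deme
study fixture for the end-to-end discrimination checks.
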