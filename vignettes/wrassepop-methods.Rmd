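---
title: "Models and methods in wrassepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in wrassepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `wrassepop`, the
choices made where the methods literature leaves options open, what the
synthetic-data generators do and do not emulate, and the package's known
limitations. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## The k-mer spectrum mixture

A k-mer multiplicity histogram from whole-genome reads mixes several
classes of distinct k-mers: sequencing-error k-mers (rare, low
multiplicity), k-mers unique to one haplotype at heterozygous sites
(coverage λ per haplotype), single-copy homozygous k-mers (coverage 2λ),
and repeats (2λc for copy number c). `fitSpectrum` fits, by EM on the
categorical likelihood of multiplicities weighted by counts:

* error: negative binomial with free mean and dispersion;
* haploid: Poisson(λ);
* diploid: Poisson(2λ), **hard-constrained** to twice the haploid mean;
* repeats: Poisson(2λc) for c = 2 .. 1 + `n_repeat_classes` (default 4).

All components are **zero-truncated**, because a k-mer observed zero times
is absent from any real counter's histogram; the simulator drops
zero-multiplicity draws for the same reason. Sharing one coverage
parameter across the Poisson classes is what makes the model identifiable
on noisy spectra — with free means the haploid/diploid/repeat labels are
arbitrary.

Numerical choices: multiplicities above ten times the initial peak
estimate are pooled into one tail bin whose exact k-mer mass is retained
for the genome-size integral; the M-steps for λ (1-D golden-section) and
the NB parameters (Nelder–Mead on log scale) are generalized EM steps
accepted only when they improve the expected complete-data objective, so
the log-likelihood trace is non-decreasing by construction (asserted in
tests); convergence is a relative log-likelihood change below `tol`
(default 1e-8, `max_iter` 2000).

Initialization is deterministic: λ starts at the highest local maximum of
the histogram above multiplicity 4, the NB moments come from the sub-λ/2
region. Because a spectrum often admits near-equal-likelihood readings —
a single peak explained as haploid at λ or diploid at λ/2; a het-dominant
double peak explained as haploid+diploid at λ or diploid+first-repeat at
λ/2 — EM is run from both the peak and half-peak starts and ties are
broken by parsimony: the fit with the least total repeat weight, then the
largest diploid weight, wins. This prefers the least repetitive, most
diploid reading of the genome, which is the conventional interpretation
of a unimodal or bimodal spectrum.

Derived quantities:

* genome size `G = Σ m·n(m)·P(non-error | m) / (2λ)` — the sequenced k-mer
  mass attributed to the genome, divided by the diploid coverage;
* heterozygous sites `n_het = Σ n(m)·P(haploid | m) / (2k)`.

The 2k divisor assumes isolated heterozygous sites (k novel k-mers on each
haplotype). Clustered polymorphism yields fewer novel k-mers per site, so
the divisor is exposed as the `kmers_per_het` argument; treat the estimate
as an upper-bound-flavored approximation when heterozygosity is dense
(at 1.5–2% heterozygosity, adjacent sites are less than 2k = 64 bp apart
on average and windows overlap). This conversion is a modelling choice of
this package; published genome profilers parameterize heterozygosity
differently.

## Locus filtering

`filterSites` applies per-site acceptance bounds with the defaults
min QUAL 600, DP within [20, 999], MQ within [0, 90]. QUAL and MQ are
site-level; the depth bound is applied to each population's mean of
per-sample FORMAT depths when the VCF provides them (falling back to site
DP), because depth is the quantity that plausibly varies by population.
Rejections are tallied against the **first** failing criterion in a fixed
order, so input = kept + Σ tally with no double counting.

`mafFilter` removes loci whose pooled minor-allele frequency is strictly
below the threshold (default 0.01; a locus exactly at the threshold is
kept). `hweTest` implements both the two-sided conditional exact test on
the heterozygote count (default — exact at the small per-population sample
sizes typical of this work) and the 1-df chi-square variant, because the
popular packages differ in their default. `hwePrune` removes a locus when
the per-population Benjamini–Hochberg-adjusted p-value falls below α in at
least `min_pops` populations (default 2 — a deviation in a single sample
is more likely a sampling artifact than a locus-level problem).
`thinByDistance` is a greedy left-to-right scan per contig keeping loci at
least `thin_bp` apart (≥, so exact spacing passes).

A sample-size caveat the package makes explicit: with 15 diploids per
population the smallest p-value the exact test can produce is ≈ 4.4e-5
(zero heterozygotes at balanced allele counts) and the chi-square test
≈ 1e-4; under BH correction across ~33k loci the significance threshold at
rank ~22 is ≈ 3.3e-5, so **no locus can be pruned at that sample size**.
The filter-bookkeeping fixture (`simulateFilterFixture`) therefore defaults
to 30 individuals per population, where planted zero-heterozygote
violators reach p ≈ 1e-9 and the planted arithmetic (33,866 − 609 − 22 =
33,235 with the default counts) is exact under both test variants.

## Diversity and differentiation

Per population and locus, gene diversity is `Hs = 2p(1−p)·n/(n−1)` with n
the number of genotyped individuals, observed heterozygosity the
heterozygote fraction, and `FIS = 1 − Ho/Hs` on locus-averaged values,
with a percentile bootstrap over loci for the FIS interval. The n/(n−1)
correction leaves a small positive FIS bias at small n (≈ +0.036 at
n = 15, ≈ +0.01 at n = 50) that vanishes as n grows; it is the
conventional small-sample form for this workflow.

`wcFst` computes Weir–Cockerham (1984) variance components a (among
populations), b (among individuals within), c (within individuals) per
locus, and combines loci as a **ratio of sums** θ = Σa / Σ(a+b+c) — not
the mean of per-locus ratios, which is biased for loci with small
denominators. Monomorphic loci contribute zeros and drop out. Negative
estimates are reported as computed; truncation at zero would distort the
bootstrap distribution. Confidence intervals are 2.5/97.5 percentiles over
1000 (default) bootstrap resamples of loci; a population pair is called
significantly differentiated when its interval excludes zero. The
estimator is verified against an independently coded brute-force
variance-component oracle to 1e-12 on fuzzed tables.

`hetDeficitTest` runs a paired t-test of per-locus (Hs − Ho), with Hs and
Ho population-averaged per locus, df = n_loci − 1. `ldSurvey` computes
genotype-dosage r² for all same-contig pairs and a seeded random sample of
cross-contig pairs (pairwise-complete individuals; pairs with fewer than 3
complete observations are skipped), plus same-contig means excluding the
nearest n loci. Nearest-n is measured in index distance within the
per-contig position order — base-pair distance is a defensible
alternative, but index distance matches how "the nearest n SNPs" reads in
the panel-design setting.

`locuswiseFstPermTest` tests per-locus differentiation by permuting
population labels with the add-one convention p = (1 + #{θ* ≥ θ}) /
(n_perm + 1). Because the permutation distribution over 0/1/2 genotype
counts is discrete, the atom at the observed value counts toward p and the
test is conservative at small n (type-I rate ~1–2% at nominal 5% with 25
diploids per group); it never exceeds the nominal rate.

## Individual structure and assignment

Distances between individuals are Provesti/allele-sharing distances,
mean |g_i − g_j| / 2 over loci non-missing in both — the natural dosage
metric, bounded by 0 (identical) and 1 (opposite homozygotes). UPGMA
(average linkage, ultrametric heights) builds the tree; clade support is
the percentage of 100 (default) loci-resampled replicate trees containing
the same leaf set, via `ape`. The hclust-based implementation is checked
against a naive O(n³) agglomeration oracle on fuzzed matrices.

DAPC: genotypes are centered by 2p and scaled by √(p(1−p)) (missing values
imputed at the locus mean after centering — PCA only; missingness is never
imputed in the statistics above), reduced to `n_pcs` principal components,
and linear discriminant axes are computed from the within/between scatter
of the PC scores with a small ridge on the within matrix for degenerate
cases. Membership probabilities are softmax(−½ D²) over squared
Mahalanobis distances to group centroids in the within-group-sphered
discriminant space — the standard Gaussian-posterior reading with equal
priors. The number of PCs to retain is chosen by a-score
(`alphaOptimize`): observed self-reassignment rate minus its mean under
label permutation (default 10 permutations), averaged over groups.

`findClusters` selects the number of clusters by
BIC(K) = n·ln(WSS/n) + K·ln(n) over seeded multi-start k-means on PC
scores. It retains the **20 leading PCs** (capped at n − 2) rather than a
variance-fraction target: at realistic differentiation (F_ST ~ 0.06,
tens of individuals, 10⁴–10⁵ loci) the population structure lives in the
first few components while each of the ~n noise components carries a
similar eigenvalue, so retaining a 95%-variance set (~n components) makes
the relative WSS drop from true clusters smaller than the BIC penalty and
K = 1 always wins, while retaining only the handful of structure PCs lets
k-means subdivide real clusters essentially free of noise and overfits K.
The 20-PC default sits in the wide stable region between those failure
modes (recovering K = 4 on a four-population study-scale simulation and
K = 1–2 in the homogeneous and two-population checks).

`monteCarloCV` evaluates assignment over a grid of training fractions
(default 0.5/0.7/0.9) × top-FST locus fractions (10/25/50/100%) × 30
repeats = 360 evaluations. Loci are ranked by Weir–Cockerham FST computed
on the **training individuals only** — a leakage guard asserted by a test
that plants a locus divergent only among held-out individuals and checks
it is not top-ranked.

## Outlier scan and panel design

`pcaOutlierScan` excludes loci with MAF < 0.05, computes K principal
components of the scaled genotypes, regresses each locus's dosages on the
K score vectors (t-statistics; vectorized for complete loci, per-locus
refits where genotypes are missing), forms robust squared Mahalanobis
distances of the z-vectors (minimum covariance determinant scatter, or a
median/MAD scale when K = 1), rescales by the genomic inflation factor
gif = median(D²)/median(χ²_K), and converts to p-values on χ²_K and
Storey q-values. K is supplied by the user from the returned
explained-variance series; the automated default takes the largest drop in
that series, standing in for the by-eye scree read. Loci with q below 0.1
(default) are flagged; `contigOutlierClusters` lists contigs carrying more
than two flags.

Storey q-values estimate π₀ on the λ-grid 0.05–0.95 with a cubic
smoothing spline evaluated at the largest λ (clipped to [0, 1]) and equal
π₀ times the BH step-up adjustment — monotone in p by construction.

A power boundary worth knowing: when "outliers" are planted by drawing
population frequencies from a higher-F Balding–Nichols distribution, the
**realized** among-population divergence of each planted locus is itself
random (roughly F·χ²_{r−1}/(r−1) across r populations). With r = 4, a
background F of 0.02 and 10⁴ tests, the q < 0.1 detection envelope
corresponds to realized divergence ≈ 0.12, and about a quarter of loci
planted at F = 0.3 realize less than that — independent of sample size —
while ~10% more drift below the scan's own MAF ≥ 0.05 exclusion. Measured
recovery under these conditions is therefore ~60–65%, an intrinsic
property of drift-style planting, not of the scan: divergence that was
never realized in the data cannot be detected by any method. Directional
(selection-style) frequency shifts would be recovered essentially
completely.

`selectPanel` takes, per scaffold, the maximum pairwise-FST SNP (ties
broken by lowest position), ranks candidates across scaffolds by
descending FST and truncates at the floor (default 0.15). The floor is
applied to the cross-scaffold ranked list; applying it before or after the
per-scaffold maximum is equivalent for the per-scaffold winners.
`genotypeConcordance` partitions shared discovery/validation cells into
matching / missing / non-matching percentages summing to 100 (a cell
missing in either dataset counts as missing). `robustSubset` applies
strict per-population mean-quality thresholds.

## What the simulators emulate — and what they do not

`simulatePopulations` is a Balding–Nichols sampler: ancestral frequencies
uniform on [0.05, 0.5] by default (the ascertainment regime of discovery
panels that exclude rare variants), per-population frequencies
Beta-distributed with divergence parameter F (scalar or per locus),
binomial genotypes, optional planted high-F outliers, uniform missingness
(default 2% — a free parameter, since no empirical rate is implied), and
regular locus coordinates for thinning tests. It reproduces exactly the
statistical structure the estimators assume: allele-frequency divergence
with E[FST] = F, Hardy–Weinberg genotypes within populations, and
independent loci. It does **not** emulate linkage blocks (see
`simulateLinkedPair` for two-locus LD), demographic history, clines or
admixture, genotyping error, or non-random missingness. Tests passing on
these simulations therefore validate the estimators and their calibration
— not robustness to the full messiness of real data.

`simulateKmerSpectrum` draws class sizes from the same mixture the EM
fits, with one structural difference kept deliberately: heterozygous
k-mer windows are counted as disjoint (2k distinct haploid k-mers per
site), so dense heterozygosity in the simulator slightly overstates the
haploid class relative to a real genome with clustered SNPs.

Problem sizes used by the test suite and acceptance script — 20,000 loci
× 60 individuals for estimator recovery, 200 replicates × 1,000 loci ×
200 bootstrap resamples for interval coverage, a 6 Mb genome analog over
a coverage grid {10, 15, 30, 60} × 20 seeds, 10⁴ loci × 160 individuals
× 10 seeds for the outlier scan, and the full 360-cell cross-validation
grid — were chosen as the smallest designs at which the claims are
statistically sharp; coverage of a loci-resampling bootstrap, in
particular, is a property of the resampling scheme rather than of the
locus count.

## Known limitations

* The heterozygous-site conversion divisor (2k) is approximate for dense
  or clustered polymorphism; see above.
* FIS carries the small positive n/(n−1) finite-sample bias noted above.
* LD surveys use composite genotype r², not haplotype-phase LD.
* The permutation FST test is conservative at small sample sizes.
* The a-score permutation default (10) trades Monte-Carlo noise for speed;
  raise `n_perm` for publication-grade PC selection.
* BayeScan-style Bayesian outlier detection is not implemented; external
  outlier lists can be compared via `outlierConcordance`.
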