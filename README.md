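# wrassepop

Population genomics of SNP panels in non-model species: genome
characterization from k-mer spectra, locus filtering, diversity and
differentiation statistics, individual assignment, outlier scans, and
diagnostic-marker panel design — with simulators that make every stage
testable without any external data.

The package is aimed at researchers building SNP resources for wild
populations (fisheries, aquaculture traceability, conservation genetics),
where a typical workflow runs from a de novo genome's k-mer profile through
a filtered genotype matrix to a small panel of diagnostic markers that can
assign individuals back to their population of origin.

## What it computes

* **k-mer spectrum mixture model** (`fitSpectrum`): expectation-maximization
  fit of a zero-truncated negative binomial (sequencing-error k-mers) plus
  Poisson components for the haploid (mean λ), diploid (2λ) and repeat
  (2λc) k-mer classes, with one shared coverage parameter. Yields genome
  size G = Σ m·n(m)·P(non-error|m) / 2λ and a heterozygous-site count from
  the haploid class mass (`estimateGenomeSize`, `estimateHetSites`).
* **Locus filtering** (`filterSites`, `mafFilter`, `hweTest`, `hwePrune`,
  `thinByDistance`): per-population QUAL/DP/MQ site acceptance, pooled
  minor-allele-frequency threshold, exact or chi-square Hardy–Weinberg tests
  with Benjamini–Hochberg FDR across loci, and greedy physical thinning.
* **Diversity and differentiation** (`diversityStats`, `wcFst`,
  `hetDeficitTest`, `ldSurvey`): gene diversity H_S, observed
  heterozygosity H_o, F_IS = 1 − H_o/H_S with bootstrap CIs; multi-locus
  Weir–Cockerham θ as a ratio of summed variance components
  θ = Σa / Σ(a+b+c) with percentile bootstrap-over-loci confidence
  intervals; paired t-test of per-locus heterozygote deficit; genotype-r²
  linkage surveys within and across contigs.
* **Individual structure and assignment** (`provestiDist`, `upgmaTree`,
  `bootstrapSupport`, `findClusters`, `alphaOptimize`, `dapcFit`,
  `dapcPredict`, `monteCarloCV`): allele-sharing distances, UPGMA trees
  with clade bootstrap support, BIC-based cluster number over k-means,
  discriminant analysis of principal components with a-score-optimized PC
  retention, and Monte-Carlo cross-validated assignment over a
  training-fraction × top-FST-locus-fraction grid.
* **Outlier scans and panel design** (`pcaOutlierScan`, `storeyQvalues`,
  `selectPanel`, `locuswiseFstPermTest`, `genotypeConcordance`,
  `robustSubset`): pcadapt-style PC-regression z-scores with robust
  Mahalanobis distances, genomic-inflation correction and Storey q-values;
  per-scaffold top-FST panel selection truncated at an FST floor;
  validation metrics for genotyped panels.
* **Simulators** (`simulatePopulations`, `simulateLinkedPair`,
  `simulateKmerSpectrum`, `simulateFilterFixture`): Balding–Nichols
  genotypes with target FST and planted outliers, LD locus pairs with a
  target r², parametric k-mer spectra, and filter-bookkeeping fixtures.

## Worked example

```r
library(wrassepop)

# four populations, 15 diploids each, 2,000 SNPs at F_ST = 0.06
g <- simulatePopulations(n_pops = 4, n_per_pop = 15, n_loci = 2000,
                         target_fst = 0.06, seed = 11)
g
#> GenotypeMatrix: 2000 loci x 60 individuals
#>   populations: pop1 (15), pop2 (15), pop3 (15), pop4 (15)
#>   missing genotypes: 1.92%
#>   contigs: 40

wcFst(g, n_boot = 200, seed = 2)
#> Weir-Cockerham FST ( 200 bootstraps )
#>   overall theta = 0.0580 [0.0550, 0.0615]
#>   pairwise:
#>        pop1   pop2   pop3   pop4
#>   pop1     NA 0.0598 0.0564 0.0556
#>   ...
```

The overall θ of 0.058 recovers the simulated divergence of 0.06 within
sampling error, and the bootstrap interval [0.055, 0.062] excludes zero —
the criterion for calling a pair of populations significantly
differentiated. `diversityStats(g)` on the same object reports H_S ≈ 0.359,
H_o ≈ 0.346 and a small positive within-population F_IS, the expected
signature of a finite-sample gene-diversity correction.

A k-mer spectrum of a heterozygous 6 Mb genome sequenced at 15× per
haplotype is characterized with:

```r
h <- simulateKmerSpectrum(6e6, 15, het_sites = 9e4, k = 32,
                          error_kmers = 3e5, repeat_fraction = 0.05, seed = 42)
fit <- fitSpectrum(h)
estimateGenomeSize(fit)   # 5,996,794 bp   (truth 6,000,000)
estimateHetSites(fit)     # 89,998         (truth 90,000)
```

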