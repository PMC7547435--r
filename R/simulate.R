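#' Simulate population genotypes under the Balding-Nichols model
#'
#' For each locus an ancestral allele frequency p is drawn from
#' \code{ancestral_maf} (uniform); each population's frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so the expected differentiation (FST) across
#' populations equals F; genotypes are then binomial(2, population frequency).
#' Optionally, \code{n_outliers} loci are planted with an elevated divergence
#' parameter \code{outlier_fst}, emulating loci under divergent selection.
#' The defaults mirror a four-population design with 15 diploid individuals
#' per population.
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population (scalar or one per population).
#' @param n_loci number of biallelic loci.
#' @param target_fst Balding-Nichols F: scalar, or one value per locus.
#'   F below 1e-9 is treated as exact sharing of the ancestral frequency.
#' @param ancestral_maf range of the uniform ancestral-frequency law
#'   (default c(0.05, 0.5), the ascertained-SNP regime of discovery panels
#'   that exclude rare variants).
#' @param n_outliers,outlier_fst count and divergence of planted outlier loci
#'   (positions chosen at random; flagged in \code{lociInfo()$outlier}).
#' @param missing_rate probability that any genotype is missing (default 0.02).
#' @param contig_length,snp_spacing locus coordinates: loci are laid out every
#'   \code{snp_spacing} bp on contigs of \code{contig_length} bp.
#' @param seed RNG seed (NULL = use the current stream).
#' @return a [GenotypeMatrix-class]; \code{lociInfo()} carries \code{outlier}
#'   flags and the per-locus \code{true_fst} used, \code{metadata()} the
#'   per-population allele frequencies.
#' @examples
#' g <- simulatePopulations(n_pops = 2, n_per_pop = 10, n_loci = 50,
#'                          target_fst = 0.05, seed = 1)
#' g
#' @export
simulatePopulations <- function(n_pops = 4, n_per_pop = 15, n_loci = 1000,
                                target_fst = 0.06,
                                ancestral_maf = c(0.05, 0.5),
                                n_outliers = 0, outlier_fst = 0.3,
                                missing_rate = 0.02,
                                contig_length = 20000L, snp_spacing = 400L,
                                seed = NULL) {
  stopifnot(n_pops >= 1, n_loci >= 1, all(target_fst >= 0),
            all(target_fst < 1), n_outliers <= n_loci,
            missing_rate >= 0, missing_rate < 1)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  .withSeed(seed, {
    F_loc <- rep_len(target_fst, n_loci)
    outlier <- rep(FALSE, n_loci)
    if (n_outliers > 0) {
      idx <- sample.int(n_loci, n_outliers)
      F_loc[idx] <- outlier_fst
      outlier[idx] <- TRUE
    }
    p_anc <- stats::runif(n_loci, ancestral_maf[1], ancestral_maf[2])
    pop_freq <- matrix(0, n_loci, n_pops)
    for (j in seq_len(n_pops)) {
      pj <- p_anc
      nz <- F_loc >= 1e-9
      if (any(nz)) {
        a <- p_anc[nz] * (1 - F_loc[nz]) / F_loc[nz]
        b <- (1 - p_anc[nz]) * (1 - F_loc[nz]) / F_loc[nz]
        pj[nz] <- stats::rbeta(sum(nz), a, b)
      }
      pop_freq[, j] <- pj
    }
    n_ind <- sum(n_per_pop)
    geno <- matrix(0L, n_loci, n_ind)
    col0 <- 0L
    for (j in seq_len(n_pops)) {
      nj <- n_per_pop[j]
      geno[, col0 + seq_len(nj)] <-
        stats::rbinom(n_loci * nj, 2L, rep(pop_freq[, j], nj))
      col0 <- col0 + nj
    }
    if (missing_rate > 0)
      geno[stats::runif(length(geno)) < missing_rate] <- NA
    per_contig <- max(1L, contig_length %/% snp_spacing)
    contig <- paste0("ctg", sprintf("%05d", (seq_len(n_loci) - 1L) %/%
                                      per_contig + 1L))
    pos <- ((seq_len(n_loci) - 1L) %% per_contig + 1L) * snp_spacing
    pops <- rep(paste0("pop", seq_len(n_pops)), n_per_pop)
    g <- GenotypeMatrix(geno, populations = pops, contig = contig, pos = pos)
    rowData(g)$outlier <- outlier   # locus order == construction order here
    rowData(g)$true_fst <- F_loc
    metadata(g)$pop_freq <- pop_freq
    g
  })
}

#' Simulate a pair of loci in linkage disequilibrium
#'
#' Builds two-locus haplotype frequencies with coupling coefficient
#' D = sqrt(r2_target) * maf * (1 - maf) (both loci at frequency \code{maf}),
#' draws 2n haplotypes, and returns the diploid dosages. The squared genotype
#' correlation then has expectation approximately \code{r2_target}.
#'
#' @param r2_target target squared correlation in [0, 1].
#' @param n number of diploid individuals.
#' @param maf allele frequency at both loci (in (0, 0.5]).
#' @param seed RNG seed.
#' @return a two-locus [GenotypeMatrix-class] (single population "pop1").
#' @export
simulateLinkedPair <- function(r2_target, n, maf = 0.3, seed = NULL) {
  stopifnot(r2_target >= 0, r2_target <= 1, maf > 0, maf <= 0.5, n >= 2)
  D <- sqrt(r2_target) * maf * (1 - maf)
  hap <- c(AB = maf^2 + D, Ab = maf * (1 - maf) - D,
           aB = maf * (1 - maf) - D, ab = (1 - maf)^2 + D)
  if (any(hap < -1e-12))
    stop("infeasible (r2_target, maf): haplotype frequency ",
         signif(min(hap), 3), " < 0")
  hap <- pmax(hap, 0)
  .withSeed(seed, {
    draws <- sample.int(4L, 2L * n, replace = TRUE, prob = hap)
    carriesA <- draws <= 2L          # AB, Ab
    carriesB <- draws %in% c(1L, 3L) # AB, aB
    g1 <- colSums(matrix(carriesA, 2L))
    g2 <- colSums(matrix(carriesB, 2L))
    GenotypeMatrix(rbind(locusA = g1, locusB = g2), populations = "pop1",
                   contig = c("ctgA", "ctgB"), pos = c(1L, 1L))
  })
}

#' Simulate a parametric k-mer spectrum
#'
#' Draws per-class k-mer multiplicities and tallies them into a histogram.
#' Classes: sequencing-error k-mers with negative-binomial multiplicities;
#' haploid k-mers (2k distinct per heterozygous site, one k-length window per
#' haplotype) with Poisson(lambda) multiplicities; diploid k-mers
#' (single-copy genome minus the k windows converted to haploid pairs) with
#' Poisson(2*lambda); and repeat k-mers with Poisson(2*lambda*c) for copy
#' number c >= 2 drawn from \code{repeat_copy_law} until the repeat genome
#' mass is covered. K-mers drawn with multiplicity 0 are unobservable and
#' dropped, as in real k-mer counters.
#'
#' @param genome_size haploid genome size in bp.
#' @param mean_coverage_haploid Poisson mean of the haploid class (lambda).
#' @param het_sites number of heterozygous positions.
#' @param k k-mer length (default 32).
#' @param error_kmers number of distinct error k-mers.
#' @param error_nb_mean,error_nb_dispersion negative-binomial mean and size of
#'   the error class.
#' @param repeat_fraction share of the genome in repeats (copy number >= 2).
#' @param repeat_copy_law function(n) returning n integer copy numbers >= 2
#'   (default: 2 + geometric(0.5)).
#' @param seed RNG seed.
#' @return a [KmerHistogram-class]; \code{attr(, "truth")} records the class
#'   sizes actually simulated (error, haploid, diploid, repeat distinct
#'   k-mers, plus zero-multiplicity drops).
#' @export
simulateKmerSpectrum <- function(genome_size, mean_coverage_haploid,
                                 het_sites = 0, k = 32L,
                                 error_kmers = 0, error_nb_mean = 2,
                                 error_nb_dispersion = 0.5,
                                 repeat_fraction = 0,
                                 repeat_copy_law = function(n)
                                   2L + stats::rgeom(n, 0.5),
                                 seed = NULL) {
  stopifnot(genome_size > 0, mean_coverage_haploid > 0,
            repeat_fraction >= 0, repeat_fraction < 1, het_sites >= 0)
  lam <- mean_coverage_haploid
  n_hap <- 2L * k * het_sites
  n_dip <- round(genome_size * (1 - repeat_fraction)) - k * het_sites
  if (n_dip < 0)
    stop("diploid class size negative: too many heterozygous sites for ",
         "this genome size")
  .withSeed(seed, {
    reps <- integer(0)
    if (repeat_fraction > 0) {
      target <- round(genome_size * repeat_fraction)
      got <- 0
      while (got < target) {
        batch <- repeat_copy_law(max(1000L, ceiling((target - got) / 3)))
        keep <- cumsum(batch) <= (target - got)
        if (!any(keep)) { reps <- c(reps, batch[1]); break }
        reps <- c(reps, batch[keep])
        got <- got + sum(batch[keep])
        if (!all(keep)) break
      }
    }
    m_err <- if (error_kmers > 0)
      stats::rnbinom(error_kmers, mu = error_nb_mean,
                     size = error_nb_dispersion) else integer(0)
    m_hap <- if (n_hap > 0) stats::rpois(n_hap, lam) else integer(0)
    m_dip <- if (n_dip > 0) stats::rpois(n_dip, 2 * lam) else integer(0)
    m_rep <- if (length(reps)) stats::rpois(length(reps), 2 * lam * reps)
             else integer(0)
    mult <- c(m_err, m_hap, m_dip, m_rep)
    tab <- tabulate(mult)
    keep <- tab > 0
    hist <- KmerHistogram(which(keep), tab[keep], k = k)
    attr(hist, "truth") <- list(
      error = error_kmers, haploid = n_hap, diploid = n_dip,
      repeat_distinct = length(reps), repeat_mass = sum(reps),
      # observed (multiplicity >= 1) class sizes: the mixture weights the
      # spectrum fit can actually recover
      observed = c(error = sum(m_err > 0), haploid = sum(m_hap > 0),
                   diploid = sum(m_dip > 0), repeats = sum(m_rep > 0)),
      dropped_zero = sum(mult == 0), lambda = lam)
    hist
  })
}

#' Construct a locus-filtering test dataset with known bookkeeping
#'
#' Builds a genotype dataset in which the minor-allele-frequency and
#' Hardy-Weinberg filter outcomes are known by construction: exactly
#' \code{n_maf_fail} monomorphic loci (pooled MAF 0), exactly
#' \code{n_hwe_fail} loci with an extreme heterozygote deficit (half
#' homozygous reference, half homozygous alternate; no heterozygotes) in the
#' first two populations, and a Balding-Nichols background rejection-sampled
#' so that every background locus has pooled MAF >= \code{maf_min} and exact
#' HWE p-value >= \code{hwe_p_floor} in every population. Defaults mirror a
#' 33,866-locus chain in which the two filters remove 609 and 22 loci.
#'
#' The default is 30 individuals per population: at the false-discovery-rate
#' threshold implied by 22 removals among ~33k tests (~3.3e-5), 15 diploids
#' cannot yield a small enough Hardy-Weinberg p-value under either the exact
#' test (floor 4.4e-5) or the chi-square test (~1e-4), so a fixture with
#' shallower population samples would make the pruning step vacuous.
#'
#' @param n_loci total loci.
#' @param n_maf_fail planted sub-MAF (monomorphic) loci.
#' @param n_hwe_fail planted two-population HWE violators.
#' @param n_pops,n_per_pop,target_fst background design.
#' @param maf_min,hwe_p_floor background guarantees (see description).
#' @param seed RNG seed.
#' @return a [GenotypeMatrix-class]; \code{lociInfo()$planted} marks each
#'   locus "background", "maf_fail" or "hwe_fail".
#' @export
simulateFilterFixture <- function(n_loci = 33866, n_maf_fail = 609,
                                  n_hwe_fail = 22, n_pops = 4, n_per_pop = 30,
                                  target_fst = 0.02, maf_min = 0.01,
                                  hwe_p_floor = 0.01, seed = NULL) {
  stopifnot(n_maf_fail + n_hwe_fail <= n_loci, n_pops >= 2)
  .withSeed(seed, {
    n_bg <- n_loci - n_maf_fail - n_hwe_fail
    n_ind <- n_pops * n_per_pop
    pop <- rep(seq_len(n_pops), each = n_per_pop)
    bg <- matrix(0L, 0, n_ind)
    while (nrow(bg) < n_bg) {
      cand <- genoMatrix(simulatePopulations(
        n_pops = n_pops, n_per_pop = n_per_pop,
        n_loci = ceiling((n_bg - nrow(bg)) * 1.25) + 50,
        target_fst = target_fst, missing_rate = 0))
      maf <- pmin(.alleleFreq(cand), 1 - .alleleFreq(cand))
      ok <- maf >= maf_min
      for (j in seq_len(n_pops)) {
        gj <- cand[, pop == j, drop = FALSE]
        pv <- .hweExactVec(rowSums(gj == 2L), rowSums(gj == 1L),
                           rowSums(gj == 0L))
        ok <- ok & pv >= hwe_p_floor
      }
      bg <- rbind(bg, cand[ok, , drop = FALSE])
    }
    bg <- bg[seq_len(n_bg), , drop = FALSE]
    # monomorphic loci: pooled MAF = 0 < maf_min
    maf_block <- matrix(0L, n_maf_fail, n_ind)
    # HWE violators: no heterozygotes, alleles near 0.5, in pops 1 and 2;
    # HWE-consistent and polymorphic elsewhere
    hwe_block <- matrix(0L, n_hwe_fail, n_ind)
    if (n_hwe_fail > 0) {
      viol <- rep(c(0L, 2L), length.out = n_per_pop)
      for (j in seq_len(n_pops)) {
        cols <- which(pop == j)
        if (j <= 2) hwe_block[, cols] <- rep(viol, each = n_hwe_fail)
        else hwe_block[, cols] <- stats::rbinom(n_hwe_fail * n_per_pop, 2, 0.5)
      }
    }
    geno <- rbind(bg, maf_block, hwe_block)
    planted <- rep(c("background", "maf_fail", "hwe_fail"),
                   c(n_bg, n_maf_fail, n_hwe_fail))
    perm <- sample.int(n_loci)
    geno <- geno[perm, , drop = FALSE]
    planted <- planted[perm]
    rownames(geno) <- sprintf("snp%06d", seq_len(n_loci))
    g <- GenotypeMatrix(geno, populations = paste0("pop", pop),
                        contig = sprintf("ctg%05d", (seq_len(n_loci) - 1L)
                                         %/% 30L + 1L),
                        pos = ((seq_len(n_loci) - 1L) %% 30L + 1L) * 1500L)
    rowData(g)$planted <- planted
    g
  })
}
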