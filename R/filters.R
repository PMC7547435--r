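#' Filter sites on quality, depth and mapping quality
#'
#' Applies the per-population site-acceptance criteria to a
#' [GenotypeMatrix-class] read from a VCF: a site is kept only when QUAL and
#' MQ are within bounds and every population's mean depth (mean of per-sample
#' FORMAT depths over the population's non-missing samples, falling back to
#' the site-level DP when no per-sample depths are available) is within
#' [min_dp, max_dp]. Rejections are tallied per criterion, attributing each
#' rejected site to the first criterion it fails, in the order qual, dp_min,
#' dp_max, mq_min, mq_max.
#'
#' @param g a [GenotypeMatrix-class] with \code{qual}, \code{dp}, \code{mq}
#'   locus metadata (see [readVcfGenotypes()]).
#' @param min_qual,min_dp,max_dp,min_mq,max_mq acceptance bounds (defaults
#'   600, 20, 999, 0, 90).
#' @return the filtered [GenotypeMatrix-class]; \code{metadata()$filter_tally}
#'   holds the per-criterion rejection counts and \code{metadata()$n_input}
#'   the input locus count.
#' @export
filterSites <- function(g, min_qual = 600, min_dp = 20, max_dp = 999,
                        min_mq = 0, max_mq = 90) {
  stopifnot(min_dp <= max_dp, min_mq <= max_mq)
  rd <- lociInfo(g)
  if (!all(c("qual", "dp", "mq") %in% names(rd)))
    stop("filterSites needs qual, dp and mq locus metadata")
  pop <- populations(g)
  if (any(table(pop) == 0)) stop("population with zero samples")
  L <- nrow(g)
  if ("dp_sample" %in% names(assays(g))) {
    dps <- assay(g, "dp_sample")
    pop_dp <- vapply(unique(pop), function(p)
      rowMeans(dps[, pop == p, drop = FALSE], na.rm = TRUE), numeric(L))
    pop_dp <- matrix(pop_dp, nrow = L)
  } else {
    pop_dp <- matrix(rd$dp, L, 1)
  }
  dp_lo <- apply(pop_dp, 1, min, na.rm = TRUE)
  dp_hi <- apply(pop_dp, 1, max, na.rm = TRUE)
  fail <- cbind(qual  = rd$qual < min_qual,
                dp_min = dp_lo < min_dp,
                dp_max = dp_hi > max_dp,
                mq_min = rd$mq < min_mq,
                mq_max = rd$mq > max_mq)
  fail[is.na(fail)] <- TRUE
  first <- apply(fail, 1, function(z) if (any(z)) which(z)[1] else 0L)
  tally <- vapply(seq_len(ncol(fail)),
                  function(j) sum(first == j), integer(1))
  names(tally) <- colnames(fail)
  out <- g[first == 0L, ]
  metadata(out)$filter_tally <- tally
  metadata(out)$n_input <- L
  out
}

#' Remove loci below a minor-allele-frequency threshold
#'
#' The minor-allele frequency is computed over non-missing genotypes pooled
#' across populations; loci with MAF strictly below \code{maf_min} are
#' removed (a locus at exactly the threshold is kept).
#'
#' @param g a [GenotypeMatrix-class].
#' @param maf_min threshold (default 0.01).
#' @return filtered [GenotypeMatrix-class]; \code{metadata()$maf_removed}
#'   counts the dropped loci.
#' @export
mafFilter <- function(g, maf_min = 0.01) {
  p <- .alleleFreq(genoMatrix(g))
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0
  keep <- maf >= maf_min
  if (!any(keep)) warning("all loci removed by MAF filter")
  out <- g[keep, ]
  metadata(out)$maf_removed <- sum(!keep)
  out
}

# Vectorized exact HWE p-values from per-locus genotype counts
# (n2 = hom alt, n1 = het, n0 = hom ref). Two-sided conditional exact test:
# the p-value is the total probability of heterozygote counts (given the
# allele counts) no more probable than the observed one.
.hweExactVec <- function(n2, n1, n0) {
  n <- n2 + n1 + n0
  nA <- 2L * n0 + n1          # reference-allele count
  key <- paste(n, nA, n1)
  out <- numeric(length(n))
  for (k in unique(key)) {
    idx <- which(key == k)
    ni <- n[idx[1]]; nAi <- nA[idx[1]]; obs <- n1[idx[1]]
    out[idx] <- .hweExactOne(ni, nAi, obs)
  }
  out
}

.hweExactOne <- function(n, nA, het_obs) {
  na <- 2L * n - nA
  if (nA == 0L || na == 0L) return(1)
  hmax <- min(nA, na)
  h <- seq.int(nA %% 2L, hmax, by = 2L)
  # P(h hets | allele counts) = n! 2^h / (nAA! h! naa!) / C(2n, nA)
  logp <- lgamma(n + 1) + h * log(2) -
    lgamma((nA - h) / 2 + 1) - lgamma(h + 1) - lgamma((na - h) / 2 + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[match(het_obs, h)] * (1 + 1e-9)]))
}

#' Hardy-Weinberg equilibrium tests per locus
#'
#' Tests each locus for deviation from Hardy-Weinberg genotype proportions,
#' by default per population. The exact method is the two-sided conditional
#' exact test on the heterozygote count given the allele counts; the chi2
#' method is the 1-df goodness-of-fit test (no continuity correction).
#' Monomorphic loci get p = 1 by convention.
#'
#' @param g a [GenotypeMatrix-class].
#' @param per_population test within each population (default) or pooled.
#' @param method "exact" (default) or "chi2".
#' @return a loci-by-populations matrix of p-values (single column "all"
#'   when \code{per_population = FALSE}).
#' @export
hweTest <- function(g, per_population = TRUE, method = c("exact", "chi2")) {
  method <- match.arg(method)
  geno <- genoMatrix(g)
  groups <- if (per_population) split(seq_len(ncol(geno)),
                                      populations(g))
            else list(all = seq_len(ncol(geno)))
  res <- vapply(groups, function(cols) {
    gg <- geno[, cols, drop = FALSE]
    n2 <- rowSums(gg == 2L, na.rm = TRUE)
    n1 <- rowSums(gg == 1L, na.rm = TRUE)
    n0 <- rowSums(gg == 0L, na.rm = TRUE)
    if (method == "exact") .hweExactVec(n2, n1, n0)
    else .hweChi2Vec(n2, n1, n0)
  }, numeric(nrow(geno)))
  matrix(res, nrow = nrow(geno),
         dimnames = list(rownames(geno), names(groups)))
}

.hweChi2Vec <- function(n2, n1, n0) {
  n <- n2 + n1 + n0
  p <- (2 * n2 + n1) / (2 * n)
  e2 <- n * p^2; e1 <- 2 * n * p * (1 - p); e0 <- n * (1 - p)^2
  stat <- (n2 - e2)^2 / e2 + (n1 - e1)^2 / e1 + (n0 - e0)^2 / e0
  out <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out[p == 0 | p == 1 | n == 0] <- 1
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone in rank), as used after per-population
#' Hardy-Weinberg testing.
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
fdrBH <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Remove loci out of Hardy-Weinberg equilibrium in multiple populations
#'
#' Adjusts the per-population p-values for the false discovery rate
#' (Benjamini-Hochberg, across loci within each population) and removes a
#' locus when the adjusted p-value falls below \code{alpha} in at least
#' \code{min_pops} populations.
#'
#' @param g a [GenotypeMatrix-class].
#' @param hwe_p loci-by-populations p-value matrix from [hweTest()]
#'   (recomputed with defaults when NULL).
#' @param alpha FDR-adjusted significance level (default 0.05).
#' @param min_pops populations a locus must violate HWE in to be dropped
#'   (default 2).
#' @return filtered [GenotypeMatrix-class]; \code{metadata()$hwe_removed}
#'   counts the dropped loci.
#' @export
hwePrune <- function(g, hwe_p = NULL, alpha = 0.05, min_pops = 2) {
  if (is.null(hwe_p)) hwe_p <- hweTest(g)
  adj <- apply(hwe_p, 2, fdrBH)
  n_viol <- rowSums(adj < alpha)
  keep <- n_viol < min_pops
  out <- g[keep, ]
  metadata(out)$hwe_removed <- sum(!keep)
  out
}

#' Thin loci by physical distance
#'
#' Greedy left-to-right scan within each contig: the first locus is kept and
#' each subsequent locus is kept iff its position is at least \code{thin_bp}
#' beyond the last kept position (a spacing of exactly \code{thin_bp} is
#' kept).
#'
#' @param g a [GenotypeMatrix-class] (loci are stored sorted by contig, pos).
#' @param thin_bp minimum spacing in bp (default 1000).
#' @return thinned [GenotypeMatrix-class]; \code{metadata()$thin_removed}
#'   counts the dropped loci.
#' @export
thinByDistance <- function(g, thin_bp = 1000) {
  rd <- lociInfo(g)
  keep <- logical(nrow(g))
  last_contig <- ""
  last_pos <- -Inf
  for (i in seq_len(nrow(g))) {
    if (rd$contig[i] != last_contig || rd$pos[i] - last_pos >= thin_bp) {
      keep[i] <- TRUE
      last_contig <- rd$contig[i]
      last_pos <- rd$pos[i]
    }
  }
  out <- g[keep, ]
  metadata(out)$thin_removed <- sum(!keep)
  out
}
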