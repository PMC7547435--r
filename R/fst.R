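# Weir & Cockerham (1984) variance components per locus, vectorized.
# Returns per-locus a (among-population), and the full denominator a+b+c.
# Loci monomorphic across the analysed populations contribute zeros and are
# excluded from ratio-of-sums by the caller (0/0 handling).
.wcComponents <- function(geno, pop) {
  s <- .popSummaries(geno, pop)
  n <- s$n; p <- s$p; h <- s$h
  r <- ncol(n)
  ok <- rowSums(n >= 1) == r & rowSums(n) > r  # every pop observed
  sum_n <- rowSums(n)
  nbar <- sum_n / r
  nc <- (sum_n - rowSums(n^2) / sum_n) / (r - 1)
  pbar <- rowSums(n * p) / sum_n
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / sum_n
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  mono <- !ok | pbar <= 0 | pbar >= 1
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  list(a = a, abc = a + b + cc, mono = mono)
}

.ratioOfSums <- function(a, abc) {
  d <- sum(abc)
  if (d <= 0) return(NA_real_)
  sum(a) / d
}

#' Weir-Cockerham FST with bootstrap confidence intervals
#'
#' Estimates multi-locus theta (Weir & Cockerham 1984) for every population
#' pair and over all populations, as the ratio of summed among-population
#' variance components to summed total components (loci monomorphic in the
#' compared populations contribute nothing). 95% confidence intervals are the
#' 2.5/97.5 percentiles of theta over bootstrap resamples of loci. Negative
#' estimates are reported as computed, not truncated at zero.
#'
#' @param g a [GenotypeMatrix-class] with at least two populations.
#' @param pair optional character vector of two population names: estimate
#'   that pair only.
#' @param n_boot bootstrap replicates (default 1000; 0 skips CIs).
#' @param seed RNG seed for the bootstrap.
#' @return an [FstResult-class].
#' @examples
#' g <- simulatePopulations(2, 20, 500, target_fst = 0.05, seed = 7)
#' wcFst(g, n_boot = 100, seed = 1)
#' @export
wcFst <- function(g, pair = NULL, n_boot = 1000, seed = NULL) {
  geno <- genoMatrix(g)
  pop <- populations(g)
  lv <- if (is.null(pair)) sort(unique(pop)) else pair
  stopifnot(length(lv) >= 2, all(lv %in% pop))
  if (any(table(pop[pop %in% lv]) < 2))
    stop("each population needs at least 2 individuals")
  .withSeed(seed, {
    boot_idx <- if (n_boot > 0)
      matrix(sample.int(nrow(geno), nrow(geno) * n_boot, replace = TRUE),
             ncol = n_boot)
    est <- function(pops_used) {
      sel <- pop %in% pops_used
      comp <- .wcComponents(geno[, sel, drop = FALSE], pop[sel])
      theta <- .ratioOfSums(comp$a, comp$abc)
      ci <- c(NA_real_, NA_real_)
      if (n_boot > 0) {
        bt <- vapply(seq_len(n_boot), function(b) {
          i <- boot_idx[, b]
          .ratioOfSums(comp$a[i], comp$abc[i])
        }, numeric(1))
        ci <- unname(stats::quantile(bt, c(0.025, 0.975), na.rm = TRUE))
      }
      list(theta = theta, ci = ci, comp = comp)
    }
    overall <- est(lv)
    P <- length(lv)
    pw <- cil <- cih <- matrix(NA_real_, P, P, dimnames = list(lv, lv))
    if (P > 2 || !is.null(pair) || P == 2) {
      for (i in seq_len(P - 1)) for (j in (i + 1):P) {
        e <- est(c(lv[i], lv[j]))
        pw[i, j] <- pw[j, i] <- e$theta
        cil[i, j] <- cil[j, i] <- e$ci[1]
        cih[i, j] <- cih[j, i] <- e$ci[2]
      }
    }
    per_locus <- overall$comp$a / overall$comp$abc
    per_locus[overall$comp$abc == 0] <- NA_real_
    new("FstResult", pairwise = pw, ci_low = cil, ci_high = cih,
        overall = overall$theta, overall_ci = overall$ci,
        per_locus = per_locus, n_boot = as.integer(n_boot))
  })
}

#' Per-locus Weir-Cockerham theta
#'
#' Convenience wrapper returning only the per-locus estimates for a given
#' population pair (or all populations), as used for locus ranking when
#' building diagnostic panels. Monomorphic loci get NA.
#'
#' @inheritParams wcFst
#' @return numeric vector of per-locus theta, named by locus.
#' @export
perLocusFst <- function(g, pair = NULL) {
  geno <- genoMatrix(g)
  pop <- populations(g)
  if (!is.null(pair)) {
    sel <- pop %in% pair
    geno <- geno[, sel, drop = FALSE]
    pop <- pop[sel]
  }
  comp <- .wcComponents(geno, pop)
  out <- comp$a / comp$abc
  out[comp$abc == 0] <- NA_real_
  names(out) <- rownames(geno)
  out
}

#' Permutation test of per-locus differentiation
#'
#' Tests each locus's Weir-Cockerham theta between two populations by
#' permuting population labels over individuals: p = (1 + #(permuted theta >=
#' observed)) / (n_perm + 1). Monomorphic loci get p = 1. P-values are not
#' corrected for multiple comparisons.
#'
#' @param g a [GenotypeMatrix-class].
#' @param pair two population names (default: the two present).
#' @param n_perm label permutations (default 1000).
#' @param seed RNG seed.
#' @return numeric vector of per-locus p-values.
#' @export
locuswiseFstPermTest <- function(g, pair = NULL, n_perm = 1000, seed = NULL) {
  pop <- populations(g)
  if (is.null(pair)) pair <- sort(unique(pop))
  stopifnot(length(pair) == 2)
  sel <- pop %in% pair
  geno <- genoMatrix(g)[, sel, drop = FALSE]
  pop <- pop[sel]
  comp <- .wcComponents(geno, pop)
  obs <- comp$a / comp$abc
  mono <- comp$abc == 0
  .withSeed(seed, {
    exceed <- integer(nrow(geno))
    for (b in seq_len(n_perm)) {
      cp <- .wcComponents(geno, sample(pop))
      th <- cp$a / cp$abc
      th[cp$abc == 0] <- -Inf
      exceed <- exceed + (th >= obs - 1e-12)
    }
    p <- (1 + exceed) / (n_perm + 1)
    p[mono] <- 1
    names(p) <- rownames(geno)
    p
  })
}
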