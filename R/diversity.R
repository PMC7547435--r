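# Per-population per-locus gene diversity (expected heterozygosity with the
# n/(n-1) small-sample correction, n = individuals genotyped) and observed
# heterozygosity. Loci with fewer than 2 genotypes in a population are NA
# there.
.hsHoMatrices <- function(geno, pop) {
  s <- .popSummaries(geno, pop)
  hs <- 2 * s$p * (1 - s$p) * s$n / (s$n - 1)
  hs[s$n < 2] <- NA
  ho <- s$h
  ho[s$n < 2] <- NA
  list(hs = hs, ho = ho, n = s$n, levels = s$levels)
}

#' Within-population diversity: Hs, Ho and FIS
#'
#' Per population (and averaged over populations): gene diversity Hs
#' (expected heterozygosity with the n/(n-1) small-sample correction,
#' averaged over loci), observed heterozygosity Ho, and the inbreeding
#' coefficient FIS = 1 - Ho/Hs, with a bootstrap-over-loci 95% confidence
#' interval for FIS.
#'
#' @param g a [GenotypeMatrix-class].
#' @param n_boot bootstrap replicates for the FIS CI (default 1000; 0 skips).
#' @param seed RNG seed for the bootstrap.
#' @return a data.frame with one row per population plus an "overall" row
#'   (unweighted mean of the population Hs/Ho; FIS from those means), columns
#'   \code{population}, \code{hs}, \code{ho}, \code{fis}, \code{fis_ci_low},
#'   \code{fis_ci_high}.
#' @export
diversityStats <- function(g, n_boot = 1000, seed = NULL) {
  geno <- genoMatrix(g)
  m <- .hsHoMatrices(geno, populations(g))
  lv <- m$levels
  fis_of <- function(hs, ho) 1 - mean(ho, na.rm = TRUE) / mean(hs, na.rm = TRUE)
  .withSeed(seed, {
    L <- nrow(geno)
    boot_idx <- if (n_boot > 0)
      matrix(sample.int(L, L * n_boot, replace = TRUE), ncol = n_boot)
    row_for <- function(hs_l, ho_l, label) {
      hs <- mean(hs_l, na.rm = TRUE)
      ho <- mean(ho_l, na.rm = TRUE)
      ci <- c(NA_real_, NA_real_)
      if (n_boot > 0) {
        bt <- vapply(seq_len(n_boot),
                     function(b) fis_of(hs_l[boot_idx[, b]],
                                        ho_l[boot_idx[, b]]),
                     numeric(1))
        ci <- unname(stats::quantile(bt, c(0.025, 0.975), na.rm = TRUE))
      }
      data.frame(population = label, hs = hs, ho = ho, fis = 1 - ho / hs,
                 fis_ci_low = ci[1], fis_ci_high = ci[2])
    }
    out <- do.call(rbind, lapply(seq_along(lv), function(i)
      row_for(m$hs[, i], m$ho[, i], lv[i])))
    overall <- row_for(rowMeans(m$hs, na.rm = TRUE),
                       rowMeans(m$ho, na.rm = TRUE), "overall")
    rbind(out, overall)
  })
}

#' Paired t-test for an overall heterozygote deficit
#'
#' Tests whether gene diversity exceeds observed heterozygosity across loci:
#' a paired t-test of the per-locus (Hs - Ho) differences, where Hs and Ho
#' are population means per locus. df = n_loci - 1.
#'
#' @param g a [GenotypeMatrix-class] with at least 2 loci.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
hetDeficitTest <- function(g) {
  geno <- genoMatrix(g)
  if (nrow(geno) < 2) stop("need at least 2 loci")
  m <- .hsHoMatrices(geno, populations(g))
  hs <- rowMeans(m$hs, na.rm = TRUE)
  ho <- rowMeans(m$ho, na.rm = TRUE)
  dif <- hs - ho
  if (stats::sd(dif) == 0) {
    # degenerate constant differences: t is 0 (no deficit) or +/-Inf
    tstat <- if (mean(dif) == 0) 0 else sign(mean(dif)) * Inf
    return(list(t = tstat, df = length(dif) - 1,
                p = if (tstat == 0) 1 else 0))
  }
  tt <- stats::t.test(hs, ho, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Linkage-disequilibrium survey
#'
#' Computes genotype-dosage r2 (squared Pearson correlation over individuals
#' with both loci non-missing) for (i) every pair of loci on the same contig
#' and (ii) a seeded random sample of cross-contig pairs, plus same-contig
#' means after excluding the nearest n loci (index distance in the per-contig
#' position order). Pairs with fewer than 3 complete observations are
#' skipped.
#'
#' @param g a [GenotypeMatrix-class].
#' @param n_random_pairs cross-contig pairs to sample (default 100000).
#' @param exclude_nearest integer vector of n values for the nearest-n
#'   exclusion series (default c(5, 10, 15)).
#' @param seed RNG seed for the random pairs.
#' @return list with \code{same_contig_mean/sd}, \code{random_mean/sd},
#'   \code{n_same_contig_pairs}, \code{n_random_pairs},
#'   \code{nearest_excluded_means} (named by n), and the raw same-contig
#'   pair table \code{same_contig} (contig, index distance, r2).
#' @export
ldSurvey <- function(g, n_random_pairs = 100000,
                     exclude_nearest = c(5, 10, 15), seed = NULL) {
  geno <- genoMatrix(g)
  contig <- lociInfo(g)$contig
  by_contig <- split(seq_len(nrow(geno)), contig)
  by_contig <- by_contig[lengths(by_contig) >= 2]
  if (!length(by_contig)) stop("no contig carries 2 or more loci")
  sc <- do.call(rbind, lapply(names(by_contig), function(ct) {
    idx <- by_contig[[ct]]   # already in position order
    cm <- suppressWarnings(
      stats::cor(t(geno[idx, , drop = FALSE]),
                 use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cm), arr.ind = TRUE)
    data.frame(contig = ct, dist_idx = pr[, 2] - pr[, 1],
               r2 = cm[pr]^2)
  }))
  sc <- sc[!is.na(sc$r2), , drop = FALSE]
  nem <- vapply(exclude_nearest, function(n)
    mean(sc$r2[sc$dist_idx > n]), numeric(1))
  names(nem) <- paste0("n", exclude_nearest)
  rnd <- .withSeed(seed, {
    i <- sample.int(nrow(geno), n_random_pairs, replace = TRUE)
    j <- sample.int(nrow(geno), n_random_pairs, replace = TRUE)
    ok <- contig[i] != contig[j]
    .pairR2(geno, i[ok], j[ok])
  })
  rnd <- rnd[!is.na(rnd)]
  list(same_contig_mean = mean(sc$r2), same_contig_sd = stats::sd(sc$r2),
       random_mean = mean(rnd), random_sd = stats::sd(rnd),
       n_same_contig_pairs = nrow(sc), n_random_pairs = length(rnd),
       nearest_excluded_means = nem, same_contig = sc)
}

# Vectorized r2 for pairs of rows (i, j) of a loci x individuals matrix,
# with pairwise-complete observations; NA when < 3 complete pairs or a
# locus is constant within the complete set.
.pairR2 <- function(geno, i, j, chunk = 20000L) {
  if (length(i) == 0) return(numeric(0))
  out <- numeric(length(i))
  for (s in seq(1, length(i), by = chunk)) {
    e <- min(s + chunk - 1L, length(i))
    x <- geno[i[s:e], , drop = FALSE]
    y <- geno[j[s:e], , drop = FALSE]
    mask <- !is.na(x) & !is.na(y)
    x[!mask] <- 0; y[!mask] <- 0
    n <- rowSums(mask)
    sx <- rowSums(x); sy <- rowSums(y)
    sxx <- rowSums(x^2); syy <- rowSums(y^2); sxy <- rowSums(x * y)
    num <- (n * sxy - sx * sy)^2
    den <- (n * sxx - sx^2) * (n * syy - sy^2)
    r2 <- ifelse(n >= 3 & den > 0, num / den, NA_real_)
    out[s:e] <- r2
  }
  out
}
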