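test_that("Weir-Cockerham theta matches hand-derived limiting cases", {
  # identical tables in both populations -> theta ~ 0 (may be negative)
  set.seed(3)
  block <- matrix(stats::rbinom(200, 2, 0.4), 20, 10)
  g <- GenotypeMatrix(cbind(block, block),
                      populations = rep(c("A", "B"), each = 10))
  # estimator bias for identical finite tables is negative, O(1/n)
  expect_lte(wcFst(g, n_boot = 0)@overall, 0.005)
  # fixed difference, equal n -> per-locus theta = 1
  g2 <- GenotypeMatrix(matrix(c(rep(0L, 8), rep(2L, 8)), 1, 16),
                       populations = rep(c("A", "B"), each = 8))
  expect_equal(unname(perLocusFst(g2)), 1)
})

test_that("wcFst equals the brute-force variance-component oracle on fuzzed tables", {
  set.seed(101)
  for (i in 1:200) {
    n_pop <- sample(2:3, 1)
    n_per <- 6
    L <- 3
    geno <- matrix(sample(0:2, L * n_pop * n_per, replace = TRUE),
                   L, n_pop * n_per)
    geno[stats::runif(length(geno)) < 0.1] <- NA
    pop <- rep(paste0("p", seq_len(n_pop)), each = n_per)
    # ensure >= 1 genotype per pop per locus for a fair comparison
    keep_ok <- TRUE
    for (pp in unique(pop))
      keep_ok <- keep_ok &&
        all(rowSums(!is.na(geno[, pop == pp, drop = FALSE])) >= 1)
    if (!keep_ok) next
    g <- GenotypeMatrix(geno, populations = pop)
    mine <- wcFst(g, n_boot = 0)@overall
    orac <- oracle_wc_fst(genoMatrix(g), populations(g))
    if (is.na(mine) || is.na(orac)) {
      expect_true(is.na(mine) && is.na(orac))
    } else {
      expect_equal(mine, orac, tolerance = 1e-12)
    }
  }
})

test_that("pairwise FST matrix is symmetric with CIs bracketing the estimate", {
  g <- simulatePopulations(3, 12, 400, target_fst = 0.08, seed = 55)
  f <- wcFst(g, n_boot = 100, seed = 56)
  expect_equal(f@pairwise, t(f@pairwise))
  off <- upper.tri(f@pairwise)
  expect_true(all(f@ci_low[off] <= f@pairwise[off] + 1e-9))
  expect_true(all(f@ci_high[off] >= f@pairwise[off] - 1e-9))
  expect_true(f@overall_ci[1] <= f@overall && f@overall <= f@overall_ci[2])
})

test_that("diversity table reproduces hand arithmetic and the F=0 null", {
  # genotypes (0,0,1,1): p = 0.25, Hs = 2*0.25*0.75*(4/3) = 0.5, Ho = 0.5
  g <- GenotypeMatrix(matrix(c(0L, 0L, 1L, 1L), 1, 4),
                      populations = rep("A", 4))
  d <- diversityStats(g, n_boot = 0)
  expect_equal(d$hs[1], 0.5)
  expect_equal(d$ho[1], 0.5)
  expect_equal(d$fis[1], 0)
  # all heterozygotes -> Ho = 1
  g2 <- GenotypeMatrix(matrix(1L, 1, 6), populations = rep("A", 6))
  expect_equal(diversityStats(g2, n_boot = 0)$ho[1], 1)
  # Balding-Nichols F -> 0 at n = 50: within-population FIS ~ 0
  g3 <- simulatePopulations(1, 50, 5000, target_fst = 1e-6,
                            missing_rate = 0, seed = 61)
  d3 <- diversityStats(g3, n_boot = 0)
  expect_lt(abs(d3$fis[1]), 0.02)
})

test_that("heterozygote-deficit paired t-test behaves at its closed-form anchors", {
  # Hs == Ho at every locus -> t = 0 (all-het loci)
  g <- GenotypeMatrix(matrix(c(0L, 0L, 1L, 1L), 4, 4, byrow = TRUE),
                      populations = rep("A", 4))
  ht <- hetDeficitTest(g)
  expect_equal(ht$df, 3)
  expect_equal(ht$t, 0, tolerance = 1e-9)
  # constructed difference series: t = mean/(sd/sqrt(n))
  set.seed(71)
  g2 <- simulatePopulations(2, 15, 100, target_fst = 0.05, seed = 72)
  ht2 <- hetDeficitTest(g2)
  m <- wrassepop:::.hsHoMatrices(genoMatrix(g2), populations(g2))
  dif <- rowMeans(m$hs, na.rm = TRUE) - rowMeans(m$ho, na.rm = TRUE)
  expect_equal(ht2$t, mean(dif) / (stats::sd(dif) / sqrt(100)),
               tolerance = 1e-9)
  expect_equal(ht2$df, 99)
  expect_error(hetDeficitTest(g[1, ]), "at least 2 loci")
})

test_that("locus-wise permutation test is calibrated and seeded", {
  # fixed difference: observed theta unmatched by label permutations
  g2 <- GenotypeMatrix(matrix(c(rep(0L, 10), rep(2L, 10)), 3, 20,
                              byrow = TRUE),
                       populations = rep(c("A", "B"), each = 10))
  p <- locuswiseFstPermTest(g2, n_perm = 99, seed = 5)
  expect_true(all(p <= 0.02))
  expect_identical(p, locuswiseFstPermTest(g2, n_perm = 99, seed = 5))
  # null calibration at alpha = 0.05: valid (never anti-conservative) but
  # conservative below the nominal rate, because the permutation
  # distribution of theta is discrete and the probability atom at the
  # observed value counts against significance (as in Fisher's exact test)
  gn <- simulatePopulations(2, 25, 400, target_fst = 1e-6,
                            missing_rate = 0, seed = 81)
  pn <- locuswiseFstPermTest(gn, n_perm = 999, seed = 82)
  expect_gt(mean(pn < 0.05), 0.003)
  expect_lte(mean(pn < 0.05), 0.07)
})
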