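make_site_g <- function(qual, dp, mq, n_ind = 6) {
  L <- length(qual)
  GenotypeMatrix(matrix(1L, L, n_ind),
                 populations = rep(c("A", "B"), each = n_ind / 2),
                 contig = rep("c1", L), pos = seq_len(L) * 100L,
                 qual = qual, dp = dp, mq = mq)
}

test_that("site filters keep in-bound sites and tally first-failing criteria", {
  g <- make_site_g(qual = c(650, 650, 650), dp = c(100, 100, 100),
                   mq = c(60, 60, 60))
  out <- filterSites(g)
  expect_equal(nrow(out), 3L)
  expect_equal(sum(S4Vectors::metadata(out)$filter_tally), 0L)
  # 10 sites, 3 engineered to fail distinct criteria
  qual <- rep(650, 10); dp <- rep(100, 10); mq <- rep(60, 10)
  qual[2] <- 500   # fails min_qual
  dp[5] <- 15      # fails min_dp
  mq[8] <- 95      # fails max_mq
  out2 <- filterSites(make_site_g(qual, dp, mq))
  expect_equal(nrow(out2), 7L)
  tally <- S4Vectors::metadata(out2)$filter_tally
  expect_equal(unname(tally[c("qual", "dp_min", "mq_max")]), c(1L, 1L, 1L))
  expect_equal(sum(tally), 3L)
  # bookkeeping conserves loci
  expect_equal(S4Vectors::metadata(out2)$n_input, nrow(out2) + sum(tally))
})

test_that("per-population mean sample depth drives the DP bounds", {
  L <- 2L
  dps <- rbind(c(30, 30, 30, 10, 10, 10),   # pop B mean 10 < 20 -> reject
               c(30, 30, 30, 25, 25, 25))
  g <- GenotypeMatrix(matrix(1L, L, 6),
                      populations = rep(c("A", "B"), each = 3),
                      contig = rep("c1", L), pos = c(100L, 200L),
                      qual = c(700, 700), dp = c(120, 165), mq = c(60, 60),
                      dp_sample = dps)
  out <- filterSites(g)
  expect_equal(nrow(out), 1L)
  expect_equal(unname(S4Vectors::metadata(out)$filter_tally["dp_min"]), 1L)
})

test_that("MAF filter removes strictly-below-threshold loci over pooled samples", {
  # loci: monomorphic; one heterozygote among all individuals
  geno <- rbind(rep(0L, 60), c(1L, rep(0L, 59)))
  # with 50 individuals the single het is 1/100 alleles = exactly 0.01: kept
  g50 <- GenotypeMatrix(geno[, 1:50, drop = FALSE],
                        populations = rep("A", 50))
  out <- mafFilter(g50, maf_min = 0.01)
  expect_equal(S4Vectors::metadata(out)$maf_removed, 1L)  # monomorphic only
  expect_true("locus2" %in% rownames(out))                # boundary kept
  # with 60 individuals it is 1/120 = 0.0083 < 0.01: removed too
  g60 <- GenotypeMatrix(geno, populations = rep("A", 60))
  expect_warning(out60 <- mafFilter(g60, maf_min = 0.01), "all loci removed")
  expect_equal(S4Vectors::metadata(out60)$maf_removed, 2L)
})

test_that("exact HWE test matches full enumeration and handles conventions", {
  # monomorphic
  g <- GenotypeMatrix(matrix(0L, 1, 10), populations = rep("A", 10))
  expect_equal(unname(hweTest(g)[1, 1]), 1)
  # (AA=5, Aa=0, aa=5) against the enumeration oracle
  geno <- matrix(c(rep(0L, 5), rep(2L, 5)), 1, 10)
  g2 <- GenotypeMatrix(geno, populations = rep("A", 10))
  expect_equal(unname(hweTest(g2)[1, 1]), oracle_hwe_exact(5, 0, 5),
               tolerance = 1e-12)
  # modal configuration has p = 1
  g3 <- GenotypeMatrix(matrix(c(0L, 1L, 1L, 2L), 1, 4),
                       populations = rep("A", 4))
  expect_equal(unname(hweTest(g3)[1, 1]), 1)
  # fuzz against the oracle
  set.seed(77)
  for (i in 1:50) {
    n <- sample(4:25, 1)
    gv <- sample(0:2, n, replace = TRUE)
    gm <- GenotypeMatrix(matrix(as.integer(gv), 1, n),
                         populations = rep("A", n))
    expect_equal(unname(hweTest(gm)[1, 1]),
                 oracle_hwe_exact(sum(gv == 0), sum(gv == 1), sum(gv == 2)),
                 tolerance = 1e-10)
  }
  # chi2 variant agrees with stats::chisq.test machinery on a known case
  pv <- hweTest(g2, method = "chi2")[1, 1]
  expect_lt(pv, 0.01)
})

test_that("BH adjustment matches the hand step-up and is monotone in rank", {
  expect_equal(fdrBH(0.03), 0.03)
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrBH(rep(1, 5)), rep(1, 5))
  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    adj <- fdrBH(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("HWE pruning drops loci violating in at least min_pops populations", {
  set.seed(9)
  n_per <- 20
  base <- matrix(stats::rbinom(10 * 4 * n_per, 2, 0.5), 10, 4 * n_per)
  viol <- rep(c(0L, 2L), length.out = n_per)
  base[1, 1:(2 * n_per)] <- rep(viol, 2)          # violates in pops 1+2
  base[2, 1:n_per] <- viol                        # violates in pop 1 only
  base[3, c(1:n_per, 2 * n_per + 1:n_per)] <- rep(viol, 2)  # pops 1+3
  g <- GenotypeMatrix(base, populations = rep(paste0("p", 1:4),
                                              each = n_per))
  out <- hwePrune(g, alpha = 0.05, min_pops = 2)
  expect_equal(S4Vectors::metadata(out)$hwe_removed, 2L)
  expect_false("locus1" %in% rownames(out))
  expect_true("locus2" %in% rownames(out))
  expect_false("locus3" %in% rownames(out))
})

test_that("distance thinning keeps the greedy >= thin_bp spacing per contig", {
  g <- GenotypeMatrix(matrix(0:1, 3, 4),
                      populations = rep("A", 4),
                      contig = rep("c1", 3), pos = c(100L, 900L, 1100L))
  out <- thinByDistance(g, 1000)
  expect_equal(lociInfo(out)$pos, c(100L, 1100L))
  # exact spacing kept; one locus per contig untouched
  g2 <- GenotypeMatrix(matrix(0:1, 3, 4), populations = rep("A", 4),
                       contig = c("c1", "c1", "c2"),
                       pos = c(100L, 1100L, 50L))
  expect_equal(nrow(thinByDistance(g2, 1000)), 3L)
})
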