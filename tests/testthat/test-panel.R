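test_that("panel selection takes one top-FST SNP per scaffold above the floor", {
  # two loci on one scaffold: the higher-FST one wins
  geno <- rbind(c(rep(0L, 10), rep(1L, 10)),   # moderate divergence
                c(rep(0L, 10), rep(2L, 10)),   # fixed difference
                c(rep(1L, 10), rep(1L, 10)))   # monomorphic-ish
  g <- GenotypeMatrix(geno, populations = rep(c("A", "B"), each = 10),
                      contig = c("s1", "s1", "s2"), pos = c(10L, 20L, 5L))
  pan <- selectPanel(g, fst_floor = 0.15)
  expect_equal(nrow(pan), 1L)
  expect_equal(pan$pos, 20L)
  expect_equal(pan$fst, 1)
  # all below floor -> empty with warning
  g0 <- simulatePopulations(2, 20, 50, target_fst = 1e-6,
                            missing_rate = 0, seed = 121)
  expect_warning(p0 <- selectPanel(g0, fst_floor = 0.9), "no locus")
  expect_equal(nrow(p0), 0L)
})

test_that("planted high-FST loci on distinct scaffolds fill the panel in order", {
  # 20 scaffolds x (4 weakly divergent background loci + 1 strongly
  # divergent locus with a deterministic frequency contrast)
  set.seed(122)
  n_per <- 30
  n_scaf <- 20
  geno <- matrix(0L, 0, 2 * n_per)
  contig <- character(0); pos <- integer(0); planted <- character(0)
  for (sc in 1:n_scaf) {
    bg <- matrix(stats::rbinom(4 * 2 * n_per, 2, 0.4), 4)
    div <- c(stats::rbinom(n_per, 2, 0.05 + 0.01 * sc),
             stats::rbinom(n_per, 2, 0.95 - 0.01 * sc))
    block <- rbind(bg, div)
    rn <- sprintf("s%02d_l%d", sc, 1:5)
    rownames(block) <- rn
    geno <- rbind(geno, block)
    contig <- c(contig, rep(sprintf("s%02d", sc), 5))
    pos <- c(pos, (1:5) * 500L)
    planted <- c(planted, rn[5])
  }
  g <- GenotypeMatrix(geno, populations = rep(c("A", "B"), each = n_per),
                      contig = contig, pos = pos)
  pan <- selectPanel(g, fst_floor = 0.15)
  expect_true(all(diff(pan$fst) <= 1e-12))      # descending order
  expect_true(all(pan$fst >= 0.15))
  expect_lte(max(table(pan$contig)), 1)         # one candidate per scaffold
  expect_true(all(planted %in% pan$locus))      # every planted locus selected
  expect_equal(nrow(pan), n_scaf)
})

test_that("genotype concordance partitions cells into match/missing/mismatch", {
  a <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 0L), 2, 2,
                             dimnames = list(c("l1", "l2"), c("i1", "i2"))),
                      populations = c("A", "A"))
  expect_equal(genotypeConcordance(a, a)$matching, 100)
  b <- a
  bm <- genoMatrix(b); bm["l1", "i1"] <- 1L
  b <- GenotypeMatrix(bm, populations = c("A", "A"))
  cc <- genotypeConcordance(a, b)
  expect_equal(cc$matching, 75)
  expect_equal(cc$non_matching, 25)
  expect_equal(cc$matching + cc$missing + cc$non_matching, 100)
  bm["l1", "i1"] <- NA
  b2 <- GenotypeMatrix(bm, populations = c("A", "A"))
  cc2 <- genotypeConcordance(a, b2)
  expect_equal(cc2$missing, 25)
  expect_equal(cc2$matching, 75)
  expect_error(genotypeConcordance(a, GenotypeMatrix(
    matrix(0L, 1, 1, dimnames = list("zz", "qq")), populations = "A")),
    "no shared")
})

test_that("FST method correlation equals the closed-form least squares", {
  expect_equal(suppressWarnings(fstMethodCorrelation(1:5, 1:5)$r2), 1)
  expect_equal(suppressWarnings(fstMethodCorrelation(c(1, 2, 3),
                                                     c(3, 2, 1))$r2), 1)
  set.seed(123)
  x <- stats::runif(10); y <- 0.3 * x + stats::rnorm(10, 0, 0.1)
  mine <- fstMethodCorrelation(x, y)
  orac <- oracle_ols_r2(x, y)
  expect_equal(mine$r2, orac$r2, tolerance = 1e-10)
  expect_equal(mine$p, orac$p, tolerance = 1e-10)
  expect_error(fstMethodCorrelation(rep(1, 5), 1:5), "zero variance")
})

test_that("robust subset applies strict per-population quality thresholds", {
  loci <- sprintf("L%03d", 1:173)
  set.seed(124)
  q <- cbind(Bodo = stats::runif(173, 0, 100),
             Varberg = stats::runif(173, 0, 80))
  rownames(q) <- loci
  pass <- q[, "Bodo"] > 50 & q[, "Varberg"] > 40
  # engineer exactly 74 passers
  need <- 74 - sum(pass)
  if (need > 0) {
    ix <- which(!pass)[seq_len(need)]
    q[ix, ] <- c(60, 50)[col(q[ix, , drop = FALSE])]
  } else if (need < 0) {
    ix <- which(pass)[seq_len(-need)]
    q[ix, "Bodo"] <- 10
  }
  sub <- robustSubset(loci, q, thresholds = c(Bodo = 50, Varberg = 40))
  expect_length(sub, 74)
  expect_true(all(sub %in% loci))
  # boundary: quality (51, 39) fails the strict > rule on the second pop
  q2 <- matrix(c(51, 39), 1, 2,
               dimnames = list("Lx", c("Bodo", "Varberg")))
  expect_length(robustSubset("Lx", q2, c(Bodo = 50, Varberg = 40)), 0)
  # zero thresholds keep the full panel
  expect_length(robustSubset(loci, q, c(Bodo = 0, Varberg = 0)), 173)
})
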