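test_that("membership rows sum to one and separation limits hold", {
  g <- simulatePopulations(2, 15, 300, target_fst = 0.5, missing_rate = 0,
                           seed = 91)
  fit <- dapcFit(g, n_pcs = 8)
  expect_equal(unname(rowSums(fit@membership)), rep(1, 30), tolerance = 1e-10)
  own <- fit@membership[cbind(1:30, as.integer(fit@groups))]
  expect_true(all(own >= 0.99))
  # F -> 0: self-assignment ~ chance for 2 equal groups
  g0 <- simulatePopulations(2, 30, 300, target_fst = 1e-6,
                            missing_rate = 0, seed = 92)
  f0 <- dapcFit(g0, n_pcs = 8)
  own0 <- f0@membership[cbind(1:60, as.integer(f0@groups))]
  expect_lt(mean(own0), 0.75)
  expect_gt(mean(own0), 0.4)
})

test_that("dapcPredict projects new individuals into the training space", {
  g <- simulatePopulations(2, 25, 200, target_fst = 0.3, missing_rate = 0,
                           seed = 93)
  train <- c(1:20, 26:45)
  test_idx <- setdiff(1:50, train)
  fit <- dapcFit(g[, train], n_pcs = 6)
  memb <- dapcPredict(fit, g[, test_idx])
  expect_equal(unname(rowSums(memb)), rep(1, 10), tolerance = 1e-10)
  assigned <- colnames(memb)[max.col(memb)]
  expect_gte(mean(assigned == populations(g)[test_idx]), 0.9)
})

test_that("BIC-based cluster count recovers planted structure", {
  g1 <- simulatePopulations(1, 40, 2000, target_fst = 1e-6, seed = 94)
  expect_equal(unname(findClusters(g1, seed = 95)$best_k), 1L)
  g2 <- simulatePopulations(2, 30, 2000, target_fst = 0.2, seed = 96)
  expect_equal(unname(findClusters(g2, seed = 95)$best_k), 2L)
})

test_that("a-score hits its ceiling, null and stability anchors", {
  g <- simulatePopulations(2, 15, 400, target_fst = 0.5, missing_rate = 0,
                           seed = 97)
  ao <- alphaOptimize(g, pc_grid = c(2, 5), n_perm = 5, seed = 98)
  # perfectly separated groups: a-score ~ 1 - 1/n_groups
  expect_gt(max(ao$a_score), 0.35)
  # label-permuted data: a-score ~ 0
  set.seed(99)
  gp <- GenotypeMatrix(genoMatrix(g),
                       populations = sample(populations(g)),
                       contig = lociInfo(g)$contig, pos = lociInfo(g)$pos)
  aop <- alphaOptimize(gp, pc_grid = c(2, 5), n_perm = 5, seed = 98)
  expect_lt(abs(max(aop$a_score)), 0.25)
})

test_that("alpha optimum is stable across seeds on a two-population simulation", {
  g <- simulatePopulations(2, 20, 500, target_fst = 0.1, missing_rate = 0,
                           seed = 100)
  opts <- vapply(1:10, function(s)
    alphaOptimize(g, pc_grid = c(1, 3, 6, 12), n_perm = 5,
                  seed = 200 + s)$optimum, numeric(1))
  mode_freq <- max(table(opts)) / 10
  expect_gte(mode_freq, 0.7)
})

test_that("cross-validation grid sizes, chance level, and leakage guard", {
  # chance level at F -> 0
  g0 <- simulatePopulations(2, 20, 200, target_fst = 1e-6,
                            missing_rate = 0, seed = 102)
  cv0 <- monteCarloCV(g0, train_fracs = 0.7, locus_fracs = c(0.25, 1),
                      n_rep = 10, seed = 103)
  expect_equal(nrow(cv0), 20L)
  expect_lt(abs(mean(cv0$accuracy) - 0.5), 0.2)
  # fully diverged populations: accuracy 1 in every cell
  g1 <- simulatePopulations(2, 12, 200, target_fst = 0.7,
                            missing_rate = 0, seed = 104)
  cv1 <- monteCarloCV(g1, train_fracs = c(0.5, 0.9), locus_fracs = 1,
                      n_rep = 5, seed = 105)
  expect_true(all(cv1$accuracy == 1))
  # leakage guard: a locus divergent ONLY in held-out individuals must not
  # be top-ranked by the training-only FST ranking
  set.seed(106)
  geno <- matrix(stats::rbinom(100 * 40, 2, 0.5), 100, 40)
  groups <- factor(rep(c("A", "B"), each = 20))
  train <- c(1:10, 21:30)
  held <- setdiff(1:40, train)
  geno[1, held] <- rep(c(0L, 2L), each = 10)   # perfect split, held-out only
  geno[2, train] <- rep(c(0L, 2L), each = 10)  # perfect split, training
  fst <- wrassepop:::.cvRankLoci(geno, groups, train)
  expect_equal(which.max(fst), 2L)
  expect_lt(fst[1], 0.5)
})

test_that("assignment accuracy is non-decreasing in simulated divergence", {
  accs <- vapply(c(0.01, 0.05, 0.1, 0.2), function(Fv) {
    med <- vapply(1:3, function(s) {
      g <- simulatePopulations(2, 20, 300, target_fst = Fv,
                               missing_rate = 0, seed = 300 + 10 * s)
      cv <- monteCarloCV(g, train_fracs = 0.7, locus_fracs = 1, n_rep = 5,
                         seed = 400 + s)
      mean(cv$accuracy)
    }, numeric(1))
    stats::median(med)
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))
  expect_gt(accs[4], accs[1])
})
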