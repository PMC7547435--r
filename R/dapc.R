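#' Choose the number of genetic clusters by BIC over k-means solutions
#'
#' PCA on centered/scaled genotypes, then k-means on the leading PC scores
#' for K = 1..k_max (multi-start, seeded) and
#' BIC(K) = n * ln(WSS/n) + K * ln(n); the best K has the lowest BIC.
#' \code{n_pcs} leading PCs are retained (default 20, capped at n - 2):
#' population structure at realistic differentiation lives in the first few
#' components, and retaining the full noise bulk flattens the
#' within-cluster-variance signal the BIC compares, while too few retained
#' PCs lets k-means overfit pure structure space.
#'
#' @param g a [GenotypeMatrix-class].
#' @param k_max largest K considered (default 10); must be < n individuals.
#' @param n_pcs leading PCs retained for clustering (default 20).
#' @param n_start k-means restarts (default 10).
#' @param seed RNG seed.
#' @return list with \code{bic} (named numeric over K), \code{best_k},
#'   \code{n_pcs_used}, and \code{cluster} (assignment under best K).
#' @export
findClusters <- function(g, k_max = 10, n_pcs = 20, n_start = 10,
                         seed = NULL) {
  geno <- genoMatrix(g)
  n <- ncol(geno)
  stopifnot(n > k_max)
  x <- .scaleGenotypes(geno)
  n_pcs <- min(n_pcs, n - 2L)
  sv <- svd(x, nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  .withSeed(seed, {
    bic <- numeric(k_max)
    clus <- vector("list", k_max)
    for (K in seq_len(k_max)) {
      if (K == 1) {
        wss <- sum(scale(scores, scale = FALSE)^2)
        clus[[K]] <- rep(1L, n)
      } else {
        km <- NULL
        for (try in 1:5) {
          km <- tryCatch(stats::kmeans(scores, K, nstart = n_start,
                                       iter.max = 50),
                         error = function(e) NULL)
          if (!is.null(km)) break
        }
        if (is.null(km)) { bic[K] <- Inf; next }
        wss <- km$tot.withinss
        clus[[K]] <- km$cluster
      }
      bic[K] <- n * log(wss / n) + K * log(n)
    }
    names(bic) <- seq_len(k_max)
    best <- which.min(bic)
    list(bic = bic, best_k = best, n_pcs_used = n_pcs,
         cluster = clus[[best]])
  })
}

# PCA + linear discriminant machinery shared by dapcFit and friends.
# Returns discriminant axes scaled so the pooled within-group covariance in
# discriminant space is the identity, making squared distances to centroids
# Mahalanobis distances.
.ldaOnScores <- function(scores, groups, ridge = 1e-8) {
  lv <- levels(groups)
  d <- ncol(scores)
  mu <- rowsum(scores, groups) / as.vector(table(groups))
  W <- matrix(0, d, d)
  for (k in seq_along(lv)) {
    xk <- scores[groups == lv[k], , drop = FALSE]
    xk <- sweep(xk, 2, mu[k, ])
    W <- W + crossprod(xk)
  }
  W <- W / (nrow(scores) - length(lv))
  gm <- colMeans(scores)
  B <- matrix(0, d, d)
  for (k in seq_along(lv)) {
    v <- mu[k, ] - gm
    B <- B + sum(groups == lv[k]) * tcrossprod(v)
  }
  B <- B / nrow(scores)
  Wr <- W + diag(ridge * mean(diag(W)) + ridge, d)
  eig <- eigen(solve(Wr, B))
  n_axes <- min(length(lv) - 1L, d)
  axes <- Re(eig$vectors[, seq_len(n_axes), drop = FALSE])
  # sphere: unit pooled within-group variance along each axis
  for (a in seq_len(n_axes)) {
    s <- sqrt(drop(crossprod(axes[, a], Wr %*% axes[, a])))
    axes[, a] <- axes[, a] / s
  }
  list(axes = axes, centroids = mu %*% axes)
}

# softmax of -0.5 * squared distance to each centroid
.membershipFromDisc <- function(disc, centroids) {
  d2 <- outer(rowSums(disc^2), rowSums(centroids^2), "+") -
    2 * disc %*% t(centroids)
  logw <- -d2 / 2
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw)
  w / rowSums(w)
}

#' Fit a discriminant analysis of principal components (DAPC)
#'
#' Centered/scaled genotypes are reduced to \code{n_pcs} principal
#' components; linear discriminant axes maximizing the between/within group
#' variance ratio are then computed on the PC scores. Group membership
#' probabilities are the softmax of -1/2 times the squared Mahalanobis
#' distance to each group centroid in discriminant space (pooled within-group
#' covariance).
#'
#' @param g a [GenotypeMatrix-class].
#' @param groups group labels, one per individual (default: the population
#'   labels).
#' @param n_pcs PCs to retain; must be < n individuals - n groups. See
#'   [alphaOptimize()] for a principled choice.
#' @return a [DapcModel-class].
#' @export
dapcFit <- function(g, groups = populations(g), n_pcs = 10) {
  geno <- genoMatrix(g)
  groups <- droplevels(as.factor(rep_len(groups, ncol(geno))))
  n <- ncol(geno)
  n_pcs <- as.integer(min(n_pcs, n - nlevels(groups) - 1L))
  stopifnot(n_pcs >= 1)
  p <- .alleleFreq(geno)
  s <- sqrt(p * (1 - p)); s[s == 0 | is.na(s)] <- 1
  center <- 2 * p
  x <- t((geno - center) / s)
  x[is.na(x)] <- 0
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  lda <- .ldaOnScores(scores, groups)
  disc <- scores %*% lda$axes
  memb <- .membershipFromDisc(disc, lda$centroids)
  colnames(memb) <- levels(groups)
  rownames(memb) <- colnames(geno)
  new("DapcModel", n_pcs = n_pcs, center = center, scale = s,
      loadings = sv$v, axes = lda$axes, centroids = lda$centroids,
      groups = groups, membership = memb, locus_ids = rownames(geno))
}

#' Assign new individuals with a fitted DAPC model
#'
#' Projects new genotypes (same locus set as the training data) through the
#' stored centering/scaling, PC loadings and discriminant axes, and returns
#' membership probabilities to the training groups.
#'
#' @param model a [DapcModel-class].
#' @param g_new a [GenotypeMatrix-class] over the model's loci.
#' @return individuals-by-groups membership probability matrix (rows sum
#'   to 1).
#' @export
dapcPredict <- function(model, g_new) {
  geno <- genoMatrix(g_new)
  if (!identical(rownames(geno), model@locus_ids)) {
    if (!all(model@locus_ids %in% rownames(geno)))
      stop("new data lack some model loci")
    geno <- geno[model@locus_ids, , drop = FALSE]
  }
  x <- t((geno - model@center) / model@scale)
  x[is.na(x)] <- 0
  disc <- x %*% model@loadings %*% model@axes
  memb <- .membershipFromDisc(disc, model@centroids)
  colnames(memb) <- levels(model@groups)
  rownames(memb) <- colnames(geno)
  memb
}

#' Choose the number of retained PCs by a-score (alpha) optimization
#'
#' For each candidate PC count, fits the DAPC and computes the a-score: the
#' mean over groups of (observed correct self-reassignment rate minus the
#' mean rate obtained after randomly permuting group labels,
#' \code{n_perm} permutations). The optimum is the PC count with the highest
#' a-score; the penalty term guards against retaining so many PCs that the
#' discriminant step overfits.
#'
#' @param g a [GenotypeMatrix-class].
#' @param groups group labels (default: population labels).
#' @param pc_grid candidate PC counts (default 1..min(20, n - n_groups - 1)).
#' @param n_perm label permutations per candidate (default 10).
#' @param seed RNG seed.
#' @return list with \code{a_score} (named by PC count) and \code{optimum}.
#' @export
alphaOptimize <- function(g, groups = populations(g), pc_grid = NULL,
                          n_perm = 10, seed = NULL) {
  groups <- droplevels(as.factor(rep_len(groups, ncol(g))))
  n <- ncol(g)
  max_pc <- n - nlevels(groups) - 1L
  if (is.null(pc_grid)) pc_grid <- seq_len(min(20L, max_pc))
  pc_grid <- pc_grid[pc_grid <= max_pc & pc_grid >= 1]
  .withSeed(seed, {
    rate_by_group <- function(memb, grp) {
      assigned <- colnames(memb)[max.col(memb, ties.method = "first")]
      vapply(levels(grp), function(l)
        mean(assigned[grp == l] == l), numeric(1))
    }
    scores <- vapply(pc_grid, function(npc) {
      fit <- dapcFit(g, groups, n_pcs = npc)
      obs <- rate_by_group(fit@membership, groups)
      perm <- replicate(n_perm, {
        pg <- factor(sample(as.character(groups)), levels = levels(groups))
        pf <- dapcFit(g, pg, n_pcs = npc)
        mean(rate_by_group(pf@membership, pg))
      })
      mean(obs) - mean(perm)
    }, numeric(1))
    names(scores) <- pc_grid
    list(a_score = scores, optimum = pc_grid[which.max(scores)])
  })
}

# Per-locus FST for ranking inside cross-validation: computed on the
# TRAINING individuals only (held-out genotypes must not influence locus
# choice); monomorphic-in-training loci rank as 0.
.cvRankLoci <- function(geno, groups, train) {
  comp <- .wcComponents(geno[, train, drop = FALSE], groups[train])
  fst <- comp$a / comp$abc
  fst[comp$abc == 0 | is.na(fst)] <- 0
  fst
}

#' Monte-Carlo cross-validated assignment accuracy
#'
#' Resampling grid: training fractions x locus subsets x repeats. In each
#' cell, training individuals are sampled stratified by group; loci are
#' ranked by their pairwise Weir-Cockerham FST computed on the training
#' individuals only (monomorphic-in-training loci rank as 0); the top
#' \code{locus_frac} share of loci is kept; a DAPC is fitted on the training
#' set and the held-out individuals are assigned to the group of highest
#' membership. Accuracy is the correct-assignment fraction, per group and
#' overall. The default grid (3 fractions x 4 locus subsets x 30 repeats)
#' yields 360 evaluations.
#'
#' @param g a [GenotypeMatrix-class].
#' @param groups group labels (default: population labels).
#' @param train_fracs training fractions (default c(0.5, 0.7, 0.9)).
#' @param locus_fracs shares of top-FST loci (default c(0.1, 0.25, 0.5, 1)).
#' @param n_rep repeats per cell (default 30).
#' @param n_pcs PCs for the DAPC (capped per training size; default 10).
#' @param seed RNG seed.
#' @return data.frame with one row per evaluation: \code{train_frac},
#'   \code{locus_frac}, \code{rep}, \code{accuracy} (overall) and one
#'   \code{accuracy_<group>} column per group.
#' @export
monteCarloCV <- function(g, groups = populations(g),
                         train_fracs = c(0.5, 0.7, 0.9),
                         locus_fracs = c(0.1, 0.25, 0.5, 1),
                         n_rep = 30, n_pcs = 10, seed = NULL) {
  groups <- droplevels(as.factor(rep_len(groups, ncol(g))))
  lv <- levels(groups)
  geno <- genoMatrix(g)
  idx_by_group <- split(seq_len(ncol(geno)), groups)
  min_train <- min(train_fracs) * min(lengths(idx_by_group))
  if (floor(min_train) < 2)
    stop("smallest training fraction leaves fewer than 2 ",
         "individuals in a group")
  .withSeed(seed, {
    rows <- list()
    for (tf in train_fracs) for (lf in locus_fracs) for (r in seq_len(n_rep)) {
      train <- unlist(lapply(idx_by_group, function(ix)
        sample(ix, max(2L, floor(tf * length(ix))))))
      test <- setdiff(seq_len(ncol(geno)), train)
      fst <- .cvRankLoci(geno, groups, train)
      n_keep <- max(2L, ceiling(lf * nrow(geno)))
      keep <- order(fst, decreasing = TRUE)[seq_len(n_keep)]
      gtr <- g[sort(keep), train]
      fit <- dapcFit(gtr, groups[train], n_pcs = n_pcs)
      memb <- dapcPredict(fit, g[sort(keep), test])
      assigned <- colnames(memb)[max.col(memb, ties.method = "first")]
      truth <- as.character(groups[test])
      acc_g <- vapply(lv, function(l)
        mean(assigned[truth == l] == l), numeric(1))
      row <- data.frame(train_frac = tf, locus_frac = lf, rep = r,
                        accuracy = mean(assigned == truth))
      row[paste0("accuracy_", lv)] <- as.list(acc_g)
      rows[[length(rows) + 1L]] <- row
    }
    do.call(rbind, rows)
  })
}
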