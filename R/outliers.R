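#' PCA-based genome scan for outlier loci
#'
#' pcadapt-style scan: loci with minor-allele frequency below \code{maf_min}
#' are excluded; genotypes are centered and scaled and the first K principal
#' components computed; each locus's genotypes are regressed on the K PC
#' score vectors, giving K z-scores per locus; the robust squared Mahalanobis
#' distance of the z-vector (minimum covariance determinant estimate of
#' location/scatter; median/MAD when K = 1) is divided by the genomic
#' inflation factor gif = median(D2) / median(chi2_K) and referred to a
#' chi-square with K df for p-values; Storey q-values then flag outliers at
#' \code{q_threshold}.
#'
#' @param g a [GenotypeMatrix-class].
#' @param k retained PCs (chosen from the scree series; see
#'   \code{explained_var} in the result). Default "elbow" picks the largest
#'   drop in the explained-variance series.
#' @param maf_min minor-allele-frequency exclusion threshold (default 0.05).
#' @param q_threshold q-value cutoff for the outlier flag (default 0.1).
#' @return an [OutlierReport-class].
#' @examples
#' g <- simulatePopulations(2, 25, 500, target_fst = 0.05,
#'                          n_outliers = 10, outlier_fst = 0.4, seed = 3)
#' pcaOutlierScan(g, k = 1)
#' @export
pcaOutlierScan <- function(g, k = "elbow", maf_min = 0.05,
                           q_threshold = 0.1) {
  geno <- genoMatrix(g)
  p <- .alleleFreq(geno)
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0
  maf_filtered <- maf < maf_min
  gg <- geno[!maf_filtered, , drop = FALSE]
  if (nrow(gg) < 10) stop("too few loci after MAF filtering")
  x <- .scaleGenotypes(gg)          # individuals x loci
  n <- nrow(x)
  sv <- svd(x)
  ev <- sv$d^2 / sum(sv$d^2)
  if (identical(k, "elbow")) {
    drop <- -diff(ev[seq_len(min(20, length(ev) - 1))])
    k <- which.max(drop)
  }
  k <- as.integer(k)
  stopifnot(k >= 1, k < n)
  scores <- sv$u[, seq_len(k), drop = FALSE]   # orthonormal columns
  # regression z-scores of each locus's genotypes on the K score vectors
  Z <- .pcRegressionZ(gg, scores)
  keep <- stats::complete.cases(Z) & apply(is.finite(Z), 1, all)
  D2 <- rep(NA_real_, nrow(Z))
  Zk <- Z[keep, , drop = FALSE]
  if (k == 1) {
    ctr <- stats::median(Zk)
    scl <- stats::mad(Zk)^2
    D2[keep] <- (Zk - ctr)^2 / scl
  } else {
    rob <- MASS::cov.rob(Zk, method = "mcd")
    D2[keep] <- stats::mahalanobis(Zk, rob$center, rob$cov)
  }
  gif <- stats::median(D2, na.rm = TRUE) / stats::qchisq(0.5, k)
  pv <- stats::pchisq(D2 / gif, df = k, lower.tail = FALSE)
  qv <- rep(NA_real_, length(pv))
  qv[!is.na(pv)] <- storeyQvalues(pv[!is.na(pv)])
  new("OutlierReport",
      locus = rownames(gg), contig = as.character(lociInfo(g)$contig[!maf_filtered]),
      pos = as.integer(lociInfo(g)$pos[!maf_filtered]),
      zscores = Z, mahalanobis = D2, gif = gif, pvalue = pv, qvalue = qv,
      outlier = !is.na(qv) & qv < q_threshold,
      maf_filtered = unname(maf_filtered), k = k,
      explained_var = ev[seq_len(min(20, length(ev)))],
      q_threshold = q_threshold)
}

# z-scores (t-statistics) of the multiple regression of each locus's
# genotypes on K PC score vectors (orthonormal columns). Loci without
# missing data are handled in one matrix pass; loci with missing genotypes
# are refit individually.
.pcRegressionZ <- function(geno, scores) {
  n <- ncol(geno)
  k <- ncol(scores)
  Z <- matrix(NA_real_, nrow(geno), k)
  complete <- !apply(is.na(geno), 1, any)
  if (any(complete)) {
    Y <- t(geno[complete, , drop = FALSE])        # n x Lc
    Ym <- sweep(Y, 2, colMeans(Y))
    B <- crossprod(scores, Ym)                    # k x Lc (S'S = I)
    fitted <- scores %*% B
    rss <- colSums((Ym - fitted)^2)
    df <- n - k - 1L
    sigma2 <- rss / df
    Z[complete, ] <- t(B) / sqrt(sigma2)          # var(beta_j) = sigma2
  }
  for (i in which(!complete)) {
    y <- geno[i, ]
    ok <- !is.na(y)
    if (sum(ok) <= k + 1) next
    fit <- stats::lm.fit(cbind(1, scores[ok, , drop = FALSE]), y[ok])
    rdf <- sum(ok) - k - 1L
    s2 <- sum(fit$residuals^2) / rdf
    xtx <- solve(crossprod(cbind(1, scores[ok, , drop = FALSE])))
    Z[i, ] <- fit$coefficients[-1] / sqrt(s2 * diag(xtx)[-1])
  }
  rownames(Z) <- rownames(geno)
  Z
}

#' Storey q-values
#'
#' Estimates the proportion of true nulls pi0 on the lambda grid
#' 0.05..0.95 (pi0(lambda) = #(p > lambda) / (m (1 - lambda))) with a cubic
#' smoothing spline evaluated at the largest lambda, clipped to [0, 1], and
#' returns q = pi0 times the Benjamini-Hochberg step-up adjusted p-values
#' (monotone in p).
#'
#' @param p p-values in [0, 1].
#' @param lambda tuning grid (default seq(0.05, 0.95, 0.05)).
#' @return q-values, same length and order as \code{p}.
#' @export
storeyQvalues <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (all(pi0_l == 0)) 0 else {
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(sp, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, 0), 1)
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Concordance between two outlier locus sets
#'
#' @param a,b character vectors of locus ids (same locus universe).
#' @return list with \code{intersection}, \code{a_only}, \code{b_only}
#'   counts and the shared ids in \code{shared}.
#' @export
outlierConcordance <- function(a, b) {
  shared <- intersect(a, b)
  list(intersection = length(shared),
       a_only = length(setdiff(a, b)),
       b_only = length(setdiff(b, a)),
       shared = shared)
}

#' Contigs carrying clustered outlier loci
#'
#' Lists the contigs on which more than \code{min_outliers - 1} flagged loci
#' lie (default: contigs with more than 2 outliers), a possible sign of
#' selection acting along a sequence despite physical thinning.
#'
#' @param report an [OutlierReport-class].
#' @param min_outliers a contig is reported when it carries at least this
#'   many outliers (default 3).
#' @return data.frame with \code{contig} and \code{n_outliers}.
#' @export
contigOutlierClusters <- function(report, min_outliers = 3) {
  tab <- table(report@contig[report@outlier])
  tab <- tab[tab >= min_outliers]
  data.frame(contig = names(tab), n_outliers = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
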