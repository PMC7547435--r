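# Internal helpers shared across modules.

# Evaluate expr under a local RNG state. seed = NULL leaves the global
# stream untouched (draws still advance it).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Pooled alt-allele frequency per locus over non-missing genotypes.
.alleleFreq <- function(geno) {
  rowMeans(geno, na.rm = TRUE) / 2
}

# Center/scale genotypes for PCA: center by 2*p, scale by sqrt(p*(1-p)),
# missing values set to 0 after centering (i.e. locus-mean imputation).
# Returns individuals x loci. Monomorphic loci get scale 1 (all-zero column).
.scaleGenotypes <- function(geno) {
  p <- .alleleFreq(geno)
  s <- sqrt(p * (1 - p))
  s[s == 0 | is.na(s)] <- 1
  x <- (geno - 2 * p) / s
  x[is.na(x)] <- 0
  t(x)
}

# PCA of an individuals x loci matrix (already centered); returns scores,
# loadings (rotation) and the explained-variance series.
.pcaScores <- function(x, n_pcs) {
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  ev <- sv$d^2 / sum(sv$d^2)
  list(scores = sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs),
       loadings = sv$v, d = sv$d, explained_var = ev)
}

# Per-population per-locus summaries needed by WC FST and diversity:
# lists of L x npop matrices n (non-missing individuals), p (alt freq),
# h (observed het fraction).
.popSummaries <- function(geno, pop) {
  pop <- as.factor(pop)
  lv <- levels(pop)
  L <- nrow(geno)
  n <- p <- h <- matrix(0, L, length(lv), dimnames = list(NULL, lv))
  for (i in seq_along(lv)) {
    gi <- geno[, pop == lv[i], drop = FALSE]
    ni <- rowSums(!is.na(gi))
    n[, i] <- ni
    p[, i] <- ifelse(ni > 0, rowSums(gi, na.rm = TRUE) / (2 * ni), NA)
    h[, i] <- ifelse(ni > 0, rowSums(gi == 1, na.rm = TRUE) / ni, NA)
  }
  list(n = n, p = p, h = h, levels = lv)
}
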