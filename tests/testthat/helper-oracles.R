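# Independent brute-force oracles, deliberately coded from the textbook
# definitions rather than sharing any implementation with the package.

# Weir & Cockerham (1984) theta: plain scalar loops, straight from the
# published variance-component formulas. geno: loci x individuals in 0/1/2,
# NA allowed.
oracle_wc_fst <- function(geno, pop) {
  pops <- sort(unique(pop))
  r <- length(pops)
  num <- den <- 0
  for (l in seq_len(nrow(geno))) {
    ni <- pi <- hi <- numeric(r)
    for (k in seq_len(r)) {
      gk <- geno[l, pop == pops[k]]
      gk <- gk[!is.na(gk)]
      ni[k] <- length(gk)
      if (length(gk) == 0) next
      pi[k] <- sum(gk) / (2 * length(gk))
      hi[k] <- mean(gk == 1)
    }
    if (any(ni < 1) || sum(ni) <= r) next
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    pbar <- sum(ni * pi) / sum(ni)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
      ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Naive O(n^3) UPGMA returning the cophenetic distance matrix: clusters are
# merged at the smallest size-weighted average distance; members of clusters
# merged at distance d sit at cophenetic distance d.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  dd <- d
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (ai in seq_along(idx)) for (bi in seq_along(idx)) {
      if (bi <= ai) next
      i <- idx[ai]; j <- idx[bi]
      # average linkage over original pairs
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < bestd - 1e-12) { bestd <- dij; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (x in clusters[[i]]) for (y in clusters[[j]]) {
      coph[x, y] <- coph[y, x] <- bestd
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active[j] <- FALSE
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[ro]
}

# Exact HWE test by direct enumeration with choose() products.
oracle_hwe_exact <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- sapply(hs, function(h) {
    nbb <- (na - h) / 2
    naa2 <- (nA - h) / 2
    choose(n, naa2) * choose(n - naa2, h) * 2^h
  })
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hs)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# OLS R^2 and F-test p from closed forms.
oracle_ols_r2 <- function(x, y) {
  r2 <- stats::cor(x, y)^2
  n <- length(x)
  fstat <- r2 / (1 - r2) * (n - 2)
  list(r2 = r2, p = stats::pf(fstat, 1, n - 2, lower.tail = FALSE))
}

# Small genotype objects used across tests.
make_gm <- function(geno, pops, ...) {
  GenotypeMatrix(geno, populations = pops, ...)
}
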