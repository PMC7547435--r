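#' Provesti (allele-sharing) distance between individuals
#'
#' d(i, j) = mean over loci non-missing in both individuals of
#' |g_i - g_j| / 2, where g are alt-allele counts. Ranges from 0 (identical
#' genotypes) to 1 (opposite homozygotes at every locus).
#'
#' @param g a [GenotypeMatrix-class] with at least 2 individuals.
#' @return a symmetric individuals-by-individuals distance matrix.
#' @export
provestiDist <- function(g) {
  geno <- genoMatrix(g)
  n <- ncol(geno)
  stopifnot(n >= 2)
  d <- matrix(0, n, n, dimnames = list(colnames(geno), colnames(geno)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(geno[, i]) & !is.na(geno[, j])
    if (!any(ok))
      stop("individuals ", colnames(geno)[i], " and ", colnames(geno)[j],
           " share no non-missing loci")
    d[i, j] <- d[j, i] <- mean(abs(geno[ok, i] - geno[ok, j])) / 2
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration yielding a rooted ultrametric tree; a pair
#' at distance d joins at height d/2.
#'
#' @param d symmetric distance matrix (or \code{dist}).
#' @return an \pkg{ape} \code{phylo} tree.
#' @export
upgmaTree <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for a UPGMA individual tree
#'
#' Builds the Provesti/UPGMA tree, then resamples loci with replacement
#' \code{n_boot} times, rebuilds the tree, and scores each internal node by
#' the percentage of replicate trees containing the same clade (leaf set).
#'
#' @param g a [GenotypeMatrix-class].
#' @param n_boot bootstrap replicates (default 100; 0 returns the tree with
#'   no support values).
#' @param seed RNG seed.
#' @param min_support support values below this percentage are reported as NA
#'   (tree-figure convention; default 0 keeps all).
#' @return list with \code{tree} (phylo, tip labels = individuals) and
#'   \code{support} (percentage per internal node, in
#'   \code{tree$node.label} order).
#' @export
bootstrapSupport <- function(g, n_boot = 100, seed = NULL, min_support = 0) {
  tree <- upgmaTree(provestiDist(g))
  if (n_boot == 0)
    return(list(tree = tree, support = NULL))
  geno <- genoMatrix(g)
  .withSeed(seed, {
    boots <- lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(geno), nrow(geno), replace = TRUE)
      upgmaTree(provestiDist2(geno[idx, , drop = FALSE]))
    })
    counts <- ape::prop.clades(tree, boots, rooted = TRUE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / n_boot
    support[support < min_support] <- NA
    tree$node.label <- support
    list(tree = tree, support = support)
  })
}

# provestiDist on a raw matrix (used by the bootstrap, where resampled loci
# may duplicate coordinates and so cannot form a GenotypeMatrix).
provestiDist2 <- function(geno) {
  n <- ncol(geno)
  d <- matrix(0, n, n, dimnames = list(colnames(geno), colnames(geno)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(geno[, i]) & !is.na(geno[, j])
    d[i, j] <- d[j, i] <- mean(abs(geno[ok, i] - geno[ok, j])) / 2
  }
  d
}
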