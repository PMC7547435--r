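#' Select a diagnostic SNP panel by pairwise FST ranking
#'
#' For one population pair: on each contig/scaffold, take the SNP with the
#' highest pairwise Weir-Cockerham FST (ties broken by lowest position); rank
#' the per-contig candidates from highest to lowest FST; truncate the ranked
#' list at \code{fst_floor}.
#'
#' @param g a [GenotypeMatrix-class].
#' @param pair two population names (default: first two present).
#' @param fst_floor keep candidates with FST >= this value (default 0.15).
#' @return data.frame of panel loci in descending FST order: \code{locus},
#'   \code{contig}, \code{pos}, \code{fst}. Empty (with a warning) when no
#'   locus reaches the floor.
#' @export
selectPanel <- function(g, pair = NULL, fst_floor = 0.15) {
  pop <- populations(g)
  if (is.null(pair)) pair <- sort(unique(pop))[1:2]
  fst <- perLocusFst(g, pair = pair)
  rd <- lociInfo(g)
  df <- data.frame(locus = rownames(g), contig = as.character(rd$contig),
                   pos = rd$pos, fst = fst, stringsAsFactors = FALSE)
  df <- df[!is.na(df$fst), , drop = FALSE]
  # per contig: max FST, ties -> lowest position (rows are position-sorted)
  df <- df[order(df$contig, -df$fst, df$pos), , drop = FALSE]
  cand <- df[!duplicated(df$contig), , drop = FALSE]
  cand <- cand[order(-cand$fst, cand$contig, cand$pos), , drop = FALSE]
  panel <- cand[cand$fst >= fst_floor, , drop = FALSE]
  if (!nrow(panel)) warning("no locus reaches the FST floor of ", fst_floor)
  rownames(panel) <- NULL
  panel
}

#' Genotype concordance between discovery and validation data
#'
#' Cellwise comparison over the shared individuals and loci (matched by id):
#' a cell missing in either dataset counts as missing; otherwise it is
#' matching or non-matching. The three percentages sum to 100.
#'
#' @param discovery,validation [GenotypeMatrix-class] objects sharing
#'   individual and locus ids.
#' @return list with \code{matching}, \code{missing}, \code{non_matching}
#'   (percent over all compared cells) and \code{n_cells}.
#' @export
genotypeConcordance <- function(discovery, validation) {
  ind <- intersect(colnames(discovery), colnames(validation))
  loc <- intersect(rownames(discovery), rownames(validation))
  if (!length(ind) || !length(loc))
    stop("no shared individuals/loci between the datasets")
  a <- genoMatrix(discovery)[loc, ind, drop = FALSE]
  b <- genoMatrix(validation)[loc, ind, drop = FALSE]
  miss <- is.na(a) | is.na(b)
  match_ <- !miss & a == b
  n <- length(a)
  list(matching = 100 * sum(match_) / n,
       missing = 100 * sum(miss) / n,
       non_matching = 100 * sum(!miss & !match_) / n,
       n_cells = n)
}

#' Correlation between two per-locus FST series
#'
#' Ordinary least-squares R-squared between locus-wise FST estimated by two
#' methods (e.g. sequence-derived vs genotyping-derived), with the F-test
#' p-value of the regression.
#'
#' @param fst_a,fst_b numeric vectors over the same loci (>= 3 finite pairs).
#' @return list with \code{r2}, \code{p}, \code{n}.
#' @export
fstMethodCorrelation <- function(fst_a, fst_b) {
  ok <- is.finite(fst_a) & is.finite(fst_b)
  stopifnot(sum(ok) >= 3)
  x <- fst_a[ok]; y <- fst_b[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in an FST vector")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(r2 = sm$r.squared,
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                            lower.tail = FALSE)),
       n = sum(ok))
}

#' Robust subset of a panel by per-population mapping quality
#'
#' Keeps the panel loci whose per-population mean quality exceeds every
#' population's threshold simultaneously (strict >). Loci with a missing
#' quality value in any thresholded population are excluded.
#'
#' @param panel character vector of locus ids (or the data.frame from
#'   [selectPanel()], whose \code{locus} column is used).
#' @param mean_mapq_by_pop loci-by-populations matrix (or data.frame) of mean
#'   quality values, rownames = locus ids.
#' @param thresholds named numeric: minimum mean quality per population, e.g.
#'   \code{c(popA = 50, popB = 40)}.
#' @return character vector: the loci passing all thresholds.
#' @export
robustSubset <- function(panel, mean_mapq_by_pop, thresholds) {
  if (is.data.frame(panel) && "locus" %in% names(panel))
    panel <- panel$locus
  q <- as.matrix(mean_mapq_by_pop)
  stopifnot(!is.null(names(thresholds)),
            all(names(thresholds) %in% colnames(q)))
  keep <- vapply(panel, function(l) {
    if (!l %in% rownames(q)) return(FALSE)
    v <- q[l, names(thresholds)]
    all(!is.na(v)) && all(v > thresholds)
  }, logical(1))
  panel[keep]
}
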