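#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData rowData<- colData
NULL

#' GenotypeMatrix: diploid SNP genotypes with population labels
#'
#' Container for biallelic SNP genotypes coded as the number of copies of the
#' alternate allele (0, 1, 2; \code{NA} = missing), stored loci-by-individuals
#' as a \linkS4class{SummarizedExperiment}. Locus metadata (\code{contig},
#' \code{pos}, and optional per-site \code{qual}, \code{dp}, \code{mq}) live in
#' \code{rowData}; the per-individual population label lives in
#' \code{colData$population}. Loci are kept sorted by (contig, position) with
#' no duplicate coordinates.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}; the genotype
#'   codes are in \code{assay(x, "geno")}.
#' @seealso [GenotypeMatrix()], [genoMatrix()], [populations()], [lociInfo()]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

.validGenotypeMatrix <- function(object) {
  msg <- character()
  if (!"geno" %in% names(assays(object)))
    msg <- c(msg, "assay 'geno' is required")
  else {
    g <- assay(object, "geno")
    v <- g[!is.na(g)]
    if (length(v) && !all(v %in% c(0L, 1L, 2L)))
      msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  if (!all(c("contig", "pos") %in% names(rd)))
    msg <- c(msg, "rowData must contain 'contig' and 'pos'")
  else {
    if (any(rd$pos < 1L)) msg <- c(msg, "positions must be >= 1")
    o <- order(as.character(rd$contig), rd$pos)
    if (!identical(o, seq_len(nrow(rd))))
      msg <- c(msg, "loci must be sorted by (contig, pos)")
    if (anyDuplicated(paste(rd$contig, rd$pos)))
      msg <- c(msg, "duplicate (contig, pos) loci are not allowed")
  }
  if (!"population" %in% names(colData(object)))
    msg <- c(msg, "colData must contain 'population'")
  else if (anyNA(colData(object)$population))
    msg <- c(msg, "every individual needs a population label")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param geno integer matrix of alt-allele counts, loci in rows and
#'   individuals in columns (values 0/1/2/\code{NA}). Row and column names, if
#'   absent, are generated.
#' @param populations character or factor of population labels, one per
#'   individual (recycled if length 1).
#' @param contig,pos locus coordinates (1-based positions). Default: all loci
#'   on one contig at positions \code{1:n}.
#' @param qual,dp,mq optional per-site quality, depth and mapping quality.
#' @param dp_sample optional loci-by-individuals matrix of per-sample depths.
#' @return a [GenotypeMatrix-class] object with loci sorted by (contig, pos).
#' @examples
#' g <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'                     populations = c("A", "B"))
#' genoMatrix(g)
#' @export
GenotypeMatrix <- function(geno, populations,
                           contig = rep("ctg1", nrow(geno)),
                           pos = seq_len(nrow(geno)),
                           qual = NULL, dp = NULL, mq = NULL,
                           dp_sample = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("locus", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  populations <- rep_len(as.character(populations), ncol(geno))
  rd <- DataFrame(contig = as.character(contig), pos = as.integer(pos))
  if (!is.null(qual)) rd$qual <- as.numeric(qual)
  if (!is.null(dp))   rd$dp   <- as.numeric(dp)
  if (!is.null(mq))   rd$mq   <- as.numeric(mq)
  o <- order(rd$contig, rd$pos)
  geno <- geno[o, , drop = FALSE]
  rd <- rd[o, , drop = FALSE]
  asy <- list(geno = geno)
  if (!is.null(dp_sample)) {
    dp_sample <- as.matrix(dp_sample)[o, , drop = FALSE]
    dimnames(dp_sample) <- dimnames(geno)
    asy$dp_sample <- dp_sample
  }
  se <- SummarizedExperiment(
    assays = asy, rowData = rd,
    colData = DataFrame(population = populations, row.names = colnames(geno)))
  new("GenotypeMatrix", se)
}

#' KmerHistogram: a k-mer multiplicity spectrum
#'
#' Histogram of k-mer multiplicities: for each multiplicity m >= 1, the number
#' of distinct k-mers observed exactly m times in a read set.
#'
#' @slot k k-mer length in bp.
#' @slot multiplicity strictly increasing integer multiplicities (>= 1).
#' @slot count number of distinct k-mers at each multiplicity (>= 0).
#' @export
setClass("KmerHistogram",
         representation(k = "integer", multiplicity = "integer",
                        count = "numeric"))

setValidity("KmerHistogram", function(object) {
  msg <- character()
  if (length(object@multiplicity) != length(object@count))
    msg <- c(msg, "multiplicity and count lengths differ")
  if (length(object@multiplicity)) {
    if (any(object@multiplicity < 1L)) msg <- c(msg, "multiplicities must be >= 1")
    if (is.unsorted(object@multiplicity, strictly = TRUE))
      msg <- c(msg, "multiplicities must be strictly increasing")
  }
  if (any(object@count < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a KmerHistogram
#'
#' @param multiplicity integer multiplicities (>= 1); need not be sorted.
#' @param count distinct-k-mer count per multiplicity.
#' @param k k-mer length in bp (default 32).
#' @return a [KmerHistogram-class].
#' @export
KmerHistogram <- function(multiplicity, count, k = 32L) {
  o <- order(multiplicity)
  new("KmerHistogram", k = as.integer(k),
      multiplicity = as.integer(multiplicity[o]),
      count = as.numeric(count[o]))
}

#' FstResult: Weir-Cockerham differentiation estimates with bootstrap CIs
#'
#' @slot pairwise symmetric matrix of pairwise multi-locus theta.
#' @slot ci_low,ci_high 95% bootstrap percentile bounds, same shape.
#' @slot overall multi-locus theta over all populations, with its CI in
#'   \code{overall_ci}.
#' @slot per_locus per-locus theta (all populations; NA where monomorphic).
#' @slot n_boot bootstrap replicate count.
#' @export
setClass("FstResult",
         representation(pairwise = "matrix", ci_low = "matrix",
                        ci_high = "matrix", overall = "numeric",
                        overall_ci = "numeric", per_locus = "numeric",
                        n_boot = "integer"))

#' SpectrumFit: EM fit of the k-mer spectrum mixture
#'
#' Mixture of a zero-truncated negative binomial (sequencing-error k-mers) and
#' zero-truncated Poissons for the haploid (mean lambda), diploid (2*lambda)
#' and repeat (2*lambda*c, c = 2,3,...) classes, fitted to a
#' [KmerHistogram-class] by expectation-maximization.
#'
#' @slot lambda_hap haploid-class Poisson mean (coverage per haplotype).
#' @slot error_mean,error_dispersion negative-binomial mean and size.
#' @slot weights mixing proportions (error, haploid, diploid, repeat classes).
#' @slot n_repeat_classes repeat copy classes modeled.
#' @slot loglik,loglik_trace final log-likelihood and per-iteration trace.
#' @slot n_iter,converged EM iteration count and convergence flag.
#' @slot posterior bin-by-component responsibility matrix.
#' @slot multiplicity,count,tail_mass the (tail-pooled) histogram the fit used;
#'   \code{tail_mass} is the total k-mer mass (sum of m*count) in the pooled
#'   tail bin.
#' @slot k k-mer length carried from the histogram.
#' @export
setClass("SpectrumFit",
         representation(lambda_hap = "numeric", error_mean = "numeric",
                        error_dispersion = "numeric", weights = "numeric",
                        n_repeat_classes = "integer", loglik = "numeric",
                        loglik_trace = "numeric", n_iter = "integer",
                        converged = "logical", posterior = "matrix",
                        multiplicity = "numeric", count = "numeric",
                        tail_mass = "numeric", k = "integer"))

#' DapcModel: discriminant analysis of principal components
#'
#' @slot n_pcs PCs retained before the discriminant step.
#' @slot center,scale per-locus centering/scaling used before PCA.
#' @slot loadings locus-by-PC loading matrix.
#' @slot axes PC-by-discriminant axis matrix (within-group sphered).
#' @slot centroids group centroids in discriminant space.
#' @slot groups training group factor; \code{membership} the training
#'   individuals' posterior membership matrix (rows sum to 1).
#' @slot locus_ids locus identifiers the model expects.
#' @export
setClass("DapcModel",
         representation(n_pcs = "integer", center = "numeric",
                        scale = "numeric", loadings = "matrix",
                        axes = "matrix", centroids = "matrix",
                        groups = "factor", membership = "matrix",
                        locus_ids = "character"))

#' OutlierReport: PCA/Mahalanobis genome-scan results
#'
#' @slot locus,contig,pos locus identity (loci that passed the MAF filter).
#' @slot zscores locus-by-K matrix of PC regression z-scores.
#' @slot mahalanobis robust squared Mahalanobis distances.
#' @slot gif genomic inflation factor.
#' @slot pvalue,qvalue chi-square p-values (gif-corrected) and Storey q-values.
#' @slot outlier flag: qvalue < q_threshold.
#' @slot maf_filtered flags over the input loci: TRUE where MAF < maf_min
#'   excluded a locus from the scan.
#' @slot k retained PCs; \code{explained_var} the PCA scree series.
#' @slot q_threshold the q-value cutoff used for flags.
#' @export
setClass("OutlierReport",
         representation(locus = "character", contig = "character",
                        pos = "integer", zscores = "matrix",
                        mahalanobis = "numeric", gif = "numeric",
                        pvalue = "numeric", qvalue = "numeric",
                        outlier = "logical", maf_filtered = "logical",
                        k = "integer", explained_var = "numeric",
                        q_threshold = "numeric"))
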