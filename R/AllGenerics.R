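#' Accessors for GenotypeMatrix and result objects
#'
#' \code{genoMatrix} returns the loci-by-individuals integer matrix of
#' alt-allele counts; \code{populations} the per-individual population labels;
#' \code{lociInfo} the locus metadata (\code{DataFrame} with contig, pos, ...).
#'
#' @param x a [GenotypeMatrix-class].
#' @return see description.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("genoMatrix", function(x) standardGeneric("genoMatrix"))

#' @rdname genotype-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname genotype-accessors
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname genotype-accessors
setMethod("genoMatrix", "GenotypeMatrix", function(x) assay(x, "geno"))

#' @rdname genotype-accessors
setMethod("populations", "GenotypeMatrix",
          function(x) as.character(colData(x)$population))

#' @rdname genotype-accessors
setMethod("lociInfo", "GenotypeMatrix", function(x) rowData(x))

setMethod("show", "GenotypeMatrix", function(object) {
  pops <- table(populations(object))
  cat("GenotypeMatrix:", nrow(object), "loci x", ncol(object),
      "individuals\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  g <- genoMatrix(object)
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(g))))
  cat("  contigs:", length(unique(lociInfo(object)$contig)), "\n")
})

setMethod("show", "KmerHistogram", function(object) {
  cat("KmerHistogram (k =", object@k, "):",
      length(object@multiplicity), "multiplicities,",
      format(sum(object@count), big.mark = ","), "distinct k-mers\n")
})

setMethod("show", "FstResult", function(object) {
  cat("Weir-Cockerham FST (", object@n_boot, "bootstraps )\n")
  cat(sprintf("  overall theta = %.4f [%.4f, %.4f]\n", object@overall,
              object@overall_ci[1], object@overall_ci[2]))
  if (nrow(object@pairwise) > 1) {
    cat("  pairwise:\n")
    print(round(object@pairwise, 4))
  }
})

setMethod("show", "SpectrumFit", function(object) {
  cat("SpectrumFit: lambda =", signif(object@lambda_hap, 5),
      "| error NB mean =", signif(object@error_mean, 4),
      "size =", signif(object@error_dispersion, 4), "\n")
  cat("  weights:", paste(sprintf("%s=%.3f", names(object@weights),
                                  object@weights), collapse = " "), "\n")
  cat("  loglik =", format(object@loglik), "after", object@n_iter,
      "iterations; converged:", object@converged, "\n")
})

setMethod("show", "DapcModel", function(object) {
  cat("DapcModel:", object@n_pcs, "PCs,", ncol(object@axes),
      "discriminant axes,", nlevels(object@groups), "groups\n")
  cat("  mean self-assignment membership:",
      sprintf("%.3f", mean(object@membership[
        cbind(seq_along(object@groups), as.integer(object@groups))])), "\n")
})

setMethod("show", "OutlierReport", function(object) {
  cat("OutlierReport: K =", object@k, "| gif =", signif(object@gif, 4), "\n")
  cat("  ", sum(object@outlier), "of", length(object@locus),
      "scanned loci flagged at q <", object@q_threshold, "(",
      sum(object@maf_filtered), "loci MAF-excluded )\n")
})
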