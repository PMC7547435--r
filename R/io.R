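#' Read a genotype matrix from delimited text
#'
#' Reads a tab-separated genotype table into a [GenotypeMatrix-class].
#' Two layouts are auto-detected from the header:
#' \itemize{
#'   \item loci as rows: columns \code{id}, \code{contig}, \code{pos},
#'     then one column per individual (the layout [writeGenotypeTable()]
#'     produces);
#'   \item individuals as rows: columns \code{individual},
#'     \code{population} (optional), then one column per locus. Locus
#'     coordinates are parsed from ids of the form \code{contig_pos} when
#'     possible.
#' }
#' Cells must be 0, 1, 2 or NA (alt-allele counts). Labels given in the table
#' itself take precedence over \code{population_map}.
#'
#' @param path file path.
#' @param population_map optional population labels: a named character vector
#'   (names = individual ids), a two-column data.frame, or the path of a
#'   two-column \code{individual<TAB>population} file.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeTable <- function(path, population_map = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty genotype table: ", path)
  hdr <- names(tab)
  if (identical(hdr[1:3], c("id", "contig", "pos"))) {
    ind <- hdr[-(1:3)]
    geno <- as.matrix(tab[, -(1:3), drop = FALSE])
    rownames(geno) <- tab$id
    contig <- tab$contig
    pos <- tab$pos
    pops <- .resolvePopulations(ind, NULL, population_map)
  } else if (hdr[1] %in% c("individual", "ind", "sample")) {
    has_pop <- hdr[2] == "population"
    first_locus <- if (has_pop) 3L else 2L
    ind <- tab[[1]]
    geno <- t(as.matrix(tab[, first_locus:ncol(tab), drop = FALSE]))
    colnames(geno) <- ind
    loc_ids <- hdr[first_locus:ncol(tab)]
    m <- regmatches(loc_ids, regexec("^(.*)_([0-9]+)$", loc_ids))
    parsed <- lengths(m) == 3L
    contig <- ifelse(parsed, vapply(m, function(z) z[2], ""), loc_ids)
    pos <- ifelse(parsed, as.integer(vapply(m, function(z) z[3], "")), 1L)
    rownames(geno) <- loc_ids
    pops <- .resolvePopulations(ind, if (has_pop) tab$population else NULL,
                                population_map)
  } else {
    stop("unrecognised genotype table header in ", path)
  }
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(geno)), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code at locus row %d, individual column %d",
                 idx[1], idx[2]))
  }
  GenotypeMatrix(geno, populations = pops, contig = contig, pos = pos)
}

.resolvePopulations <- function(individuals, table_pops, population_map) {
  if (!is.null(table_pops)) return(table_pops)
  if (is.null(population_map))
    stop("population labels missing: supply population_map")
  map <- population_map
  if (is.character(map) && is.null(names(map)) && length(map) == 1L &&
      file.exists(map))
    map <- readPopulationMap(map)
  if (is.data.frame(map)) map <- stats::setNames(map[[2]], map[[1]])
  missing_ind <- setdiff(individuals, names(map))
  if (length(missing_ind))
    stop("individuals absent from population map: ",
         paste(missing_ind, collapse = ", "))
  as.character(map[individuals])
}

#' Write a genotype matrix as delimited text
#'
#' Writes the loci-as-rows layout read back by [readGenotypeTable()]:
#' \code{id}, \code{contig}, \code{pos}, then one column per individual.
#' Population labels are not stored in this layout; write them with
#' [writePopulationMap()].
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTable <- function(g, path) {
  geno <- genoMatrix(g)
  rd <- lociInfo(g)
  out <- data.frame(id = rownames(geno), contig = rd$contig, pos = rd$pos,
                    geno, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a two-column population map
#'
#' Tab-separated \code{individual<TAB>population}, with or without a header
#' line.
#'
#' @param path file path.
#' @return \code{readPopulationMap}: data.frame with columns
#'   \code{individual}, \code{population}.
#' @export
readPopulationMap <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("individual", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab[, 1:2], c("individual", "population"))
}

#' @rdname readPopulationMap
#' @param g a [GenotypeMatrix-class].
#' @export
writePopulationMap <- function(g, path) {
  utils::write.table(
    data.frame(individual = colnames(g), population = populations(g)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a k-mer multiplicity histogram
#'
#' Two whitespace-separated columns: multiplicity, count (the format written
#' by common k-mer counters).
#'
#' @param path file path.
#' @param k k-mer length to record on the object (default 32).
#' @return \code{readKmerHistogram}: a [KmerHistogram-class].
#' @export
readKmerHistogram <- function(path, k = 32L) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE,
                      colClasses = c("integer", "numeric")),
    error = function(e) stop("cannot parse k-mer histogram ", path, ": ",
                             conditionMessage(e)))
  if (!nrow(tab)) stop("empty k-mer histogram: ", path)
  KmerHistogram(tab[[1]], tab[[2]], k = k)
}

#' @rdname readKmerHistogram
#' @param hist a [KmerHistogram-class].
#' @export
writeKmerHistogram <- function(hist, path) {
  writeLines(sprintf("%d\t%s", hist@multiplicity,
                     format(hist@count, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Reads a VCF v4.x with \pkg{vcfR}, keeps biallelic SNPs only (multi-allelic
#' records are skipped with a warning), and recodes GT fields as alt-allele
#' counts (0/1/2, missing -> NA). Site QUAL, INFO DP and MQ, and per-sample
#' FORMAT DP (when present) are carried into the result's \code{rowData} /
#' assays for [filterSites()].
#'
#' @param path VCF file path.
#' @param population_map population labels for every sample in the VCF (see
#'   [readGenotypeTable()] for accepted forms).
#' @return a [GenotypeMatrix-class] with \code{qual}, \code{dp}, \code{mq}
#'   locus metadata.
#' @export
readVcfGenotypes <- function(path, population_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    alt != "."
  if (any(!biallelic))
    warning(sum(!biallelic), " multi-allelic or non-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- gt[biallelic, , drop = FALSE]
  allele1 <- substr(gt, 1, 1)
  allele2 <- substr(gt, 3, 3)
  geno <- (allele1 == "1") + (allele2 == "1")
  geno[allele1 == "." | allele2 == "." | is.na(gt) | nchar(gt) < 3] <- NA
  geno <- matrix(as.integer(geno), nrow = sum(biallelic),
                 dimnames = dimnames(gt))
  dp_sample <- NULL
  if (any(grepl("DP", v@gt[, "FORMAT"]))) {
    dp_sample <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    dp_sample <- dp_sample[biallelic, , drop = FALSE]
  }
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (is.null(x)) rep(NA_real_, nrow(fix)) else x
  }
  pops <- .resolvePopulations(colnames(gt), NULL, population_map)
  GenotypeMatrix(geno, populations = pops,
                 contig = fix[biallelic, "CHROM"],
                 pos = as.integer(fix[biallelic, "POS"]),
                 qual = as.numeric(fix[biallelic, "QUAL"]),
                 dp = info_num("DP")[biallelic],
                 mq = info_num("MQ")[biallelic],
                 dp_sample = dp_sample)
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Emits a VCF v4.2 with GT (and per-sample DP when present); site QUAL and
#' INFO DP/MQ are taken from the locus metadata when available. REF/ALT are
#' written as A/C placeholders unless \code{ref}/\code{alt} columns exist in
#' \code{lociInfo(g)}.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVcfGenotypes <- function(g, path) {
  geno <- genoMatrix(g)
  rd <- lociInfo(g)
  qual <- if ("qual" %in% names(rd)) rd$qual else rep(".", nrow(rd))
  info <- rep(".", nrow(rd))
  if (all(c("dp", "mq") %in% names(rd)))
    info <- sprintf("DP=%s;MQ=%s", rd$dp, rd$mq)
  ref <- if ("ref" %in% names(rd)) rd$ref else rep("A", nrow(rd))
  alt <- if ("alt" %in% names(rd)) rd$alt else rep("C", nrow(rd))
  gt_code <- c("0/0", "0/1", "1/1")
  has_dp <- "dp_sample" %in% names(assays(g))
  fmt <- if (has_dp) "GT:DP" else "GT"
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
             "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             if (has_dp)
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(geno)), function(i) {
    cells <- ifelse(is.na(geno[i, ]), "./.", gt_code[geno[i, ] + 1L])
    if (has_dp)
      cells <- paste(cells, assay(g, "dp_sample")[i, ], sep = ":")
    paste(c(rd$contig[i], rd$pos[i], rownames(geno)[i], ref[i], alt[i],
            qual[i], "PASS", info[i], fmt, cells), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}
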