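#' Access the dosage matrix of a panel
#'
#' @param x a [GenotypePanel-class]
#' @return integer matrix, SNPs x samples, entries 0/1/2/NA.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypePanel", function(x) assay(x, "dosage"))

#' Breed code of every sample
#'
#' @param x a [GenotypePanel-class]
#' @return named character vector, one breed code per sample.
#' @export
setGeneric("breeds", function(x) standardGeneric("breeds"))

#' @rdname breeds
#' @export
setMethod("breeds", "GenotypePanel", function(x)
    stats::setNames(as.character(colData(x)$breed), colnames(x)))

#' SNP metadata table
#'
#' @param x a [GenotypePanel-class]
#' @return data.frame with columns id, chrom, pos, ref, alt, maf
#'   (maf is NA until [computeMaf()] has been run).
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "GenotypePanel", function(x) {
    rr <- rowRanges(x)
    data.frame(id = names(rr),
               chrom = as.character(seqnames(rr)),
               pos = start(rr),
               ref = mcols(rr)$ref,
               alt = mcols(rr)$alt,
               maf = mcols(rr)$maf,
               row.names = NULL)
})

#' Per-SNP minor allele frequency
#'
#' @param x a [GenotypePanel-class] on which [computeMaf()] has been run.
#' @return named numeric vector of MAFs in [0, 0.5] (NA where not computed).
#' @export
setGeneric("snpMaf", function(x) standardGeneric("snpMaf"))

#' @rdname snpMaf
#' @export
setMethod("snpMaf", "GenotypePanel", function(x)
    stats::setNames(rowData(x)$maf, rownames(x)))

#' Embedding coordinates
#'
#' @param x an [EmbeddingResult-class]
#' @return samples x k coordinate matrix.
#' @export
setGeneric("embeddingCoordinates",
           function(x) standardGeneric("embeddingCoordinates"))

#' @rdname embeddingCoordinates
#' @export
setMethod("embeddingCoordinates", "EmbeddingResult",
          function(x) x@coordinates)

#' Variance-explained fractions of an embedding
#'
#' @param x an [EmbeddingResult-class]
#' @return numeric vector of per-axis variance fractions.
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' @rdname varianceFraction
#' @export
setMethod("varianceFraction", "EmbeddingResult",
          function(x) x@varianceFraction)

#' Significant SNPs of a breed scan
#'
#' @param x a [BreedScanResult-class]
#' @return character vector of SNP ids with pvalue < alpha, in panel order.
#' @export
setGeneric("significantSnps", function(x) standardGeneric("significantSnps"))

#' @rdname significantSnps
#' @export
setMethod("significantSnps", "BreedScanResult", function(x) x@significant)

#' Per-SNP p-values of a breed scan
#'
#' @param x a [BreedScanResult-class]
#' @return named numeric vector of p-values.
#' @export
setGeneric("scanPvalues", function(x) standardGeneric("scanPvalues"))

#' @rdname scanPvalues
#' @export
setMethod("scanPvalues", "BreedScanResult",
          function(x) stats::setNames(x@pvalue, x@snpId))

#' Per-SNP PLS coefficients of a breed scan
#'
#' @param x a [BreedScanResult-class]
#' @return named numeric vector of PLS regression coefficients.
#' @export
setGeneric("scanStatistics", function(x) standardGeneric("scanStatistics"))

#' @rdname scanStatistics
#' @export
setMethod("scanStatistics", "BreedScanResult",
          function(x) stats::setNames(x@statistic, x@snpId))
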