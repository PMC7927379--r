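#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames rowRanges rowData rowData<- colData
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end ranges ranges<- findOverlaps
#' @importFrom IRanges IRanges
NULL

#' GenotypePanel: a multi-breed SNP dosage panel
#'
#' The central data container of the package: a
#' \linkS4class{RangedSummarizedExperiment} whose single \code{"dosage"}
#' assay holds diploid alternate-allele counts (0, 1, 2, or \code{NA} for
#' missing) with SNPs as rows and samples as columns.  Row ranges carry the
#' SNP coordinates (1-based, width 1) together with \code{ref}, \code{alt}
#' and (once computed) \code{maf} metadata columns; the column data carry a
#' \code{breed} code per sample.  SNPs are kept sorted by (chromosome,
#' position).
#'
#' @seealso [GenotypePanel()] for construction, [dosages()], [breeds()],
#'   [snpInfo()] for access, [computeMaf()], [filterMaf()],
#'   [imputeMissing()] for QC.
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
    msg <- character(0)
    if (!"dosage" %in% assayNames(object))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    dv <- d[!is.na(d)]
    if (length(dv) && !all(dv == 0L | dv == 1L | dv == 2L))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    rr <- rowRanges(object)
    if (length(rr)) {
        need <- c("ref", "alt")
        if (!all(need %in% names(mcols(rr))))
            msg <- c(msg, "rowRanges need 'ref' and 'alt' metadata columns")
        else if (any(as.character(mcols(rr)$ref) == as.character(mcols(rr)$alt)))
            msg <- c(msg, "ref and alt alleles must differ")
        if (any(start(rr) < 1L))
            msg <- c(msg, "positions must be 1-based (>= 1)")
        chrom <- as.character(seqnames(rr))
        runs <- rle(chrom)$values
        if (anyDuplicated(runs))
            msg <- c(msg, "SNPs must be grouped by chromosome")
        if (any(unlist(tapply(start(rr), factor(chrom, levels = unique(chrom)),
                              function(p) diff(p) < 0L))))
            msg <- c(msg, "positions must be sorted within chromosome")
        if (is.null(rownames(object)))
            msg <- c(msg, "SNP ids (rownames) are required")
    }
    if (!"breed" %in% names(colData(object)))
        msg <- c(msg, "colData needs a 'breed' column")
    else {
        b <- as.character(colData(object)$breed)
        if (any(is.na(b) | b == ""))
            msg <- c(msg, "breed codes must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param dosages integer/numeric matrix of alternate-allele dosages with
#'   SNPs as rows and samples as columns; entries 0, 1, 2 or \code{NA}.
#' @param snps data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt} and optionally \code{maf}, one row
#'   per SNP in the row order of \code{dosages}.
#' @param samples data.frame with columns \code{id} and \code{breed}, one
#'   row per column of \code{dosages}.
#'
#' @details SNPs are sorted by (chromosome, position) on construction;
#'   chromosome names that parse as numbers sort numerically, others
#'   alphabetically after them.
#'
#' @return A [GenotypePanel-class] object.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 0L), nrow = 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' snps <- data.frame(id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'                    ref = "A", alt = "G")
#' samples <- data.frame(id = c("s1", "s2"), breed = c("HD", "SMS"))
#' GenotypePanel(d, snps, samples)
#' @export
GenotypePanel <- function(dosages, snps, samples) {
    dosages <- as.matrix(dosages)
    if (nrow(snps) != nrow(dosages))
        stop("'snps' must have one row per dosage row")
    if (nrow(samples) != ncol(dosages))
        stop("'samples' must have one row per dosage column")
    o <- order(.chromRank(snps$chrom), snps$pos)
    snps <- snps[o, , drop = FALSE]
    dosages <- dosages[o, , drop = FALSE]
    gr <- GRanges(as.character(snps$chrom),
                  IRanges(as.integer(snps$pos), width = 1L))
    mcols(gr)$ref <- as.character(snps$ref)
    mcols(gr)$alt <- as.character(snps$alt)
    mcols(gr)$maf <- if ("maf" %in% names(snps)) as.numeric(snps$maf) else NA_real_
    names(gr) <- as.character(snps$id)
    dimnames(dosages) <- list(as.character(snps$id), as.character(samples$id))
    se <- SummarizedExperiment(
        assays = list(dosage = dosages),
        rowRanges = gr,
        colData = DataFrame(breed = as.character(samples$breed),
                            row.names = as.character(samples$id)))
    new("GenotypePanel", se)
}

#' @describeIn GenotypePanel-class compact display
#' @param object a \code{GenotypePanel}
#' @export
setMethod("show", "GenotypePanel", function(object) {
    b <- table(colData(object)$breed)
    nmiss <- sum(is.na(assay(object, "dosage")))
    cat("GenotypePanel:", nrow(object), "SNPs x", ncol(object), "samples\n")
    cat("  breeds (", length(b), "): ",
        paste0(names(b), "=", as.integer(b), collapse = " "), "\n", sep = "")
    cat("  missing dosages:", nmiss, "\n")
    maf <- rowData(object)$maf
    if (length(maf) && !all(is.na(maf)))
        cat("  MAF: computed, range ",
            paste(signif(range(maf), 3), collapse = "-"), "\n", sep = "")
})

#' SimulationConfig: parameters of the multi-breed genotype simulator
#'
#' Holds every knob of the Balding-Nichols generator: panel layout (breeds,
#' per-breed sample sizes, SNP count, chromosomes), the divergence
#' parameter \code{fst}, the planted breed-specific signal
#' (\code{nPlantedPerBreed} loci per breed, each shifted by
#' \code{plantedDelta} in the focal breed only), the missing-genotype rate
#' and the random seed.  The default configuration emulates a 24-breed,
#' 1069-animal panel (unequal breed sizes between 10 and 97) typed at
#' 62,822 biallelic SNPs on 18 autosomes.
#'
#' @slot nBreeds number of breeds.
#' @slot samplesPerBreed integer vector of per-breed sample counts.
#' @slot breedCodes character vector of breed codes.
#' @slot nSnps number of simulated SNPs.
#' @slot fst Balding-Nichols divergence parameter, in (0, 1).
#' @slot nPlantedPerBreed number of breed-specific loci planted per breed.
#' @slot plantedDelta allele-frequency shift applied at planted loci, in [0, 1].
#' @slot missingRate per-entry missing-genotype probability, in [0, 1).
#' @slot ancestralMafRange range the ancestral allele frequency is drawn from.
#' @slot nChromosomes number of chromosomes positions are spread over.
#' @slot chromLengthBp chromosome length in base pairs.
#' @slot seed integer random seed governing the whole generator chain.
#' @seealso [SimulationConfig()], [simulateBreedPanel()]
#' @export
setClass("SimulationConfig", representation(
    nBreeds = "integer",
    samplesPerBreed = "integer",
    breedCodes = "character",
    nSnps = "integer",
    fst = "numeric",
    nPlantedPerBreed = "integer",
    plantedDelta = "numeric",
    missingRate = "numeric",
    ancestralMafRange = "numeric",
    nChromosomes = "integer",
    chromLengthBp = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (object@nBreeds < 1L) msg <- c(msg, "nBreeds must be >= 1")
    if (length(object@samplesPerBreed) != object@nBreeds)
        msg <- c(msg, "samplesPerBreed must have one entry per breed")
    if (any(object@samplesPerBreed < 1L))
        msg <- c(msg, "all samplesPerBreed must be >= 1")
    if (length(object@breedCodes) != object@nBreeds ||
        anyDuplicated(object@breedCodes))
        msg <- c(msg, "breedCodes must be unique, one per breed")
    if (!(object@fst > 0 && object@fst < 1))
        msg <- c(msg, "fst must lie strictly in (0, 1)")
    if (object@nPlantedPerBreed < 0L)
        msg <- c(msg, "nPlantedPerBreed must be >= 0")
    if (object@nPlantedPerBreed * object@nBreeds > object@nSnps)
        msg <- c(msg, "cannot plant more loci than SNPs (nPlantedPerBreed * nBreeds > nSnps)")
    if (object@plantedDelta < 0 || object@plantedDelta > 1)
        msg <- c(msg, "plantedDelta must lie in [0, 1]")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must lie in [0, 1)")
    r <- object@ancestralMafRange
    if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
        msg <- c(msg, "ancestralMafRange must be increasing within (0, 1)")
    if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be >= 1")
    if (object@chromLengthBp < object@nSnps / object@nChromosomes)
        msg <- c(msg, "chromLengthBp too small to place SNPs at distinct positions")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class compact display
#' @param object a \code{SimulationConfig}
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nBreeds, "breeds,",
        sum(object@samplesPerBreed), "samples,", object@nSnps, "SNPs\n")
    cat("  fst =", object@fst, " planted =", object@nPlantedPerBreed,
        "per breed (delta =", object@plantedDelta, ")\n")
    cat("  missing rate =", object@missingRate,
        " seed =", object@seed, "\n")
})

#' BreedScanResult: one breed's one-vs-rest PLS scan
#'
#' Per-SNP PLS regression coefficients for the contrast of one breed
#' against all others, their genome-wide standardized values \code{z},
#' two-sided p-values, and the significant subset at the strict threshold
#' \code{alpha} (SNPs with \code{pvalue < alpha}).
#'
#' @slot breed focal breed code.
#' @slot snpId SNP identifiers, in panel order.
#' @slot statistic per-SNP PLS regression coefficient.
#' @slot z genome-wide standardized coefficient.
#' @slot pvalue per-SNP p-value in (0, 1].
#' @slot alpha call threshold (strict inequality).
#' @slot method p-value method used ("zscore" or "permutation").
#' @slot nComponents number of PLS components fitted.
#' @slot significant SNP ids called significant, in panel order.
#' @seealso [scanAllBreeds()], [manhattanTable()]
#' @export
setClass("BreedScanResult", representation(
    breed = "character",
    snpId = "character",
    statistic = "numeric",
    z = "numeric",
    pvalue = "numeric",
    alpha = "numeric",
    method = "character",
    nComponents = "integer",
    significant = "character"))

setValidity("BreedScanResult", function(object) {
    msg <- character(0)
    n <- length(object@snpId)
    if (length(object@statistic) != n || length(object@z) != n ||
        length(object@pvalue) != n)
        msg <- c(msg, "statistic, z and pvalue must have one entry per SNP")
    if (any(object@pvalue <= 0 | object@pvalue > 1))
        msg <- c(msg, "p-values must lie in (0, 1]")
    if (!identical(object@significant,
                   object@snpId[object@pvalue < object@alpha]))
        msg <- c(msg, "'significant' must equal SNPs with pvalue < alpha")
    if (length(msg)) msg else TRUE
})

#' @describeIn BreedScanResult-class compact display
#' @param object a \code{BreedScanResult}
#' @export
setMethod("show", "BreedScanResult", function(object) {
    cat("BreedScanResult for breed", object@breed, "\n")
    cat("  ", length(object@snpId), " SNPs scanned (", object@method,
        ", ", object@nComponents, " component(s))\n", sep = "")
    cat("  ", length(object@significant), " significant at p < ",
        object@alpha, "\n", sep = "")
})

#' EmbeddingResult: a low-dimensional population-structure embedding
#'
#' Coordinates of samples on the leading axes of a PCA of the genetic
#' relationship matrix or a classical principal coordinates analysis,
#' together with the fraction of variance explained per retained axis and
#' the full eigenvalue spectrum (PCoA keeps negative eigenvalues in the
#' spectrum but never in the coordinates).
#'
#' @slot coordinates samples x k coordinate matrix.
#' @slot varianceFraction per-axis variance-explained fraction, non-increasing.
#' @slot eigenvalues full eigenvalue spectrum.
#' @slot method "PCA" or "PCoA".
#' @slot breeds breed code per sample (may be empty).
#' @seealso [runPCA()], [runPCoA()]
#' @export
setClass("EmbeddingResult", representation(
    coordinates = "matrix",
    varianceFraction = "numeric",
    eigenvalues = "numeric",
    method = "character",
    breeds = "character"))

setValidity("EmbeddingResult", function(object) {
    msg <- character(0)
    vf <- object@varianceFraction
    if (length(vf)) {
        if (any(vf < -1e-9 | vf > 1 + 1e-9))
            msg <- c(msg, "variance fractions must lie in [0, 1]")
        if (any(diff(vf) > 1e-9))
            msg <- c(msg, "variance fractions must be non-increasing")
        if (sum(vf) > 1 + 1e-9)
            msg <- c(msg, "variance fractions must sum to at most 1")
    }
    if (!object@method %in% c("PCA", "PCoA"))
        msg <- c(msg, "method must be 'PCA' or 'PCoA'")
    if (length(msg)) msg else TRUE
})

#' @describeIn EmbeddingResult-class compact display
#' @param object an \code{EmbeddingResult}
#' @export
setMethod("show", "EmbeddingResult", function(object) {
    cat(object@method, "embedding:", nrow(object@coordinates), "samples,",
        ncol(object@coordinates), "axes\n")
    vf <- object@varianceFraction
    cat("  variance explained (%):",
        paste(sprintf("%.2f", 100 * utils::head(vf, 5)), collapse = " "),
        if (length(vf) > 5) "...\n" else "\n")
    if (object@method == "PCoA" && any(object@eigenvalues < 0))
        cat("  negative eigenvalues:", sum(object@eigenvalues < 0),
            "(excluded from coordinates)\n")
})
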