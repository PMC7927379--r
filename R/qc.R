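#' Impute missing genotypes within breeds
#'
#' Replaces every missing dosage.  Mode \code{"major"} (default) uses the
#' most frequent dosage at the SNP within the sample's breed, ties going to
#' the smaller dosage; mode \code{"draw"} samples a dosage from
#' Binomial(2, f) with f the breed's observed alternate-allele frequency,
#' reproducibly under \code{seed}.  A SNP entirely missing within a breed
#' falls back to the panel-wide major dosage (or frequency), with a logged
#' count.  Non-missing entries are never altered.
#'
#' @param panel a [GenotypePanel-class].
#' @param mode "major" or "draw".
#' @param seed integer seed (used by "draw" only).
#' @return the panel with a complete dosage matrix.
#' @export
imputeMissing <- function(panel, mode = c("major", "draw"), seed = 1L) {
    mode <- match.arg(mode)
    d <- dosages(panel)
    if (!anyNA(d)) return(panel)
    allMissing <- rowSums(!is.na(d)) == 0L
    if (any(allMissing))
        stop(sum(allMissing), " SNP(s) have no observed genotype in the panel")
    # panel-wide fallbacks
    n0 <- rowSums(d == 0L, na.rm = TRUE)
    n1 <- rowSums(d == 1L, na.rm = TRUE)
    n2 <- rowSums(d == 2L, na.rm = TRUE)
    globalMajor <- max.col(cbind(n0, n1, n2), ties.method = "first") - 1L
    globalFreq <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
    if (mode == "draw") set.seed(seed)
    br <- breeds(panel)
    nFallback <- 0L
    for (b in unique(br)) {
        idx <- which(br == b)
        sub <- d[, idx, drop = FALSE]
        miss <- is.na(sub)
        if (!any(miss)) next
        noneSeen <- rowSums(!miss) == 0L
        nFallback <- nFallback + sum(noneSeen & rowSums(miss) > 0L)
        if (mode == "major") {
            c0 <- rowSums(sub == 0L, na.rm = TRUE)
            c1 <- rowSums(sub == 1L, na.rm = TRUE)
            c2 <- rowSums(sub == 2L, na.rm = TRUE)
            fill <- max.col(cbind(c0, c1, c2), ties.method = "first") - 1L
            fill[noneSeen] <- globalMajor[noneSeen]
            sub[miss] <- fill[row(sub)[miss]]
        } else {
            f <- rowSums(sub, na.rm = TRUE) / (2 * rowSums(!miss))
            f[noneSeen] <- globalFreq[noneSeen]
            sub[miss] <- stats::rbinom(sum(miss), 2L, f[row(sub)[miss]])
        }
        d[, idx] <- sub
    }
    if (nFallback > 0L)
        .log(nFallback, " breed-by-SNP cell(s) entirely missing; ",
             "panel-wide fallback used")
    assay(panel, "dosage") <- d
    panel
}

#' Compute per-SNP minor allele frequencies
#'
#' The alternate-allele frequency at SNP j is the dosage sum divided by
#' twice the number of non-missing samples; the MAF is \code{min(f, 1-f)}.
#' Missing entries are excluded from the counts, so the function may be run
#' before or after imputation.
#'
#' @param panel a [GenotypePanel-class].
#' @return the panel with the \code{maf} row metadata column filled
#'   (accessible via [snpMaf()]).
#' @export
computeMaf <- function(panel) {
    d <- dosages(panel)
    nm <- rowSums(!is.na(d))
    if (any(nm == 0L))
        stop(sum(nm == 0L), " SNP(s) have zero non-missing calls")
    f <- rowSums(d, na.rm = TRUE) / (2 * nm)
    rowData(panel)$maf <- pmin(f, 1 - f)
    panel
}

#' Filter SNPs by minor allele frequency
#'
#' Retains exactly the SNPs with MAF greater than or equal to the
#' threshold (inclusive), preserving order; the number removed is logged.
#' MAF is computed on the fly when absent.
#'
#' @param panel a [GenotypePanel-class].
#' @param threshold MAF threshold in [0, 0.5]; default 0.05.
#' @return the filtered panel.
#' @examples
#' sim <- simulateBreedPanel(SimulationConfig(nBreeds = 3,
#'     samplesPerBreed = rep(15L, 3), nSnps = 300, fst = 0.1, seed = 3))
#' filterMaf(imputeMissing(sim$panel), 0.05)
#' @export
filterMaf <- function(panel, threshold = 0.05) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold < 0 || threshold > 0.5)
        stop("'threshold' must be a single frequency in [0, 0.5]")
    maf <- snpMaf(panel)
    if (all(is.na(maf))) {
        panel <- computeMaf(panel)
        maf <- snpMaf(panel)
    }
    keep <- maf >= threshold
    .log(sum(!keep), " SNP(s) removed at MAF < ", threshold,
         "; ", sum(keep), " retained")
    panel[keep, ]
}

#' Windowed SNP density
#'
#' Counts SNPs in non-overlapping windows of \code{windowBp} per
#' chromosome.  Window k covers the 1-based half-open interval
#' [k*w + 1, (k+1)*w]; empty windows inside the occupied range are
#' reported with count 0, so counts always sum to the panel SNP count.
#'
#' @param panel a [GenotypePanel-class].
#' @param windowBp window size in bp (default 400 kb).
#' @return data.frame with columns chrom, window_start, window_end, count.
#' @export
snpDensity <- function(panel, windowBp = 400000L) {
    info <- snpInfo(panel)
    out <- lapply(unique(info$chrom), function(cc) {
        pos <- info$pos[info$chrom == cc]
        k <- (pos - 1) %/% windowBp
        kk <- seq(0, max(k))
        cnt <- tabulate(k + 1L, nbins = max(k) + 1L)
        data.frame(chrom = cc,
                   window_start = kk * windowBp + 1,
                   window_end = (kk + 1) * windowBp,
                   count = cnt)
    })
    do.call(rbind, out)
}
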