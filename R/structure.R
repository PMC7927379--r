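# GRM-style standardization: (x - 2p) / sqrt(2p(1-p)) per SNP, with p the
# alternate-allele frequency; returns samples x SNPs
.grmStandardize <- function(panel) {
    d <- dosages(panel)
    if (anyNA(d))
        stop("panel contains missing dosages; run imputeMissing() first")
    p <- rowMeans(d) / 2
    if (any(p == 0 | p == 1))
        stop("monomorphic SNP(s) present (p = 0 or 1); run filterMaf() first")
    t((d - 2 * p) / sqrt(2 * p * (1 - p)))
}

# deterministic sign convention: the entry of largest magnitude in each
# column is made positive
.fixSigns <- function(v) {
    s <- apply(v, 2, function(x) sign(x[which.max(abs(x))]))
    s[s == 0] <- 1
    sweep(v, 2, s, "*")
}

#' Principal component analysis of the genetic relationship matrix
#'
#' Dosages are standardized per SNP as \eqn{(x - 2p)/\sqrt{2p(1-p)}} with
#' \eqn{p} the alternate-allele frequency, the genetic relationship matrix
#' \eqn{G = ZZ^T/m} is eigendecomposed, coordinates are the top-k
#' eigenvectors scaled by the square root of their eigenvalues, and
#' variance fractions are eigenvalues over the sum of all positive
#' eigenvalues.
#'
#' @param panel an imputed, MAF-filtered [GenotypePanel-class].
#' @param k number of components, less than the sample count.
#' @return An [EmbeddingResult-class] with method "PCA".
#' @examples
#' sim <- simulateBreedPanel(SimulationConfig(nBreeds = 3,
#'     samplesPerBreed = rep(15L, 3), nSnps = 500, fst = 0.2,
#'     missingRate = 0, seed = 11))
#' emb <- runPCA(filterMaf(sim$panel), k = 4)
#' round(100 * varianceFraction(emb), 2)
#' @export
runPCA <- function(panel, k = 10L) {
    Z <- .grmStandardize(panel)
    n <- nrow(Z)
    if (k >= n) stop("'k' must be smaller than the number of samples")
    G <- tcrossprod(Z) / ncol(Z)
    e <- eigen(G, symmetric = TRUE)
    lam <- e$values
    v <- .fixSigns(e$vectors[, seq_len(k), drop = FALSE])
    coords <- sweep(v, 2, sqrt(pmax(lam[seq_len(k)], 0)), "*")
    dimnames(coords) <- list(rownames(Z), paste0("PC", seq_len(k)))
    new("EmbeddingResult",
        coordinates = coords,
        varianceFraction = lam[seq_len(k)] / sum(lam[lam > 0]),
        eigenvalues = lam,
        method = "PCA",
        breeds = unname(breeds(panel)))
}

#' Pairwise distances between samples
#'
#' Metric \code{"euclidean"} (default) operates on the GRM-standardized
#' dosages; \code{"allele-sharing"} is 1 minus the proportion of alleles
#' identical by state, i.e. mean(|d_i - d_j|)/2 over SNPs.
#'
#' @param panel an imputed [GenotypePanel-class].
#' @param metric "euclidean" or "allele-sharing".
#' @return symmetric sample-by-sample distance matrix.
#' @export
pairwiseDistance <- function(panel, metric = c("euclidean", "allele-sharing")) {
    metric <- match.arg(metric)
    if (metric == "euclidean")
        return(as.matrix(stats::dist(.grmStandardize(panel))))
    d <- dosages(panel)
    if (anyNA(d))
        stop("panel contains missing dosages; run imputeMissing() first")
    as.matrix(stats::dist(t(d), method = "manhattan")) / (2 * nrow(d))
}

#' Classical principal coordinates analysis (metric MDS)
#'
#' Gower double-centering of the squared distance matrix,
#' \eqn{B = -\frac{1}{2} J (D \circ D) J} with \eqn{J = I - 11^T/n},
#' followed by eigendecomposition.  Coordinates come from the
#' positive-eigenvalue axes scaled by the square root of the eigenvalue;
#' negative eigenvalues are kept in the reported spectrum (and logged) but
#' excluded from the coordinates.
#'
#' @param distanceMatrix symmetric, zero-diagonal, non-negative matrix (or
#'   a \code{dist} object).
#' @param k number of axes to return.
#' @param breeds optional breed code per sample, for plotting.
#' @return An [EmbeddingResult-class] with method "PCoA".
#' @export
runPCoA <- function(distanceMatrix, k = 10L, breeds = character(0)) {
    D <- as.matrix(distanceMatrix)
    n <- nrow(D)
    if (n != ncol(D) || max(abs(D - t(D))) > 1e-8)
        stop("distance matrix must be symmetric")
    if (any(D < 0)) stop("distances must be non-negative")
    if (max(abs(diag(D))) > 1e-8) stop("distance matrix must have zero diagonal")
    if (k >= n) stop("'k' must be smaller than the number of samples")
    D2 <- D * D
    rm <- rowMeans(D2)
    B <- -0.5 * (D2 - outer(rm, rm, "+") + mean(D2))
    e <- eigen(B, symmetric = TRUE)
    lam <- e$values
    tol <- 1e-9 * max(abs(lam), 1)
    nPos <- sum(lam > tol)
    nNeg <- sum(lam < -tol)
    if (nNeg > 0)
        .log(nNeg, " negative PCoA eigenvalue(s) excluded from coordinates")
    kUse <- min(k, nPos)
    coords <- matrix(0, n, k,
                     dimnames = list(rownames(D), paste0("Axis", seq_len(k))))
    if (kUse > 0) {
        v <- .fixSigns(e$vectors[, seq_len(kUse), drop = FALSE])
        coords[, seq_len(kUse)] <- sweep(v, 2, sqrt(lam[seq_len(kUse)]), "*")
    }
    vf <- numeric(k)
    if (nPos > 0)
        vf[seq_len(kUse)] <- lam[seq_len(kUse)] / sum(lam[lam > tol])
    new("EmbeddingResult",
        coordinates = coords,
        varianceFraction = vf,
        eigenvalues = lam,
        method = "PCoA",
        breeds = as.character(breeds))
}
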