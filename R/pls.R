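#' Encode the one-vs-rest response for a breed
#'
#' Samples of the focal breed get 1, all other samples 0.
#'
#' @param panel a [GenotypePanel-class].
#' @param breedCode focal breed code, present in the panel.
#' @return named integer vector of 0/1 per sample.
#' @export
encodeResponse <- function(panel, breedCode) {
    br <- breeds(panel)
    if (!breedCode %in% br)
        stop("unknown breed code: ", breedCode)
    y <- as.integer(br == breedCode)
    if (all(y == 1L))
        stop("breed '", breedCode, "' covers every sample; the response is constant")
    stats::setNames(y, names(br))
}

#' Fit a PLS1 regression by NIPALS
#'
#' Single-response partial least squares with NIPALS deflation.  The first
#' component's weight vector is \eqn{w_1 \propto X^T y_c} normalized to
#' unit length (with \eqn{y_c} the centered response); scores are
#' \eqn{t = X w}; X is deflated by \eqn{t p^T} (and y by \eqn{t q}) before
#' each further component.  Regression coefficients are mapped back to the
#' original predictor space as \eqn{\beta = W (P^T W)^{-1} q}; for a
#' one-component fit \eqn{\beta \propto w_1}.
#'
#' @param X numeric predictor matrix, samples x SNPs, column-standardized
#'   (mean 0, unit variance).
#' @param y numeric response; centered internally.
#' @param nComponents number of latent components (>= 1, at most the rank
#'   of X).
#' @return list with \code{weights} (m x A matrix W), \code{loadings}
#'   (m x A matrix P), \code{yLoadings} (length-A q), \code{scores}
#'   (n x A matrix T), \code{coefficients} (length-m beta) and
#'   \code{nComponents}.
#' @examples
#' X <- scale(matrix(c(0, 1, 2, 1, 1, 1, 0, 2), nrow = 4))
#' y <- c(1, 1, 0, 0)
#' fit <- plsFit(X, y, nComponents = 1)
#' fit$coefficients
#' @export
plsFit <- function(X, y, nComponents = 1L) {
    X <- as.matrix(X)
    n <- nrow(X)
    m <- ncol(X)
    if (length(y) != n) stop("'y' must have one entry per row of X")
    yc <- y - mean(y)
    if (all(abs(yc) < 1e-12)) stop("constant response")
    A <- as.integer(nComponents)
    if (A < 1L) stop("'nComponents' must be >= 1")
    if (A > min(n - 1L, m))
        stop("'nComponents' exceeds the rank bound min(n - 1, m)")
    W <- matrix(0, m, A)
    P <- matrix(0, m, A)
    Tm <- matrix(0, n, A)
    q <- numeric(A)
    Xd <- X
    yd <- yc
    for (a in seq_len(A)) {
        w <- drop(crossprod(Xd, yd))
        nw <- sqrt(sum(w * w))
        if (nw < 1e-12)
            stop("residual X'y vanished at component ", a,
                 "; reduce nComponents")
        w <- w / nw
        t1 <- drop(Xd %*% w)
        tt <- sum(t1 * t1)
        if (tt < 1e-12)
            stop("degenerate score at component ", a)
        p1 <- drop(crossprod(Xd, t1)) / tt
        q1 <- sum(yd * t1) / tt
        Xd <- Xd - tcrossprod(t1, p1)
        yd <- yd - q1 * t1
        W[, a] <- w
        P[, a] <- p1
        Tm[, a] <- t1
        q[a] <- q1
    }
    beta <- drop(W %*% solve(crossprod(P, W), q))
    names(beta) <- colnames(X)
    list(weights = W, loadings = P, yLoadings = q, scores = Tm,
         coefficients = beta, nComponents = A)
}

# one-component PLS coefficients for B permuted responses at once:
# beta_b = X'y_b / ||t_b||^2 with t_b = X w_b, w_b = X'y_b normalized
.permCoefficients1 <- function(X, yc, B) {
    Yp <- vapply(seq_len(B), function(i) sample(yc), numeric(length(yc)))
    Cp <- crossprod(X, Yp)
    nw <- sqrt(colSums(Cp * Cp))
    Tp <- X %*% sweep(Cp, 2, nw, "/")
    sweep(Cp, 2, colSums(Tp * Tp), "/")
}

#' Per-SNP p-values for PLS scan coefficients
#'
#' Method \code{"zscore"} (default) standardizes the coefficients genome
#' wide, \eqn{z_j = (c_j - \bar c)/sd(c)}, and converts to two-sided
#' standard-normal tail probabilities.  Method \code{"permutation"}
#' permutes the response B times, refits, and reports add-one empirical
#' p-values \eqn{p_j = (1 + \#\{|c^{(b)}_j| \ge |c_j|\})/(B + 1)}; with
#' \code{standardize = TRUE} (default) coefficients are z-standardized
#' within each permutation before comparison, which makes the reference
#' distribution scale-free (the raw-coefficient comparison is globally
#' mis-scaled when the panel carries strong population structure, because
#' the observed score variance differs systematically from the permuted
#' one).
#'
#' @param fit a [plsFit()] result, or a bare coefficient vector (zscore
#'   method only).
#' @param X,y the design and response used for the fit (permutation only).
#' @param method "zscore" or "permutation".
#' @param nPermutations number of permutations B (>= 1).
#' @param seed integer seed for the permutations.
#' @param standardize compare standardized coefficients between
#'   permutations (permutation method only).
#' @return list with \code{z} (standardized coefficients) and
#'   \code{pvalue} (in (0, 1]).
#' @export
snpPvalues <- function(fit, X = NULL, y = NULL,
                       method = c("zscore", "permutation"),
                       nPermutations = 500L, seed = 1L,
                       standardize = TRUE) {
    method <- match.arg(method)
    cc <- if (is.list(fit)) fit$coefficients else fit
    s <- stats::sd(cc)
    if (!is.finite(s) || s == 0)
        stop("coefficient standard deviation is zero")
    z <- (cc - mean(cc)) / s
    if (method == "zscore") {
        p <- 2 * stats::pnorm(-abs(z))
        return(list(z = z, pvalue = pmin(pmax(p, .Machine$double.xmin), 1)))
    }
    B <- as.integer(nPermutations)
    if (B < 1L) stop("'nPermutations' must be >= 1")
    if (is.null(X) || is.null(y))
        stop("permutation p-values need 'X' and 'y'")
    A <- if (is.list(fit)) fit$nComponents else 1L
    set.seed(seed)
    if (A == 1L) {
        Bp <- .permCoefficients1(X, y - mean(y), B)
    } else {
        Bp <- vapply(seq_len(B), function(i)
            plsFit(X, sample(y), A)$coefficients, numeric(length(cc)))
    }
    if (standardize) {
        Zp <- scale(Bp)
        exceed <- rowSums(abs(Zp) >= abs(z))
    } else {
        exceed <- rowSums(abs(Bp) >= abs(cc))
    }
    list(z = z, pvalue = (1 + exceed) / (B + 1))
}

#' Scan every breed against the rest
#'
#' For each breed in turn, the 0/1 breed-membership response is regressed
#' on all SNP dosages (column z-scored) by [plsFit()], per-SNP p-values are
#' derived by [snpPvalues()], and SNPs with \code{p < alpha} are called
#' significant.  The scan is deterministic given the seed.
#'
#' @param panel an imputed, MAF-filtered [GenotypePanel-class] with at
#'   least two breeds, each with at least two samples.
#' @param nComponents PLS components (default 1: a one-vs-rest contrast
#'   targets a single discriminant direction).
#' @param alpha significance threshold, strict inequality (default 0.01).
#' @param method p-value method, "zscore" (default) or "permutation".
#' @param nPermutations permutations per breed (permutation method).
#' @param seed integer seed; breed b uses seed + b's index.
#' @param standardize see [snpPvalues()].
#' @return A \linkS4class{SimpleList} of [BreedScanResult-class], one per
#'   breed, with a metadata summary (per-breed significant counts plus the
#'   union and the sum over breeds, which differ when SNPs are significant
#'   in several breeds).
#' @examples
#' sim <- simulateBreedPanel(SimulationConfig(nBreeds = 3,
#'     samplesPerBreed = rep(15L, 3), nSnps = 400, fst = 0.1,
#'     missingRate = 0, nPlantedPerBreed = 2L, plantedDelta = 0.5,
#'     seed = 5))
#' scans <- scanAllBreeds(filterMaf(sim$panel))
#' scanSummary(scans)$perBreed
#' @export
scanAllBreeds <- function(panel, nComponents = 1L, alpha = 0.01,
                          method = c("zscore", "permutation"),
                          nPermutations = 500L, seed = 1L,
                          standardize = TRUE) {
    method <- match.arg(method)
    d <- dosages(panel)
    if (anyNA(d))
        stop("panel contains missing dosages; run imputeMissing() first")
    br <- breeds(panel)
    tab <- table(br)
    if (length(tab) < 2L) stop("scanning needs at least two breeds")
    if (any(tab < 2L))
        stop("every breed needs at least two samples: ",
             paste(names(tab)[tab < 2L], collapse = ", "))
    X <- scale(t(d))
    if (anyNA(X))
        stop("monomorphic SNP(s) present; run filterMaf() first")
    ids <- rownames(panel)
    codes <- unique(unname(br))
    results <- lapply(seq_along(codes), function(i) {
        b <- codes[i]
        y <- encodeResponse(panel, b)
        fit <- plsFit(X, y, nComponents)
        pv <- snpPvalues(fit, X = X, y = y, method = method,
                        nPermutations = nPermutations, seed = seed + i,
                        standardize = standardize)
        new("BreedScanResult",
            breed = b,
            snpId = ids,
            statistic = unname(fit$coefficients),
            z = unname(pv$z),
            pvalue = unname(pv$pvalue),
            alpha = alpha,
            method = method,
            nComponents = as.integer(nComponents),
            significant = ids[pv$pvalue < alpha])
    })
    out <- SimpleList(results)
    names(out) <- codes
    metadata(out) <- list(alpha = alpha, method = method,
                          nComponents = as.integer(nComponents),
                          seed = as.integer(seed),
                          standardize = standardize)
    out
}

#' Summarize a multi-breed scan
#'
#' @param scans result of [scanAllBreeds()].
#' @return list with \code{perBreed} (data.frame breed, n_snps,
#'   n_significant), \code{unionSignificant} (count of distinct SNPs
#'   significant in at least one breed) and \code{sumSignificant} (sum of
#'   per-breed counts; equals the union only when no SNP is shared).
#' @export
scanSummary <- function(scans) {
    perBreed <- data.frame(
        breed = vapply(scans, function(r) r@breed, character(1)),
        n_snps = vapply(scans, function(r) length(r@snpId), integer(1)),
        n_significant = vapply(scans, function(r) length(r@significant),
                               integer(1)),
        row.names = NULL)
    list(perBreed = perBreed,
         unionSignificant = length(unique(unlist(
             lapply(scans, significantSnps), use.names = FALSE))),
         sumSignificant = sum(perBreed$n_significant))
}

#' Per-SNP Manhattan table for one breed
#'
#' @param result a [BreedScanResult-class].
#' @param panel the scanned [GenotypePanel-class] (supplies coordinates).
#' @return data.frame with snp_id, chrom, pos, statistic, z, pvalue and
#'   neg_log10_p, one row per scanned SNP.
#' @export
manhattanTable <- function(result, panel) {
    info <- snpInfo(panel)
    idx <- match(result@snpId, info$id)
    if (anyNA(idx))
        stop("scan result contains SNPs absent from the panel")
    data.frame(snp_id = result@snpId,
               chrom = info$chrom[idx],
               pos = info$pos[idx],
               statistic = result@statistic,
               z = result@z,
               pvalue = result@pvalue,
               neg_log10_p = -log10(result@pvalue))
}
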