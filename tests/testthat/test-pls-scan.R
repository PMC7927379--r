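test_that("the one-vs-rest response partitions the panel", {
    sim <- simPanel(3, nBreeds = 4, n = 10L, nSnps = 100)
    panel <- sim$panel
    y <- encodeResponse(panel, "B02")
    expect_equal(sum(y), 10L)
    total <- Reduce(`+`, lapply(unique(breeds(panel)), function(b)
        encodeResponse(panel, b)))
    expect_true(all(total == 1L))
    expect_error(encodeResponse(panel, "NOPE"), "unknown breed")
    one <- toyPanel(matrix(0:1, 2, 4), breed = rep("A", 4))
    expect_error(encodeResponse(one, "A"), "constant")
})

test_that("the first PLS component weight is the normalized cross-covariance", {
    # hand-checked toy: dosages per sample (0,1),(1,1),(2,0),(1,2)
    X <- scale(matrix(c(0, 1, 2, 1,
                        1, 1, 0, 2), nrow = 4))
    y <- c(1, 1, 0, 0)
    fit <- plsFit(X, y, nComponents = 1)
    w <- drop(crossprod(X, y - mean(y)))
    w <- w / sqrt(sum(w^2))
    expect_equal(unname(fit$weights[, 1]), unname(w), tolerance = 1e-12)
    expect_equal(unname(fit$coefficients / sqrt(sum(fit$coefficients^2))),
                 unname(w * sign(sum(fit$coefficients * w))),
                 tolerance = 1e-12)

    # property over random panels
    set.seed(100)
    for (i in 1:20) {
        n <- sample(10:40, 1); m <- sample(20:80, 1)
        Xi <- scale(matrix(rnorm(n * m), n, m))
        yi <- rbinom(n, 1, 0.3); if (sum(yi) %in% c(0, n)) yi[1:2] <- c(0, 1)
        wi <- drop(crossprod(Xi, yi - mean(yi)))
        wi <- wi / sqrt(sum(wi^2))
        expect_lt(max(abs(plsFit(Xi, yi, 1)$weights[, 1] - wi)), 1e-10)
    }

    # a predictor orthogonal to the response gets zero first-component weight
    yo <- c(1, 1, 0, 0)
    Xo <- cbind(scale(c(1, -1, 1, -1)), scale(c(0, 1, 2, 1)))
    expect_lt(abs(plsFit(Xo, yo, 1)$weights[1, 1]), 1e-12)

    expect_error(plsFit(X, rep(1, 4), 1), "constant")
    expect_error(plsFit(X, y, 5), "rank")
})

test_that("multi-component fits match the mixOmics NIPALS reference", {
    set.seed(7)
    for (i in 1:3) {
        X <- scale(matrix(rnorm(30 * 100), 30, 100))
        colnames(X) <- paste0("v", seq_len(ncol(X)))
        y <- rbinom(30, 1, 0.4); if (sum(y) %in% c(0, 30)) y[1:2] <- c(0, 1)
        fit <- plsFit(X, y, nComponents = 3)
        ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE,
                             mode = "regression")
        refB <- predict(ref, X[1:2, , drop = FALSE])$B.hat[, 1, 3]
        expect_equal(unname(fit$coefficients), unname(refB),
                     tolerance = 1e-8)
        for (a in 1:3) {
            wa <- fit$weights[, a]; ra <- ref$loadings$X[, a]
            expect_lt(min(max(abs(wa - ra)), max(abs(wa + ra))), 1e-8)
        }
    }
    # the fitted values equal least squares of y on the latent scores
    X <- scale(matrix(rnorm(25 * 40), 25, 40))
    y <- rbinom(25, 1, 0.5); if (sum(y) %in% c(0, 25)) y[1:2] <- c(0, 1)
    fit <- plsFit(X, y, 2)
    yc <- y - mean(y)
    proj <- fit$scores %*% solve(crossprod(fit$scores),
                                 crossprod(fit$scores, yc))
    expect_equal(drop(X %*% fit$coefficients), drop(proj), tolerance = 1e-8)
})

test_that("z-score p-values follow the standard-normal tail", {
    # coefficients built to have mean 0 and unit sd: z is the value itself
    cc <- drop(scale(c(-3, -1, 0, 1, 3, 2.5758293, rnorm(200, 0, 1))))
    pv <- snpPvalues(cc, method = "zscore")
    expect_equal(pv$pvalue, 2 * pnorm(-abs(pv$z)), tolerance = 1e-12)
    iz <- which.min(abs(pv$z - 2.5758293))
    expect_equal(pv$pvalue[iz], 2 * pnorm(-abs(pv$z[iz])), tolerance = 1e-12)
    # a coefficient at the genome-wide mean gets p = 1
    sym <- c(-2, -1, 0, 1, 2)
    expect_equal(snpPvalues(sym, method = "zscore")$pvalue[3], 1)
    expect_error(snpPvalues(rep(1, 5), method = "zscore"), "zero")
})

test_that("permutation p-values respect the add-one lower bound", {
    sim <- simPanel(77, nBreeds = 3, n = 12L, nSnps = 150, fst = 0.05,
                    nPlanted = 2L, delta = 0.6)
    panel <- sim$panel
    X <- scale(t(dosages(panel)))
    y <- encodeResponse(panel, sim$truth$breed_code[1])
    fit <- plsFit(X, y, 1)
    pv <- snpPvalues(fit, X = X, y = y, method = "permutation",
                     nPermutations = 99, seed = 5)
    expect_true(all(pv$pvalue >= 1 / 100))
    expect_true(all(pv$pvalue <= 1))
    # strongly planted loci reach the attainable minimum
    expect_equal(min(pv$pvalue), 1 / 100)
    # reproducible under the seed
    pv2 <- snpPvalues(fit, X = X, y = y, method = "permutation",
                      nPermutations = 99, seed = 5)
    expect_identical(pv$pvalue, pv2$pvalue)
    expect_error(snpPvalues(fit, X = X, y = y, method = "permutation",
                            nPermutations = 0), "nPermutations")
})

test_that("a two-breed scan is symmetric between the breeds", {
    sim <- simPanel(12, nBreeds = 2, n = 15L, nSnps = 200, fst = 0.1)
    scans <- scanAllBreeds(sim$panel)
    a <- scans[[1]]; b <- scans[[2]]
    expect_equal(a@statistic, -b@statistic, tolerance = 1e-10)
    expect_equal(a@pvalue, b@pvalue, tolerance = 1e-10)
    expect_identical(significantSnps(a), significantSnps(b))
})

test_that("scan results are invariant to sample order", {
    sim <- simPanel(13, nBreeds = 3, n = 10L, nSnps = 150, fst = 0.1)
    panel <- sim$panel
    set.seed(1)
    perm <- sample(ncol(panel))
    s1 <- scanAllBreeds(panel)
    s2 <- scanAllBreeds(panel[, perm])
    for (b in names(s1))
        expect_equal(s1[[b]]@pvalue, s2[[b]]@pvalue, tolerance = 1e-10)
})

test_that("planted loci are recovered in the strong-signal regime", {
    hits <- integer(0); total <- integer(0)
    for (seed in 1:3) {
        sim <- simPanel(seed + 200, nBreeds = 6, n = 20L, nSnps = 2000,
                        fst = 0.05, nPlanted = 5L, delta = 0.5)
        scans <- scanAllBreeds(sim$panel, alpha = 0.01)
        present <- sim$truth$snp_id %in% rownames(sim$panel)
        hit <- mapply(function(id, b) id %in% significantSnps(scans[[b]]),
                      sim$truth$snp_id, sim$truth$breed_code)
        hits <- c(hits, sum(hit & present))
        total <- c(total, sum(present))
    }
    expect_gt(sum(hits) / sum(total), 0.8)
})

test_that("the Manhattan table carries every SNP with its -log10 p", {
    sim <- simPanel(14, nBreeds = 3, n = 8L, nSnps = 120)
    scans <- scanAllBreeds(sim$panel)
    tab <- manhattanTable(scans[[1]], sim$panel)
    expect_equal(nrow(tab), nrow(sim$panel))
    expect_equal(tab$neg_log10_p, -log10(tab$pvalue))
    expect_equal(tab$neg_log10_p[tab$pvalue == 1],
                 rep(0, sum(tab$pvalue == 1)))
    expect_false(anyNA(tab$pos))
    summ <- scanSummary(scans)
    expect_equal(summ$sumSignificant, sum(summ$perBreed$n_significant))
    expect_lte(summ$unionSignificant, summ$sumSignificant)
})
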