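test_that("the generator chain is deterministic under a fixed seed", {
    cfg <- SimulationConfig(nBreeds = 3, samplesPerBreed = rep(10L, 3),
                            nSnps = 300, fst = 0.1, nPlantedPerBreed = 2L,
                            plantedDelta = 0.4, missingRate = 0.05, seed = 9)
    a <- simulateBreedPanel(cfg)
    b <- simulateBreedPanel(cfg)
    expect_identical(dosages(a$panel), dosages(b$panel))
    expect_identical(a$truth, b$truth)
    expect_identical(a$frequencies, b$frequencies)
    cfg2 <- cfg; cfg2@seed <- 10L
    expect_false(identical(dosages(a$panel),
                           dosages(simulateBreedPanel(cfg2)$panel)))
})

test_that("Balding-Nichols frequencies have the right moments", {
    # divergence-free limit: breed frequencies collapse onto the ancestral
    cfg0 <- SimulationConfig(nBreeds = 6, samplesPerBreed = rep(5L, 6),
                             nSnps = 2000, fst = 1e-6, seed = 21)
    fr0 <- drawBreedFrequencies(cfg0)
    anc <- attr(fr0, "ancestral")
    expect_lt(max(abs(sweep(fr0, 2, anc))), 0.01)
    expect_true(all(fr0 > 0 & fr0 < 1))

    # method-of-moments Fst recovered from the frequency matrix
    cfg <- SimulationConfig(nBreeds = 6, samplesPerBreed = rep(5L, 6),
                            nSnps = 10000, fst = 0.2, seed = 33)
    fr <- drawBreedFrequencies(cfg)
    est <- estimateFst(fr)
    expect_gt(est, 0.17)
    expect_lt(est, 0.23)

    expect_error(SimulationConfig(nBreeds = 2, samplesPerBreed = c(5L, 5L),
                                  nSnps = 100, fst = 1.2),
                 "fst")
})

test_that("planting shifts exactly one breed per locus by the stated rule", {
    cfg <- SimulationConfig(nBreeds = 6, samplesPerBreed = rep(5L, 6),
                            nSnps = 500, fst = 0.1, nPlantedPerBreed = 5L,
                            plantedDelta = 0, seed = 2)
    fr <- drawBreedFrequencies(cfg)
    pl <- plantBreedSpecificLoci(fr, cfg)
    # delta 0: truth recorded, frequencies untouched
    expect_identical(pl$frequencies, fr)
    expect_equal(nrow(pl$truth), 30L)
    expect_false(anyDuplicated(pl$truth$snp_index) > 0)
    expect_equal(unname(table(pl$truth$breed_code)), rep(5L, 6),
                 ignore_attr = TRUE)

    # shift rule: a focal frequency of 0.5 with delta 0.4 lands on 0.9
    # (shift toward the boundary with more room), clipped to [0.02, 0.98]
    cfg2 <- SimulationConfig(nBreeds = 2, samplesPerBreed = c(5L, 5L),
                             nSnps = 50, fst = 0.1, nPlantedPerBreed = 10L,
                             plantedDelta = 0.4, seed = 5)
    frFlat <- matrix(0.5, 2, 50,
                     dimnames = list(cfg2@breedCodes, sprintf("snp_%06d", 1:50)))
    pl2 <- plantBreedSpecificLoci(frFlat, cfg2)
    shifted <- mapply(function(i, b) pl2$frequencies[b, i],
                      pl2$truth$snp_index, pl2$truth$breed_code)
    expect_true(all(shifted == 0.9))
    untouched <- pl2$frequencies
    for (r in seq_len(nrow(pl2$truth)))
        untouched[pl2$truth$breed_code[r], pl2$truth$snp_index[r]] <- 0.5
    expect_true(all(untouched == 0.5))

    # clipping keeps planted loci polymorphic
    frHigh <- matrix(0.7, 2, 50, dimnames = dimnames(frFlat))
    pl3 <- plantBreedSpecificLoci(frHigh, cfg2)
    sh3 <- mapply(function(i, b) pl3$frequencies[b, i],
                  pl3$truth$snp_index, pl3$truth$breed_code)
    expect_true(all(sh3 >= 0.02 & sh3 <= 0.98))

    # overlapping planted sets are impossible to request
    expect_error(SimulationConfig(nBreeds = 4, samplesPerBreed = rep(5L, 4),
                                  nSnps = 10, fst = 0.1,
                                  nPlantedPerBreed = 5L),
                 "plant")
})

test_that("genotypes are binomial in the breed frequency", {
    cfg <- SimulationConfig(nBreeds = 1, samplesPerBreed = 30L, nSnps = 50,
                            fst = 0.1, nPlantedPerBreed = 0L,
                            missingRate = 0, seed = 7)
    # degenerate frequency 1 -> every dosage is 2
    fr1 <- matrix(1, 1, 50, dimnames = list(cfg@breedCodes,
                                            sprintf("snp_%06d", 1:50)))
    expect_true(all(dosages(simulateGenotypes(fr1, cfg)) == 2L))

    # frequency 0.5: per-SNP mean dosage concentrates around 1
    fr5 <- matrix(0.5, 1, 50, dimnames = dimnames(fr1))
    d <- dosages(simulateGenotypes(fr5, cfg))
    expect_false(anyNA(d))
    expect_gt(mean(d[1, ]), 0.7)
    expect_lt(mean(d[1, ]), 1.3)
    expect_gt(mean(d), 0.9)
    expect_lt(mean(d), 1.1)

    # missing entries appear at the requested rate
    cfgM <- cfg; cfgM@missingRate <- 0.1
    dm <- dosages(simulateGenotypes(fr5, cfgM))
    expect_gt(mean(is.na(dm)), 0.05)
    expect_lt(mean(is.na(dm)), 0.15)
})

test_that("SNP positions are sorted, 1-based and spread over chromosomes", {
    cfg <- SimulationConfig(nBreeds = 2, samplesPerBreed = c(4L, 4L),
                            nSnps = 100, fst = 0.1, nChromosomes = 5L,
                            missingRate = 0, seed = 1)
    info <- snpInfo(simulateBreedPanel(cfg)$panel)
    expect_setequal(unique(info$chrom), as.character(1:5))
    expect_true(all(info$pos >= 1))
    for (cc in unique(info$chrom))
        expect_false(is.unsorted(info$pos[info$chrom == cc]))
})

test_that("empirical allele frequencies converge to the drawn matrix", {
    cfg <- SimulationConfig(nBreeds = 1, samplesPerBreed = 500L,
                            nSnps = 1000, fst = 0.1, nPlantedPerBreed = 0L,
                            missingRate = 0, seed = 17)
    fr <- drawBreedFrequencies(cfg)
    d <- dosages(simulateGenotypes(fr, cfg))
    emp <- rowSums(d) / (2 * 500)
    dev <- abs(emp - as.numeric(fr[1, ]))
    expect_gt(mean(dev < 0.05), 0.95)
})

test_that("planted loci stand out from Balding-Nichols drift", {
    # strong-signal regime: the focal-vs-rest frequency gap of planted
    # loci exceeds the 99th percentile of the drift-only gaps
    sim <- simPanel(31, nBreeds = 6, n = 5L, nSnps = 5000, fst = 0.05,
                    nPlanted = 5L, delta = 0.5)
    fr <- sim$frequencies
    gap <- function(b, j) abs(fr[b, j] - mean(fr[rownames(fr) != b, j]))
    plantedGaps <- mapply(gap, sim$truth$breed_code, sim$truth$snp_index)
    unplanted <- setdiff(seq_len(ncol(fr)), sim$truth$snp_index)
    nullGaps <- unlist(lapply(rownames(fr), function(b)
        vapply(sample(unplanted, 500), function(j) gap(b, j), numeric(1))))
    expect_gt(mean(plantedGaps > stats::quantile(nullGaps, 0.99)), 0.9)
})
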