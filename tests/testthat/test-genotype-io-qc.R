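test_that("VCF reading maps GT to dosage and skips non-SNP records", {
    fx <- fixtureVcf()
    panel <- suppressMessages(readGenotypeVcf(fx$vcf, fx$breeds))
    expect_s4_class(panel, "GenotypePanel")
    expect_equal(nrow(panel), 4L)           # multiallelic + indel skipped
    expect_message(readGenotypeVcf(fx$vcf, fx$breeds), "skipped")
    d <- dosages(panel)
    expect_equal(unname(d["snpA", ]), c(0L, 1L, 2L))
    expect_equal(unname(d["snpB", ]), c(1L, NA_integer_, 2L))  # phased + missing
    expect_equal(unname(d["snpD", ]), c(0L, 0L, 0L))
    expect_equal(unname(breeds(panel)), c("HD", "HD", "SMS"))

    # a VCF sample absent from the breed table is an error
    short <- tempfile()
    writeLines(c("p1\tHD", "p2\tHD"), short)
    expect_error(suppressMessages(readGenotypeVcf(fx$vcf, short)), "p3")
})

test_that("write + read round-trips a panel exactly", {
    sim <- simulateBreedPanel(SimulationConfig(
        nBreeds = 3, samplesPerBreed = c(5L, 7L, 4L), nSnps = 120,
        fst = 0.15, missingRate = 0.05, seed = 13))
    dir <- tempfile(); dir.create(dir)
    vcf <- file.path(dir, "panel.vcf")
    tsv <- file.path(dir, "breeds.tsv")
    writeGenotypeVcf(sim$panel, vcf)
    writeBreedTable(sim$panel, tsv)
    back <- readGenotypeVcf(vcf, tsv)
    expect_identical(dosages(back), dosages(sim$panel))
    expect_identical(breeds(back), breeds(sim$panel))
    expect_identical(snpInfo(back)[, 1:5], snpInfo(sim$panel)[, 1:5])

    # dosage encoding in the text itself
    txt <- readLines(vcf)
    expect_true(any(grepl("\t0/1", txt)))
    expect_true(any(grepl("\t\\./\\.", txt)))

    # empty panel: header-only VCF
    empty <- sim$panel[integer(0), ]
    writeGenotypeVcf(empty, vcf)
    expect_length(readLines(vcf), 4L)
})

test_that("imputation fills every hole without touching observed calls", {
    sim <- simulateBreedPanel(SimulationConfig(
        nBreeds = 3, samplesPerBreed = rep(8L, 3), nSnps = 200, fst = 0.1,
        missingRate = 0.1, seed = 23))
    panel <- sim$panel
    obs <- !is.na(dosages(panel))
    for (mode in c("major", "draw")) {
        imp <- imputeMissing(panel, mode, seed = 4)
        expect_false(anyNA(dosages(imp)))
        expect_identical(dosages(imp)[obs], dosages(panel)[obs])
    }
    # a complete panel comes back unchanged
    complete <- imputeMissing(panel)
    expect_identical(imputeMissing(complete), complete)
    # draw mode is reproducible under its seed
    expect_identical(dosages(imputeMissing(panel, "draw", seed = 4)),
                     dosages(imputeMissing(panel, "draw", seed = 4)))

    # breed dosages (2, 2, NA) impute to the breed major 2
    toy <- toyPanel(matrix(c(2L, 2L, NA), 1), breed = rep("HD", 3))
    expect_equal(unname(dosages(imputeMissing(toy))[1, 3]), 2L)

    # SNP entirely missing within one breed falls back panel-wide, logged
    d2 <- matrix(c(NA, NA, 0L, 0L, 0L), 1)
    toy2 <- toyPanel(d2, breed = c("HD", "HD", "SMS", "SMS", "SMS"))
    expect_message(imp2 <- imputeMissing(toy2), "fallback")
    expect_equal(unname(dosages(imp2)[1, 1:2]), c(0L, 0L))
})

test_that("MAF computation matches brute-force allele counting", {
    expect_equal(unname(snpMaf(computeMaf(
        toyPanel(matrix(0L, 1, 4), rep("A", 4))))), 0)
    expect_equal(unname(snpMaf(computeMaf(
        toyPanel(matrix(c(0L, 1L, 1L, 2L), 1), rep("A", 4))))), 0.5)

    sim <- simulateBreedPanel(SimulationConfig(
        nBreeds = 2, samplesPerBreed = c(9L, 6L), nSnps = 150, fst = 0.2,
        missingRate = 0.07, seed = 3))
    maf <- snpMaf(computeMaf(sim$panel))
    d <- dosages(sim$panel)
    oracle <- vapply(seq_len(nrow(d)), function(j) {
        x <- d[j, ]
        x <- x[!is.na(x)]
        f <- sum(x) / (2 * length(x))
        min(f, 1 - f)
    }, numeric(1))
    expect_equal(unname(maf), oracle, tolerance = 1e-12)
})

test_that("MAF filtering is inclusive, idempotent and oracle-exact", {
    # 50 samples -> 100 alleles: alt counts 4, 5, 30 give MAFs .04/.05/.30
    d <- rbind(c(rep(1L, 4), rep(0L, 46)),
               c(rep(1L, 5), rep(0L, 45)),
               c(rep(1L, 30), rep(0L, 20)))
    panel <- computeMaf(toyPanel(d, rep("A", 50)))
    expect_equal(unname(snpMaf(panel)), c(0.04, 0.05, 0.30))
    kept <- suppressMessages(filterMaf(panel, 0.05))
    expect_equal(nrow(kept), 2L)                    # boundary is inclusive
    expect_equal(unname(snpMaf(kept)), c(0.05, 0.30))
    expect_equal(nrow(suppressMessages(filterMaf(panel, 0))), 3L)
    twice <- suppressMessages(filterMaf(kept, 0.05))
    expect_identical(dosages(twice), dosages(kept)) # idempotent

    expect_error(filterMaf(panel, 0.7), "threshold")

    sim <- simPanel(19, nSnps = 500, missingRate = 0.03)
    oracleKeep <- names(which(snpMaf(sim$panel) >= 0.05))
    expect_identical(rownames(suppressMessages(filterMaf(sim$panel, 0.05))),
                     oracleKeep)
})

test_that("windowed SNP density uses half-open 400-kb windows and conserves counts", {
    toy <- toyPanel(matrix(0:1, 4, 2), rep(c("A", "B"), 1),
                    chrom = rep("1", 4),
                    pos = c(1L, 400000L, 400001L, 800001L))
    dd <- snpDensity(toy)
    expect_equal(dd$count, c(2L, 1L, 1L))           # 1 and 400000 share window 0
    expect_equal(dd$window_start, c(1, 400001, 800001))
    expect_equal(dd$window_end, c(400000, 800000, 1200000))
    expect_equal(sum(dd$count), nrow(toy))

    # 10k uniformly spaced SNPs: brute-force binning oracle + near-even fill
    cfg <- SimulationConfig(nBreeds = 2, samplesPerBreed = c(5L, 5L),
                            nSnps = 10000, fst = 0.1, nChromosomes = 2L,
                            missingRate = 0, seed = 8)
    panel <- simulateBreedPanel(cfg)$panel
    dens <- snpDensity(panel)
    expect_equal(sum(dens$count), nrow(panel))
    info <- snpInfo(panel)
    brute <- table(paste(info$chrom, (info$pos - 1) %/% 400000L))
    expect_equal(sum(dens$count), sum(brute))
    withSnps <- dens[dens$count > 0, ]
    expect_equal(sort(as.integer(brute)), sort(withSnps$count))
    inner <- do.call(rbind, lapply(split(dens, dens$chrom),
                                   function(x) x[-nrow(x), ]))
    expect_lt(max(inner$count) / min(inner$count), 2)
})
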