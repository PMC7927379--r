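# independent oracles and fixture builders shared across tests

# right-tail hypergeometric probability by explicit pmf summation
bruteHyper <- function(N, K, n, k) {
    kk <- seq(max(0, k), min(n, K))
    if (k > min(n, K)) return(0)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# small panel straight from a dosage matrix (SNPs x samples)
toyPanel <- function(d, breed, chrom = NULL, pos = NULL) {
    m <- nrow(d)
    if (is.null(chrom)) chrom <- rep("1", m)
    if (is.null(pos)) pos <- seq_len(m) * 1000L
    GenotypePanel(d,
                  snps = data.frame(id = sprintf("s%03d", seq_len(m)),
                                    chrom = chrom, pos = pos,
                                    ref = "A", alt = "G"),
                  samples = data.frame(id = sprintf("ind%03d", seq_len(ncol(d))),
                                       breed = breed))
}

# complete filtered panel from the simulator, ready for scanning
simPanel <- function(seed, nBreeds = 4L, n = 20L, nSnps = 1000L, fst = 0.1,
                     nPlanted = 0L, delta = 0, missingRate = 0) {
    cfg <- SimulationConfig(nBreeds = nBreeds,
                            samplesPerBreed = rep(as.integer(n), nBreeds),
                            nSnps = as.integer(nSnps), fst = fst,
                            nPlantedPerBreed = as.integer(nPlanted),
                            plantedDelta = delta,
                            missingRate = missingRate, seed = seed)
    sim <- simulateBreedPanel(cfg)
    panel <- sim$panel
    if (missingRate > 0) panel <- imputeMissing(panel, seed = seed)
    suppressMessages(list(panel = filterMaf(computeMaf(panel)),
                          truth = sim$truth,
                          frequencies = sim$frequencies))
}

# hand-written VCF fixture: 4 usable SNPs, 1 multiallelic, 1 indel;
# sample dosages at snpA are 0, 1, 2
fixtureVcf <- function(dir = tempfile("fixture")) {
    dir.create(dir, showWarnings = FALSE)
    vcf <- file.path(dir, "fixture.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "p1", "p2", "p3", sep = "\t"),
        "1\t100\tsnpA\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
        "1\t200\tsnpB\tC\tT\t.\t.\t.\tGT\t0|1\t./.\t1/1",
        "1\t300\tmulti\tA\tG,T\t.\t.\t.\tGT\t0/0\t0/1\t0/2",
        "2\t150\tindel\tAT\tA\t.\t.\t.\tGT\t0/0\t0/0\t0/1",
        "2\t400\tsnpC\tG\tA\t.\t.\t.\tGT\t1/1\t1/1\t0/1",
        "2\t500\tsnpD\tT\tC\t.\t.\t.\tGT\t0/0\t0/0\t0/0"), vcf)
    breeds <- file.path(dir, "breeds.tsv")
    writeLines(c("p1\tHD", "p2\tHD", "p3\tSMS"), breeds)
    list(vcf = vcf, breeds = breeds)
}
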