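#' Simulator configuration
#'
#' Builds a validated [SimulationConfig-class].  The default configuration
#' emulates the statistical structure of a 24-breed pig panel: 1069 animals
#' in breeds of unequal size (10 to 97; five commercial Western breeds plus
#' nineteen Chinese indigenous breeds, using their conventional
#' abbreviations as codes) typed at 62,822 biallelic SNPs spread over 18
#' autosomes.  Between-breed divergence follows the Balding-Nichols model;
#' its parameter defaults to \code{fst = 0.15}, exposed here because the
#' true divergence of any given panel is data-dependent.
#'
#' @param nBreeds number of breeds.
#' @param samplesPerBreed per-breed sample counts (defaults to the 24-breed
#'   panel sizes when \code{nBreeds} is 24, else 30 per breed).
#' @param breedCodes breed codes (defaults to the panel abbreviations when
#'   \code{nBreeds} is 24, else "B01", "B02", ...).
#' @param nSnps number of SNPs.
#' @param fst Balding-Nichols divergence parameter in (0, 1).
#' @param nPlantedPerBreed breed-specific loci planted per breed.
#' @param plantedDelta allele-frequency shift at planted loci, in [0, 1];
#'   0 records ground truth without altering frequencies.
#' @param missingRate per-entry missing probability in [0, 1).
#' @param ancestralMafRange range of the uniform ancestral allele frequency.
#' @param nChromosomes chromosomes the SNPs are evenly spread over.
#' @param chromLengthBp chromosome length in bp.
#' @param seed integer seed; the whole generator chain is a deterministic
#'   function of the configuration and this seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' SimulationConfig(nBreeds = 4, samplesPerBreed = rep(20L, 4),
#'                  nSnps = 1000, fst = 0.1, seed = 7)
#' @export
SimulationConfig <- function(nBreeds = 24L,
                             samplesPerBreed = NULL,
                             breedCodes = NULL,
                             nSnps = 62822L,
                             fst = 0.15,
                             nPlantedPerBreed = 5L,
                             plantedDelta = 0.4,
                             missingRate = 0.02,
                             ancestralMafRange = c(0.05, 0.5),
                             nChromosomes = 18L,
                             chromLengthBp = 1.4e8,
                             seed = 1L) {
    if (is.null(samplesPerBreed) && is.null(breedCodes) && nBreeds == 24L) {
        samplesPerBreed <- .referencePanel$size
        breedCodes <- .referencePanel$code
    }
    if (!is.null(samplesPerBreed) && missing(nBreeds))
        nBreeds <- length(samplesPerBreed)
    if (is.null(samplesPerBreed))
        samplesPerBreed <- rep(30L, nBreeds)
    if (is.null(breedCodes))
        breedCodes <- sprintf("B%02d", seq_len(nBreeds))
    new("SimulationConfig",
        nBreeds = as.integer(nBreeds),
        samplesPerBreed = as.integer(samplesPerBreed),
        breedCodes = as.character(breedCodes),
        nSnps = as.integer(nSnps),
        fst = as.numeric(fst),
        nPlantedPerBreed = as.integer(nPlantedPerBreed),
        plantedDelta = as.numeric(plantedDelta),
        missingRate = as.numeric(missingRate),
        ancestralMafRange = as.numeric(ancestralMafRange),
        nChromosomes = as.integer(nChromosomes),
        chromLengthBp = as.numeric(chromLengthBp),
        seed = as.integer(seed))
}

# breed codes and sizes of the emulated 24-breed reference panel
.referencePanel <- data.frame(
    code = c("D", "L", "Y", "P", "B",
             "SMS", "MI", "EH", "DC", "HB", "HD", "JQ", "SZ",
             "BH", "CA", "CL", "JHL", "LX", "SH", "JX",
             "MMS", "SW", "FJ", "PD"),
    size = c(49L, 21L, 53L, 20L, 16L,
             75L, 36L, 42L, 10L, 34L, 30L, 38L, 20L,
             30L, 59L, 22L, 57L, 40L, 64L, 91L,
             97L, 65L, 32L, 68L))

.snpIdFormat <- function(m) sprintf("snp_%06d", seq_len(m))

#' Draw per-breed allele frequencies under the Balding-Nichols model
#'
#' For each SNP an ancestral alternate-allele frequency \eqn{p} is drawn
#' uniformly from \code{ancestralMafRange}; each breed's frequency is then
#' drawn independently from \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)} with
#' \eqn{F} the \code{fst} slot, so that
#' \eqn{E[p_b] = p} and \eqn{Var(p_b) = F\,p(1-p)}.
#'
#' @param config a [SimulationConfig-class].
#' @return numeric matrix of frequencies, breeds x SNPs, all entries in
#'   (0, 1), with an \code{"ancestral"} attribute holding the per-SNP
#'   ancestral frequencies.
#' @examples
#' f <- drawBreedFrequencies(SimulationConfig(nBreeds = 3,
#'     samplesPerBreed = rep(10L, 3), nSnps = 100, fst = 0.2))
#' dim(f)
#' @export
drawBreedFrequencies <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    m <- config@nSnps
    B <- config@nBreeds
    F <- config@fst
    p <- stats::runif(m, config@ancestralMafRange[1], config@ancestralMafRange[2])
    a <- p * (1 - F) / F
    b <- (1 - p) * (1 - F) / F
    fr <- matrix(stats::rbeta(B * m, rep(a, each = B), rep(b, each = B)),
                 nrow = B,
                 dimnames = list(config@breedCodes, .snpIdFormat(m)))
    # keep frequencies strictly inside (0, 1): extreme Beta draws can
    # underflow to exactly 0 or 1
    fr <- pmin(pmax(fr, 1e-9), 1 - 1e-9)
    attr(fr, "ancestral") <- p
    fr
}

#' Plant single-breed-specific loci into a frequency matrix
#'
#' Selects \code{nPlantedPerBreed} distinct SNPs per breed (no SNP is
#' planted for more than one breed) and shifts the focal breed's allele
#' frequency by \code{plantedDelta} toward whichever allele-frequency
#' boundary has more room (up when the frequency is at most 0.5, down
#' otherwise), clipping the result to [0.02, 0.98] so planted loci stay
#' polymorphic and survive MAF filtering.  All other breeds are untouched.
#' A \code{plantedDelta} of 0 records the ground truth without altering
#' any frequency.
#'
#' @param freqs breeds x SNPs frequency matrix from
#'   [drawBreedFrequencies()].
#' @param config the same [SimulationConfig-class].
#' @return list with \code{frequencies} (modified matrix) and \code{truth},
#'   a data.frame of (snp_index, snp_id, breed_code) rows — the planted
#'   ground truth, each SNP appearing for exactly one breed.
#' @export
plantBreedSpecificLoci <- function(freqs, config) {
    stopifnot(is(config, "SimulationConfig"))
    m <- ncol(freqs)
    B <- nrow(freqs)
    nP <- config@nPlantedPerBreed
    if (nP * B > m)
        stop("planted sets would overlap: nPlantedPerBreed * nBreeds > nSnps")
    set.seed(config@seed + 1L)
    idx <- sample.int(m, nP * B)
    truth <- data.frame(
        snp_index = idx,
        snp_id = colnames(freqs)[idx],
        breed_code = rep(rownames(freqs), each = nP),
        stringsAsFactors = FALSE)
    d <- config@plantedDelta
    if (d > 0 && nrow(truth)) {
        for (r in seq_len(nrow(truth))) {
            f <- freqs[truth$breed_code[r], truth$snp_index[r]]
            shifted <- if (f <= 0.5) f + d else f - d
            freqs[truth$breed_code[r], truth$snp_index[r]] <-
                min(max(shifted, 0.02), 0.98)
        }
    }
    list(frequencies = freqs, truth = truth)
}

#' Simulate genotypes from a per-breed frequency matrix
#'
#' Each individual's dosage at SNP j is Binomial(2, f) with f its breed's
#' frequency at j; entries are then set missing independently with
#' probability \code{missingRate}.  SNPs are placed at evenly spaced
#' 1-based positions across \code{nChromosomes} chromosomes (contiguous
#' blocks of SNPs per chromosome) and breed labels are attached to the
#' samples.
#'
#' @param freqs breeds x SNPs frequency matrix.
#' @param config the matching [SimulationConfig-class].
#' @return A [GenotypePanel-class].
#' @export
simulateGenotypes <- function(freqs, config) {
    stopifnot(is(config, "SimulationConfig"))
    if (nrow(freqs) != config@nBreeds || ncol(freqs) != config@nSnps)
        stop("frequency matrix does not match the configuration")
    set.seed(config@seed + 2L)
    m <- config@nSnps
    n <- sum(config@samplesPerBreed)
    breed <- rep(config@breedCodes, times = config@samplesPerBreed)
    # per-sample frequency matrix, SNPs x samples
    P <- t(freqs)[, rep(seq_len(config@nBreeds),
                        times = config@samplesPerBreed), drop = FALSE]
    d <- matrix(stats::rbinom(m * n, 2L, P), nrow = m)
    if (config@missingRate > 0)
        d[stats::runif(m * n) < config@missingRate] <- NA_integer_
    # evenly spaced positions over contiguous per-chromosome blocks
    C <- config@nChromosomes
    base <- m %/% C
    counts <- base + as.integer(seq_len(C) <= m %% C)
    chrom <- rep(as.character(seq_len(C)), times = counts)
    pos <- unlist(lapply(counts[counts > 0L], function(k)
        pmax(1L, as.integer(round(seq_len(k) * config@chromLengthBp / (k + 1))))),
        use.names = FALSE)
    bases <- c("A", "C", "G", "T")
    snps <- data.frame(id = colnames(freqs), chrom = chrom, pos = pos,
                       ref = rep_len(bases, m),
                       alt = rep_len(c("G", "T", "A", "C"), m))
    sampleId <- paste0(breed, "_",
                       unlist(lapply(config@samplesPerBreed, seq_len)))
    GenotypePanel(d, snps, data.frame(id = sampleId, breed = breed))
}

#' Run the full generator chain
#'
#' Convenience wrapper: [drawBreedFrequencies()], then
#' [plantBreedSpecificLoci()], then [simulateGenotypes()].  The output is a
#' deterministic function of the configuration (identical config and seed
#' give identical panels).
#'
#' @param config a [SimulationConfig-class].
#' @return list with \code{panel} (a [GenotypePanel-class]), \code{truth}
#'   (planted-locus table) and \code{frequencies} (the post-planting
#'   breeds x SNPs frequency matrix, ancestral frequencies as attribute).
#' @examples
#' sim <- simulateBreedPanel(SimulationConfig(nBreeds = 3,
#'     samplesPerBreed = rep(10L, 3), nSnps = 200, fst = 0.1,
#'     nPlantedPerBreed = 2L, seed = 42))
#' sim$panel
#' sim$truth
#' @export
simulateBreedPanel <- function(config) {
    fr <- drawBreedFrequencies(config)
    pl <- plantBreedSpecificLoci(fr, config)
    panel <- simulateGenotypes(pl$frequencies, config)
    list(panel = panel, truth = pl$truth, frequencies = pl$frequencies)
}

#' Method-of-moments Fst estimate from a frequency matrix
#'
#' Variance-decomposition estimator used to check the generator: the
#' across-breed variance of allele frequencies at each locus is pooled and
#' divided by the pooled \eqn{\bar p(1-\bar p)}.
#'
#' @param freqs breeds x SNPs frequency matrix.
#' @return a single Fst estimate.
#' @export
estimateFst <- function(freqs) {
    pbar <- colMeans(freqs)
    v <- apply(freqs, 2, stats::var)
    sum(v) / sum(pbar * (1 - pbar))
}

#' Simulate gene models, term sets and an interaction graph for a panel
#'
#' Generates the annotation side of a benchmark run: gene spans centered on
#' a random subset of the panel's SNP positions (so that SNP-to-gene
#' mapping has realistic coverage regardless of the simulated marker
#' density), a term database of random gene sets (GMT-like) and an
#' undirected gene-interaction graph with random edges.  These emulate
#' only the combinatorial structure that enrichment and network scoring
#' consume, not any real functional content.
#'
#' @param panel a [GenotypePanel-class] giving the chromosome layout.
#' @param nGenes number of genes (capped at the panel SNP count).
#' @param geneWidthBp width of each gene span in bp.
#' @param nTerms number of terms.
#' @param termSizeRange range of genes per term.
#' @param meanDegree average number of interaction partners per gene.
#' @param seed integer seed.
#' @return list with \code{genes} (GRanges with a \code{gene_id} column),
#'   \code{terms} (named list of gene-id sets) and \code{graph} (an
#'   \pkg{igraph} undirected graph on the gene ids).
#' @export
simulateAnnotation <- function(panel, nGenes = 300L, geneWidthBp = 2e4,
                               nTerms = 60L, termSizeRange = c(5L, 40L),
                               meanDegree = 4, seed = 1L) {
    set.seed(seed)
    info <- snpInfo(panel)
    nGenes <- min(as.integer(nGenes), nrow(info))
    anchor <- sort(sample.int(nrow(info), nGenes))
    half <- as.integer(geneWidthBp) %/% 2L
    ids <- sprintf("gene_%04d", seq_len(nGenes))
    genes <- GRanges(info$chrom[anchor],
                     IRanges(pmax(1L, info$pos[anchor] - half),
                             info$pos[anchor] + half))
    mcols(genes)$gene_id <- ids
    terms <- lapply(seq_len(nTerms), function(i)
        sort(sample(ids, sample(seq(termSizeRange[1], termSizeRange[2]), 1L))))
    names(terms) <- sprintf("term_%03d", seq_len(nTerms))
    nEdges <- as.integer(round(meanDegree * nGenes / 2))
    e1 <- sample(ids, nEdges, replace = TRUE)
    e2 <- sample(ids, nEdges, replace = TRUE)
    keep <- e1 != e2
    g <- igraph::graph_from_data_frame(
        data.frame(from = e1[keep], to = e2[keep]),
        directed = FALSE, vertices = ids)
    g <- igraph::simplify(g)
    list(genes = genes, terms = terms, graph = g)
}
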