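#' Pipeline run configuration
#'
#' Collects every input and threshold of a full run.  Exactly one of the
#' two input modes must be used: a \code{simulation} block (a
#' [SimulationConfig-class]) or file paths (\code{vcf} plus
#' \code{breedTable}).  Annotation inputs (\code{geneModels} GFF3/BED,
#' \code{gmt}, \code{edgeList}) are optional; in simulation mode, when
#' omitted, a synthetic annotation set is generated alongside the panel so
#' the whole pipeline can run end to end.
#'
#' @param outDir output directory (created if needed).
#' @param simulation optional [SimulationConfig-class].
#' @param vcf,breedTable optional input file paths.
#' @param geneModels,gmt,edgeList optional annotation file paths.
#' @param mafThreshold MAF filter threshold (default 0.05, inclusive).
#' @param alpha per-SNP significance threshold (default 0.01, strict).
#' @param enrichmentAlphas enrichment reporting thresholds
#'   (default 0.05 and 0.01, strict).
#' @param scoreThreshold network-module score cut for counting (default 2).
#' @param flankBp SNP-to-gene assignment flank (default 10 kb).
#' @param nComponents PLS components (default 1).
#' @param pMethod p-value method, "zscore" or "permutation".
#' @param nPermutations permutations per breed when \code{pMethod} is
#'   "permutation".
#' @param imputeMode imputation mode, "major" or "draw".
#' @param distanceMetric PCoA distance, "euclidean" or "allele-sharing".
#' @param k number of embedding axes (default 10, capped below the sample
#'   count).
#' @param windowBp SNP-density window (default 400 kb).
#' @param seed integer seed governing every stochastic stage.
#' @param makePlots write PNG figures (skipped automatically when the
#'   R build lacks png support).
#' @return a validated configuration list of class \code{"RunConfig"}.
#' @seealso [runPipeline()], [readRunConfig()]
#' @export
runConfig <- function(outDir,
                      simulation = NULL,
                      vcf = NULL, breedTable = NULL,
                      geneModels = NULL, gmt = NULL, edgeList = NULL,
                      mafThreshold = 0.05,
                      alpha = 0.01,
                      enrichmentAlphas = c(0.05, 0.01),
                      scoreThreshold = 2,
                      flankBp = 10000L,
                      nComponents = 1L,
                      pMethod = c("zscore", "permutation"),
                      nPermutations = 500L,
                      imputeMode = c("major", "draw"),
                      distanceMetric = c("euclidean", "allele-sharing"),
                      k = 10L,
                      windowBp = 400000L,
                      seed = 1L,
                      makePlots = TRUE) {
    simMode <- !is.null(simulation)
    fileMode <- !is.null(vcf) || !is.null(breedTable)
    if (simMode == fileMode)
        stop("exactly one of a simulation block or vcf+breedTable paths ",
             "must be given")
    if (fileMode && (is.null(vcf) || is.null(breedTable)))
        stop("file mode needs both 'vcf' and 'breedTable'")
    if (simMode) stopifnot(is(simulation, "SimulationConfig"))
    if (mafThreshold < 0 || mafThreshold > 0.5)
        stop("'mafThreshold' must lie in [0, 0.5]")
    if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
    if (any(enrichmentAlphas <= 0 | enrichmentAlphas >= 1))
        stop("'enrichmentAlphas' must lie in (0, 1)")
    structure(list(
        outDir = outDir, simulation = simulation,
        vcf = vcf, breedTable = breedTable,
        geneModels = geneModels, gmt = gmt, edgeList = edgeList,
        mafThreshold = mafThreshold, alpha = alpha,
        enrichmentAlphas = enrichmentAlphas,
        scoreThreshold = scoreThreshold, flankBp = as.integer(flankBp),
        nComponents = as.integer(nComponents),
        pMethod = match.arg(pMethod),
        nPermutations = as.integer(nPermutations),
        imputeMode = match.arg(imputeMode),
        distanceMetric = match.arg(distanceMetric),
        k = as.integer(k), windowBp = as.integer(windowBp),
        seed = as.integer(seed), makePlots = isTRUE(makePlots)),
        class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [runConfig()]; a nested
#' \code{simulation} mapping mirrors [SimulationConfig()].
#'
#' @param path path to a YAML file.
#' @return a \code{"RunConfig"} list.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$simulation))
        y$simulation <- do.call(SimulationConfig, y$simulation)
    do.call(runConfig, y)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full breed-specificity pipeline
#'
#' Simulate or load a genotype panel, impute and MAF-filter it, summarize
#' SNP density and population structure (PCA and PCoA), scan every breed
#' one-vs-rest by PLS, map each breed's significant SNPs to genes, run
#' hypergeometric term enrichment, build and score interaction-network
#' modules, and write all tables, figures and a machine-readable JSON
#' summary to the output directory.  Identical configuration and seed give
#' a byte-identical summary.
#'
#' @param config a \code{"RunConfig"} from [runConfig()] or
#'   [readRunConfig()].
#' @return the summary list, invisibly (also written as
#'   \code{summary.json}).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    out <- config$outDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    plots <- config$makePlots && capabilities("png")
    if (config$makePlots && !plots)
        .log("png device unavailable; figures skipped")
    truth <- NULL
    genes <- terms <- graph <- NULL

    ## -- input ---------------------------------------------------------
    panel <- .stage("input", {
        if (!is.null(config$simulation)) {
            sim <- simulateBreedPanel(config$simulation)
            truth <- sim$truth
            writeGenotypeVcf(sim$panel, file.path(out, "panel.vcf"))
            writeBreedTable(sim$panel, file.path(out, "breeds.tsv"))
            .writeTsv(truth, file.path(out, "truth.tsv"))
            sim$panel
        } else {
            readGenotypeVcf(config$vcf, config$breedTable)
        }
    })
    .stage("annotation-input", {
        if (!is.null(config$geneModels))
            genes <- readGeneModels(config$geneModels)
        if (!is.null(config$gmt)) terms <- readGmt(config$gmt)
        if (!is.null(config$edgeList)) graph <- readEdgeList(config$edgeList)
        if (!is.null(config$simulation) && is.null(genes)) {
            ann <- simulateAnnotation(panel, seed = config$seed)
            genes <- ann$genes; terms <- ann$terms; graph <- ann$graph
            writeGeneModels(genes, file.path(out, "genes.gff3"))
            writeGmt(terms, file.path(out, "terms.gmt"))
            writeEdgeList(graph, file.path(out, "edges.tsv"))
        }
    })
    nInput <- nrow(panel)

    ## -- qc ------------------------------------------------------------
    panel <- .stage("qc", {
        p <- imputeMissing(panel, config$imputeMode, seed = config$seed)
        p <- computeMaf(p)
        filterMaf(p, config$mafThreshold)
    })
    density <- .stage("density", {
        d <- snpDensity(panel, config$windowBp)
        .writeTsv(d, file.path(out, "snp_density.tsv"))
        if (plots) plotSnpDensity(d, file.path(out, "snp_density.png"))
        d
    })

    ## -- structure -----------------------------------------------------
    k <- min(config$k, ncol(panel) - 1L)
    pca <- .stage("structure", {
        e <- runPCA(panel, k)
        D <- pairwiseDistance(panel, config$distanceMetric)
        pcoa <- runPCoA(D, k, breeds = unname(breeds(panel)))
        for (emb in list(e, pcoa)) {
            tag <- tolower(emb@method)
            tab <- data.frame(sample_id = colnames(panel),
                              breed = unname(breeds(panel)),
                              emb@coordinates)
            .writeTsv(tab, file.path(out, paste0(tag, ".tsv")))
            if (plots) plotEmbedding(emb, file.path(out, paste0(tag, ".png")))
        }
        list(pca = e, pcoa = pcoa)
    })

    ## -- scan ----------------------------------------------------------
    scans <- .stage("scan", {
        s <- scanAllBreeds(panel, nComponents = config$nComponents,
                           alpha = config$alpha, method = config$pMethod,
                           nPermutations = config$nPermutations,
                           seed = config$seed)
        for (r in as.list(s)) {
            .writeTsv(manhattanTable(r, panel),
                      file.path(out, paste0("scan_", r@breed, ".tsv")))
            if (plots)
                plotManhattan(r, panel,
                              file.path(out, paste0("manhattan_", r@breed,
                                                    ".png")))
        }
        s
    })
    scanSum <- scanSummary(scans)

    ## -- annotation / enrichment ---------------------------------------
    breedGenes <- NULL
    enrichCounts <- NULL
    if (!is.null(genes)) {
        breedGenes <- .stage("gene-mapping", {
            bg <- lapply(as.list(scans), function(r)
                mapSnpsToGenes(significantSnps(r), panel, genes,
                               config$flankBp))
            for (b in names(bg))
                writeLines(bg[[b]], file.path(out, paste0("genes_", b, ".txt")))
            bg
        })
        if (!is.null(terms)) {
            enrichCounts <- .stage("enrichment", {
                background <- mapSnpsToGenes(rownames(panel), panel, genes,
                                             config$flankBp)
                counts <- lapply(names(breedGenes), function(b) {
                    rec <- enrichTerms(breedGenes[[b]], terms, background)
                    .writeTsv(rec, file.path(out, paste0("enrichment_", b,
                                                         ".tsv")))
                    countSignificant(rec, config$enrichmentAlphas)
                })
                names(counts) <- names(breedGenes)
                counts
            })
        }
    }

    ## -- networks ------------------------------------------------------
    networkTable <- NULL
    if (!is.null(graph) && !is.null(breedGenes)) {
        networkTable <- .stage("networks", {
            mods <- lapply(breedGenes, scoreModules, graph = graph)
            all <- do.call(rbind, lapply(names(mods), function(b)
                if (nrow(mods[[b]])) cbind(breed = b, mods[[b]]) else NULL))
            if (!is.null(all))
                .writeTsv(all, file.path(out, "modules.tsv"))
            rk <- rankAndCount(mods, config$scoreThreshold)
            .writeTsv(rk, file.path(out, "network_ranking.tsv"))
            rk
        })
    }

    ## -- summary -------------------------------------------------------
    summary <- .stage("summary", {
        perBreed <- scanSum$perBreed
        if (!is.null(breedGenes))
            perBreed$n_genes <- vapply(breedGenes[perBreed$breed],
                                       length, integer(1))
        if (!is.null(enrichCounts))
            for (a in config$enrichmentAlphas)
                perBreed[[paste0("n_terms_p", a)]] <- vapply(
                    enrichCounts[perBreed$breed], function(x)
                        unname(x[paste0("p<", a)]), integer(1))
        if (!is.null(networkTable)) {
            idx <- match(perBreed$breed, networkTable$breed)
            perBreed$n_networks <- networkTable$n_modules[idx]
            perBreed$n_networks_scored <- networkTable$n_above_threshold[idx]
        }
        recovery <- NULL
        if (!is.null(truth) && nrow(truth)) {
            hits <- mapply(function(id, b)
                id %in% rownames(panel) &&
                    id %in% significantSnps(scans[[b]]),
                truth$snp_id, truth$breed_code)
            recovery <- list(n_planted = nrow(truth),
                             n_recovered = sum(hits),
                             recovery_rate = mean(hits))
        }
        s <- list(
            parameters = list(
                maf_threshold = config$mafThreshold,
                alpha = config$alpha,
                enrichment_alphas = config$enrichmentAlphas,
                score_threshold = config$scoreThreshold,
                flank_bp = config$flankBp,
                n_components = config$nComponents,
                p_method = config$pMethod,
                impute_mode = config$imputeMode,
                distance_metric = config$distanceMetric,
                window_bp = config$windowBp,
                seed = config$seed),
            n_samples = ncol(panel),
            n_breeds = length(unique(breeds(panel))),
            n_snps_input = nInput,
            n_snps_filtered = nrow(panel),
            pca_variance_pct = round(100 * pca$pca@varianceFraction, 4),
            pcoa_variance_pct = round(100 * pca$pcoa@varianceFraction, 4),
            per_breed = perBreed,
            significant_snps_union = scanSum$unionSignificant,
            significant_snps_sum = scanSum$sumSignificant,
            planted_recovery = recovery)
        jsonlite::write_json(s, file.path(out, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             dataframe = "columns")
        s
    })
    .log("pipeline complete; outputs in ", out)
    invisible(summary)
}
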