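#' Map SNPs to overlapping genes
#'
#' A gene is reported iff at least one of the given SNPs lies within
#' [start - flank, end + flank] of the gene on the same chromosome
#' (boundaries inclusive; strand ignored).  Each gene is reported once.
#'
#' @param snpIds SNP ids, all present in the panel.
#' @param panel a [GenotypePanel-class] carrying the SNP coordinates.
#' @param genes GRanges of gene models with a \code{gene_id} column
#'   (see [readGeneModels()]).
#' @param flankBp symmetric flank in bp added to each gene span
#'   (default 10 kb).
#' @return sorted character vector of unique gene ids.
#' @export
mapSnpsToGenes <- function(snpIds, panel, genes, flankBp = 10000L) {
    unknown <- setdiff(snpIds, rownames(panel))
    if (length(unknown))
        stop("unknown SNP id(s): ", paste(utils::head(unknown, 5),
                                          collapse = ", "))
    if (length(snpIds) == 0L) return(character(0))
    gr <- rowRanges(panel)[snpIds]
    flanked <- genes
    ranges(flanked) <- IRanges(pmax(1L, start(genes) - as.integer(flankBp)),
                               end(genes) + as.integer(flankBp))
    hits <- findOverlaps(gr, flanked, ignore.strand = TRUE)
    sort(unique(mcols(flanked)$gene_id[S4Vectors::subjectHits(hits)]))
}

#' Hypergeometric term enrichment (Fisher's exact test, right tail)
#'
#' For each term, the overlap k between the query gene set and the term's
#' genes (both intersected with the background) is tested against the
#' right tail of the hypergeometric distribution:
#' \eqn{p = P[\mathrm{Hyper}(N, K, n) \ge k]} with N the background size,
#' K the term size in the background and n the query size.  No
#' multiple-testing correction is applied; records are sorted by
#' ascending p, ties broken by term id.
#'
#' @param geneSet character vector of query gene ids, a subset of
#'   \code{background}.
#' @param termDb named list of term gene sets (see [readGmt()]).
#' @param background character vector: the gene universe.
#' @return data.frame with columns term_id, k, n, K, N, pvalue.
#' @examples
#' db <- list(t1 = c("g1", "g2", "g3"), t2 = c("g4", "g5"))
#' enrichTerms(c("g1", "g2"), db, paste0("g", 1:10))
#' @export
enrichTerms <- function(geneSet, termDb, background) {
    background <- unique(as.character(background))
    if (length(background) == 0L) stop("empty background")
    gs <- unique(as.character(geneSet))
    outside <- setdiff(gs, background)
    if (length(outside))
        stop("query gene(s) not in background: ",
             paste(utils::head(outside, 5), collapse = ", "))
    N <- length(background)
    n <- length(gs)
    K <- vapply(termDb, function(g)
        length(intersect(g, background)), integer(1))
    k <- vapply(termDb, function(g)
        length(intersect(g, gs)), integer(1))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    df <- data.frame(term_id = names(termDb), k = k, n = n, K = K, N = N,
                     pvalue = p, row.names = NULL)
    df[order(df$pvalue, df$term_id), , drop = FALSE]
}

#' Count significant enrichment records at several thresholds
#'
#' Strict-inequality counts, mirroring the convention of reporting terms
#' at p < 0.05 and p < 0.01 per breed.
#'
#' @param records data.frame with a \code{pvalue} column (from
#'   [enrichTerms()]), or a bare p-value vector.
#' @param alphas thresholds (default 0.05 and 0.01).
#' @return named integer vector of counts, one per threshold.
#' @export
countSignificant <- function(records, alphas = c(0.05, 0.01)) {
    p <- if (is.data.frame(records)) records$pvalue else as.numeric(records)
    stats::setNames(vapply(alphas, function(a) sum(p < a), integer(1)),
                    paste0("p<", alphas))
}
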