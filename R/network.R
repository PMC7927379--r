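#' Build interaction-network modules around focus genes
#'
#' Greedy seed-and-grow decomposition of a gene-interaction graph, in the
#' spirit of commercial pathway-analysis tools (whose exact algorithm is
#' proprietary; module membership is therefore a documented stand-in while
#' the scoring formula in [scoreModule()] is exact).  The unassigned focus
#' gene of highest degree seeds a module (ties by lexicographic id); the
#' module repeatedly absorbs the unassigned neighbor adjacent to most
#' current members (ties broken by higher degree, then lexicographic id)
#' until it reaches \code{maxSize} or no candidate remains.  Genes belong
#' to at most one module; seeding repeats until every matchable focus gene
#' is assigned.  Modules containing fewer than two focus genes are
#' discarded at the end (their genes stay consumed, keeping the
#' decomposition deterministic).
#'
#' @param graph an undirected \pkg{igraph} graph with named vertices
#'   (see [readEdgeList()]).
#' @param focusGenes character vector of genes of interest (typically one
#'   breed's significant genes); ids absent from the graph are logged and
#'   ignored.
#' @param maxSize module size cap (default 35, the conventional module
#'   size of pathway-analysis reports).
#' @return list of modules, each a list with \code{genes} (sorted ids),
#'   \code{focusCount} and \code{seed}.
#' @export
buildModules <- function(graph, focusGenes, maxSize = 35L) {
    if (igraph::vcount(graph) == 0L) stop("empty interaction graph")
    nodes <- igraph::V(graph)$name
    if (is.null(nodes)) stop("graph vertices must be named by gene id")
    focus <- intersect(unique(as.character(focusGenes)), nodes)
    dropped <- setdiff(unique(as.character(focusGenes)), nodes)
    if (length(dropped))
        .log(length(dropped), " focus gene(s) not in the interaction graph")
    deg <- stats::setNames(igraph::degree(graph), nodes)
    adjl <- lapply(igraph::as_adj_list(graph, mode = "all"),
                   function(v) nodes[as.integer(v)])
    names(adjl) <- nodes
    assigned <- character(0)
    modules <- list()
    remaining <- focus
    while (length(remaining)) {
        seed <- remaining[order(-deg[remaining], remaining)][1]
        mod <- seed
        while (length(mod) < maxSize) {
            cand <- setdiff(unique(unlist(adjl[mod], use.names = FALSE)),
                            c(mod, assigned))
            if (!length(cand)) break
            adjCount <- vapply(cand, function(g) sum(adjl[[g]] %in% mod),
                               integer(1))
            mod <- c(mod, cand[order(-adjCount, -deg[cand], cand)][1])
        }
        assigned <- c(assigned, mod)
        remaining <- setdiff(remaining, assigned)
        modules[[length(modules) + 1L]] <-
            list(genes = sort(mod),
                 focusCount = sum(mod %in% focus),
                 seed = seed)
    }
    keep <- vapply(modules, function(m) m$focusCount >= 2L, logical(1))
    if (any(!keep))
        .log(sum(!keep), " module(s) with < 2 focus genes discarded")
    modules[keep]
}

#' Score a module by the focus-gene overlap
#'
#' The significance of seeing \code{focusCount} focus genes in a module of
#' size n drawn from a universe of N genes containing K focus genes is the
#' right tail of the hypergeometric distribution (Fisher's exact test);
#' the score is its negative decimal logarithm, capped at 300.
#'
#' @param module a module from [buildModules()], or a bare character
#'   vector of gene ids.
#' @param focusGenes the focus gene set.
#' @param universe the gene universe (the interaction-graph node set).
#' @return non-negative score; 0 when the module holds no focus gene.
#' @export
scoreModule <- function(module, focusGenes, universe) {
    genes <- if (is.list(module)) module$genes else as.character(module)
    universe <- unique(as.character(universe))
    N <- length(universe)
    n <- length(genes)
    if (n > N) stop("module larger than the universe")
    K <- length(intersect(unique(as.character(focusGenes)), universe))
    k <- length(intersect(genes, intersect(focusGenes, universe)))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    min(-log10(p), 300)
}

#' Build and score one breed's modules
#'
#' @param graph an undirected \pkg{igraph} gene-interaction graph.
#' @param focusGenes the breed's significant genes.
#' @param maxSize module size cap (see [buildModules()]).
#' @return data.frame with columns rank, score, focus_count, size, genes
#'   (semicolon-joined), sorted by descending score with deterministic
#'   tie-breaking (larger module first, then gene ids).
#' @export
scoreModules <- function(graph, focusGenes, maxSize = 35L) {
    mods <- buildModules(graph, focusGenes, maxSize)
    universe <- igraph::V(graph)$name
    if (!length(mods))
        return(data.frame(rank = integer(0), score = numeric(0),
                          focus_count = integer(0), size = integer(0),
                          genes = character(0)))
    df <- data.frame(
        score = vapply(mods, scoreModule, numeric(1),
                       focusGenes = focusGenes, universe = universe),
        focus_count = vapply(mods, function(m) m$focusCount, integer(1)),
        size = vapply(mods, function(m) length(m$genes), integer(1)),
        genes = vapply(mods, function(m)
            paste(m$genes, collapse = ";"), character(1)))
    df <- df[order(-df$score, -df$size, df$genes), , drop = FALSE]
    df <- cbind(rank = seq_len(nrow(df)), df)
    rownames(df) <- NULL
    df
}

#' Rank breeds by their number of high-scoring modules
#'
#' @param modulesPerBreed named list of per-breed module tables from
#'   [scoreModules()].
#' @param scoreThreshold count modules with score at or above this value
#'   (default 2, i.e. overlap p <= 0.01).
#' @return data.frame with columns breed, n_modules (all returned
#'   modules), n_above_threshold, top_score and rank; breeds ordered by
#'   descending n_above_threshold (ties by n_modules, then breed code).
#' @export
rankAndCount <- function(modulesPerBreed, scoreThreshold = 2) {
    df <- data.frame(
        breed = names(modulesPerBreed),
        n_modules = vapply(modulesPerBreed, nrow, integer(1)),
        n_above_threshold = vapply(modulesPerBreed, function(m)
            sum(m$score >= scoreThreshold), integer(1)),
        top_score = vapply(modulesPerBreed, function(m)
            if (nrow(m)) max(m$score) else 0, numeric(1)),
        row.names = NULL)
    df <- df[order(-df$n_above_threshold, -df$n_modules, df$breed), ,
             drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    df
}
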