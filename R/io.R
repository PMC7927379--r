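#' Read a genotype panel from VCF plus a sample-to-breed table
#'
#' Loads diploid GT calls from a VCF (v4.x) as alternate-allele dosages.
#' Only biallelic single-nucleotide records are loaded; multiallelic or
#' non-SNP records are skipped with a logged count.  Genotypes with any
#' missing allele (e.g. \code{"./."}) become \code{NA}; phased separators
#' are accepted.  Samples are matched by id against the breed table.
#'
#' @param vcfPath path to a VCF file.
#' @param breedTablePath path to a two-column, headerless TSV
#'   (sample_id, breed_code) covering every VCF sample.
#' @return A [GenotypePanel-class].
#' @seealso [writeGenotypeVcf()]
#' @export
readGenotypeVcf <- function(vcfPath, breedTablePath) {
    v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
        nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
    if (any(!keep))
        .log(sum(!keep), " multiallelic/non-SNP record(s) skipped")
    if (!any(keep))
        stop("no biallelic SNP records in ", vcfPath)
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    clean <- gsub("|", "/", gt, fixed = TRUE)
    u <- unique(as.vector(clean))
    uval <- vapply(u, function(g) {
        if (is.na(g)) return(NA_integer_)
        al <- strsplit(g, "/", fixed = TRUE)[[1]]
        if (length(al) != 2L || any(al == ".")) return(NA_integer_)
        sum(al == "1")
    }, integer(1))
    d <- matrix(uval[match(clean, u)], nrow = nrow(clean),
                dimnames = dimnames(clean))
    breedMap <- readBreedTable(breedTablePath)
    missing <- setdiff(colnames(d), names(breedMap))
    if (length(missing))
        stop("VCF sample(s) missing from breed table: ",
             paste(utils::head(missing, 5), collapse = ", "))
    id <- fix[keep, "ID"]
    bad <- is.na(id) | id == "."
    id[bad] <- paste0(fix[keep, "CHROM"][bad], "_", fix[keep, "POS"][bad])
    snps <- data.frame(id = id,
                       chrom = fix[keep, "CHROM"],
                       pos = as.integer(fix[keep, "POS"]),
                       ref = ref[keep], alt = alt[keep])
    samples <- data.frame(id = colnames(d),
                          breed = unname(breedMap[colnames(d)]))
    GenotypePanel(d, snps, samples)
}

#' Write a genotype panel as VCF v4.2
#'
#' One record per SNP, GT-only FORMAT; missing dosages are written as
#' \code{"./."}.  An empty panel produces a header-only VCF.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(panel, path) {
    info <- snpInfo(panel)
    header <- c(
        "##fileformat=VCFv4.2",
        "##source=breedPLS",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(panel)), collapse = "\t"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    if (nrow(panel)) {
        d <- dosages(panel)
        gtmap <- c("0/0", "0/1", "1/1")
        gt <- matrix(ifelse(is.na(d), "./.", gtmap[d + 1L]), nrow = nrow(d))
        cols <- c(list(info$chrom, info$pos, info$id, info$ref, info$alt,
                       ".", ".", ".", "GT"),
                  lapply(seq_len(ncol(gt)), function(j) gt[, j]),
                  list(sep = "\t"))
        writeLines(do.call(paste, cols), con)
    }
    invisible(path)
}

#' Read a sample-to-breed table
#'
#' @param path two-column headerless TSV: sample_id, breed_code.
#' @return named character vector mapping sample id to breed code.
#' @export
readBreedTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L)
        stop("breed table must have two columns (sample_id, breed_code)")
    stats::setNames(df[[2]], df[[1]])
}

#' Write the sample-to-breed table of a panel
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path (two-column headerless TSV).
#' @return \code{path}, invisibly.
#' @export
writeBreedTable <- function(panel, path) {
    .writeTsv(data.frame(colnames(panel), unname(breeds(panel))),
              path, col.names = FALSE)
    invisible(path)
}

#' Read a GMT term-to-genes file
#'
#' Standard tab-separated GMT: one term per line, fields term id,
#' description, then member gene ids.  Terms left without genes are dropped
#' with a logged count.
#'
#' @param path path to a GMT file.
#' @return named list of character gene-id vectors; term descriptions kept
#'   in the \code{"description"} attribute.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    terms <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
    names(terms) <- vapply(parts, `[`, character(1), 1L)
    desc <- vapply(parts, function(x)
        if (length(x) >= 2L) x[2] else "", character(1))
    empty <- lengths(terms) == 0L
    if (any(empty)) {
        .log(sum(empty), " empty term(s) dropped from ", path)
        terms <- terms[!empty]
        desc <- desc[!empty]
    }
    attr(terms, "description") <- stats::setNames(desc, names(terms))
    terms
}

#' Write a term database as GMT
#'
#' @param terms named list of gene-id vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(terms, path) {
    desc <- attr(terms, "description")
    if (is.null(desc)) desc <- stats::setNames(rep("", length(terms)),
                                               names(terms))
    writeLines(vapply(names(terms), function(t)
        paste(c(t, desc[[t]], terms[[t]]), collapse = "\t"),
        character(1)), path)
    invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 files are filtered to \code{type == "gene"} records (when a type
#' column is present) and the gene identifier is taken from the
#' \code{gene_id}, \code{ID} or \code{Name} attribute, in that order.  BED
#' files use the name column.  Coordinates are returned 1-based inclusive.
#'
#' @param path path to a .gff3/.gff or .bed file.
#' @return GRanges with a \code{gene_id} metadata column.
#' @export
readGeneModels <- function(path) {
    if (grepl("\\.bed$", path, ignore.case = TRUE)) {
        gr <- rtracklayer::import(path, format = "BED")
        if (is.null(mcols(gr)$name))
            stop("BED gene models need a name column")
        mcols(gr) <- DataFrame(gene_id = as.character(mcols(gr)$name))
        return(gr)
    }
    gr <- rtracklayer::import(path)
    mc <- mcols(gr)
    if ("type" %in% names(mc) && any(mc$type == "gene"))
        gr <- gr[mc$type == "gene"]
    mc <- mcols(gr)
    gid <- NULL
    for (col in c("gene_id", "ID", "Name"))
        if (is.null(gid) && col %in% names(mc)) gid <- as.character(mc[[col]])
    if (is.null(gid) || any(is.na(gid)))
        stop("could not determine gene ids from ", path)
    mcols(gr) <- DataFrame(gene_id = gid)
    gr
}

#' Write gene models as GFF3
#'
#' @param genes GRanges with a \code{gene_id} metadata column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
    lines <- paste(as.character(seqnames(genes)), "breedPLS", "gene",
                   start(genes), end(genes), ".", "+", ".",
                   paste0("ID=", mcols(genes)$gene_id),
                   sep = "\t")
    writeLines(c("##gff-version 3", lines), path)
    invisible(path)
}

#' Read an undirected gene-interaction edge list
#'
#' @param path two-column TSV (gene_a, gene_b), no header.  Self-loops and
#'   duplicate edges are removed.
#' @return an undirected \pkg{igraph} graph.
#' @export
readEdgeList <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L) stop("edge list must have two columns")
    g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
    igraph::simplify(g)
}

#' Write an interaction graph as an edge-list TSV
#'
#' @param graph an \pkg{igraph} graph.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
    e <- igraph::as_edgelist(graph)
    .writeTsv(as.data.frame(e), path, col.names = FALSE)
    invisible(path)
}
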