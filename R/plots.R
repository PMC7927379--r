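#' Manhattan plot of one breed's scan
#'
#' Plots -log10(p) per SNP along a cumulative genome coordinate with
#' chromosomes in alternating shades and a horizontal line at the call
#' threshold.
#'
#' @param result a [BreedScanResult-class].
#' @param panel the scanned [GenotypePanel-class].
#' @param file optional PNG path; when given the plot is written there.
#' @param width,height device size in pixels when writing a file.
#' @return the Manhattan table, invisibly.
#' @export
plotManhattan <- function(result, panel, file = NULL,
                          width = 1200, height = 400) {
    tab <- manhattanTable(result, panel)
    chroms <- unique(tab$chrom)
    offset <- 0
    xs <- numeric(nrow(tab))
    mids <- numeric(length(chroms))
    for (i in seq_along(chroms)) {
        sel <- tab$chrom == chroms[i]
        xs[sel] <- tab$pos[sel] + offset
        mids[i] <- offset + max(tab$pos[sel]) / 2
        offset <- offset + max(tab$pos[sel])
    }
    if (!is.null(file)) {
        grDevices::png(file, width = width, height = height)
        on.exit(grDevices::dev.off())
    }
    cols <- c("grey30", "steelblue")[(match(tab$chrom, chroms) %% 2) + 1]
    graphics::plot(xs, tab$neg_log10_p, pch = 20, cex = 0.5, col = cols,
                   xaxt = "n", xlab = "chromosome",
                   ylab = expression(-log[10](p)),
                   main = paste("Breed", result@breed, "vs rest"))
    graphics::axis(1, at = mids, labels = chroms, tick = FALSE)
    graphics::abline(h = -log10(result@alpha), col = "red", lty = 2)
    invisible(tab)
}

#' Scatter plot of an embedding
#'
#' First two axes, colored by breed, with variance-explained percentages
#' in the axis labels (PCA/PCoA).
#'
#' @param embedding an [EmbeddingResult-class].
#' @param file optional PNG path.
#' @param width,height device size in pixels when writing a file.
#' @return the coordinate matrix, invisibly.
#' @export
plotEmbedding <- function(embedding, file = NULL, width = 700, height = 600) {
    co <- embedding@coordinates
    if (ncol(co) < 2L) stop("embedding has fewer than two axes")
    vf <- embedding@varianceFraction
    lab <- function(i) sprintf("%s%d (%.2f%%)", embedding@method, i,
                               100 * vf[i])
    br <- embedding@breeds
    if (!length(br)) br <- rep("sample", nrow(co))
    f <- factor(br)
    pal <- grDevices::hcl.colors(max(3L, nlevels(f)), "Dark 3")
    if (!is.null(file)) {
        grDevices::png(file, width = width, height = height)
        on.exit(grDevices::dev.off())
    }
    graphics::plot(co[, 1], co[, 2], col = pal[as.integer(f)], pch = 19,
                   xlab = lab(1), ylab = lab(2),
                   main = paste(embedding@method, "of genotype panel"))
    graphics::legend("topright", legend = levels(f),
                     col = pal[seq_len(nlevels(f))], pch = 19, cex = 0.7,
                     ncol = max(1L, nlevels(f) %/% 12L))
    invisible(co)
}

#' SNP density plot per chromosome
#'
#' @param density a density table from [snpDensity()].
#' @param file optional PNG path.
#' @param width,height device size in pixels when writing a file.
#' @return \code{density}, invisibly.
#' @export
plotSnpDensity <- function(density, file = NULL, width = 900, height = 500) {
    if (!is.null(file)) {
        grDevices::png(file, width = width, height = height)
        on.exit(grDevices::dev.off())
    }
    chroms <- unique(density$chrom)
    graphics::par(mfrow = c(ceiling(length(chroms) / 3), 3),
                  mar = c(2, 4, 2, 1))
    for (cc in chroms) {
        sub <- density[density$chrom == cc, ]
        graphics::plot(sub$window_start / 1e6, sub$count, type = "h",
                       xlab = "", ylab = "SNPs / window",
                       main = paste("chr", cc))
    }
    invisible(density)
}
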