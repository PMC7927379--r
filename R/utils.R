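# internal helpers

# chromosome sort rank: numeric-looking names (optionally "chr"-prefixed)
# sort numerically first, the rest alphabetically after them
.chromRank <- function(chrom) {
    chrom <- as.character(chrom)
    u <- unique(chrom)
    num <- suppressWarnings(as.numeric(sub("^[Cc]hr", "", u)))
    ord <- u[order(is.na(num), num, u)]
    match(chrom, ord)
}

.log <- function(...) message("[breedPLS] ", ...)

# write a data.frame as TSV (no quoting, no row names)
.writeTsv <- function(df, path, col.names = TRUE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
}
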