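## Independent brute-force oracles used throughout the suite. These stay
## deliberately naive (per-base scans, closed-form combinatorics) so they
## share no code path with the implementation they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(SummarizedExperiment)
})

## minimal gap between two 1-based closed intervals by scanning base pairs
bruteDistance <- function(c1, s1, e1, c2, s2, e2) {
    if (c1 != c2) return(Inf)
    pa <- s1:e1; pb <- s2:e2
    if (any(pa %in% pb)) return(0)
    min(abs(outer(pa, pb, "-"))) - 1
}

## one-sided (upper tail) Fisher p by explicit combinatorics
enumFisherOne <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; N <- a + b + c + d
    sup <- max(0, r1 + c1 - N):min(r1, c1)
    prob <- choose(c1, sup) * choose(N - c1, r1 - sup) / choose(N, r1)
    sum(prob[sup >= a])
}

## two-sided Fisher p: all tables no more probable than the observed
enumFisherTwo <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; N <- a + b + c + d
    sup <- max(0, r1 + c1 - N):min(r1, c1)
    prob <- choose(c1, sup) * choose(N - c1, r1 - sup) / choose(N, r1)
    sum(prob[prob <= prob[sup == a] * (1 + 1e-7)])
}

## random toy annotation on one small chromosome; returns plain vectors so
## oracle checks never touch GRanges machinery
randomToyIntervals <- function(n, chromLen = 10000, maxLen = 500,
                               chroms = "chrT") {
    chrom <- sample(chroms, n, replace = TRUE)
    st <- sample(chromLen - maxLen, n, replace = TRUE)
    len <- sample(maxLen, n, replace = TRUE)
    data.frame(chrom = chrom, start = st, end = pmin(st + len - 1, chromLen),
               stringsAsFactors = FALSE)
}

toyGRanges <- function(df, strand = "*") {
    GRanges(df$chrom, IRanges(df$start, df$end), strand = strand)
}

## simple gene fixture: k genes with ids and required mcols
toyGenes <- function(starts, ends, strand = "+", chrom = "chrT",
                     chromLen = max(100000, max(ends) + 1000), ...) {
    n <- length(starts)
    g <- GRanges(chrom, IRanges(starts, ends),
                 strand = rep(strand, length.out = n),
                 gene_id = sprintf("g%03d", seq_len(n)),
                 symbol = sprintf("G%03d", seq_len(n)),
                 biotype = "protein_coding", ...)
    suppressWarnings(seqlengths(g) <- setNames(rep(chromLen,
        length(unique(chrom))), unique(chrom)))
    g
}

toyRepeats <- function(starts, ends, family, repclass = "LINE",
                       strand = "+", chrom = "chrT", divergence = NA_real_) {
    n <- length(starts)
    GRanges(chrom, IRanges(starts, ends), strand = rep(strand, length.out = n),
            family = rep(family, length.out = n),
            repclass = rep(repclass, length.out = n),
            divergence = rep(divergence, length.out = n))
}
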