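## Strand-aware interval arithmetic on GRanges. All downstream proximity and
## overlap logic reduces to these primitives.

.checkIntervals <- function(x, what = "interval") {
    if (!is(x, "GRanges"))
        stop(what, " must be a GRanges", call. = FALSE)
    if (any(width(x) <= 0))
        stop(what, " has zero or negative width", call. = FALSE)
    invisible(x)
}

#' Gap distance between genomic intervals
#'
#' Element-wise distance between two GRanges of equal length (or one of
#' length 1, recycled). The distance is 0 when the intervals share at least
#' one base or abut on the same chromosome, the gap between the nearest edges
#' otherwise, and Inf when the chromosomes differ. Symmetric in its
#' arguments.
#'
#' @param a,b GRanges of equal length (or either of length 1).
#' @return Numeric vector of distances in bp (Inf across chromosomes).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 400))
#' intervalDistance(a, b)  # 100
#' @export
intervalDistance <- function(a, b) {
    .checkIntervals(a, "a"); .checkIntervals(b, "b")
    d <- suppressWarnings(GenomicRanges::distance(a, b, ignore.strand = TRUE))
    d <- as.numeric(d)
    d[is.na(d)] <- Inf
    d
}

#' Is a query interval within a radius of an anchor?
#'
#' At \code{w = 0} the query must share at least one base with the anchor
#' (abutting intervals do not count); at \code{w > 0} a gap of up to and
#' including \code{w} bp qualifies, so the predicate is monotone
#' non-decreasing in \code{w}.
#'
#' @param anchor,query GRanges of equal length (or either of length 1).
#' @param w radius in bp, >= 0.
#' @return Logical vector.
#' @export
withinRadius <- function(anchor, query, w) {
    if (length(w) != 1L || is.na(w) || w < 0)
        stop("w must be a single non-negative number", call. = FALSE)
    if (w == 0) {
        ## require a shared base, not a zero gap: abutting does not count
        n <- max(length(anchor), length(query))
        aa <- rep(anchor, length.out = n); bb <- rep(query, length.out = n)
        as.character(seqnames(aa)) == as.character(seqnames(bb)) &
            start(aa) <= end(bb) & start(bb) <= end(aa)
    } else {
        intervalDistance(anchor, query) <= w
    }
}

#' Upstream region of a gene
#'
#' Returns the strand-aware region of length \code{len} immediately upstream
#' of each gene span, clipped to the chromosome bounds. For a + strand gene
#' the region abuts the gene start; for a - strand gene it abuts the gene
#' end. Genes whose upstream region is clipped to zero length are returned
#' with width 0 and \code{mcols()$clipped_empty = TRUE}; callers exclude them
#' from downstream tallies.
#'
#' @param gene GRanges with strand + or - and seqlengths set, or an explicit
#'   \code{chromLen} named vector.
#' @param len region length in bp, > 0 (default 3000, the upstream window
#'   used for LTR promoter analysis).
#' @param chromLen optional named vector of chromosome lengths overriding
#'   \code{seqlengths(gene)}.
#' @return GRanges of upstream regions, parallel to \code{gene}, with a
#'   \code{clipped_empty} metadata column.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 8000), "+")
#' GenomeInfoDb::seqlengths(g) <- c(chr1 = 20000)
#' upstreamRegion(g, 3000)  # chr1:2001-5000
#' @export
upstreamRegion <- function(gene, len = 3000, chromLen = NULL) {
    .checkIntervals(gene, "gene")
    if (len <= 0) stop("len must be > 0", call. = FALSE)
    st <- as.character(strand(gene))
    if (any(st == "*"))
        stop("gene strand must be + or -", call. = FALSE)
    if (is.null(chromLen)) chromLen <- seqlengths(gene)
    sn <- as.character(seqnames(gene))
    if (anyNA(chromLen[sn]))
        stop("chromosome lengths unavailable; set seqlengths or chromLen",
             call. = FALSE)
    plus <- st == "+"
    up_start <- ifelse(plus, pmax(1, start(gene) - len), end(gene) + 1)
    up_end <- ifelse(plus, start(gene) - 1,
                     pmin(as.numeric(chromLen[sn]), end(gene) + len))
    empty <- up_end < up_start
    ## keep parallel structure: zero-width placeholders for clipped-out genes
    out <- GRanges(factor(sn, levels = names(chromLen)),
                   IRanges(ifelse(empty, start(gene), up_start),
                           width = ifelse(empty, 0, up_end - up_start + 1)),
                   strand = st)
    mcols(out)$clipped_empty <- empty
    suppressWarnings(seqlengths(out) <- chromLen)
    out
}

#' Orientation of a repeat relative to a gene
#'
#' "sense" when the repeat strand equals the gene strand, "antisense" when it
#' is the opposite strand, "unknown" when the repeat strand is "*"
#' (unstranded repeats are excluded from orientation-bias tables).
#'
#' @param gene GRanges with strand + or -.
#' @param repeat_ GRanges of repeat instances (recycled against gene).
#' @return Character vector in {sense, antisense, unknown}.
#' @export
relativeOrientation <- function(gene, repeat_) {
    n <- max(length(gene), length(repeat_))
    gs <- rep(as.character(strand(gene)), length.out = n)
    rs <- rep(as.character(strand(repeat_)), length.out = n)
    if (any(gs == "*")) stop("gene strand must be + or -", call. = FALSE)
    ifelse(rs == "*", "unknown", ifelse(rs == gs, "sense", "antisense"))
}
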