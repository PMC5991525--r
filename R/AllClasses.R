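#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps countOverlaps distance distanceToNearest pintersect resize shift
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<- seqnames<-
#' @importFrom stats median phyper dhyper pnorm rnbinom rpois runif rbinom rnorm
#'   p.adjust sd quantile setNames var rlnorm
#' @importFrom utils read.delim write.table head
NULL

REPCLASS_VOCAB <- c("LINE", "LTR", "SINE", "Satellite", "DNA", "Other")

#' AnnotationBundle: genes, repeats and family metadata for one genome
#'
#' The central annotation container. Genes and repeat instances are held as
#' \link[GenomicRanges]{GRanges} (1-based, closed intervals, the native R
#' convention; BED input is converted on read). Gene ranges carry metadata
#' columns \code{gene_id}, \code{symbol}, \code{biotype}, \code{conservation}
#' (fraction of the gene conserved across placental mammals, in [0,1] or NA)
#' and \code{lca_clade} (last-common-ancestor clade label or NA). Repeat
#' ranges carry \code{family}, \code{repclass} (one of LINE, LTR, SINE,
#' Satellite, DNA, Other) and \code{divergence} (percent mismatch from the
#' family consensus, in [0,100] or NA). \code{familyInfo} is a
#' \link[S4Vectors]{DataFrame} with one row per repeat family: \code{family},
#' \code{repclass}, \code{age_myr}, \code{active}, \code{consensus_length}.
#'
#' @slot genes GRanges of gene spans with gene metadata columns.
#' @slot repeats GRanges of repeat instances with repeat metadata columns.
#' @slot familyInfo DataFrame of per-family metadata.
#' @slot chromSizes named integer vector of chromosome lengths.
#'
#' @export
setClass("AnnotationBundle",
    representation(
        genes = "GRanges",
        repeats = "GRanges",
        familyInfo = "DataFrame",
        chromSizes = "integer"
    )
)

setValidity("AnnotationBundle", function(object) {
    msg <- character()
    g <- object@genes
    r <- object@repeats
    fi <- object@familyInfo
    cs <- object@chromSizes
    if (length(cs) && (is.null(names(cs)) || anyNA(cs) || any(cs <= 0)))
        msg <- c(msg, "chromSizes must be a named positive integer vector")
    need_g <- c("gene_id", "symbol", "biotype")
    if (length(g)) {
        if (!all(need_g %in% colnames(mcols(g))))
            msg <- c(msg, sprintf("genes must carry mcols: %s",
                                  paste(need_g, collapse = ", ")))
        else {
            if (anyDuplicated(g$gene_id))
                msg <- c(msg, "duplicate gene_id in genes")
            if (any(as.character(strand(g)) == "*"))
                msg <- c(msg, "gene strand must be + or -")
        }
        if (!is.null(g$conservation) &&
            any(!is.na(g$conservation) & (g$conservation < 0 | g$conservation > 1)))
            msg <- c(msg, "gene conservation must lie in [0,1]")
    }
    if (length(r)) {
        need_r <- c("family", "repclass")
        if (!all(need_r %in% colnames(mcols(r))))
            msg <- c(msg, "repeats must carry mcols: family, repclass")
        else {
            if (!all(r$repclass %in% REPCLASS_VOCAB))
                msg <- c(msg, "repeat repclass outside the fixed vocabulary")
            if (any(!nzchar(r$family)))
                msg <- c(msg, "repeat family must be non-empty")
        }
        if (!is.null(r$divergence) &&
            any(!is.na(r$divergence) & (r$divergence < 0 | r$divergence > 100)))
            msg <- c(msg, "repeat divergence must lie in [0,100]")
        if (any(width(r) <= 0)) msg <- c(msg, "repeat width must be > 0")
    }
    if (length(cs)) {
        for (x in list(g, r)) {
            if (!length(x)) next
            sn <- as.character(seqnames(x))
            bad <- !(sn %in% names(cs)) | end(x) > cs[sn] | start(x) < 1
            if (any(bad))
                msg <- c(msg, "intervals outside chromSizes bounds")
        }
    }
    if (nrow(fi) && !all(c("family", "repclass", "consensus_length") %in% colnames(fi)))
        msg <- c(msg, "familyInfo needs columns family, repclass, consensus_length")
    if (length(msg)) msg else TRUE
})

#' Construct an AnnotationBundle
#'
#' @param genes GRanges of gene spans (mcols gene_id, symbol, biotype,
#'   optionally conservation, lca_clade).
#' @param repeats GRanges of repeat instances (mcols family, repclass,
#'   optionally divergence).
#' @param familyInfo DataFrame or data.frame of per-family metadata.
#' @param chromSizes named numeric vector of chromosome lengths.
#' @return A validated \linkS4class{AnnotationBundle}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000), "+",
#'     gene_id = "g1", symbol = "G1", biotype = "protein_coding")
#' AnnotationBundle(genes = gr, chromSizes = c(chr1 = 10000))
#' @export
AnnotationBundle <- function(genes = GRanges(), repeats = GRanges(),
                             familyInfo = DataFrame(), chromSizes = integer()) {
    if (is.data.frame(familyInfo)) familyInfo <- DataFrame(familyInfo)
    cs <- setNames(as.integer(chromSizes), names(chromSizes))
    new("AnnotationBundle", genes = genes, repeats = repeats,
        familyInfo = familyInfo, chromSizes = cs)
}

#' @rdname AnnotationBundle
#' @param x,object An AnnotationBundle.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname AnnotationBundle
#' @export
setMethod("genes", "AnnotationBundle", function(x) x@genes)

#' @rdname AnnotationBundle
#' @export
setGeneric("repeats", function(x) standardGeneric("repeats"))
#' @rdname AnnotationBundle
#' @export
setMethod("repeats", "AnnotationBundle", function(x) x@repeats)

#' @rdname AnnotationBundle
#' @export
setGeneric("familyInfo", function(x) standardGeneric("familyInfo"))
#' @rdname AnnotationBundle
#' @export
setMethod("familyInfo", "AnnotationBundle", function(x) x@familyInfo)

#' @rdname AnnotationBundle
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @rdname AnnotationBundle
#' @export
setMethod("chromSizes", "AnnotationBundle", function(x) x@chromSizes)

#' @rdname AnnotationBundle
#' @export
setMethod("show", "AnnotationBundle", function(object) {
    cat("AnnotationBundle\n")
    cat(sprintf("  %d genes, %d repeat instances (%d families), %d chromosomes\n",
                length(object@genes), length(object@repeats),
                length(unique(object@repeats$family)), length(object@chromSizes)))
    if (nrow(object@familyInfo))
        cat(sprintf("  familyInfo: %d families (%d flagged active)\n",
                    nrow(object@familyInfo), sum(object@familyInfo$active %in% TRUE)))
})

#' RepeatFilter: a selector over repeat instances
#'
#' Selects repeat instances by class, family, minimum instance length and/or
#' a full-length rule. At least one selector must be active. The full-length
#' rule keeps LINEs with length strictly greater than \code{minLength} and
#' LTR-class instances with length at least \code{fullLengthFrac} of the
#' family consensus length.
#'
#' @slot classes character subset of LINE, LTR, SINE, Satellite, DNA, Other.
#' @slot families character vector of family names (empty = no family filter).
#' @slot minLength minimum instance length in bp (kept if length > minLength
#'   when > 0).
#' @slot fullLengthOnly logical; apply the LTR consensus-fraction rule.
#' @slot fullLengthFrac fraction of consensus length defining a full-length
#'   LTR instance (default 0.9).
#' @slot label display label.
#' @export
setClass("RepeatFilter",
    representation(classes = "character", families = "character",
                   minLength = "numeric", fullLengthOnly = "logical",
                   fullLengthFrac = "numeric", label = "character"))

setValidity("RepeatFilter", function(object) {
    msg <- character()
    if (length(object@classes) && !all(object@classes %in% REPCLASS_VOCAB))
        msg <- c(msg, "classes outside the repclass vocabulary")
    if (object@minLength < 0) msg <- c(msg, "minLength must be >= 0")
    if (!length(object@classes) && !length(object@families) &&
        object@minLength == 0 && !object@fullLengthOnly)
        msg <- c(msg, "at least one selector must be active")
    if (length(msg)) msg else TRUE
})

#' Construct a RepeatFilter
#'
#' @param classes,families,minLength,fullLengthOnly,fullLengthFrac,label see
#'   \linkS4class{RepeatFilter} slots.
#' @return A validated RepeatFilter.
#' @examples
#' repeatFilter(classes = "LINE", minLength = 5000, label = "LINEs >5kb")
#' @export
repeatFilter <- function(classes = character(), families = character(),
                         minLength = 0, fullLengthOnly = FALSE,
                         fullLengthFrac = 0.9, label = "") {
    if (!nzchar(label)) {
        parts <- c(
            if (length(classes)) paste(classes, collapse = "/"),
            if (length(families)) sprintf("%d families", length(families)),
            if (minLength > 0) sprintf(">%dbp", as.integer(minLength)),
            if (fullLengthOnly) "full-length")
        label <- paste(parts, collapse = " ")
    }
    new("RepeatFilter", classes = classes, families = families,
        minLength = as.numeric(minLength), fullLengthOnly = fullLengthOnly,
        fullLengthFrac = fullLengthFrac, label = label)
}

setMethod("show", "RepeatFilter", function(object) {
    cat("RepeatFilter:", object@label, "\n")
})
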