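## The central computation: repeat-content enrichment of gene sets at
## distance windows versus random gene backgrounds, L1 array statistics,
## and the upstream-LTR orientation-bias test.

#' Apply a RepeatFilter to repeat instances
#'
#' Selects by class, family and instance length. With \code{minLength > 0}
#' LINE instances are kept only when strictly longer than the threshold;
#' with \code{fullLengthOnly}, LTR-class instances are kept when their
#' length is at least \code{fullLengthFrac} of the family consensus length
#' (consensus lengths come from \code{info}).
#'
#' @param repeats GRanges of repeat instances.
#' @param filter A \linkS4class{RepeatFilter}.
#' @param info familyInfo DataFrame (needed for the full-length LTR rule).
#' @return The selected GRanges subset.
#' @export
selectRepeats <- function(repeats, filter, info = NULL) {
    stopifnot(is(filter, "RepeatFilter"))
    keep <- rep(TRUE, length(repeats))
    if (length(filter@classes))
        keep <- keep & repeats$repclass %in% filter@classes
    if (length(filter@families))
        keep <- keep & repeats$family %in% filter@families
    if (filter@minLength > 0)
        keep <- keep & width(repeats) > filter@minLength
    if (filter@fullLengthOnly) {
        if (is.null(info))
            stop("fullLengthOnly needs familyInfo consensus lengths",
                 call. = FALSE)
        cons <- info$consensus_length[match(repeats$family, info$family)]
        is_ltr <- repeats$repclass == "LTR"
        fl <- !is.na(cons) & width(repeats) >= filter@fullLengthFrac * cons
        keep <- keep & (!is_ltr | fl)
    }
    repeats[keep]
}

#' @rdname selectRepeats
#' @export
selectFullLength <- selectRepeats

#' Per-gene repeat-presence flags
#'
#' For each gene in the set, whether at least one repeat passing the filter
#' lies within radius \code{w} of the gene span (shared base required at
#' w = 0; a repeat partly inside the window counts).
#'
#' @param gs gene set (gene_ids list or character vector).
#' @param genes GRanges gene annotation.
#' @param repeats GRanges of repeat instances.
#' @param filter RepeatFilter.
#' @param w radius in bp.
#' @param info familyInfo (for the full-length LTR rule).
#' @return List: \code{flags} (named logical per gene), \code{count}
#'   (flagged genes) and \code{per_gene} (qualifying-repeat count per
#'   gene).
#' @export
genesWithRepeat <- function(gs, genes, repeats, filter, w = 20000,
                            info = NULL) {
    g <- .resolveGenes(gs, genes)
    r <- selectRepeats(repeats, filter, info)
    maxgap <- if (w == 0) -1L else as.integer(w)
    nhit <- countOverlaps(g, r, maxgap = maxgap, ignore.strand = TRUE)
    flags <- setNames(nhit > 0, g$gene_id)
    list(flags = flags, count = sum(flags),
         per_gene = setNames(nhit, g$gene_id))
}

#' Repeat enrichment of a gene set versus a background
#'
#' At each distance window, builds the 2x2 table (set vs background) x
#' (has-repeat vs not) from per-gene flags and tests set enrichment with a
#' one-sided Fisher test. Fold is the ratio of flagged fractions; when the
#' background has no flagged gene the fold is reported as Inf and flagged.
#'
#' @param gs,bg gene sets (test and background).
#' @param genes GRanges gene annotation.
#' @param repeats GRanges of repeat instances.
#' @param filter RepeatFilter.
#' @param windows distance windows in bp (default 0, 5000, 20000).
#' @param info familyInfo.
#' @return data.frame, one row per window: counts, fold, p, fold_infinite
#'   flag.
#' @export
enrichmentVsBackground <- function(gs, bg, genes, repeats, filter,
                                   windows = c(0, 5000, 20000), info = NULL) {
    rows <- lapply(windows, function(w) {
        s <- genesWithRepeat(gs, genes, repeats, filter, w, info)
        b <- genesWithRepeat(bg, genes, repeats, filter, w, info)
        st <- length(s$flags); bt <- length(b$flags)
        sp <- s$count; bp <- b$count
        fold <- if (bp == 0) Inf else (sp / st) / (bp / bt)
        data.frame(window = w, filter = filter@label,
                   set_positive = sp, set_total = st,
                   bg_positive = bp, bg_total = bt,
                   fold = fold, fold_infinite = bp == 0,
                   p = fisherOneSided(sp, st - sp, bp, bt - bp))
    })
    do.call(rbind, rows)
}

#' Fraction of genes with any of several repeat categories nearby
#'
#' @param gs gene set.
#' @param genes,repeats,info as in \code{genesWithRepeat}.
#' @param filters list of RepeatFilter objects.
#' @param w radius in bp (default 20000).
#' @return Fraction of genes flagged by at least one filter.
#' @export
fractionWithAny <- function(gs, genes, repeats, filters, w = 20000,
                            info = NULL) {
    if (is(filters, "RepeatFilter")) filters <- list(filters)
    fl <- Reduce(`|`, lapply(filters, function(f)
        genesWithRepeat(gs, genes, repeats, f, w, info)$flags))
    mean(fl)
}

#' Fraction of repeat-containing genes that carry arrays
#'
#' Of the genes flagged by the filter at radius \code{w}, the fraction with
#' at least \code{minCount} qualifying repeats (default 2: "multiple"
#' copies, i.e. an array).
#'
#' @inheritParams genesWithRepeat
#' @param minCount minimum qualifying repeats (default 2).
#' @return Fraction among flagged genes (NA when none is flagged).
#' @export
l1ArrayFraction <- function(gs, genes, repeats, filter, w = 20000,
                            minCount = 2, info = NULL) {
    r <- genesWithRepeat(gs, genes, repeats, filter, w, info)
    if (!any(r$flags)) return(NA_real_)
    mean(r$per_gene[r$flags] >= minCount)
}

#' Upstream-LTR orientation bias
#'
#' Extracts the \code{upstreamLen} region upstream of every gene in the
#' test and background sets, collects the LTR-class instances overlapping
#' those regions (any overlap; unstranded LTRs are excluded), scores each
#' instance sense/antisense relative to its gene, pools instances across
#' genes within each group, and tests sense over-representation in the
#' test group with a one-sided Fisher test. Genes with a fully clipped
#' upstream region are excluded.
#'
#' @param gs,bg gene sets.
#' @param genes GRanges gene annotation (seqlengths set, or chromLen given).
#' @param ltrs GRanges of LTR-class repeat instances.
#' @param upstreamLen upstream region length in bp (default 3000).
#' @param chromLen optional named chromosome lengths.
#' @return List: per-group sense/antisense counts and sense fractions, and
#'   the one-sided p-value.
#' @export
orientationBias <- function(gs, bg, genes, ltrs, upstreamLen = 3000,
                            chromLen = NULL) {
    countGroup <- function(set) {
        g <- .resolveGenes(set, genes)
        up <- upstreamRegion(g, upstreamLen, chromLen = chromLen)
        ok <- !up$clipped_empty
        g <- g[ok]; up <- up[ok]
        hits <- findOverlaps(up, ltrs, ignore.strand = TRUE)
        ori <- relativeOrientation(g[queryHits(hits)], ltrs[subjectHits(hits)])
        c(sense = sum(ori == "sense"), antisense = sum(ori == "antisense"))
    }
    s <- countGroup(gs); b <- countGroup(bg)
    list(set_sense = s[["sense"]], set_antisense = s[["antisense"]],
         bg_sense = b[["sense"]], bg_antisense = b[["antisense"]],
         sense_fraction_set = s[["sense"]] / sum(s),
         sense_fraction_bg = b[["sense"]] / sum(b),
         p = fisherOneSided(s[["sense"]], s[["antisense"]],
                            b[["sense"]], b[["antisense"]]))
}
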