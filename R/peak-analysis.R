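## ChIP peak statistics: reproducible-peak filtering, clustering fraction,
## histone-mark overlap at two stringencies, peak-to-repeat assignment,
## family-level IP/input binding enrichment, and consensus coverage
## profiles.

#' Reproducible peaks across replicates, input-subtracted
#'
#' Keeps the replicate-1 peaks that overlap (>= 1 bp) at least one
#' replicate-2 peak and no input peak; output coordinates are the
#' replicate-1 intervals.
#'
#' @param rep1,rep2 GRanges of replicate peak calls.
#' @param input GRanges of input/control peaks (any overlap removes a
#'   peak).
#' @return GRanges subset of rep1.
#' @export
reproduciblePeaks <- function(rep1, rep2, input = GRanges()) {
    if (!length(rep1) || !length(rep2)) {
        warning("empty replicate peak set; no reproducible peaks")
        return(rep1[integer()])
    }
    keep <- overlapsAny(rep1, rep2, ignore.strand = TRUE) &
        !overlapsAny(rep1, input, ignore.strand = TRUE)
    rep1[keep]
}

#' Peak clustering fraction
#'
#' The fraction of peaks whose gap distance to the nearest other peak is at
#' most \code{d} bp. A single peak (or a peak alone on its chromosome)
#' contributes FALSE.
#'
#' @param peaks GRanges of peaks.
#' @param d clustering distance in bp (default 50000).
#' @return Fraction in [0, 1] (NA for an empty input).
#' @export
clusterFraction <- function(peaks, d = 50000) {
    if (!length(peaks)) return(NA_real_)
    if (length(peaks) == 1) return(0)
    dn <- distanceToNearest(peaks, ignore.strand = TRUE)  # self excluded
    near <- rep(FALSE, length(peaks))
    near[queryHits(dn)] <- mcols(dn)$distance <= d
    mean(near)
}

#' Overlap of peaks with a histone-mark interval set
#'
#' Mode "any" requires at least one shared base; mode "frac" requires the
#' covered fraction of the peak (shared bases divided by peak length, the
#' peak-relative convention) to reach \code{minFrac}.
#'
#' @param peaks GRanges of peaks.
#' @param marks GRanges of mark intervals.
#' @param mode "any" or "frac".
#' @param minFrac minimum covered fraction for mode "frac" (default 0.8).
#' @return List: \code{fraction} of peaks flagged and per-peak
#'   \code{flags}.
#' @export
markOverlap <- function(peaks, marks, mode = c("any", "frac"),
                        minFrac = 0.8) {
    mode <- match.arg(mode)
    if (mode == "any") {
        flags <- overlapsAny(peaks, marks, ignore.strand = TRUE)
    } else {
        cov <- numeric(length(peaks))
        hits <- findOverlaps(peaks, marks, ignore.strand = TRUE)
        if (length(hits)) {
            ## union of covering marks per peak, to avoid double counting
            pieces <- pintersect(peaks[queryHits(hits)],
                                 marks[subjectHits(hits)],
                                 ignore.strand = TRUE)
            covered <- tapply(seq_along(hits), queryHits(hits), function(i)
                sum(width(GenomicRanges::reduce(pieces[i], ignore.strand = TRUE))))
            cov[as.integer(names(covered))] <- covered
        }
        flags <- cov / width(peaks) >= minFrac
    }
    list(fraction = mean(flags), flags = flags)
}

#' Assign peaks to repeat categories
#'
#' Each peak is assigned to the overlapping repeat with the largest shared
#' length (ties broken in favour of young over inactive L1 families, then
#' first occurrence); the category is young_L1 / inactive_L1 when that
#' repeat's family is in the corresponding list, other_repeat for any other
#' overlap, and no_repeat otherwise.
#'
#' @param peaks GRanges of peaks.
#' @param repeats GRanges of repeat instances.
#' @param youngFamilies,inactiveFamilies family name lists (defaults:
#'   \code{youngL1Families()}, \code{inactiveL1Families()}).
#' @return List: \code{assignment} data.frame (per peak: category, family,
#'   overlap bp) and \code{summary} category counts.
#' @export
assignPeaks <- function(peaks, repeats,
                        youngFamilies = youngL1Families(),
                        inactiveFamilies = inactiveL1Families()) {
    n <- length(peaks)
    category <- rep("no_repeat", n)
    family <- rep(NA_character_, n)
    ov_bp <- rep(0L, n)
    hits <- findOverlaps(peaks, repeats, ignore.strand = TRUE)
    if (length(hits)) {
        shared <- width(pintersect(peaks[queryHits(hits)],
                                   repeats[subjectHits(hits)],
                                   ignore.strand = TRUE))
        fam <- repeats$family[subjectHits(hits)]
        ## rank: larger overlap first, young beats inactive on ties
        pref <- ifelse(fam %in% youngFamilies, 2L,
                       ifelse(fam %in% inactiveFamilies, 1L, 0L))
        ord <- order(queryHits(hits), -shared, -pref)
        first <- !duplicated(queryHits(hits)[ord])
        pick <- ord[first]
        qi <- queryHits(hits)[pick]
        family[qi] <- fam[pick]
        ov_bp[qi] <- shared[pick]
        category[qi] <- ifelse(fam[pick] %in% youngFamilies, "young_L1",
                        ifelse(fam[pick] %in% inactiveFamilies, "inactive_L1",
                               "other_repeat"))
    }
    assignment <- data.frame(peak = seq_len(n), category = category,
                             family = family, overlap_bp = ov_bp)
    summary <- table(factor(category, levels = c("young_L1", "inactive_L1",
                                                 "other_repeat", "no_repeat")))
    list(assignment = assignment, summary = summary)
}

.rpkm <- function(counts, lengths, total) {
    1e9 * counts / (lengths * total)
}

#' Family-level IP/input binding enrichment (RPKM ratios)
#'
#' Computes RPKM per family (reads per kb of consensus per million mapped
#' reads) for IP and input samples, averages replicates, and reports the
#' IP/input ratio. A 0.5-read pseudocount is added to every family in both
#' samples before the RPKM computation, so the ratio is defined for
#' zero-count families and biased against low-count false positives.
#' Families at or above \code{minRatio} (inclusive) form the selected
#' (bound) set.
#'
#' @param ip matrix (families x replicates) or vector of IP counts.
#' @param input matrix or vector of input counts, same family universe.
#' @param consensusLengths named vector of family consensus lengths (bp).
#' @param minRatio selection threshold on the ratio (default 4, inclusive).
#' @param totalIp,totalInput optional per-replicate totals of mapped reads
#'   (default: column sums).
#' @return data.frame per family (rpkm_ip, rpkm_input, ratio, selected)
#'   plus the selected family names as attribute "selected".
#' @export
bindingEnrichment <- function(ip, input, consensusLengths, minRatio = 4,
                              totalIp = NULL, totalInput = NULL) {
    ip <- as.matrix(ip); input <- as.matrix(input)
    if (is.null(rownames(ip)) || is.null(rownames(input)))
        stop("count matrices need family rownames", call. = FALSE)
    if (!setequal(rownames(ip), rownames(input)))
        stop("IP and input family universes differ", call. = FALSE)
    input <- input[rownames(ip), , drop = FALSE]
    len <- consensusLengths[rownames(ip)]
    if (anyNA(len)) stop("missing consensus lengths", call. = FALSE)
    if (is.null(totalIp)) totalIp <- colSums(ip)
    if (is.null(totalInput)) totalInput <- colSums(input)
    rpkm_ip <- rowMeans(sweep(.rpkm(ip + 0.5, len, 1), 2, totalIp, `/`))
    rpkm_in <- rowMeans(sweep(.rpkm(input + 0.5, len, 1), 2, totalInput, `/`))
    ratio <- rpkm_ip / rpkm_in
    out <- data.frame(family = rownames(ip), rpkm_ip = rpkm_ip,
                      rpkm_input = rpkm_in, ratio = ratio,
                      selected = ratio >= minRatio, row.names = NULL)
    attr(out, "selected") <- out$family[out$selected]
    out
}

#' Fraction of genes flanked by bound repeats, per category
#'
#' For each category (FAM208A-bound inactive L1s; ERVKs), the fraction of
#' genes in the set with at least one qualifying instance within \code{w}
#' bp of the gene span.
#'
#' @param gs gene set.
#' @param genes GRanges gene annotation.
#' @param repeats GRanges of repeat instances.
#' @param boundFamilies families called bound (e.g. from
#'   \code{bindingEnrichment}).
#' @param inactiveFamilies inactive L1 family list.
#' @param ervkFamilies ERVK family list.
#' @param w radius in bp (default 20000).
#' @return Named numeric: fraction with a bound inactive L1, fraction with
#'   an ERVK.
#' @export
flankingBindingFraction <- function(gs, genes, repeats, boundFamilies,
                                    inactiveFamilies = inactiveL1Families(),
                                    ervkFamilies, w = 20000) {
    fr <- function(fams) {
        if (!length(fams)) return(0)
        f <- repeatFilter(families = fams)
        genesWithRepeat(gs, genes, repeats, f, w)$count /
            length(if (is.list(gs)) gs$gene_ids else gs)
    }
    c(bound_inactive_l1 = fr(intersect(boundFamilies, inactiveFamilies)),
      ervk = fr(ervkFamilies))
}

#' Binned consensus coverage profile and 3'/5' ratio
#'
#' Averages a per-position coverage vector along a consensus into
#' \code{nBins} bins, normalizes to the profile mean, and reports the ratio
#' of the mean coverage of the 3' half to the 5' half (Inf-flagged when the
#' 5' half is empty). A 3'-skewed binding profile ("coating the 3' half")
#' gives a ratio above 1.
#'
#' @param coverage numeric vector of per-position coverage (5' to 3').
#' @param nBins number of bins (default 20).
#' @return List: \code{bins} (mean-normalized), \code{ratio} and
#'   \code{ratio_infinite} flag.
#' @export
consensusProfile <- function(coverage, nBins = 20) {
    L <- length(coverage)
    if (L < nBins) stop("coverage shorter than the bin count", call. = FALSE)
    idx <- ceiling(seq_along(coverage) / (L / nBins))
    bins <- as.numeric(tapply(coverage, idx, mean))
    m <- mean(coverage)
    bins <- if (m > 0) bins / m else bins
    half <- floor(L / 2)
    m5 <- mean(coverage[seq_len(half)])
    m3 <- mean(coverage[(half + 1):L])
    inf <- m5 == 0 && m3 > 0
    list(bins = bins, ratio = if (inf) Inf else m3 / m5,
         ratio_infinite = inf)
}
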