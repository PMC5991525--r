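## Family-level repeat expression analysis: derepression testing,
## co-repressed family intersection, read-fraction summaries, and family
## age / divergence classification.

#' Derepressed repeat families
#'
#' Runs the NB differential test on a family-level count table and selects
#' families up-regulated more than \code{foldMin}-fold (strict) at
#' significance \code{alpha}. Whether the threshold is applied to the raw or
#' the BH-adjusted p-value is configurable (\code{useAdjusted}, default
#' adjusted). Identically named duplicate features are summed before
#' testing.
#'
#' @param counts family-level count matrix or SummarizedExperiment.
#' @param group two-level sample labels (first level = control).
#' @param foldMin minimum fold change, strict (default 2).
#' @param alpha significance threshold (default 0.05).
#' @param useAdjusted apply alpha to padj (TRUE, default) or raw p.
#' @param label label for the returned set.
#' @return List with \code{families} (character vector), \code{label} and
#'   \code{de} (the full DE table). An empty selection is an empty set, not
#'   an error.
#' @export
derepressedFamilies <- function(counts, group, foldMin = 2, alpha = 0.05,
                                useAdjusted = TRUE, label = "derepressed") {
    m <- .asCountMatrix(counts)
    if (anyDuplicated(rownames(m)))
        m <- rowsum(m, rownames(m))
    de <- nbTest(m, group)
    crit <- if (useAdjusted) de$padj else de$p
    sel <- !is.na(de$log2fc) & de$log2fc > log2(foldMin) &
        !is.na(crit) & crit <= alpha
    list(families = de$feature[sel], label = label, de = de)
}

#' Intersect family (or gene) sets
#'
#' Set intersection with concatenated labels; commutative, associative and
#' idempotent in its members.
#'
#' @param setA,setB lists with \code{families} (or \code{gene_ids}) and
#'   \code{label}, or plain character vectors.
#' @return List with the intersected members and the combined label.
#' @export
intersectFamilySets <- function(setA, setB) {
    mem <- function(s) if (is.list(s)) (s$families %||% s$gene_ids) else s
    lab <- function(s, d) if (is.list(s) && !is.null(s$label)) s$label else d
    list(families = intersect(mem(setA), mem(setB)),
         label = paste(lab(setA, "A"), lab(setB, "B"), sep = " & "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage of reads mapping to repeats, by group
#'
#' @param repeatMapped integer vector, repeat-mapped reads per sample.
#' @param totalMapped integer vector, total mapped reads per sample.
#' @param group per-sample group labels.
#' @return data.frame per group: mean percent, spread (SD for n >= 3, SEM
#'   for n == 2, NA for n == 1) and the spread type used.
#' @export
percentReadsRepeats <- function(repeatMapped, totalMapped, group) {
    if (any(repeatMapped > totalMapped))
        stop("repeatMapped exceeds totalMapped", call. = FALSE)
    pct <- 100 * repeatMapped / totalMapped
    out <- lapply(split(pct, group), function(x) {
        n <- length(x)
        if (n >= 3) data.frame(mean = mean(x), spread = sd(x), type = "sd", n = n)
        else if (n == 2) data.frame(mean = mean(x), spread = sd(x) / sqrt(2),
                                    type = "sem", n = n)
        else data.frame(mean = mean(x), spread = NA_real_, type = "none", n = n)
    })
    cbind(group = names(out), do.call(rbind, out), row.names = NULL)
}

#' Fraction of families younger than an age cutoff
#'
#' Strict inequality: a family whose age equals the cutoff is counted as not
#' under it. Families without an age are excluded with a warning.
#'
#' @param families character vector of family names.
#' @param info familyInfo DataFrame (columns family, age_myr).
#' @param cutoffMyr age cutoff in Myr.
#' @return List: \code{fraction} (of age-bearing families strictly younger
#'   than the cutoff) and \code{table} (per-family age and under-cutoff
#'   flag).
#' @export
classifyFamilyAges <- function(families, info, cutoffMyr) {
    age <- info$age_myr[match(families, info$family)]
    miss <- is.na(age)
    if (any(miss))
        warning(sprintf("%d families without age excluded", sum(miss)))
    tab <- data.frame(family = families, age_myr = age,
                      under_cutoff = !miss & age < cutoffMyr)
    frac <- if (all(miss)) NA_real_ else sum(tab$under_cutoff) / sum(!miss)
    list(fraction = frac, table = tab)
}

#' Mean divergence per repeat family
#'
#' Arithmetic mean of per-instance percent divergence from the family
#' consensus; families with only missing divergence are omitted.
#'
#' @param repeats GRanges of repeat instances (mcols family, divergence).
#' @param families optional subset of families to report.
#' @return Named numeric vector of mean divergences, sorted ascending
#'   (youngest first).
#' @export
meanDivergence <- function(repeats, families = NULL) {
    df <- data.frame(family = repeats$family, div = repeats$divergence)
    if (!is.null(families)) df <- df[df$family %in% families, , drop = FALSE]
    df <- df[!is.na(df$div), , drop = FALSE]
    if (!nrow(df)) return(setNames(numeric(), character()))
    sort(tapply(df$div, df$family, mean))
}
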