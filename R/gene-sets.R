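## Co-repressed gene-set derivation, random backgrounds, peak-proximity
## fractions, and gene evolutionary-age classification.

#' Up-regulated genes from a differential-expression table
#'
#' Genes with fold change strictly above \code{foldMin} (so log2fc = 1
#' exactly is excluded at the default) and BH-adjusted p at or below
#' \code{fdr}.
#'
#' @param de data.frame as returned by \code{nbTest}.
#' @param foldMin minimum fold change, strict (default 2).
#' @param fdr adjusted-p threshold, inclusive (default 0.05).
#' @param label set label.
#' @return List with \code{gene_ids} and \code{label}.
#' @export
upregulatedGenes <- function(de, foldMin = 2, fdr = 0.05, label = "up") {
    sel <- !is.na(de$log2fc) & de$log2fc > log2(foldMin) &
        !is.na(de$padj) & de$padj <= fdr
    list(gene_ids = de$feature[sel], label = label)
}

#' Co-repressed genes: intersection of two up-regulated sets
#'
#' @param setA,setB gene sets (lists with gene_ids/label, or character
#'   vectors).
#' @return List with \code{gene_ids} and combined label.
#' @export
corepressedGenes <- function(setA, setB) {
    r <- intersectFamilySets(
        list(gene_ids = if (is.list(setA)) setA$gene_ids else setA,
             label = if (is.list(setA)) setA$label %||% "A" else "A"),
        list(gene_ids = if (is.list(setB)) setB$gene_ids else setB,
             label = if (is.list(setB)) setB$label %||% "B" else "B"))
    list(gene_ids = r$families, label = r$label)
}

#' Random gene background sets
#'
#' Samples \code{k} sets of \code{n} genes uniformly without replacement
#' from the annotation universe (disjointness across sets is not enforced).
#' Reproducible from the seed.
#'
#' @param universe character vector of gene ids (or GRanges with gene_id).
#' @param n genes per set (default 100).
#' @param k number of sets (default 3).
#' @param seed RNG seed.
#' @return List of k gene sets (lists with gene_ids, label).
#' @export
randomGeneSets <- function(universe, n = 100, k = 3, seed) {
    if (is(universe, "GRanges")) universe <- universe$gene_id
    if (length(universe) < n)
        stop("universe smaller than requested set size", call. = FALSE)
    set.seed(seed)
    lapply(seq_len(k), function(i)
        list(gene_ids = sample(universe, n), label = sprintf("random_%d", i)))
}

.resolveGenes <- function(gs, genes) {
    ids <- if (is.list(gs)) gs$gene_ids else gs
    idx <- match(ids, genes$gene_id)
    if (anyNA(idx))
        stop("gene ids not found in annotation: ",
             paste(head(ids[is.na(idx)]), collapse = ", "), call. = FALSE)
    genes[idx]
}

#' Fraction of a gene set with a peak within a radius
#'
#' @param gs gene set (gene_ids list or character vector).
#' @param genes GRanges gene annotation.
#' @param peaks GRanges of peaks.
#' @param w radius in bp (default 20000); at w = 0 a shared base is
#'   required.
#' @return Fraction of genes with at least one peak within w of the gene
#'   span.
#' @export
peakProximityFraction <- function(gs, genes, peaks, w = 20000) {
    g <- .resolveGenes(gs, genes)
    if (!length(g)) return(NA_real_)
    hit <- .flagNear(g, peaks, w)
    mean(hit)
}

## per-anchor flag: >= 1 subject within radius w (shared base at w = 0)
.flagNear <- function(anchors, subjects, w) {
    if (!length(subjects)) return(rep(FALSE, length(anchors)))
    maxgap <- if (w == 0) -1L else as.integer(w)
    overlapsAny(anchors, subjects, maxgap = maxgap, ignore.strand = TRUE)
}

#' Conservation split of a gene set
#'
#' A gene is conserved iff its conservation score is at least
#' \code{threshold} (inclusive). Genes without a score are excluded and
#' reported.
#'
#' @param gs gene set.
#' @param genes GRanges gene annotation with a conservation mcol.
#' @param threshold conservation threshold (default 0.8).
#' @return List: counts (conserved, nonconserved, unscored), fractions over
#'   scored genes (summing to 1).
#' @export
conservationSplit <- function(gs, genes, threshold = 0.8) {
    g <- .resolveGenes(gs, genes)
    sc <- g$conservation
    unscored <- sum(is.na(sc))
    cons <- sum(!is.na(sc) & sc >= threshold)
    noncons <- sum(!is.na(sc) & sc < threshold)
    n <- cons + noncons
    list(conserved = cons, nonconserved = noncons, unscored = unscored,
         fraction_conserved = if (n) cons / n else NA_real_,
         fraction_nonconserved = if (n) noncons / n else NA_real_)
}

#' Conservation enrichment of a gene set against a background set
#'
#' One-sided Fisher test for over-representation of non-conserved genes in
#' the test set versus the background.
#'
#' @inheritParams conservationSplit
#' @param bg background gene set.
#' @return List with the 2x2 counts, the two non-conserved fractions and
#'   the one-sided p-value.
#' @export
conservationEnrichment <- function(gs, bg, genes, threshold = 0.8) {
    s <- conservationSplit(gs, genes, threshold)
    b <- conservationSplit(bg, genes, threshold)
    p <- fisherOneSided(s$nonconserved, s$conserved,
                        b$nonconserved, b$conserved)
    list(set = s, background = b, p = p)
}

#' Last-common-ancestor clade enrichment
#'
#' For each clade, a one-sided Fisher test of over-representation of the
#' clade in the gene set against the rest of the genome, with BH adjustment
#' across clades. Genome composition is given either by a named count
#' vector or derived from the annotation.
#'
#' @param gs gene set.
#' @param genes GRanges gene annotation with an lca_clade mcol.
#' @param genomeCounts optional named vector of per-clade genome gene
#'   counts (defaults to the annotation tally).
#' @return data.frame per clade: set and genome counts and fractions, p,
#'   padj.
#' @export
lcaEnrichment <- function(gs, genes, genomeCounts = NULL) {
    g <- .resolveGenes(gs, genes)
    lab <- g$lca_clade
    if (anyNA(lab)) {
        warning(sprintf("%d genes without LCA label excluded", sum(is.na(lab))))
        lab <- lab[!is.na(lab)]
    }
    if (is.null(genomeCounts)) {
        all_lab <- genes$lca_clade
        genomeCounts <- table(all_lab[!is.na(all_lab)])
    }
    clades <- names(genomeCounts)
    n_set <- length(lab)
    n_genome <- sum(genomeCounts)
    rows <- lapply(clades, function(cl) {
        a <- sum(lab == cl)                      # set, in clade
        b <- n_set - a                           # set, other clade
        cc <- max(genomeCounts[[cl]] - a, 0)     # rest of genome, in clade
        d <- max((n_genome - genomeCounts[[cl]]) - b, 0)
        data.frame(clade = cl, set_count = a, set_fraction = a / n_set,
                   genome_count = as.integer(genomeCounts[[cl]]),
                   genome_fraction = genomeCounts[[cl]] / n_genome,
                   p = fisherOneSided(a, b, cc, d))
    })
    out <- do.call(rbind, rows)
    out$padj <- bhAdjust(out$p)
    out
}

#' Fraction of protein-coding genes in a set
#'
#' @param gs gene set.
#' @param genes GRanges gene annotation with a biotype mcol.
#' @return Fraction of genes with biotype protein_coding.
#' @export
biotypeFraction <- function(gs, genes) {
    g <- .resolveGenes(gs, genes)
    if (!length(g)) return(NA_real_)
    mean(g$biotype == "protein_coding")
}
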