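## Synthetic genome annotations, count matrices and ChIP peak sets with
## planted ground truth. The generator emulates the statistical structure
## the analysis assumes -- spatial enrichment of young L1s near a target
## gene subset, NB counts with planted derepression, replicate peaks
## tethered to ERVK/inactive-L1 copies, and a sense-orientation bias of
## upstream LTRs -- so that every downstream statistic can be checked
## against a known truth record.

#' Default repeat-family metadata table
#'
#' Ships a small mouse-flavoured family table covering the family groups the
#' analysis distinguishes: the five young (active, < 5 Myr) L1 subfamilies,
#' eight inactive L1 families (>= 13 Myr, present before the mouse-rat
#' split), ERVK families, a satellite, solo-LTR promoter families and a
#' SINE. Ages and consensus lengths are representative placeholder values
#' for testing and are user-replaceable via \code{readFamilyInfo}.
#'
#' @return DataFrame with columns family, repclass, superfamily, age_myr,
#'   active, consensus_length.
#' @export
defaultFamilyInfo <- function() {
    DataFrame(
        family = c("L1Md_A", "L1Md_T", "L1Md_F", "L1Md_F2", "L1Md_F3",
                   "L1_Rod", "L1MB7", "L1_Mur1", "L1_Mur2", "L1_Mur3",
                   "Lx8", "Lx9", "Lx10",
                   "IAPEz", "ETnERV2", "RLTR10",
                   "GSAT_MM",
                   "RLTR9", "ORR1A0", "MT2_Mm",
                   "B1_Mm"),
        repclass = c(rep("LINE", 13), rep("LTR", 3), "Satellite",
                     rep("LTR", 3), "SINE"),
        superfamily = c(rep("L1", 13), rep("ERVK", 3), "Satellite",
                        rep("LTR_other", 3), "Alu"),
        age_myr = c(1.5, 2, 3.5, 3, 4.5,
                    13.5, 30, 16, 18, 20, 25, 28, 32,
                    1, 2.5, 6, NA,
                    8, 10, 12, 25),
        active = c(rep(TRUE, 5), rep(FALSE, 8), TRUE, TRUE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE),
        consensus_length = c(6700, 6500, 6800, 6700, 6600,
                             rep(6000, 8), 7000, 5500, 500, 1000,
                             350, 350, 500, 150))
}

#' Young and inactive L1 family name lists
#'
#' The young, still-active mouse L1 subfamilies and the inactive L1
#' families used throughout the peak-assignment and flanking analyses.
#' @return Character vector of family names.
#' @export
youngL1Families <- function()
    c("L1Md_F", "L1Md_F2", "L1Md_F3", "L1Md_A", "L1Md_T")

#' @rdname youngL1Families
#' @export
inactiveL1Families <- function()
    c("L1_Rod", "L1MB7", "L1_Mur1", "L1_Mur2", "L1_Mur3", "Lx8", "Lx9", "Lx10")

#' Simulation parameters
#'
#' All knobs of the synthetic-data generator. Defaults encode the effect
#' sizes the analysis is designed around: a 7-fold young-L1 density
#' multiplier in the 20-kb flanks of target genes, a 0.69 sense-orientation
#' probability for upstream LTRs of target genes (0.5 elsewhere), a 0.34
#' H3K9me3 co-placement probability for true ChIP peaks, NB dispersion 0.1,
#' 41\%/14\% non-conserved and 11.8\%/0.9\% mouse-specific gene fractions in
#' the target/background groups.
#'
#' @slot seed integer RNG seed (mandatory).
#' @slot nChroms,chromLen genome shape.
#' @slot nGenes,geneLenRange gene count and length range (bp).
#' @slot targetFraction fraction of genes receiving planted structure.
#' @slot repeatRates named per-bp Poisson densities per family.
#' @slot plantedEnrichmentFold young-L1 density multiplier in target flanks.
#' @slot flankWidth flank half-width for planting (bp).
#' @slot nbDispersion NB dispersion of simulated counts.
#' @slot peakTetherProb probability a true peak sits on an ERVK/inactive L1.
#' @slot h3k9me3OverlapProb probability a true peak gets a co-placed mark.
#' @slot senseBias P(upstream LTR of a target gene is sense).
#' @slot upstreamLtrMean mean planted LTRs per 3-kb upstream region.
#' @slot upstreamLen upstream region length (bp).
#' @slot nTruePeaks,nSpuriousPerRep,nInputPeaks,peakWidth,peakJitter peak-set shape.
#' @slot targetNonconservedProb,bgNonconservedProb P(gene non-conserved).
#' @slot targetMouseSpecificProb,bgMouseSpecificProb P(mouse-specific LCA).
#' @export
setClass("SimParams", representation(
    seed = "integer", nChroms = "integer", chromLen = "numeric",
    nGenes = "integer", geneLenRange = "numeric", targetFraction = "numeric",
    repeatRates = "numeric", plantedEnrichmentFold = "numeric",
    flankWidth = "numeric", nbDispersion = "numeric",
    peakTetherProb = "numeric", h3k9me3OverlapProb = "numeric",
    senseBias = "numeric", upstreamLtrMean = "numeric", upstreamLen = "numeric",
    nTruePeaks = "integer", nSpuriousPerRep = "integer",
    nInputPeaks = "integer", peakWidth = "numeric", peakJitter = "numeric",
    targetNonconservedProb = "numeric", bgNonconservedProb = "numeric",
    targetMouseSpecificProb = "numeric", bgMouseSpecificProb = "numeric"))

setValidity("SimParams", function(object) {
    msg <- character()
    pr <- c(object@targetFraction, object@peakTetherProb,
            object@h3k9me3OverlapProb, object@senseBias,
            object@targetNonconservedProb, object@bgNonconservedProb,
            object@targetMouseSpecificProb, object@bgMouseSpecificProb)
    if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0,1]")
    if (any(object@repeatRates <= 0)) msg <- c(msg, "repeat rates must be positive")
    if (object@plantedEnrichmentFold < 1) msg <- c(msg, "enrichment fold must be >= 1")
    if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
    if (!length(object@seed) || is.na(object@seed))
        msg <- c(msg, "seed is mandatory")
    if (length(msg)) msg else TRUE
})

.defaultRepeatRates <- function() {
    c(L1Md_A = 2.5e-07, L1Md_T = 2.5e-07, L1Md_F = 2.5e-07, L1Md_F2 = 2.5e-07,
      L1Md_F3 = 2.5e-07,
      L1_Rod = 2e-06, L1MB7 = 2e-06, L1_Mur1 = 2e-06, L1_Mur2 = 2e-06,
      L1_Mur3 = 2e-06, Lx8 = 2e-06, Lx9 = 2e-06, Lx10 = 2e-06,
      IAPEz = 1.5e-06, ETnERV2 = 1e-06, RLTR10 = 1e-06,
      GSAT_MM = 5e-07,
      RLTR9 = 1e-06, ORR1A0 = 1e-06, MT2_Mm = 1e-06,
      B1_Mm = 4e-06)
}

#' Construct simulation parameters
#'
#' @param seed integer RNG seed.
#' @param ... named overrides of any \linkS4class{SimParams} slot.
#' @return Validated SimParams.
#' @examples
#' simParams(seed = 1, nGenes = 200L, nChroms = 1L)
#' @export
simParams <- function(seed, ...) {
    args <- list(...)
    defaults <- list(
        nChroms = 4L, chromLen = 1.5e7, nGenes = 1000L,
        geneLenRange = c(2000, 8000), targetFraction = 0.094,
        repeatRates = .defaultRepeatRates(), plantedEnrichmentFold = 7,
        flankWidth = 20000, nbDispersion = 0.1,
        peakTetherProb = 0.9, h3k9me3OverlapProb = 0.34, senseBias = 0.69,
        upstreamLtrMean = 4, upstreamLen = 3000,
        nTruePeaks = 1000L, nSpuriousPerRep = 150L, nInputPeaks = 100L,
        peakWidth = 600, peakJitter = 200,
        targetNonconservedProb = 0.41, bgNonconservedProb = 0.14,
        targetMouseSpecificProb = 0.118, bgMouseSpecificProb = 0.009)
    defaults[names(args)] <- args
    for (f in c("nChroms", "nGenes", "nTruePeaks", "nSpuriousPerRep",
                "nInputPeaks"))
        defaults[[f]] <- as.integer(defaults[[f]])
    do.call(new, c(list("SimParams", seed = as.integer(seed)), defaults))
}

.LCA_CLADES <- c("Mus musculus", "Mus", "Murinae", "Rodentia",
                 "Euarchontoglires", "Eutheria", "Theria", "Vertebrata")

## place k non-overlapping intervals of the given lengths uniformly on
## [1, chromLen] by partitioning the leftover space with a uniform stick
.placeNonOverlapping <- function(k, lens, chromLen) {
    if (k == 0) return(IRanges())
    free <- chromLen - sum(lens)
    if (free <= k)
        stop("densities imply overlap saturation on a chromosome", call. = FALSE)
    gaps <- diff(c(0, sort(runif(k, 0, free)), free))[seq_len(k)]
    starts <- cumsum(gaps) + cumsum(c(0, lens[-k])) + 1
    starts <- pmin(round(starts), chromLen - lens + 1)
    IRanges(starts, width = lens)
}

#' Simulate a genome annotation with planted structure
#'
#' Places genes uniformly without overlap, repeats by a per-family Poisson
#' process, multiplies the young-L1 density in the +/- \code{flankWidth}
#' flanks of a random target-gene subset by \code{plantedEnrichmentFold},
#' plants Poisson-many promoter LTRs in each gene's upstream region with a
#' sense bias for target genes, and assigns conservation / LCA / biotype
#' labels with target-vs-background composition given by the parameters.
#' Fully reproducible from the seed.
#'
#' @param params A \linkS4class{SimParams} object.
#' @return List with elements \code{bundle} (\linkS4class{AnnotationBundle})
#'   and \code{truth} (target gene ids, planted repeat flags, upstream-LTR
#'   orientation truth).
#' @export
simulateAnnotation <- function(params) {
    stopifnot(is(params, "SimParams"))
    set.seed(params@seed)
    fi <- defaultFamilyInfo()
    chroms <- paste0("chr", seq_len(params@nChroms))
    cs <- setNames(rep(params@chromLen, params@nChroms), chroms)

    ## --- genes ---
    ngc <- as.vector(stats::rmultinom(1, params@nGenes,
                                      rep(1 / params@nChroms, params@nChroms)))
    glens <- round(runif(params@nGenes, params@geneLenRange[1],
                         params@geneLenRange[2]))
    gr_list <- list(); off <- 0
    for (i in seq_along(chroms)) {
        k <- ngc[i]
        if (k == 0) next
        ir <- .placeNonOverlapping(k, glens[off + seq_len(k)], params@chromLen)
        gr_list[[i]] <- GRanges(factor(chroms[i], levels = chroms), ir,
                                strand = sample(c("+", "-"), k, replace = TRUE))
        off <- off + k
    }
    genes <- sort(do.call(c, gr_list), ignore.strand = TRUE)
    n <- length(genes)
    genes$gene_id <- sprintf("g%04d", seq_len(n))
    genes$symbol <- toupper(genes$gene_id)
    genes$biotype <- sample(c("protein_coding", "other"), n, replace = TRUE,
                            prob = c(0.72, 0.28))
    n_target <- round(params@targetFraction * n)
    target_ids <- sort(sample(genes$gene_id, n_target))
    is_target <- genes$gene_id %in% target_ids
    p_nc <- ifelse(is_target, params@targetNonconservedProb,
                   params@bgNonconservedProb)
    noncons <- runif(n) < p_nc
    genes$conservation <- ifelse(noncons, runif(n, 0, 0.79), runif(n, 0.8, 1))
    p_ms <- ifelse(is_target, params@targetMouseSpecificProb,
                   params@bgMouseSpecificProb)
    ms <- runif(n) < p_ms
    genes$lca_clade <- ifelse(ms, "Mus musculus",
                              sample(.LCA_CLADES[-1], n, replace = TRUE))
    suppressWarnings(seqlengths(genes) <- cs)

    ## --- background repeats: independent Poisson process per family ---
    rates <- params@repeatRates
    fam_meta <- fi[match(names(rates), fi$family), ]
    total_len <- sum(cs)
    rep_list <- list()
    for (j in seq_along(rates)) {
        fam <- names(rates)[j]
        k <- rpois(1, rates[j] * total_len)
        if (k == 0) next
        rep_list[[fam]] <- .drawRepeats(fam, fam_meta[j, ], k, cs)
    }
    repeats <- do.call(c, unname(rep_list))
    repeats$planted <- FALSE
    repeats$promoter_of <- NA_character_

    ## --- planted young-L1 flank enrichment around target genes ---
    young <- youngL1Families()
    y_rates <- rates[young]
    tg <- genes[is_target]
    ## flanks may poke past chromosome ends before trimming
    fl <- suppressWarnings(GenomicRanges::trim(c(
        GenomicRanges::flank(tg, params@flankWidth, start = TRUE,
                             ignore.strand = TRUE),
        GenomicRanges::flank(tg, params@flankWidth, start = FALSE,
                             ignore.strand = TRUE))))
    fl <- fl[width(fl) > 0]
    extra_rate <- sum(y_rates) * (params@plantedEnrichmentFold - 1)
    k_extra <- rpois(length(fl), extra_rate * width(fl))
    fidx <- rep(seq_along(fl), k_extra)
    if (length(fidx)) {
        fams <- sample(young, length(fidx), replace = TRUE,
                       prob = y_rates / sum(y_rates))
        planted <- lapply(unique(fams), function(fam) {
            sel <- fams == fam
            .drawRepeats(fam, fi[fi$family == fam, ], sum(sel), cs,
                         within = fl[fidx[sel]])
        })
        pg <- do.call(c, unname(planted))
        pg$planted <- TRUE
        pg$promoter_of <- NA_character_
        repeats <- c(repeats, pg)
    }

    ## --- upstream promoter LTRs with planted sense bias ---
    up <- upstreamRegion(genes, params@upstreamLen, chromLen = cs)
    usable <- !up$clipped_empty & width(up) >= 700
    n_up <- rpois(n, params@upstreamLtrMean) * usable
    ltr_fams <- c("RLTR9", "ORR1A0", "MT2_Mm")
    gidx <- rep(seq_len(n), n_up)
    sense_truth <- NULL
    if (length(gidx)) {
        k <- length(gidx)
        len <- round(runif(k, 300, 600))
        st <- round(runif(k, start(up)[gidx], end(up)[gidx] - len))
        sense <- runif(k) < ifelse(is_target[gidx], params@senseBias, 0.5)
        gstrand <- as.character(strand(genes))[gidx]
        rstrand <- ifelse(sense, gstrand, chartr("+-", "-+", gstrand))
        g <- GRanges(factor(as.character(seqnames(genes))[gidx],
                            levels = chroms),
                     IRanges(st, width = len),
                     strand = rstrand,
                     family = sample(ltr_fams, k, replace = TRUE),
                     repclass = "LTR",
                     divergence = round(runif(k, 5, 20), 2),
                     planted = FALSE, promoter_of = genes$gene_id[gidx])
        repeats <- c(repeats, g)
        sense_truth <- data.frame(gene_id = genes$gene_id[gidx], sense = sense)
    }
    repeats <- sort(repeats, ignore.strand = TRUE)
    suppressWarnings(seqlengths(repeats) <- cs)
    repeats <- GenomicRanges::trim(repeats)

    bundle <- AnnotationBundle(genes = genes, repeats = repeats,
                               familyInfo = fi, chromSizes = cs)
    truth <- list(
        target_genes = target_ids,
        planted_repeats = which(repeats$planted),
        upstream_ltr = sense_truth,
        params = params)
    list(bundle = bundle, truth = truth)
}

## draw k instances of one family, uniform on the genome (or within a
## given region), with family-appropriate length and divergence
.drawRepeats <- function(fam, meta, k, chromSizes, within = NULL) {
    cons <- meta$consensus_length
    if (meta$repclass == "LINE") {
        full <- runif(k) < 0.2
        len <- ifelse(full, round(runif(k, 5001, cons)),
                      round(runif(k, 500, 4500)))
    } else if (meta$repclass %in% c("LTR", "SINE")) {
        len <- round(runif(k, 0.3, 1) * cons)
    } else {
        len <- round(runif(k, 500, 5000))
    }
    len <- pmax(len, 50)
    age <- if (is.na(meta$age_myr)) 10 else meta$age_myr
    div <- pmax(0.05, rnorm(k, mean = min(age, 30), sd = 0.5))
    if (is.null(within)) {
        chrom <- sample(names(chromSizes), k, replace = TRUE,
                        prob = chromSizes / sum(chromSizes))
        st <- round(runif(k, 1, chromSizes[chrom] - len))
    } else {
        ## `within` is a GRanges parallel to the k draws
        chrom <- as.character(seqnames(within))
        st <- round(runif(k, start(within), pmax(start(within),
                                                 end(within) - len)))
    }
    st <- pmax(pmin(st, chromSizes[chrom] - 49), 1)
    len <- pmax(pmin(len, chromSizes[chrom] - st + 1), 50)
    GRanges(factor(chrom, levels = names(chromSizes)),
            IRanges(st, width = len),
            strand = sample(c("+", "-"), k, replace = TRUE),
            family = fam, repclass = meta$repclass,
            divergence = round(div, 2))
}

#' Simulate an NB count matrix with planted effects
#'
#' Draws negative-binomial counts for the given features in a two-group
#' design (control vs treatment), applying a planted log2 fold change to the
#' treatment group and per-sample depth factors that act as true size
#' factors.
#'
#' @param params SimParams (seed and nbDispersion are used).
#' @param features character vector of feature names.
#' @param plantedLog2fc named numeric of planted log2 fold changes
#'   (treatment over control); features absent from it are null.
#' @param nPerGroup samples per group (default 3).
#' @param baseMean optional named per-feature base means; by default drawn
#'   log-normally around 200.
#' @param depths optional per-sample depth factors (length 2*nPerGroup).
#' @param seedOffset added to the seed so several matrices can be drawn
#'   from one parameter set independently.
#' @return List with \code{se} (SummarizedExperiment, colData group =
#'   ctrl/treat) and \code{truth} (planted fold changes, base means,
#'   depths).
#' @export
simulateCounts <- function(params, features, plantedLog2fc = numeric(),
                           nPerGroup = 3, baseMean = NULL, depths = NULL,
                           seedOffset = 1L) {
    stopifnot(is(params, "SimParams"))
    set.seed(params@seed + seedOffset)
    nf <- length(features)
    ns <- 2 * nPerGroup
    if (is.null(baseMean))
        baseMean <- setNames(rlnorm(nf, log(200), 1), features)
    if (is.null(depths))
        depths <- runif(ns, 0.7, 1.3)
    lfc <- setNames(rep(0, nf), features)
    lfc[names(plantedLog2fc)] <- plantedLog2fc
    group <- rep(c("ctrl", "treat"), each = nPerGroup)
    mu <- outer(baseMean, depths) *
        2^outer(lfc, as.numeric(group == "treat"))
    m <- matrix(rnbinom(nf * ns, mu = mu, size = 1 / params@nbDispersion),
                nrow = nf,
                dimnames = list(features,
                                paste0(group, "_", rep(seq_len(nPerGroup), 2))))
    se <- countTable(m, group = group)
    list(se = se,
         truth = list(planted = plantedLog2fc, base_mean = baseMean,
                      depths = depths))
}

#' Simulate replicate ChIP peak sets with planted structure
#'
#' True peaks are tethered to ERVK or inactive-L1 repeat instances with
#' probability \code{peakTetherProb} (uniform genome placement otherwise),
#' jittered independently per replicate by up to \code{peakJitter} bp per
#' endpoint, and co-placed with an H3K9me3 interval with probability
#' \code{h3k9me3OverlapProb}. Per-replicate spurious peaks and input-only
#' peaks are added on top.
#'
#' @param params SimParams.
#' @param bundle AnnotationBundle providing repeats and chromosome sizes.
#' @return List with rep1, rep2, input, h3k9me3 (GRanges) and truth
#'   (true peaks, tether index or NA, mark-assignment flags).
#' @export
simulatePeaks <- function(params, bundle) {
    stopifnot(is(params, "SimParams"), is(bundle, "AnnotationBundle"))
    set.seed(params@seed + 2L)
    cs <- chromSizes(bundle)
    rp <- repeats(bundle)
    fi <- familyInfo(bundle)
    ervk <- fi$family[fi$superfamily %in% "ERVK"]
    tether_pool <- which(rp$family %in% c(ervk, inactiveL1Families()))
    if (!length(tether_pool))
        stop("no ERVK or inactive-L1 instances to tether peaks to", call. = FALSE)
    nP <- params@nTruePeaks
    w <- params@peakWidth
    tethered <- runif(nP) < params@peakTetherProb
    ## tether without replacement when the pool allows, so that co-placed
    ## marks stay specific to their own peak
    picks <- sample(tether_pool, min(nP, length(tether_pool)),
                    replace = length(tether_pool) < nP)
    idx <- rep(NA_integer_, nP)
    idx[tethered] <- rep_len(picks, sum(tethered))
    chrom <- character(nP); center <- numeric(nP)
    for (i in seq_len(nP)) {
        if (tethered[i]) {
            r <- rp[idx[i]]
            chrom[i] <- as.character(seqnames(r))
            center[i] <- round(runif(1, start(r), end(r)))
        } else {
            chrom[i] <- sample(names(cs), 1, prob = cs / sum(cs))
            center[i] <- round(runif(1, w, cs[chrom[i]] - w))
        }
    }
    true_peaks <- GRanges(factor(chrom, levels = names(cs)),
                          IRanges(pmax(1, round(center - w / 2)), width = w))
    jitterPeaks <- function(x) {
        s <- start(x) + round(runif(length(x), 0, params@peakJitter)) *
            sample(c(-1, 1), length(x), replace = TRUE)
        e <- end(x) + round(runif(length(x), 0, params@peakJitter)) *
            sample(c(-1, 1), length(x), replace = TRUE)
        s <- pmax(1, s)
        e <- pmin(pmax(s + 50, e), cs[as.character(seqnames(x))])
        GRanges(seqnames(x), IRanges(s, e))
    }
    spurious <- function(k) {
        chrom <- sample(names(cs), k, replace = TRUE, prob = cs / sum(cs))
        st <- round(runif(k, 1, cs[chrom] - w))
        GRanges(factor(chrom, levels = names(cs)), IRanges(st, width = w))
    }
    rep1 <- c(jitterPeaks(true_peaks), spurious(params@nSpuriousPerRep))
    rep2 <- c(jitterPeaks(true_peaks), spurious(params@nSpuriousPerRep))
    input <- spurious(params@nInputPeaks)
    has_mark <- runif(nP) < params@h3k9me3OverlapProb
    mk_st <- pmax(1, round(center[has_mark] - 500))
    mk_en <- pmin(mk_st + 999, cs[chrom[has_mark]])
    marks_on <- GRanges(factor(chrom[has_mark], levels = names(cs)),
                        IRanges(mk_st, mk_en))
    marks_bg <- spurious(100L)
    h3k9me3 <- sort(c(marks_on, marks_bg), ignore.strand = TRUE)
    withLen <- function(x) {
        suppressWarnings(seqlengths(x)[names(cs)] <- cs)
        x
    }
    list(rep1 = withLen(sort(rep1, ignore.strand = TRUE)),
         rep2 = withLen(sort(rep2, ignore.strand = TRUE)),
         input = withLen(input), h3k9me3 = withLen(h3k9me3),
         truth = list(true_peaks = true_peaks, tether_index = idx,
                      tethered = tethered, has_mark = has_mark))
}

#' Write a complete synthetic fixture directory
#'
#' Generates the annotation, two knockdown gene-count matrices and two
#' family-count matrices (both with planted up-regulation of the target
#' genes / young-L1 and ERVK families), replicate peak sets, and writes all
#' of them plus a pipeline config and a YAML truth record into \code{dir}.
#'
#' @param params SimParams.
#' @param dir output directory (created).
#' @param geneLog2fc planted gene log2 fold change (default 2).
#' @param familyLog2fc planted family log2 fold change (default 3).
#' @return Invisibly, the list of generated objects (bundle, counts, peaks,
#'   truth, config).
#' @export
simulateFixture <- function(params, dir, geneLog2fc = 2, familyLog2fc = 3) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ann <- simulateAnnotation(params)
    bundle <- ann$bundle
    fi <- familyInfo(bundle)
    target <- ann$truth$target_genes

    gene_lfc <- setNames(rep(geneLog2fc, length(target)), target)
    gc1 <- simulateCounts(params, genes(bundle)$gene_id, gene_lfc,
                          seedOffset = 11L)
    gc2 <- simulateCounts(params, genes(bundle)$gene_id, gene_lfc,
                          seedOffset = 12L)
    ervk <- fi$family[fi$superfamily %in% "ERVK"]
    dere <- c(youngL1Families(), ervk, "GSAT_MM")
    fam_lfc <- setNames(rep(familyLog2fc, length(dere)), dere)
    fc1 <- simulateCounts(params, fi$family, fam_lfc, seedOffset = 13L)
    fc2 <- simulateCounts(params, fi$family, fam_lfc, seedOffset = 14L)
    pk <- simulatePeaks(params, bundle)

    writeGeneTable(genes(bundle), file.path(dir, "genes.tsv"))
    writeRepeatTable(repeats(bundle), file.path(dir, "repeats.tsv"))
    writeFamilyInfo(fi, file.path(dir, "family_info.tsv"))
    write.table(data.frame(chrom = names(chromSizes(bundle)),
                           length = as.integer(chromSizes(bundle))),
                file.path(dir, "chrom_sizes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeCountTable(gc1$se, file.path(dir, "gene_counts_trim28.tsv"))
    writeCountTable(gc2$se, file.path(dir, "gene_counts_fam208a.tsv"))
    writeCountTable(fc1$se, file.path(dir, "family_counts_trim28.tsv"))
    writeCountTable(fc2$se, file.path(dir, "family_counts_fam208a.tsv"))
    for (nm in c("rep1", "rep2", "input", "h3k9me3"))
        writeBed(pk[[nm]], file.path(dir, paste0("peaks_", nm, ".bed")))
    cfg <- pipelineConfig(dir = dir, seed = params@seed)
    cfg_out <- cfg
    for (f in c("gene_counts", "family_counts", "peaks"))
        cfg_out[[f]] <- as.list(cfg_out[[f]])  # keep names through YAML
    yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
    yaml::write_yaml(list(target_genes = target,
                          derepressed_families = dere,
                          n_true_peaks = params@nTruePeaks,
                          sense_bias = params@senseBias),
                     file.path(dir, "truth.yaml"))
    invisible(list(bundle = bundle, truth = ann$truth,
                   gene_counts = list(trim28 = gc1, fam208a = gc2),
                   family_counts = list(trim28 = fc1, fam208a = fc2),
                   peaks = pk, config = cfg))
}
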