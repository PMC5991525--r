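## End-to-end orchestration: a validated config, a driver that runs every
## stage on a fixture directory, TSV artifacts and a machine-readable JSON
## summary keyed by analysis names.

#' Default pipeline configuration
#'
#' All thresholds default to the values the analysis is built around:
#' fold > 2 and FDR 0.05 for differential selection, distance windows 0/5/20
#' kb, 50-kb peak clustering, 3-kb upstream regions, 0.8 conservation,
#' 4-fold binding ratio, 5-kb full-length L1s, 3 and 5 Myr age cutoffs, and
#' the young/inactive L1 family lists.
#'
#' @param dir fixture directory holding the standard file names written by
#'   \code{simulateFixture} (individual paths can be overridden).
#' @param seed RNG seed for the random background sets.
#' @param ... overrides of any config field.
#' @return Named list, validated.
#' @export
pipelineConfig <- function(dir = ".", seed = 1L, ...) {
    cfg <- list(
        dir = dir, seed = as.integer(seed),
        genes = "genes.tsv", repeats = "repeats.tsv",
        family_info = "family_info.tsv", chrom_sizes = "chrom_sizes.tsv",
        gene_counts = c(trim28 = "gene_counts_trim28.tsv",
                        fam208a = "gene_counts_fam208a.tsv"),
        family_counts = c(trim28 = "family_counts_trim28.tsv",
                          fam208a = "family_counts_fam208a.tsv"),
        peaks = c(rep1 = "peaks_rep1.bed", rep2 = "peaks_rep2.bed",
                  input = "peaks_input.bed", h3k9me3 = "peaks_h3k9me3.bed"),
        fold = 2, fdr = 0.05, use_adjusted = TRUE,
        windows = c(0, 5000, 20000), cluster_d = 50000, upstream = 3000,
        conservation = 0.8, binding_ratio = 4, full_length = 5000,
        age_cutoffs = c(3, 5), n_random = 100, k_random = 3,
        young_l1 = youngL1Families(), inactive_l1 = inactiveL1Families())
    over <- list(...)
    cfg[names(over)] <- over
    validatePipelineConfig(cfg)
}

#' @rdname pipelineConfig
#' @param cfg config list to validate.
#' @export
validatePipelineConfig <- function(cfg) {
    num_pos <- c("fold", "fdr", "cluster_d", "upstream", "conservation",
                 "binding_ratio", "full_length")
    for (f in num_pos)
        if (is.null(cfg[[f]]) || !is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0))
            stop("config field must be positive: ", f, call. = FALSE)
    if (!length(cfg$young_l1) || !length(cfg$inactive_l1))
        stop("family lists (young_l1, inactive_l1) must be non-empty",
             call. = FALSE)
    if (any(cfg$windows < 0) || any(cfg$age_cutoffs <= 0))
        stop("windows must be >= 0 and age cutoffs > 0", call. = FALSE)
    cfg
}

.cfgPath <- function(cfg, x) file.path(cfg$dir, x)

#' Run the full analysis pipeline
#'
#' Reads the annotation, count tables and peak sets named in the config,
#' then runs every stage: gene-level NB tests for the two knockdowns and
#' their co-repressed intersection; random background sets; conservation,
#' LCA and biotype composition; family-level derepression and co-repressed
#' family intersection with age classification; young-L1 proximity
#' enrichment at the configured windows; the upstream-LTR orientation-bias
#' test; reproducible-peak filtering, clustering, H3K9me3 overlap at both
#' stringencies, and peak-to-repeat assignment. Writes per-stage TSVs and a
#' JSON summary into \code{outDir} and returns the summary invisibly.
#' Deterministic given the config seed.
#'
#' @param cfg config list from \code{pipelineConfig} or
#'   \code{readPipelineConfig}.
#' @param outDir output directory (default: \code{file.path(cfg$dir,
#'   "report")}).
#' @return Invisibly, the summary list written to summary.json.
#' @export
runPipeline <- function(cfg, outDir = file.path(cfg$dir, "report")) {
    cfg <- validatePipelineConfig(cfg)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    log <- function(...) message("[pipeline] ", sprintf(...))

    log("reading annotation from %s", cfg$dir)
    genes_gr <- readGeneTable(.cfgPath(cfg, cfg$genes))
    repeats_gr <- readRepeatTable(.cfgPath(cfg, cfg$repeats))
    fi <- readFamilyInfo(.cfgPath(cfg, cfg$family_info))
    cs_df <- read.delim(.cfgPath(cfg, cfg$chrom_sizes))
    cs <- setNames(cs_df$length, cs_df$chrom)
    suppressWarnings(seqlengths(genes_gr)[names(cs)] <- cs)
    bundle <- AnnotationBundle(genes_gr, repeats_gr, fi, cs)

    ## sample groups are encoded in the column names as <group>_<replicate>
    groupsOf <- function(se)
        sub("_[0-9]+$", "", colnames(SummarizedExperiment::assay(se, "counts")))

    ## --- gene-level DE and co-repressed set ---
    up <- lapply(names(cfg$gene_counts), function(kd) {
        se <- readCountTable(.cfgPath(cfg, cfg$gene_counts[[kd]]))
        de <- nbTest(se, groupsOf(se))
        write.table(de, file.path(outDir, paste0("de_genes_", kd, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        log("%s: %d genes tested", kd, nrow(de))
        upregulatedGenes(de, cfg$fold, cfg$fdr, label = kd)
    })
    corep <- corepressedGenes(up[[1]], up[[2]])
    log("co-repressed genes: %d (fold > %g, FDR <= %g)",
        length(corep$gene_ids), cfg$fold, cfg$fdr)

    ## --- backgrounds and gene-age composition ---
    rnd <- randomGeneSets(genes_gr, n = cfg$n_random, k = cfg$k_random,
                          seed = cfg$seed)
    pooled_bg <- list(gene_ids = unlist(lapply(rnd, `[[`, "gene_ids")),
                      label = "pooled_random")
    consv <- conservationEnrichment(corep, pooled_bg, genes_gr,
                                    cfg$conservation)
    lca <- lcaEnrichment(corep, genes_gr)
    write.table(lca, file.path(outDir, "lca_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    ## --- family-level derepression ---
    fam_sets <- lapply(names(cfg$family_counts), function(kd) {
        se <- readCountTable(.cfgPath(cfg, cfg$family_counts[[kd]]))
        derepressedFamilies(se, groupsOf(se),
                            cfg$fold, cfg$fdr, cfg$use_adjusted, label = kd)
    })
    corep_fam <- intersectFamilySets(fam_sets[[1]], fam_sets[[2]])
    l1_corep <- intersect(corep_fam$families, fi$family[fi$superfamily == "L1"])
    ages <- lapply(cfg$age_cutoffs, function(a)
        classifyFamilyAges(l1_corep, fi, a)$fraction)
    names(ages) <- paste0("frac_l1_under_", cfg$age_cutoffs, "myr")
    log("co-repressed families: %d (%d L1)", length(corep_fam$families),
        length(l1_corep))

    ## --- proximity enrichment and orientation bias ---
    young_filter <- repeatFilter(families = cfg$young_l1, label = "young L1")
    enr <- enrichmentVsBackground(corep, pooled_bg, genes_gr, repeats_gr,
                                  young_filter, cfg$windows, fi)
    write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ltrs <- repeats_gr[repeats_gr$repclass == "LTR"]
    orient <- orientationBias(corep, pooled_bg, genes_gr, ltrs,
                              cfg$upstream, chromLen = cs)

    ## --- peak statistics ---
    pk <- lapply(cfg$peaks, function(p) readBed(.cfgPath(cfg, p)))
    repro <- reproduciblePeaks(pk$rep1, pk$rep2, pk$input)
    writeBed(repro, file.path(outDir, "reproducible_peaks.bed"))
    clus <- clusterFraction(repro, cfg$cluster_d)
    mk_any <- markOverlap(repro, pk$h3k9me3, "any")
    mk_frac <- markOverlap(repro, pk$h3k9me3, "frac")
    asg <- assignPeaks(repro, repeats_gr, cfg$young_l1, cfg$inactive_l1)
    write.table(asg$assignment, file.path(outDir, "peak_assignment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log("peaks: %d reproducible, clustering %.3f, mark overlap %.3f/%.3f",
        length(repro), clus, mk_any$fraction, mk_frac$fraction)

    summary <- list(
        seed = cfg$seed,
        n_genes = length(genes_gr), n_repeats = length(repeats_gr),
        up_genes = setNames(lapply(up, function(u) length(u$gene_ids)),
                            names(cfg$gene_counts)),
        corepressed_genes = length(corep$gene_ids),
        protein_coding_fraction = biotypeFraction(corep, genes_gr),
        nonconserved_fraction_set = consv$set$fraction_nonconserved,
        nonconserved_fraction_bg = consv$background$fraction_nonconserved,
        conservation_fisher_p = consv$p,
        mouse_specific_fraction =
            lca$set_fraction[lca$clade == "Mus musculus"],
        corepressed_families = length(corep_fam$families),
        corepressed_l1_families = length(l1_corep),
        l1_age_fractions = ages,
        young_l1_enrichment = list(
            window = enr$window, fold = enr$fold, p = enr$p),
        orientation = orient[c("sense_fraction_set", "sense_fraction_bg", "p")],
        peaks = list(reproducible = length(repro),
                     cluster_fraction = clus,
                     mark_overlap_any = mk_any$fraction,
                     mark_overlap_frac80 = mk_frac$fraction,
                     assignment = as.list(asg$summary)))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
}
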