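## Readers/writers for the external formats the pipeline touches. BED and
## GTF go through rtracklayer; the gene/repeat/family/count TSV dialects are
## simple headered tables validated on read. Every reader reports accepted
## and rejected record counts via message().

#' Read a BED3/BED6 file of intervals or peaks
#'
#' BED half-open 0-based coordinates are converted to the internal GRanges
#' convention on read. Records violating the interval invariants
#' (zero length) are rejected with an error naming the record.
#'
#' @param path BED file path.
#' @param sample optional sample label stored in \code{mcols()$sample}.
#' @return GRanges; score column preserved when present, strand "*" when
#'   absent.
#' @export
readBed <- function(path, sample = NULL) {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(width(gr) <= 0))
        stop(sprintf("%s: zero-length interval at record %d", path,
                     which(width(gr) <= 0)[1]), call. = FALSE)
    if (!is.null(sample)) mcols(gr)$sample <- sample
    message(sprintf("read_bed: %d records accepted from %s", length(gr), path))
    gr
}

#' Write intervals to BED6
#'
#' @param gr GRanges to write.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read a gene annotation (GTF or 6/8-column TSV)
#'
#' The TSV dialect has a header line with columns
#' \code{gene_id, symbol, chrom, start, end, strand, biotype} and optional
#' \code{conservation, lca_clade}; coordinates are 1-based inclusive
#' (GTF-style) in both dialects and converted internally. GTF input keeps
#' one record per \code{gene_id} (the union span over its lines). A gene id
#' appearing on two chromosomes is a hard error; records with strand other
#' than + or - are rejected with a warning.
#'
#' @param path file path.
#' @param dialect "tsv" or "gtf".
#' @return GRanges of genes with mcols gene_id, symbol, biotype and, when
#'   present, conservation and lca_clade.
#' @export
readGeneTable <- function(path, dialect = c("tsv", "gtf")) {
    dialect <- match.arg(dialect)
    if (dialect == "gtf") {
        gr <- rtracklayer::import(path, format = "GFF")
        df <- data.frame(gene_id = as.character(gr$gene_id),
                         symbol = if (!is.null(gr$gene_name))
                             as.character(gr$gene_name) else as.character(gr$gene_id),
                         chrom = as.character(seqnames(gr)),
                         start = start(gr), end = end(gr),
                         strand = as.character(strand(gr)),
                         biotype = if (!is.null(gr$gene_biotype))
                             as.character(gr$gene_biotype) else "protein_coding",
                         stringsAsFactors = FALSE)
        ## union span per gene id
        sp <- split(df, df$gene_id)
        df <- do.call(rbind, lapply(sp, function(g) {
            if (length(unique(g$chrom)) > 1)
                stop("gene id on multiple chromosomes: ", g$gene_id[1],
                     call. = FALSE)
            data.frame(gene_id = g$gene_id[1], symbol = g$symbol[1],
                       chrom = g$chrom[1], start = min(g$start),
                       end = max(g$end), strand = g$strand[1],
                       biotype = g$biotype[1], stringsAsFactors = FALSE)
        }))
        rownames(df) <- NULL
    } else {
        df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
        need <- c("gene_id", "symbol", "chrom", "start", "end", "strand", "biotype")
        if (!all(need %in% colnames(df)))
            stop("gene TSV must carry columns: ", paste(need, collapse = ", "),
                 call. = FALSE)
        if (anyDuplicated(df$gene_id))
            stop("duplicate gene_id in ", path, call. = FALSE)
    }
    ok <- df$strand %in% c("+", "-")
    if (!all(ok)) {
        warning(sprintf("%d gene records with unknown strand rejected", sum(!ok)))
        df <- df[ok, , drop = FALSE]
    }
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                  gene_id = df$gene_id, symbol = df$symbol, biotype = df$biotype)
    if ("conservation" %in% colnames(df)) gr$conservation <- df$conservation
    if ("lca_clade" %in% colnames(df)) gr$lca_clade <- df$lca_clade
    message(sprintf("read_gene_table: %d genes accepted, %d rejected",
                    length(gr), sum(!ok)))
    gr
}

#' Write genes to the TSV dialect
#' @param genes GRanges of genes (as from \code{readGeneTable}).
#' @param path output path.
#' @export
writeGeneTable <- function(genes, path) {
    df <- data.frame(gene_id = genes$gene_id, symbol = genes$symbol,
                     chrom = as.character(seqnames(genes)),
                     start = start(genes), end = end(genes),
                     strand = as.character(strand(genes)),
                     biotype = genes$biotype, stringsAsFactors = FALSE)
    if (!is.null(genes$conservation)) df$conservation <- genes$conservation
    if (!is.null(genes$lca_clade)) df$lca_clade <- genes$lca_clade
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a repeat annotation TSV
#'
#' Normalized RepeatMasker-like dialect: header columns
#' \code{chrom, start, end, strand, family, class, divergence} with 1-based
#' inclusive coordinates. Records with divergence outside [0,100], a class
#' outside the fixed vocabulary, or non-positive length are rejected with a
#' warning; divergence may be NA.
#'
#' @param path file path.
#' @return GRanges of repeat instances with mcols family, repclass,
#'   divergence.
#' @export
readRepeatTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("chrom", "start", "end", "strand", "family", "class", "divergence")
    if (!all(need %in% colnames(df)))
        stop("repeat TSV must carry columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    ok <- (is.na(df$divergence) | (df$divergence >= 0 & df$divergence <= 100)) &
        df$class %in% REPCLASS_VOCAB & nzchar(df$family) &
        df$end >= df$start & df$strand %in% c("+", "-", ".")
    if (!all(ok))
        warning(sprintf("%d repeat records rejected", sum(!ok)))
    df <- df[ok, , drop = FALSE]
    gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                  strand = ifelse(df$strand == ".", "*", df$strand),
                  family = df$family, repclass = df$class,
                  divergence = df$divergence)
    message(sprintf("read_repeat_table: %d repeats accepted, %d rejected",
                    length(gr), sum(!ok)))
    gr
}

#' Write repeats to the TSV dialect
#' @param repeats GRanges of repeat instances.
#' @param path output path.
#' @export
writeRepeatTable <- function(repeats, path) {
    df <- data.frame(chrom = as.character(seqnames(repeats)),
                     start = start(repeats), end = end(repeats),
                     strand = sub("\\*", ".", as.character(strand(repeats))),
                     family = repeats$family, class = repeats$repclass,
                     divergence = repeats$divergence, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read per-family metadata
#'
#' TSV with header \code{family, class, age_myr, active, consensus_length}.
#' @param path file path.
#' @return DataFrame suitable for the \code{familyInfo} slot.
#' @export
readFamilyInfo <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("family", "class", "age_myr", "active", "consensus_length")
    if (!all(need %in% colnames(df)))
        stop("family info TSV must carry columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    out <- DataFrame(family = df$family, repclass = df$class,
                     age_myr = df$age_myr, active = as.logical(df$active),
                     consensus_length = df$consensus_length)
    ## superfamily is optional; derive a coarse one when absent
    out$superfamily <- if ("superfamily" %in% colnames(df)) df$superfamily
        else ifelse(out$family %in% c(youngL1Families(), inactiveL1Families()),
                    "L1", ifelse(out$repclass == "Satellite", "Satellite",
                                 "Other"))
    out
}

#' @rdname readFamilyInfo
#' @param info DataFrame of family metadata.
#' @export
writeFamilyInfo <- function(info, path) {
    df <- data.frame(family = info$family, class = info$repclass,
                     age_myr = info$age_myr, active = info$active,
                     consensus_length = info$consensus_length)
    if (!is.null(info$superfamily)) df$superfamily <- info$superfamily
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read/write a count table
#'
#' TSV with a \code{feature} first column, optional \code{length} column of
#' feature lengths, and one column per sample. Returns a
#' SummarizedExperiment with assay "counts" and rowData length.
#'
#' @param path file path.
#' @return SummarizedExperiment.
#' @export
readCountTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                     check.names = FALSE)
    if (colnames(df)[1] != "feature")
        stop("count TSV must start with a 'feature' column", call. = FALSE)
    len <- NULL
    if ("length" %in% colnames(df)) {
        len <- df$length
        df$length <- NULL
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$feature
    if (anyNA(m) || any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers", call. = FALSE)
    countTable(m, length = len)
}

#' @rdname readCountTable
#' @param se SummarizedExperiment with assay "counts".
#' @export
writeCountTable <- function(se, path) {
    m <- SummarizedExperiment::assay(se, "counts")
    df <- data.frame(feature = rownames(m), check.names = FALSE)
    rl <- SummarizedExperiment::rowData(se)
    if ("length" %in% colnames(rl)) df$length <- rl$length
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Construct a count container
#'
#' @param counts integer matrix, features x samples, with rownames.
#' @param length optional per-feature lengths (bp) for RPKM computations.
#' @param group optional per-sample group labels stored in colData.
#' @return SummarizedExperiment with assay "counts".
#' @export
countTable <- function(counts, length = NULL, group = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("counts must have feature rownames", call. = FALSE)
    rd <- if (is.null(length)) DataFrame(row.names = rownames(counts))
          else DataFrame(length = length, row.names = rownames(counts))
    cd <- if (is.null(group)) DataFrame(row.names = colnames(counts))
          else DataFrame(group = group, row.names = colnames(counts))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd)
}

#' Read a pipeline configuration
#'
#' YAML with the threshold block (fold, fdr, windows, cluster_d, upstream,
#' conservation, binding_ratio, full_length, age_cutoffs), the young/inactive
#' L1 family lists, input paths and seed. Missing fields take the package
#' defaults (\code{pipelineConfig()}); validation is fail-fast.
#'
#' @param path YAML file path.
#' @return Validated config list.
#' @export
readPipelineConfig <- function(path) {
    usr <- yaml::read_yaml(path)
    cfg <- pipelineConfig()
    ## restore positional names for file maps written as plain sequences
    for (f in c("gene_counts", "family_counts", "peaks"))
        if (!is.null(usr[[f]])) {
            usr[[f]] <- unlist(usr[[f]])
            if (is.null(names(usr[[f]])) &&
                length(usr[[f]]) == length(cfg[[f]]))
                names(usr[[f]]) <- names(cfg[[f]])
        }
    cfg[names(usr)] <- usr
    validatePipelineConfig(cfg)
}
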