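test_that("up-regulated gene selection applies strict fold and inclusive FDR", {
    de <- data.frame(feature = c("a", "b", "c", "d"),
                     base_mean = 100, log2fc = c(1.1, 1.0, 3, 0.5),
                     p = 0.001, padj = c(0.01, 0.01, 0.05, 0.01))
    gs <- upregulatedGenes(de)
    expect_setequal(gs$gene_ids, c("a", "c"))  # 2^1.1 > 2; log2fc 1.0 excluded
    expect_equal(upregulatedGenes(de, fdr = 0.04)$gene_ids, "a")
    expect_setequal(corepressedGenes(gs, list(gene_ids = c("c", "d")))$gene_ids,
                    "c")
})

test_that("random gene sets are reproducible and uniform", {
    u <- sprintf("g%03d", 1:300)
    s1 <- randomGeneSets(u, n = 50, k = 3, seed = 9)
    s2 <- randomGeneSets(u, n = 50, k = 3, seed = 9)
    expect_identical(s1, s2)
    expect_setequal(randomGeneSets(u, n = 300, k = 1, seed = 1)[[1]]$gene_ids, u)
    expect_error(randomGeneSets(u, n = 301, k = 1, seed = 1), "universe")
    ## inclusion frequencies consistent with uniform sampling
    set.seed(10)
    counts <- integer(300); names(counts) <- u
    draws <- 400
    for (i in seq_len(draws)) {
        s <- randomGeneSets(u, n = 50, k = 1, seed = 1000 + i)[[1]]$gene_ids
        counts[s] <- counts[s] + 1
    }
    expec <- draws * 50 / 300
    ## chi-square goodness of fit against uniform inclusion
    stat <- sum((counts - expec)^2 / expec)
    expect_lt(stat, qchisq(0.999, df = 299))
})

test_that("peak proximity fraction matches a pairwise oracle", {
    g <- toyGenes(c(1000, 30000, 60000), c(3000, 33000, 62000))
    expect_equal(peakProximityFraction(g$gene_id, g, GRanges()), 0)
    inside <- GRanges("chrT", IRanges(c(1500, 30500, 61000),
                                      c(1600, 30600, 61100)))
    expect_equal(peakProximityFraction(g$gene_id, g, inside, w = 0), 1)
    set.seed(13)
    df <- randomToyIntervals(80, 80000)
    peaks <- toyGRanges(df)
    for (w in c(0, 2000, 20000)) {
        got <- peakProximityFraction(g$gene_id, g, peaks, w)
        flag <- sapply(seq_along(g), function(i) any(sapply(seq_len(80),
            function(j) {
                d <- bruteDistance("chrT", start(g)[i], end(g)[i],
                                   df$chrom[j], df$start[j], df$end[j])
                if (w == 0) d == 0 && (start(g)[i] <= df$end[j] &&
                                       df$start[j] <= end(g)[i]) else d <= w
            })))
        expect_equal(got, mean(flag), info = paste("w =", w))
    }
})

test_that("conservation split uses an inclusive 80% threshold", {
    g <- toyGenes(c(1000, 5000, 9000, 13000), c(2000, 6000, 10000, 14000))
    g$conservation <- c(0.85, 0.80, 0.4, NA)
    r <- conservationSplit(g$gene_id, g)
    expect_equal(r$conserved, 2)       # 0.80 exactly counts as conserved
    expect_equal(r$nonconserved, 1)
    expect_equal(r$unscored, 1)
    expect_equal(r$fraction_conserved + r$fraction_nonconserved, 1)
})

test_that("conservation enrichment reproduces the exact Fisher computation", {
    ## 94-gene set with 39 below threshold vs 100-gene background with 14
    g <- toyGenes(seq(1000, by = 2000, length.out = 194),
                  seq(1800, by = 2000, length.out = 194))
    g$conservation <- c(rep(0.5, 39), rep(0.9, 55), rep(0.5, 14), rep(0.9, 86))
    r <- conservationEnrichment(g$gene_id[1:94], g$gene_id[95:194], g)
    expect_equal(r$set$nonconserved, 39)
    expect_equal(r$background$nonconserved, 14)
    expect_equal(r$p, enumFisherOne(39, 55, 14, 86), tolerance = 1e-10)
})

test_that("LCA enrichment matches enumeration and is calibrated under the null", {
    g <- toyGenes(seq(1000, by = 2000, length.out = 100),
                  seq(1800, by = 2000, length.out = 100))
    g$lca_clade <- rep("Euarchontoglires", 100)
    gc <- c("Mus musculus" = 10, "Euarchontoglires" = 990)
    ## all 20 set genes in one clade that covers 99% of the genome
    r <- lcaEnrichment(g$gene_id[1:20], g, genomeCounts = gc)
    row <- r[r$clade == "Euarchontoglires", ]
    expect_equal(row$p, enumFisherOne(20, 0, 970, 10), tolerance = 1e-10)
    ## genome-matched null: BH-significant clades are rare over 20 seeds
    set.seed(14)
    clades <- c("Mus musculus", "Murinae", "Rodentia", "Eutheria")
    hits <- 0
    for (i in 1:20) {
        g$lca_clade <- sample(clades, 100, TRUE, prob = c(0.01, 0.1, 0.3, 0.59))
        r <- lcaEnrichment(sample(g$gene_id, 30), g)
        hits <- hits + any(r$padj <= 0.05)
    }
    expect_lte(hits, 2)
})

test_that("biotype fraction counts protein-coding genes", {
    g <- toyGenes(c(1000, 5000, 9000), c(2000, 6000, 10000))
    g$biotype <- c("protein_coding", "other", "protein_coding")
    expect_equal(biotypeFraction(g$gene_id, g), 2 / 3)
    expect_equal(biotypeFraction(g$gene_id[2], g), 0)
    expect_equal(biotypeFraction(g$gene_id[c(1, 3)], g), 1)
})
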