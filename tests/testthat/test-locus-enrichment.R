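test_that("repeat filters select by class, family, length and consensus", {
    fi <- defaultFamilyInfo()
    r <- toyRepeats(c(1000, 9000, 17000, 25000),
                    c(1000 + 4000 - 1, 9000 + 5001 - 1, 17000 + 333 - 1,
                      25000 + 100 - 1),
                    c("L1Md_T", "L1Md_T", "RLTR9", "RLTR9"),
                    c("LINE", "LINE", "LTR", "LTR"))
    long <- selectFullLength(r, repeatFilter(classes = "LINE", minLength = 5000))
    expect_equal(start(long), 9000)            # 5001 bp kept (strict >)
    none <- selectFullLength(r, repeatFilter(classes = "LINE", minLength = 5001))
    expect_equal(length(none), 0)              # 5001 dropped at boundary
    ## full-length LTR: >= 90% of the 350-bp consensus
    fl <- selectRepeats(r, repeatFilter(classes = "LTR", fullLengthOnly = TRUE),
                        info = fi)
    expect_equal(r$family[match(start(fl), start(r))], "RLTR9")
    expect_equal(width(fl), 333)               # 0.95 x consensus kept
    expect_error(selectRepeats(r, repeatFilter(classes = "LTR",
                                               fullLengthOnly = TRUE)))
    expect_error(repeatFilter())               # no selector active
})

test_that("per-gene repeat flags equal the brute-force pairwise oracle", {
    set.seed(51)
    g <- toyGenes(starts <- seq(2000, by = 3000, length.out = 30),
                  starts + 1500, chromLen = 120000)
    df <- randomToyIntervals(300, 100000)
    fam <- sample(c("L1Md_A", "L1Md_T", "Lx8"), 300, TRUE)
    r <- toyRepeats(df$start, df$end, fam, "LINE")
    filt <- repeatFilter(families = c("L1Md_A", "L1Md_T"))
    sel <- fam %in% c("L1Md_A", "L1Md_T")
    for (w in c(0, 1000, 20000)) {
        got <- genesWithRepeat(g$gene_id, g, r, filt, w)
        ref <- sapply(seq_along(g), function(i) {
            d <- mapply(bruteDistance, "chrT", start(g)[i], end(g)[i],
                        df$chrom[sel], df$start[sel], df$end[sel])
            ov <- df$start[sel] <= end(g)[i] & df$end[sel] >= start(g)[i]
            if (w == 0) sum(ov) else sum(d <= w)
        })
        expect_equal(unname(got$per_gene), ref, info = paste("w =", w))
        expect_equal(unname(got$flags), ref > 0)
    }
    ## a 4000-bp L1 fails a 5000-bp length filter even when inside the gene
    r1 <- toyRepeats(start(g)[1], start(g)[1] + 3999, "L1Md_A", "LINE")
    got <- genesWithRepeat(g$gene_id[1], g, r1,
                           repeatFilter(families = "L1Md_A", minLength = 5000), 0)
    expect_false(unname(got$flags))
})

test_that("enrichment against an identical background is null", {
    set.seed(52)
    g <- toyGenes(starts <- seq(2000, by = 4000, length.out = 40),
                  starts + 2000, chromLen = 200000)
    df <- randomToyIntervals(120, 180000)
    r <- toyRepeats(df$start, df$end, "L1Md_A", "LINE")
    filt <- repeatFilter(families = "L1Md_A")
    ## saturated windows produce empty "no-repeat" margins (p = 1, warned)
    enr <- suppressWarnings(
        enrichmentVsBackground(g$gene_id, g$gene_id, g, r, filt))
    expect_equal(enr$fold, rep(1, 3))
    expect_true(all(enr$p >= 0.5))
    ## set_positive is monotone over the windows
    expect_true(all(diff(enr$set_positive) >= 0))
    ## fold is scale-free under duplication of genes and repeats
    g2 <- suppressWarnings({
        x <- c(g, shift(g, 250000))
        seqlengths(x) <- c(chrT = 500000)
        x$gene_id <- sprintf("g%03d", seq_along(x))
        x
    })
    r2 <- suppressWarnings(c(r, shift(r, 250000)))
    e1 <- suppressWarnings(
        enrichmentVsBackground(g$gene_id[1:20], g$gene_id[21:40], g, r, filt))
    e2 <- suppressWarnings(
        enrichmentVsBackground(g2$gene_id[c(1:20, 41:60)],
                               g2$gene_id[c(21:40, 61:80)], g2, r2, filt))
    expect_equal(e1$fold, e2$fold)
    ## empty background positives flag an infinite fold
    rnone <- toyRepeats(1, 100, "L1Md_A", "LINE")
    g1 <- toyGenes(c(50, 50000), c(150, 51000))
    ei <- enrichmentVsBackground(g1$gene_id[1], g1$gene_id[2], g1, rnone,
                                 filt, windows = 0)
    expect_true(ei$fold_infinite)
    expect_equal(ei$fold, Inf)
})

test_that("any-of-filters and array fractions reduce to per-filter flags", {
    g <- toyGenes(c(2000, 42000, 82000), c(4000, 44000, 84000),
                  chromLen = 120000)
    r <- toyRepeats(c(2500, 2700, 42500, 90000),
                    c(2600, 2800, 42600, 90100),
                    c("L1Md_A", "L1Md_A", "GSAT_MM", "Lx8"),
                    c("LINE", "LINE", "Satellite", "LINE"))
    fL1 <- repeatFilter(families = "L1Md_A")
    fSat <- repeatFilter(classes = "Satellite")
    expect_equal(fractionWithAny(g$gene_id, g, r, list(fL1), w = 0),
                 unname(genesWithRepeat(g$gene_id, g, r, fL1, 0)$count) / 3)
    expect_equal(fractionWithAny(g$gene_id, g, r, list(fL1, fSat), w = 0), 2 / 3)
    ## array fraction: gene 1 has two L1Md_A, no other flagged gene has >= 2
    expect_equal(l1ArrayFraction(g$gene_id, g, r, fL1, w = 0), 1)
    expect_equal(l1ArrayFraction(g$gene_id, g, r, fL1, w = 0, minCount = 3), 0)
    rsingle <- r[c(1, 3)]
    expect_equal(l1ArrayFraction(g$gene_id, g, rsingle, fL1, w = 0), 0)
})

test_that("orientation bias pools LTR instances and tests sense excess", {
    ## all-sense in both groups: no excess, p = 1
    g <- toyGenes(c(10000, 50000), c(12000, 52000), strand = "+",
                  chromLen = 100000)
    ltr_s <- toyRepeats(c(8000, 48000), c(8400, 48400), "RLTR9", "LTR",
                        strand = "+")
    r <- orientationBias(g$gene_id[1], g$gene_id[2], g, ltr_s)
    expect_equal(r$sense_fraction_set, 1)
    expect_equal(r$p, 1)
    ## extreme split: 10 sense vs 10 antisense
    g2 <- toyGenes(rep(c(10000, 50000), c(1, 1)), c(12000, 52000),
                   strand = "+", chromLen = 100000)
    mk <- function(near, strand, n) toyRepeats(
        seq(near - 2900, by = 290, length.out = n),
        seq(near - 2900 + 100, by = 290, length.out = n),
        "RLTR9", "LTR", strand = strand)
    ltrs <- c(mk(10000, "+", 10), mk(50000, "-", 10))
    r2 <- orientationBias(g2$gene_id[1], g2$gene_id[2], g2, ltrs)
    expect_equal(r2$set_sense, 10)
    expect_equal(r2$bg_antisense, 10)
    expect_equal(r2$p, 1 / choose(20, 10), tolerance = 1e-12)
    ## unstranded LTRs are excluded from the table
    ltr_u <- toyRepeats(8000, 8400, "RLTR9", "LTR", strand = "*")
    r3 <- orientationBias(g$gene_id[1], g$gene_id[2], g, c(ltr_s, ltr_u))
    expect_equal(r3$set_sense + r3$set_antisense, 1)
})
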