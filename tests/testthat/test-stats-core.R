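test_that("one-sided Fisher matches closed forms and enumeration", {
    expect_equal(fisherOneSided(5, 0, 0, 5), 1 / choose(10, 5))
    expect_equal(fisherOneSided(1, 1, 1, 1), 5 / 6)
    expect_warning(p <- fisherOneSided(0, 0, 3, 4))
    expect_equal(p, 1)
    set.seed(1)
    for (i in 1:200) {
        t <- as.vector(stats::rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
        if ((t[1] + t[2]) == 0 || (t[3] + t[4]) == 0 ||
            (t[1] + t[3]) == 0 || (t[2] + t[4]) == 0) next
        expect_equal(fisherOneSided(t[1], t[2], t[3], t[4]),
                     enumFisherOne(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
        ## independent cross-check against the standard implementation
        ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                                 alternative = "greater")
        expect_equal(fisherOneSided(t[1], t[2], t[3], t[4]), ft$p.value,
                     tolerance = 1e-9)
    }
    expect_error(fisherOneSided(-1, 2, 3, 4))
})

test_that("two-sided Fisher matches enumeration and fisher.test", {
    expect_equal(fisherTwoSided(1, 1, 1, 1), 1)
    expect_equal(fisherTwoSided(5, 0, 0, 5), 2 / choose(10, 5))
    set.seed(2)
    for (i in 1:200) {
        t <- as.vector(stats::rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
        if ((t[1] + t[2]) == 0 || (t[3] + t[4]) == 0 ||
            (t[1] + t[3]) == 0 || (t[2] + t[4]) == 0) next
        expect_equal(fisherTwoSided(t[1], t[2], t[3], t[4]),
                     enumFisherTwo(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
        ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE))
        expect_equal(fisherTwoSided(t[1], t[2], t[3], t[4]), ft$p.value,
                     tolerance = 1e-7)
    }
})

test_that("BH adjustment matches a direct step-up computation", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhAdjust(0.5), 0.5)
    expect_equal(bhAdjust(numeric()), numeric())
    set.seed(3)
    p <- runif(100)
    ## independent step-up reference: sort, p*m/i, cumulative min from top
    o <- order(p)
    m <- length(p)
    ref <- numeric(m)
    ref[o] <- pmin(1, rev(cummin(rev(sort(p) * m / seq_len(m)))))
    got <- bhAdjust(p)
    expect_equal(got, ref)
    expect_true(all(got >= p))
    ## permutation equivariance
    perm <- sample(m)
    expect_equal(bhAdjust(p[perm]), got[perm])
    expect_error(bhAdjust(c(0.5, 1.2)))
})

test_that("median-of-ratios size factors recover known depths", {
    m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
                dimnames = list(paste0("f", 1:3), c("s1", "s2")))
    expect_equal(medianRatioSizeFactors(m), c(s1 = 1, s2 = 1))
    m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
    sf <- medianRatioSizeFactors(m2)
    expect_equal(unname(sf[2] / sf[1]), 2)
    expect_equal(exp(mean(log(sf))), 1)
    ## simulated depths at 2000 features recovered within 5%
    p <- simParams(seed = 31)
    sim <- simulateCounts(p, sprintf("f%04d", 1:2000))
    sf <- medianRatioSizeFactors(SummarizedExperiment::assay(sim$se, "counts"))
    truef <- sim$truth$depths / exp(mean(log(sim$truth$depths)))
    expect_lt(max(abs(sf / truef - 1)), 0.05)
    ## all-zero-feature fallback
    m3 <- cbind(s1 = c(0, 5, 9), s2 = c(4, 0, 9), s3 = c(2, 2, 0))
    rownames(m3) <- paste0("f", 1:3)
    expect_warning(medianRatioSizeFactors(m3), "total-count")
})

test_that("NB test fold changes behave under relabeling and identity", {
    m <- matrix(rep(c(5L, 9L, 14L, 30L), each = 6), ncol = 6, byrow = TRUE,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
    grp <- rep(c("a", "b"), each = 3)
    de <- nbTest(m, grp)
    expect_equal(de$log2fc, rep(0, 4))
    ## sign flips exactly when control is relabeled
    p <- simParams(seed = 32)
    sim <- simulateCounts(p, sprintf("f%03d", 1:300),
                          setNames(rep(1.5, 20), sprintf("f%03d", 1:20)))
    g <- SummarizedExperiment::colData(sim$se)$group
    d1 <- nbTest(sim$se, g)
    d2 <- nbTest(sim$se, g, control = "treat")
    expect_equal(d1$log2fc, -d2$log2fc)
    expect_equal(d1$p, d2$p, tolerance = 1e-12)
    ## padj never below p; all-zero features dropped with NA results
    expect_true(all(d1$padj >= d1$p - 1e-12, na.rm = TRUE))
    m0 <- rbind(m, f5 = 0L)
    d0 <- nbTest(m0, grp)
    expect_true(is.na(d0$log2fc[5]))
    ## single sample per group: fold reported, p missing
    ds <- nbTest(m[, c(1, 4)], c("a", "b"))
    expect_true(all(is.na(ds$p)))
    expect_false(any(is.na(ds$log2fc)))
})

test_that("NB test agrees directionally with DESeq2 on a planted matrix", {
    skip_if_not_installed("DESeq2")
    p <- simParams(seed = 33)
    planted <- setNames(rep(2, 30), sprintf("f%03d", 1:30))
    sim <- simulateCounts(p, sprintf("f%03d", 1:400), planted)
    m <- SummarizedExperiment::assay(sim$se, "counts")
    grp <- SummarizedExperiment::colData(sim$se)$group
    de <- nbTest(m, grp)
    dds <- DESeq2::DESeqDataSetFromMatrix(m, S4Vectors::DataFrame(
        condition = factor(grp, levels = c("ctrl", "treat"))), ~condition)
    res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
    expect_gt(cor(de$log2fc, res$log2FoldChange, use = "complete.obs"), 0.95)
    sig_mine <- de$feature[!is.na(de$padj) & de$padj <= 0.05 & de$log2fc > 1]
    sig_ref <- rownames(res)[!is.na(res$padj) & res$padj <= 0.05 &
                             res$log2FoldChange > 1]
    ## the two callers select essentially the same planted features
    expect_gt(length(intersect(sig_mine, sig_ref)) /
              max(length(union(sig_mine, sig_ref)), 1), 0.7)
})
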