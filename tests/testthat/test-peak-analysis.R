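test_that("reproducible peaks require replicate support and no input overlap", {
    rep1 <- GRanges("chr1", IRanges(1, 100))
    rep2 <- GRanges("chr1", IRanges(51, 150))
    expect_equal(granges(reproduciblePeaks(rep1, rep2)), rep1)
    input <- GRanges("chr1", IRanges(91, 200))
    expect_equal(length(reproduciblePeaks(rep1, rep2, input)), 0)
    expect_warning(reproduciblePeaks(rep1, GRanges()), "empty")
    ## brute-force triple-overlap oracle on random sets
    set.seed(61)
    d1 <- randomToyIntervals(120, 20000); d2 <- randomToyIntervals(120, 20000)
    di <- randomToyIntervals(30, 20000)
    got <- reproduciblePeaks(toyGRanges(d1), toyGRanges(d2), toyGRanges(di))
    keep <- sapply(seq_len(120), function(i) {
        ovl <- function(df) any(df$start <= d1$end[i] & df$end >= d1$start[i])
        ovl(d2) && !ovl(di)
    })
    expect_equal(granges(got), granges(toyGRanges(d1)[keep]))
    ## invariants: output within rep1, never touching input
    expect_true(all(overlapsAny(got, toyGRanges(d1))))
    expect_false(any(overlapsAny(got, toyGRanges(di))))
})

test_that("cluster fraction counts nearest-neighbour gaps and matches theory", {
    pk <- GRanges("chr1", IRanges(c(1, 30001, 200001), width = 1000))
    expect_equal(clusterFraction(pk, 50000), 2 / 3)
    expect_equal(clusterFraction(pk[1], 50000), 0)
    ## translation and chromosome relabeling invariance
    pk2 <- shift(pk, 12345)
    GenomeInfoDb::seqlevels(pk2) <- "chr1"
    pk3 <- GRanges(sub("chr1", "chrZ", seqnames(pk)), ranges(pk))
    expect_equal(clusterFraction(pk2, 50000), clusterFraction(pk, 50000))
    expect_equal(clusterFraction(pk3, 50000), clusterFraction(pk, 50000))
    ## Poisson peaks: P(nearest neighbour within d) = 1 - exp(-2 lambda d)
    set.seed(62)
    lam <- 1 / 1e5
    L <- 3e7
    st <- sort(sample(L, rpois(1, lam * L)))
    pp <- GRanges("chr1", IRanges(st, width = 1))
    d <- 50000
    expect_lt(abs(clusterFraction(pp, d) - (1 - exp(-2 * lam * d))), 0.05)
})

test_that("mark overlap supports any-overlap and peak-relative fraction", {
    pk <- GRanges("chr1", IRanges(1, 1000))
    mark <- GRanges("chr1", IRanges(901, 2000))
    expect_true(markOverlap(pk, mark, "any")$flags)
    expect_false(markOverlap(pk, mark, "frac")$flags)   # only 10% covered
    expect_true(markOverlap(pk, pk, "frac")$flags)
    expect_true(markOverlap(pk, mark, "frac", minFrac = 0.1)$flags)
    ## per-base oracle on random toys; union of marks, peak-relative
    set.seed(63)
    dp <- randomToyIntervals(60, 8000); dm <- randomToyIntervals(60, 8000)
    peaks <- toyGRanges(dp); marks <- toyGRanges(dm)
    for (mode in c("any", "frac")) {
        got <- markOverlap(peaks, marks, mode)
        ref <- sapply(seq_len(60), function(i) {
            bases <- dp$start[i]:dp$end[i]
            cov <- sapply(bases, function(b) any(dm$start <= b & dm$end >= b))
            if (mode == "any") any(cov) else mean(cov) >= 0.8
        })
        expect_equal(unname(got$flags), ref, info = mode)
    }
    ## stringency ordering holds for every input
    expect_gte(markOverlap(peaks, marks, "any")$fraction,
               markOverlap(peaks, marks, "frac")$fraction)
})

test_that("peaks are assigned to the repeat with the largest overlap", {
    r <- toyRepeats(c(1000, 5000, 5600), c(2000, 5599, 5899),
                    c("L1Md_T", "Lx8", "L1Md_A"), "LINE")
    pk <- GRanges("chrT", IRanges(c(1500, 9000, 5000), width = 600))
    asg <- assignPeaks(pk, r)
    expect_equal(asg$assignment$category,
                 c("young_L1", "no_repeat", "inactive_L1"))
    ## peak 3 overlaps Lx8 by 600 and L1Md_A by 0 bp after its span ends at
    ## 5599; widen it to create the 600 vs 300 tie-break case
    pk2 <- GRanges("chrT", IRanges(5000, 5899))
    asg2 <- assignPeaks(pk2, r)
    expect_equal(asg2$assignment$family, "Lx8")       # 600 bp beats 300 bp
    expect_equal(asg2$assignment$category, "inactive_L1")
    ## exact tie prefers young over inactive
    r3 <- toyRepeats(c(1000, 2000), c(1299, 2299), c("Lx8", "L1Md_A"), "LINE")
    pk3 <- GRanges("chrT", IRanges(1000, 2299))
    expect_equal(assignPeaks(pk3, r3)$assignment$category, "young_L1")
    expect_equal(unname(assignPeaks(pk, r)$summary["no_repeat"]), 1L)
})

test_that("binding enrichment computes RPKM ratios with inclusive selection", {
    lens <- c(famA = 1000, famB = 1000)
    ip <- matrix(c(20, 100), 2, dimnames = list(names(lens), "ip1"))
    input <- matrix(c(20, 100), 2, dimnames = list(names(lens), "in1"))
    ## identical IP and input at equal depth: ratio 1, nothing selected
    r0 <- bindingEnrichment(ip, input, lens, totalIp = 1e6, totalInput = 1e6)
    expect_equal(r0$ratio, c(1, 1))
    expect_false(any(r0$selected))
    ## depth ratio engineered to land exactly on the 4-fold threshold
    r4 <- bindingEnrichment(ip, input, lens, totalIp = 1e6, totalInput = 4e6)
    expect_equal(r4$ratio, c(4, 4))
    expect_true(all(r4$selected))                    # >= 4 is inclusive
    ## ratio invariant to a common depth rescaling
    ra <- bindingEnrichment(ip, input, lens, totalIp = 2e6, totalInput = 1e6)
    rb <- bindingEnrichment(ip, input, lens, totalIp = 6e6, totalInput = 3e6)
    expect_equal(ra$ratio, rb$ratio)
    ## simulated recovery: 22 bound families at ~6-fold IP enrichment
    set.seed(64)
    fams <- sprintf("fam%02d", 1:60)
    lens60 <- setNames(rep(3000, 60), fams)
    base <- rlnorm(60, log(400), 0.4)
    inp <- sapply(1:2, function(i) rpois(60, base))
    ipc <- sapply(1:2, function(i) rpois(60, base * c(rep(6, 22), rep(1, 38))))
    rownames(inp) <- rownames(ipc) <- fams
    rr <- bindingEnrichment(ipc, inp, lens60,
                            totalIp = rep(1e6, 2), totalInput = rep(1e6, 2))
    expect_gte(sum(rr$selected[1:22]), 20)
    expect_lte(sum(rr$selected[23:60]), 2)
})

test_that("flanking bound-repeat fractions count per category", {
    g <- toyGenes(c(30000, 90000), c(32000, 92000), chromLen = 200000)
    r <- toyRepeats(c(35000, 95000), c(36000, 96000), c("Lx8", "IAPEz"),
                    c("LINE", "LTR"))
    fr <- flankingBindingFraction(g$gene_id, g, r,
                                  boundFamilies = c("Lx8", "IAPEz"),
                                  ervkFamilies = "IAPEz")
    expect_equal(unname(fr["bound_inactive_l1"]), 0.5)
    expect_equal(unname(fr["ervk"]), 0.5)
    none <- flankingBindingFraction(g$gene_id, g, r, boundFamilies = character(),
                                    ervkFamilies = character())
    expect_equal(unname(none), c(0, 0))
})

test_that("consensus profiles normalize bins and measure 3' skew", {
    u <- consensusProfile(rep(2, 100))
    expect_equal(u$bins, rep(1, 20))
    expect_equal(u$ratio, 1)
    h <- consensusProfile(c(rep(0, 50), rep(2, 50)))
    expect_true(h$ratio_infinite)
    expect_equal(h$bins[1:10], rep(0, 10))
    expect_equal(h$bins[11:20], rep(2, 10))
    ## linear ramp sampled at bin midpoints: exact second/first half ratio 3
    L <- 100
    ramp <- (seq_len(L) - 0.5) / L
    expect_equal(consensusProfile(ramp)$ratio, 3)
    expect_error(consensusProfile(1:5, nBins = 20))
})
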