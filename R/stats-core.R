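## Exact and count-based statistics shared by all stages: Fisher tests on
## 2x2 tables, BH FDR, median-of-ratios normalization and a self-contained
## negative-binomial Wald test for two-group count comparisons.

.P_FLOOR <- 1e-300

.checkTable <- function(a, b, c, d) {
    t <- c(a, b, c, d)
    if (length(t) != 4L || anyNA(t) || any(t < 0) || any(t != round(t)))
        stop("2x2 table entries must be non-negative integers", call. = FALSE)
    invisible(t)
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' Rows are (test group, background group), columns are (positive, negative)
#' category. The p-value is the upper-tail hypergeometric probability of
#' over-representation of the positive category in the test group, i.e. the
#' probability of a table at least as enriched as observed given the margins.
#' Callers orient their tables so that "enrichment in the test group" is the
#' alternative of interest.
#'
#' @param a,b test-group positive and negative counts.
#' @param c,d background-group positive and negative counts.
#' @return p-value in (0, 1]; an empty margin returns 1 with a warning.
#' @examples
#' fisherOneSided(5, 0, 0, 5)   # 1/choose(10,5)
#' fisherOneSided(38, 55, 14, 86)
#' @export
fisherOneSided <- function(a, b, c, d) {
    .checkTable(a, b, c, d)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
        warning("empty margin in 2x2 table; p = 1")
        return(1)
    }
    ## P(X >= a), X ~ Hypergeometric(white = a+c, black = b+d, drawn = a+b)
    p <- phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
    max(min(p, 1), .P_FLOOR)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (with the customary one-part-in-1e7 tolerance for ties).
#'
#' @inheritParams fisherOneSided
#' @return p-value in (0, 1].
#' @export
fisherTwoSided <- function(a, b, c, d) {
    .checkTable(a, b, c, d)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
        warning("empty margin in 2x2 table; p = 1")
        return(1)
    }
    m <- a + c; n <- b + d; k <- a + b
    support <- max(0, k - n):min(k, m)
    dens <- dhyper(support, m, n, k)
    p <- sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
    max(min(p, 1), .P_FLOOR)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin wrapper over \code{p.adjust(method="BH")}
#' that validates its input and passes an empty vector through.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs preserved).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric())
    if (any(!is.na(p) & (p < 0 | p > 1)))
        stop("p-values must lie in [0,1]", call. = FALSE)
    p.adjust(p, method = "BH")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median ratio of each
#' sample's counts to the per-feature geometric-mean pseudo-reference, using
#' features positive in every sample; factors are rescaled so their
#' geometric mean is 1. If no feature is positive in all samples, falls back
#' to total-count ratios with a warning.
#'
#' @param counts integer matrix, features x samples (>= 2 samples).
#' @return Positive numeric vector of per-sample size factors.
#' @export
medianRatioSizeFactors <- function(counts) {
    counts <- .asCountMatrix(counts)
    if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) {
        warning("no feature positive in all samples; using total-count ratios")
        sf <- colSums(counts)
        sf <- sf / exp(mean(log(sf)))
        return(sf)
    }
    lc <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(lc)
    sf <- apply(lc, 2, function(x) exp(median(x - ref)))
    sf / exp(mean(log(sf)))
}

.asCountMatrix <- function(counts) {
    if (is(counts, "SummarizedExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- as.matrix(counts)
    if (anyNA(counts) || any(counts < 0))
        stop("counts must be non-negative and complete", call. = FALSE)
    counts
}

## Per-feature method-of-moments NB dispersion from normalized counts,
## moderated toward the global trend. With few replicates the raw MoM
## estimate has so few degrees of freedom that a Wald test built on it is
## badly miscalibrated; borrowing strength across features (weighting the
## per-feature estimate against a mean-dependent trend by residual df vs a
## prior df) restores both calibration and power. Floored at `floor`.
.nbDispersion <- function(normed, group, prior_df = 20, floor = 0.01) {
    lev <- unique(group)
    v <- sapply(lev, function(g) {
        x <- normed[, group == g, drop = FALSE]
        if (ncol(x) < 2) rep(NA_real_, nrow(normed)) else apply(x, 1, var)
    })
    n_per <- sapply(lev, function(g) sum(group == g))
    df_resid <- sum(pmax(n_per - 1, 0))
    mu_bar <- rowMeans(normed)
    ## pooled within-group variance
    wsum <- sweep(v, 2, pmax(n_per - 1, 0), `*`)
    s2 <- rowSums(wsum, na.rm = TRUE) / max(df_resid, 1)
    alpha_raw <- (s2 - mu_bar) / mu_bar^2
    alpha_raw[!is.finite(alpha_raw)] <- NA_real_
    ## global trend: median raw dispersion of the upper half of expression
    ## (where the MoM estimator is least noisy), corrected for the downward
    ## bias of a median of few-df variance estimates
    ok <- is.finite(alpha_raw) & mu_bar > median(mu_bar, na.rm = TRUE)
    med_corr <- stats::qchisq(0.5, max(df_resid, 1)) / max(df_resid, 1)
    trend <- median(alpha_raw[ok], na.rm = TRUE) / med_corr
    if (!is.finite(trend)) trend <- floor
    trend <- max(trend, floor)
    alpha <- (df_resid * pmax(alpha_raw, 0) + prior_df * trend) /
        (df_resid + prior_df)
    alpha[is.na(alpha_raw)] <- trend
    pmax(alpha, floor)
}

#' Negative-binomial two-group differential test
#'
#' Self-contained Wald-type test for differential abundance between two
#' groups of count samples (features x samples), in the spirit of the
#' standard NB differential-expression model: counts are normalized by
#' median-of-ratios size factors; the per-feature NB dispersion is estimated
#' by method of moments and moderated toward a global trend (floored at
#' 0.01); the log2 fold change (group over control, with a 0.5 pseudocount
#' on normalized group means) is tested against a delta-method standard
#' error from the NB variance function; p-values are BH-adjusted. Features
#' with all-zero counts are dropped.
#'
#' @param counts integer matrix or SummarizedExperiment (assay "counts"),
#'   features x samples.
#' @param group two-level factor or character vector of sample labels; the
#'   first level is the control/reference.
#' @param control optional explicit control level.
#' @param prior_df prior degrees of freedom for dispersion moderation.
#' @return data.frame with columns feature, base_mean, log2fc, p, padj,
#'   ordered as the input features. With a single sample per group p and
#'   padj are NA (fold changes still reported).
#' @examples
#' set.seed(1)
#' m <- matrix(rnbinom(600, mu = 50, size = 10), ncol = 6)
#' nbTest(m, rep(c("ctrl", "kd"), each = 3))[1:3, ]
#' @export
nbTest <- function(counts, group, control = NULL, prior_df = 20) {
    counts <- .asCountMatrix(counts)
    group <- as.character(group)
    if (length(group) != ncol(counts))
        stop("group must have one label per sample", call. = FALSE)
    lev <- unique(group)
    if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
    if (!is.null(control)) {
        if (!control %in% lev) stop("control level not found", call. = FALSE)
        lev <- c(control, setdiff(lev, control))
    }
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("feature_", seq_len(nrow(counts)))
    keep <- rowSums(counts) > 0
    x <- counts[keep, , drop = FALSE]
    sf <- medianRatioSizeFactors(x)
    normed <- sweep(x, 2, sf, `/`)
    i1 <- group == lev[1]; i2 <- group == lev[2]
    m1 <- rowMeans(normed[, i1, drop = FALSE])
    m2 <- rowMeans(normed[, i2, drop = FALSE])
    log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
    base_mean <- rowMeans(normed)
    if (sum(i1) < 2 && sum(i2) < 2) {
        p <- rep(NA_real_, nrow(x))
    } else {
        alpha <- .nbDispersion(normed, group, prior_df = prior_df)
        vfun <- function(m, n) (m + alpha * m^2) / n
        ## delta-method SE of log2 of the pseudocounted group means; the
        ## reference is t with the moderated degrees of freedom, which
        ## accounts for the residual noise of the dispersion estimate
        se2 <- vfun(m1, sum(i1)) / ((m1 + 0.5) * log(2))^2 +
               vfun(m2, sum(i2)) / ((m2 + 0.5) * log(2))^2
        z <- log2fc / sqrt(se2)
        df_mod <- prior_df + sum(i1) + sum(i2) - 2
        p <- 2 * stats::pt(-abs(z), df_mod)
        p <- pmax(p, .P_FLOOR)
    }
    res <- data.frame(feature = rownames(counts), base_mean = NA_real_,
                      log2fc = NA_real_, p = NA_real_, padj = NA_real_,
                      stringsAsFactors = FALSE)
    res$base_mean[keep] <- base_mean
    res$log2fc[keep] <- log2fc
    res$p[keep] <- p
    res$padj[keep][!is.na(p)] <- bhAdjust(p[!is.na(p)])
    res
}
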