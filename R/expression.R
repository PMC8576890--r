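## Family-level TE expression: count aggregation, median-of-ratios
## normalization, negative-binomial Wald test, thresholded reports,
## transcriptional load.

#' Aggregate per-copy read assignments into family counts
#'
#' Each read is assigned (upstream, by the aligner contract) to
#' exactly one TE copy; the family count is the number of reads
#' assigned to any copy of the family. A read listed twice in the
#' same sample is a validation error.
#'
#' @param assignments data.frame with columns \code{read},
#'   \code{copy}, \code{family}, \code{sample}.
#' @return Integer matrix, families x samples.
#' @examples
#' a <- data.frame(read = c("r1", "r2"), copy = c("c1", "c2"),
#'                 family = "fam1", sample = "s1")
#' aggregateFamilyCounts(a)
#' @export
aggregateFamilyCounts <- function(assignments) {
    req <- c("read", "copy", "family", "sample")
    if (!all(req %in% colnames(assignments)))
        stop("assignments need columns read, copy, family, sample")
    key <- paste(assignments$read, assignments$sample)
    if (anyDuplicated(key))
        stop("read assigned more than once in one sample: ",
             key[duplicated(key)][1L])
    tab <- table(factor(assignments$family),
                 factor(assignments$sample))
    m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    m
}

#' Median-of-ratios size factors and normalized counts
#'
#' The size factor of a sample is the median, over families with
#' nonzero counts in every sample, of the ratio of its count to the
#' family's geometric mean across samples. Normalized counts are raw
#' counts divided by the size factor. With no all-nonzero family the
#' function falls back to total-count scaling with a warning.
#'
#' @param counts Integer matrix, families x samples.
#' @return List with \code{sizeFactors} and \code{normalized}.
#' @examples
#' m <- rbind(c(10, 20), c(100, 200))
#' medianOfRatiosNormalize(m)$sizeFactors
#' @export
medianOfRatiosNormalize <- function(counts) {
    counts <- as.matrix(counts)
    allPos <- rowSums(counts == 0) == 0L
    if (!any(allPos)) {
        warning("no family with nonzero counts in all samples; ",
                "falling back to total-count scaling")
        tot <- colSums(counts)
        sf <- tot / exp(mean(log(tot)))
    } else {
        sub <- counts[allPos, , drop = FALSE]
        logGeo <- rowMeans(log(sub))
        sf <- apply(sub, 2L, function(cnt)
            exp(median(log(cnt) - logGeo)))
    }
    list(sizeFactors = sf,
         normalized = sweep(counts, 2L, sf, "/"))
}

#' Negative-binomial Wald test for differential family expression
#'
#' A simplified NB Wald test per family: counts are normalized by
#' median-of-ratios size factors; the per-family dispersion is
#' estimated by method of moments on the normalized counts (pooled
#' within conditions, floored at 1e-8). Because a moment estimate
#' from a handful of replicates is very noisy — and underestimates
#' inflate false positives — each estimate is additionally floored at
#' the across-family median dispersion (\code{moderate = TRUE}, an
#' empirical-Bayes-style moderation in the spirit of dispersion-trend
#' shrinkage). The log2 fold change is the ratio of condition means
#' with a pseudocount of 1/2; the Wald statistic divides the log2
#' fold change by its delta-method standard error and is referred to
#' the standard normal. P values are Benjamini-Hochberg adjusted
#' across tested families; families with all-zero counts are
#' excluded before testing. Status is \code{up}/\code{down} when the
#' adjusted p value is below \code{alpha} and |log2FC| exceeds
#' \code{lfcThreshold}, else \code{ns}.
#'
#' @param counts Integer matrix, families x samples.
#' @param condition Factor (two levels) or character vector of
#'   condition labels, one per column.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param lfcThreshold Absolute log2 fold-change threshold (default
#'   1).
#' @param dispersionFloor Lower bound on the dispersion estimate.
#' @param moderate Floor each per-family dispersion at the
#'   across-family median dispersion (default \code{TRUE}).
#' @return data.frame with columns \code{family}, \code{baseMean},
#'   \code{log2fc}, \code{se}, \code{p}, \code{padj}, \code{status}.
#' @export
nbWaldTest <- function(counts, condition, alpha = 0.05,
                       lfcThreshold = 1, dispersionFloor = 1e-8,
                       moderate = TRUE) {
    counts <- as.matrix(counts)
    condition <- factor(condition)
    if (nlevels(condition) != 2L)
        stop("exactly two conditions required")
    if (any(table(condition) < 2L))
        stop("each condition needs at least 2 replicates")
    lv <- levels(condition)
    norm <- medianOfRatiosNormalize(counts)$normalized
    tested <- rowSums(counts) > 0L
    A <- norm[, condition == lv[1L], drop = FALSE]
    B <- norm[, condition == lv[2L], drop = FALSE]
    nA <- ncol(A); nB <- ncol(B)
    mA <- rowMeans(A); mB <- rowMeans(B)
    vA <- apply(A, 1L, var); vB <- apply(B, 1L, var)
    mPool <- (mA + mB) / 2
    vPool <- (vA * (nA - 1L) + vB * (nB - 1L)) / (nA + nB - 2L)
    disp <- pmax((vPool - mPool) / mPool^2, dispersionFloor)
    disp[!is.finite(disp)] <- dispersionFloor
    if (moderate && any(mPool > 10)) {
        medDisp <- median(disp[mPool > 10])
        disp <- pmax(disp, medDisp)
    }
    log2fc <- log2((mB + 0.5) / (mA + 0.5))
    varMeanA <- (mA + disp * mA^2) / nA
    varMeanB <- (mB + disp * mB^2) / nB
    se <- sqrt(varMeanA / (mA + 0.5)^2 + varMeanB / (mB + 0.5)^2) /
        log(2)
    z <- log2fc / se
    p <- 2 * pnorm(-abs(z))
    p[!tested | se == 0] <- NA
    p[tested & se == 0 & log2fc == 0] <- 1
    padj <- rep(NA_real_, length(p))
    padj[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
    status <- rep("ns", length(p))
    sig <- !is.na(padj) & padj < alpha & abs(log2fc) > lfcThreshold
    status[sig & log2fc > 0] <- "up"
    status[sig & log2fc < 0] <- "down"
    fam <- rownames(counts)
    if (is.null(fam))
        fam <- sprintf("fam%04d", seq_len(nrow(counts)))
    data.frame(family = fam, baseMean = rowMeans(norm),
               log2fc = log2fc, se = se, p = p, padj = padj,
               status = status, row.names = NULL)
}

#' Summary counts of differential expression results
#'
#' Counts total differentially expressed families, those above a
#' highlighted fold-change level, and the up/down split.
#'
#' @param results data.frame from \code{\link{nbWaldTest}}.
#' @param lfcHighlight Highlight threshold on |log2FC| (default 2).
#' @return List with \code{totalDE}, \code{highlightDE}, \code{up},
#'   \code{down}.
#' @export
thresholdReport <- function(results, lfcHighlight = 2) {
    de <- results$status != "ns"
    list(totalDE = sum(de),
         highlightDE = sum(de & abs(results$log2fc) > lfcHighlight),
         up = sum(results$status == "up"),
         down = sum(results$status == "down"))
}

#' Transcriptional load of TE families
#'
#' Percentage of total reads attributable to TE consensus sequences,
#' per sample, with per-condition means when conditions are given.
#'
#' @param totalReads Named numeric vector of total reads per sample.
#' @param teReads Named numeric vector of TE-assigned reads per
#'   sample (same order; must not exceed \code{totalReads}).
#' @param condition Optional condition labels per sample.
#' @return List with \code{perSample} (percent) and
#'   \code{perCondition} (mean percent per condition, or
#'   \code{NULL}).
#' @examples
#' transcriptionalLoad(c(s1 = 1000), c(s1 = 50))
#' @export
transcriptionalLoad <- function(totalReads, teReads, condition = NULL) {
    if (length(totalReads) != length(teReads))
        stop("totalReads and teReads must have equal length")
    if (any(teReads > totalReads))
        stop("TE-assigned reads exceed total reads")
    load <- 100 * teReads / totalReads
    perCond <- NULL
    if (!is.null(condition))
        perCond <- tapply(load, condition, mean)
    list(perSample = load, perCondition = perCond)
}
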