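## Independent brute-force oracles shared by unit and acceptance
## tests. Each re-implements a rule in the most literal way possible,
## without using package internals.

## Trim/split: mark kept positions, walk runs explicitly.
bruteTrimSplit <- function(seqChr, profile, thresholdFraction,
                           minSegment) {
    if (mean(profile) == 0)
        return(character(0))
    cutoff <- thresholdFraction * mean(profile)
    keep <- profile >= cutoff
    segs <- character(0)
    i <- 1L
    while (i <= length(keep)) {
        if (keep[i]) {
            j <- i
            while (j < length(keep) && keep[j + 1L]) j <- j + 1L
            if (j - i + 1L >= minSegment)
                segs <- c(segs, substr(seqChr, i, j))
            i <- j + 1L
        } else i <- i + 1L
    }
    segs
}

## K2P: plain site counting plus the closed form.
bruteK2P <- function(copy, consensus) {
    a <- strsplit(copy, "")[[1]]
    b <- strsplit(consensus, "")[[1]]
    nSites <- 0; nTs <- 0; nTv <- 0
    pur <- c("A", "G")
    for (i in seq_along(a)) {
        if (!a[i] %in% c("A", "C", "G", "T")) next
        if (!b[i] %in% c("A", "C", "G", "T")) next
        nSites <- nSites + 1
        if (a[i] != b[i]) {
            if ((a[i] %in% pur) == (b[i] %in% pur)) nTs <- nTs + 1
            else nTv <- nTv + 1
        }
    }
    p <- nTs / nSites; q <- nTv / nSites
    arg1 <- 1 - 2 * p - q; arg2 <- 1 - 2 * q
    if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
    -0.5 * log(arg1 * sqrt(arg2))
}

## 2-of-3 vote: literal counting over the three label slots.
voteOracle <- function(nt, prot, struct, tirPresent) {
    subs <- c(nt[1], prot[1], struct[1])
    subs <- subs[!is.na(subs)]
    subclass <- NA
    for (cand in unique(subs))
        if (sum(subs == cand) >= 2) subclass <- cand
    if (is.na(subclass))
        subclass <- if (tirPresent) "TIR" else "Unknown"
    sups <- c(nt[2], prot[2])
    sups <- sups[!is.na(sups)]
    superfam <- NA_character_
    for (cand in unique(sups))
        if (sum(sups == cand) >= 2) superfam <- cand
    list(subclass = subclass, superfamily = superfam)
}

## DE status thresholding: literal rule.
bruteStatus <- function(padj, lfc, alpha = 0.05, thr = 1) {
    status <- rep("ns", length(padj))
    sig <- !is.na(padj) & padj < alpha & abs(lfc) > thr
    status[sig & lfc > 0] <- "up"
    status[sig & lfc < 0] <- "down"
    status
}

## Support filter: recompute copy-equivalents directly.
bruteFilter <- function(lens, alignedBp, minLen = 200,
                        minCopyEquiv = 2) {
    names(lens)[lens >= minLen & alignedBp / lens >= minCopyEquiv]
}
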