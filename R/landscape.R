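## Divergence landscapes: overlap resolution and genome-fraction per
## K2P bin.

#' Resolve genomic overlaps between hits
#'
#' Attributes every genomic bp covered by hits to exactly one hit:
#' overlapping bp go to the higher-scoring hit (ties to the earlier
#' start, then input order). The total attributed bp per scaffold
#' equals the bp of the union of the hit intervals.
#'
#' @param hits Repeat-hit \code{GRanges}.
#' @return A \code{GRanges} of non-overlapping attributed fragments
#'   carrying the parent hit's metadata plus \code{hitIndex}.
#' @examples
#' h <- repeatHits("s", c(100, 150), c(200, 250), "+", c("a", "b"),
#'                 1, 100, score = c(300, 200))
#' resolveOverlaps(h)
#' @export
resolveOverlaps <- function(hits) {
    if (length(hits) == 0L)
        return(GRanges())
    ord <- order(-mcols(hits)$score, start(hits), seq_along(hits))
    frags <- list()
    taken <- GRanges()
    for (i in ord) {
        left <- setdiff(granges(hits[i], use.names = FALSE), taken,
                        ignore.strand = TRUE)
        if (length(left) > 0L) {
            mcols(left) <- cbind(
                mcols(hits)[rep(i, length(left)), , drop = FALSE],
                DataFrame(hitIndex = rep(i, length(left))))
            frags[[length(frags) + 1L]] <- left
            taken <- reduce(c(taken, granges(left)),
                            ignore.strand = TRUE)
        }
    }
    out <- sort(do.call(c, frags), ignore.strand = TRUE)
    out
}

#' Build a divergence landscape table
#'
#' Bins overlap-resolved TE bp by Kimura 2-parameter divergence (1\%
#' bins, 0 to \code{maxDiv}\%) per group (subclass or superfamily),
#' reporting bp and percent of genome per bin. Fragments whose hit
#' is saturated (missing divergence) or beyond \code{maxDiv} are
#' excluded and summed into the \code{"excludedBp"} attribute. By
#' default the per-hit Kimura divergence is used, falling back to the
#' alignment's percent divergence when absent.
#'
#' @param fragments Attributed fragments from
#'   \code{\link{resolveOverlaps}} (raw hits are accepted and
#'   resolved first).
#' @param genomeSize Genome size in bp.
#' @param groupBy \code{"subclass"} or \code{"superfamily"} (parsed
#'   from the hits' \code{teClass} labels).
#' @param maxDiv Upper divergence limit in percent (default 50).
#' @param weightBy \code{"bp"} (default) or \code{"copies"} (each
#'   fragment counts 1 instead of its width).
#' @return data.frame with columns \code{group}, \code{binLo},
#'   \code{binHi}, \code{bp}, \code{pctGenome} (complete bin grid per
#'   group), with attribute \code{"excludedBp"}.
#' @export
buildLandscape <- function(fragments, genomeSize,
                           groupBy = c("subclass", "superfamily"),
                           maxDiv = 50, weightBy = c("bp", "copies")) {
    groupBy <- match.arg(groupBy)
    weightBy <- match.arg(weightBy)
    if (length(fragments) > 0L &&
        is.null(mcols(fragments)$hitIndex))
        fragments <- resolveOverlaps(fragments)
    bins <- data.frame(binLo = 0:(maxDiv - 1L), binHi = 1:maxDiv)
    if (length(fragments) == 0L) {
        out <- data.frame(group = character(0), binLo = integer(0),
                          binHi = integer(0), bp = numeric(0),
                          pctGenome = numeric(0))
        attr(out, "excludedBp") <- 0
        return(out)
    }
    m <- mcols(fragments)
    div <- ifelse(is.na(m$kimuraDiv), m$pctDiv, m$kimuraDiv)
    lab <- .splitClassLabel(m$teClass)
    grp <- if (groupBy == "subclass") lab[, "subclass"] else
        ifelse(is.na(lab[, "superfamily"]), "none",
               lab[, "superfamily"])
    wt <- if (weightBy == "bp") width(fragments) else
        rep(1, length(fragments))
    ok <- !is.na(div) & div >= 0 & div < maxDiv
    excluded <- sum(wt[!ok])
    div <- div[ok]; grp <- grp[ok]; wt <- wt[ok]
    if (length(div) == 0L) {
        out <- data.frame(group = character(0), binLo = integer(0),
                          binHi = integer(0), bp = numeric(0),
                          pctGenome = numeric(0))
        attr(out, "excludedBp") <- excluded
        return(out)
    }
    out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
        sel <- grp == g
        bp <- vapply(seq_len(nrow(bins)), function(b)
            sum(wt[sel & div >= bins$binLo[b] & div < bins$binHi[b]]),
            numeric(1L))
        data.frame(group = g, bins, bp = bp,
                   pctGenome = 100 * bp / genomeSize)
    }))
    rownames(out) <- NULL
    attr(out, "excludedBp") <- excluded
    out
}

#' Find landscape modes
#'
#' Convenience helper: the divergence bin(s) holding the most bp per
#' group.
#'
#' @param landscape Output of \code{\link{buildLandscape}}.
#' @return data.frame with columns \code{group}, \code{modeBinLo}.
#' @export
landscapeModes <- function(landscape) {
    do.call(rbind, lapply(split(landscape, landscape$group),
        function(d) data.frame(group = d$group[1L],
                               modeBinLo = d$binLo[which.max(d$bp)])))
}
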