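## Built-in genome <-> library homology search: exact k-mer seeds on
## both strands, diagonal chaining, banded local alignment extension.

## Numeric k-mer codes (base 4) at every position of a sequence; NA
## where the window contains a non-ACGT character.
.kmerCodes <- function(seqChr, k) {
    b <- match(strsplit(seqChr, "")[[1L]], DNA_BASES4) - 1
    n <- length(b)
    if (n < k)
        return(numeric(0))
    m <- n - k + 1L
    code <- numeric(m)
    for (j in 0:(k - 1L))
        code <- code * 4 + b[(1L + j):(m + j)]
    code
}

## Sorted k-mer index of one scaffold: lookup of all exact-match
## positions for arbitrary query codes.
.scaffoldIndex <- function(scafChr, k) {
    codes <- .kmerCodes(scafChr, k)
    ok <- which(!is.na(codes))
    ord <- ok[order(codes[ok])]
    list(sorted = codes[ord], pos = ord)
}

## All (gStart, cPos) exact seed matches of query codes against an
## indexed scaffold.
.seedLookup <- function(index, qcodes, qpos) {
    ok <- !is.na(qcodes)
    qcodes <- qcodes[ok]; qpos <- qpos[ok]
    if (length(qcodes) == 0L || length(index$sorted) == 0L)
        return(data.frame(gStart = integer(0), cPos = integer(0)))
    hi <- findInterval(qcodes, index$sorted)
    lo <- findInterval(qcodes - 0.5, index$sorted) + 1L
    n <- pmax(hi - lo + 1L, 0L)
    sel <- n > 0L
    if (!any(sel))
        return(data.frame(gStart = integer(0), cPos = integer(0)))
    gStart <- index$pos[sequence(n[sel], from = lo[sel])]
    data.frame(gStart = gStart,
               cPos = rep.int(qpos[sel], n[sel]))
}

## Chain seeds into candidate (window, diagonal band) regions:
## group by diagonal (gaps > bandWidth split), then by genomic
## position (gaps > chainGap split).
.seedClusters <- function(seeds, seedK, clen, scafLen, chainGap,
                          bandWidth, pad = 60L, minSeeds = 2L) {
    if (nrow(seeds) == 0L)
        return(list())
    d <- seeds$gStart - seeds$cPos
    o <- order(d, seeds$gStart)
    g <- seeds$gStart[o]; cp <- seeds$cPos[o]; d <- d[o]
    grp <- cumsum(c(TRUE, diff(d) > bandWidth))
    out <- list()
    for (ii in split(seq_along(g), grp)) {
        oo <- ii[order(g[ii])]
        brk <- cumsum(c(TRUE, diff(g[oo]) > chainGap + seedK))
        for (jj in split(oo, brk)) {
            if (length(jj) < minSeeds)
                next
            ws <- max(1L, min(g[jj]) - (min(cp[jj]) - 1L) - pad)
            we <- min(scafLen, max(g[jj]) + seedK - 1L +
                          (clen - max(cp[jj])) + pad)
            out[[length(out) + 1L]] <- list(
                ws = as.integer(ws), we = as.integer(we),
                dmin = min(d[jj]) - bandWidth,
                dmax = max(d[jj]) + bandWidth)
        }
    }
    out
}

#' k-mer seeded homology search of a genome against a TE library
#'
#' A desk-scale interspersed-repeat search: exact \code{seedK}-mer
#' seeds (sampled every \code{seedStep} bp of each consensus, both
#' strands) are chained by diagonal, and each candidate region is
#' refined by banded local alignment with affine gaps
#' (+1 match, -1 mismatch, -4 gap open, -1 gap extend by default).
#' Hits scoring below \code{minScore} are suppressed. Percent
#' divergence, deletion and insertion are computed from the
#' alignment (per aligned column), and the Kimura 2-parameter
#' divergence of each hit is recorded. Near-duplicate hits of one
#' family (either strand; terminal-inverted-repeat elements match
#' their own reverse complement) are collapsed to the
#' highest-scoring one.
#'
#' @param genome Named \code{DNAStringSet} (or single
#'   \code{DNAString}).
#' @param library \code{\link{TELibrary}} or named
#'   \code{DNAStringSet} of consensus sequences.
#' @param minScore Minimum alignment score to report (default 200).
#' @param seedK Seed k-mer length (>= 8; default 11).
#' @param seedStep Consensus spacing of sampled seeds (default 4).
#' @param chainGap Maximum genomic gap between chained seeds
#'   (default 50).
#' @param bandWidth Half-width of the alignment band around the seed
#'   diagonals (default 32).
#' @param minSeeds Minimum chained seeds per candidate region
#'   (default 2; suppresses isolated random seed matches).
#' @param match,mismatch,gapOpen,gapExtend Alignment scores (gap
#'   penalties as positive costs).
#' @param cpgAdjusted Apply CpG down-weighting when computing the
#'   per-hit Kimura divergence.
#' @param returnAlignments Keep the gapped aligned strings as hit
#'   metadata columns \code{alignedConsensus} /
#'   \code{alignedGenome} (consensus in hit orientation).
#' @return A repeat-hit \code{GRanges} (see \code{\link{repeatHits}}).
#' @examples
#' lib <- TELibrary(Biostrings::DNAStringSet(
#'     c(fam1 = as.character(makeBackbone(500, seed = 5)))))
#' gen <- Biostrings::DNAStringSet(c(scf1 = paste0(
#'     as.character(makeBackbone(300, seed = 6)),
#'     as.character(consensusSeqs(lib)[[1]]),
#'     as.character(makeBackbone(300, seed = 7)))))
#' naiveHomologySearch(gen, lib)
#' @export
naiveHomologySearch <- function(genome, library, minScore = 200,
                                seedK = 11, seedStep = 4, chainGap = 50,
                                bandWidth = 32, minSeeds = 2, match = 1,
                                mismatch = -1,
                                gapOpen = 4, gapExtend = 1,
                                cpgAdjusted = TRUE,
                                returnAlignments = FALSE) {
    if (seedK < 8)
        stop("'seedK' must be >= 8")
    if (is(genome, "DNAString"))
        genome <- DNAStringSet(setNames(as.character(genome), "scf1"))
    if (!is(genome, "DNAStringSet"))
        genome <- DNAStringSet(genome)
    if (is.null(names(genome)))
        names(genome) <- paste0("scf", seq_along(genome))
    info <- NULL
    if (is(library, "TELibrary")) {
        info <- library@info
        library <- consensusSeqs(library)
    }
    if (!is(library, "DNAStringSet"))
        library <- DNAStringSet(library)
    emptyHits <- function() repeatHits(
        character(0), integer(0), integer(0), character(0),
        character(0), integer(0), integer(0), numeric(0))
    if (length(library) == 0L)
        return(emptyHits())
    ## per-consensus oriented sequences and sampled seed codes
    pats <- list()
    for (ci in seq_along(library)) {
        clen <- width(library)[ci]
        sp <- if (clen >= seedK)
            seq.int(1L, clen - seedK + 1L, by = seedStep) else integer(0)
        for (ostrand in c("+", "-")) {
            pat <- if (ostrand == "+") as.character(library[[ci]])
                   else as.character(reverseComplement(library[[ci]]))
            codes <- .kmerCodes(pat, seedK)
            pats[[length(pats) + 1L]] <- list(
                ci = ci, strand = ostrand, seq = pat, clen = clen,
                qcodes = codes[sp], qpos = sp)
        }
    }
    out <- list()
    for (si in seq_along(genome)) {
        scafName <- names(genome)[si]
        scafChr <- as.character(genome[[si]])
        scafLen <- nchar(scafChr)
        index <- .scaffoldIndex(scafChr, seedK)
        for (pt in pats) {
            cid <- names(library)[pt$ci]
            clen <- pt$clen
            teClass <- if (!is.null(info))
                .pasteClassLabel(info$subclass[pt$ci],
                                 info$superfamily[pt$ci])
            else "Unknown"
            seeds <- .seedLookup(index, pt$qcodes, pt$qpos)
            queue <- .seedClusters(seeds, seedK, clen, scafLen,
                                   chainGap, bandWidth,
                                   minSeeds = as.integer(minSeeds))
            guard <- 0L
            while (length(queue) > 0L && guard < 1000L) {
                guard <- guard + 1L
                cd <- queue[[1L]]; queue <- queue[-1L]
                subj <- substr(scafChr, cd$ws, cd$we)
                aln <- .bandedLocalAlign(
                    pt$seq, subj, match, mismatch, gapOpen, gapExtend,
                    as.integer(cd$dmin - cd$ws + 1L),
                    as.integer(cd$dmax - cd$ws + 1L))
                if (aln$score < minScore)
                    next
                qS <- cd$ws + aln$sStart - 1L
                qE <- cd$ws + aln$sEnd - 1L
                if (pt$strand == "+") {
                    cS <- aln$pStart; cEn <- aln$pEnd
                } else {
                    cS <- clen - aln$pEnd + 1L
                    cEn <- clen - aln$pStart + 1L
                }
                ncols <- aln$nMatch + aln$nMismatch + aln$nIns + aln$nDel
                out[[length(out) + 1L]] <- list(
                    scaffold = scafName, qStart = qS, qEnd = qE,
                    strand = pt$strand, consensusId = cid,
                    cStart = cS, cEnd = cEn, score = aln$score,
                    pctDiv = 100 * aln$nMismatch / ncols,
                    pctDel = 100 * aln$nDel / ncols,
                    pctIns = 100 * aln$nIns / ncols,
                    kimuraDiv = 100 * pairwiseK2P(
                        aln$alignedSubject, aln$alignedPattern,
                        cpgAdjusted = cpgAdjusted),
                    teClass = teClass, clen = clen,
                    scafLen = scafLen,
                    alignedConsensus = aln$alignedPattern,
                    alignedGenome = aln$alignedSubject)
                ## re-scan window remainders for further copies
                if (aln$sStart - 1L >= seedK + 20L)
                    queue <- c(queue, list(list(
                        ws = cd$ws, we = cd$ws + aln$sStart - 2L,
                        dmin = cd$dmin, dmax = cd$dmax)))
                if (cd$we - cd$ws + 1L - aln$sEnd >= seedK + 20L)
                    queue <- c(queue, list(list(
                        ws = cd$ws + aln$sEnd, we = cd$we,
                        dmin = cd$dmin, dmax = cd$dmax)))
            }
        }
    }
    if (length(out) == 0L)
        return(emptyHits())
    g <- function(k, chr = FALSE) vapply(out, `[[`, if (chr)
        character(1L) else numeric(1L), k)
    hits <- repeatHits(
        scaffold = g("scaffold", TRUE), qStart = g("qStart"),
        qEnd = g("qEnd"), strand = g("strand", TRUE),
        consensusId = g("consensusId", TRUE), cStart = g("cStart"),
        cEnd = g("cEnd"), score = g("score"), pctDiv = g("pctDiv"),
        pctDel = g("pctDel"), pctIns = g("pctIns"),
        kimuraDiv = g("kimuraDiv"), teClass = g("teClass", TRUE),
        scaffoldLength = g("scafLen"), consensusLength = g("clen"))
    if (returnAlignments) {
        mcols(hits)$alignedConsensus <- g("alignedConsensus", TRUE)
        mcols(hits)$alignedGenome <- g("alignedGenome", TRUE)
    }
    ## suppress near-duplicate hits (same family, either strand,
    ## >= 90% contained in a higher-scoring hit)
    keep <- rep(TRUE, length(hits))
    ord <- order(-mcols(hits)$score)
    grKey <- paste(mcols(hits)$consensusId, seqnames(hits))
    for (key in unique(grKey)) {
        ii <- ord[grKey[ord] == key]
        if (length(ii) <= 1L) next
        kept <- integer(0)
        for (i in ii) {
            if (length(kept) > 0L) {
                ov <- sum(width(intersect(
                    ranges(hits)[i], ranges(hits)[kept])))
                if (ov >= 0.9 * width(hits)[i]) {
                    keep[i] <- FALSE
                    next
                }
            }
            kept <- c(kept, i)
        }
    }
    hits <- hits[keep]
    sort(hits, ignore.strand = TRUE)
}
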