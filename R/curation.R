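## Consensus library curation: genomic-support trimming/splitting,
## 80/80 redundancy clustering, copy-support and tandem filters,
## seed-alignment extension, and the full curation pipeline.

#' Genomic coverage profile of a consensus
#'
#' Per-position count of genomic hits supporting each consensus
#' position: \code{depth[i]} is the number of hits whose consensus
#' interval covers position \code{i}.
#'
#' @param hits Repeat-hit \code{GRanges}.
#' @param consensusId Consensus id to profile.
#' @param consensusLength Consensus length in bp.
#' @return Integer vector of length \code{consensusLength}.
#' @examples
#' h <- repeatHits("s", c(1, 51), c(100, 150), "+", "f", c(1, 51),
#'                 c(100, 150), 100)
#' coverageProfile(h, "f", 150)
#' @export
coverageProfile <- function(hits, consensusId, consensusLength) {
    m <- mcols(hits)
    sel <- m$consensusId == consensusId
    cS <- m$cStart[sel]; cE <- m$cEnd[sel]
    if (any(cE > consensusLength))
        stop("hit consensus coordinates exceed consensus length")
    as.integer(coverage(IRanges(cS, cE), width = consensusLength))
}

#' Trim or split a consensus where genomic support drops
#'
#' The support cutoff is \code{thresholdFraction} times the mean
#' coverage depth. Maximal runs of positions at or above the cutoff
#' become output segments; terminal low-support runs are trimmed and
#' internal ones split the consensus. Segments shorter than
#' \code{minSegment} are dropped. Every output is a substring of the
#' input. An all-zero profile yields an empty set (flagged via the
#' \code{"flagged"} attribute, not an error).
#'
#' @param consensus \code{DNAString} or character sequence.
#' @param profile Integer coverage vector
#'   (\code{\link{coverageProfile}}).
#' @param thresholdFraction Cutoff as a fraction of the mean depth
#'   (default 0.05).
#' @param minSegment Minimum retained segment length in bp.
#' @param id Base name for the output segments.
#' @return A named \code{DNAStringSet} of segments (possibly empty).
#' @export
trimSplitConsensus <- function(consensus, profile,
                               thresholdFraction = 0.05,
                               minSegment = 50, id = "consensus") {
    seqChr <- toupper(as.character(consensus))
    if (nchar(seqChr) != length(profile))
        stop("profile length must equal consensus length")
    if (mean(profile) == 0) {
        out <- DNAStringSet()
        attr(out, "flagged") <- "no genomic support"
        return(out)
    }
    cutoff <- thresholdFraction * mean(profile)
    r <- rle(profile >= cutoff)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minSegment
    if (!any(keep))
        return(DNAStringSet())
    segs <- substring(seqChr, starts[keep], ends[keep])
    nm <- if (sum(keep) == 1L) id else
        paste0(id, ".seg", seq_len(sum(keep)))
    DNAStringSet(setNames(segs, nm))
}

## Identity and shorter-sequence coverage of two sequences, taking the
## better of the two relative orientations. A shared-k-mer prescreen
## skips clearly unrelated pairs, and the alignment band is restricted
## to the diagonals a near-duplicate can occupy.
.pairIdentity <- function(a, b, prescreen = TRUE) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    none <- list(score = 0, identity = 0, coverage = 0)
    k <- 11L
    bCodes <- NULL
    shared <- function(pat) {
        pc <- .kmerCodes(pat, k)
        sum(!is.na(pc) & pc %in% bCodes)
    }
    if (prescreen && nchar(a) > 3L * k) {
        bCodes <- .kmerCodes(b, k)
        bCodes <- bCodes[!is.na(bCodes)]
        minShared <- max(4, 0.02 * (nchar(a) - k + 1L))
    }
    drift <- 400L
    run <- function(pat) {
        if (!is.null(bCodes) && shared(pat) < minShared)
            return(none)
        aln <- .bandedLocalAlign(pat, b, 1, -1, 4, 1,
                                 -drift, nchar(b) - nchar(pat) + drift)
        ncols <- aln$nMatch + aln$nMismatch + aln$nIns + aln$nDel
        list(score = aln$score,
             identity = if (ncols == 0) 0 else aln$nMatch / ncols,
             coverage = (aln$nMatch + aln$nMismatch + aln$nDel) /
                 nchar(pat))
    }
    r1 <- run(a)
    r2 <- run(as.character(reverseComplement(DNAString(a))))
    if (r2$score > r1$score) r2 else r1
}

#' Remove redundant consensus sequences (80/80 rule)
#'
#' Greedy length-descending clustering: a sequence is absorbed by an
#' existing (longer) representative when the two align at
#' \code{identity} or more over at least \code{coverage} of the
#' shorter sequence's length (either orientation). One
#' representative, the longest, is kept per cluster, so the output is
#' pairwise non-redundant under the same test. The operation is
#' idempotent.
#'
#' @param library \code{\link{TELibrary}} or named
#'   \code{DNAStringSet}.
#' @param identity Minimum pairwise identity (default 0.80).
#' @param coverage Minimum aligned fraction of the shorter sequence
#'   (default 0.80).
#' @return The deduplicated library (same class as the input), with a
#'   \code{"members"} attribute mapping each input id to its
#'   representative.
#' @export
clusterLibrary <- function(library, identity = 0.80, coverage = 0.80) {
    seqs <- if (is(library, "TELibrary")) consensusSeqs(library)
            else library
    if (length(seqs) == 0L)
        stop("'library' must be non-empty")
    ord <- order(-width(seqs))
    reps <- integer(0)
    members <- setNames(character(length(seqs)), names(seqs))
    for (i in ord) {
        absorbed <- FALSE
        for (r in reps) {
            st <- .pairIdentity(seqs[[i]], seqs[[r]])
            if (st$identity >= identity && st$coverage >= coverage) {
                members[i] <- names(seqs)[r]
                absorbed <- TRUE
                break
            }
        }
        if (!absorbed) {
            reps <- c(reps, i)
            members[i] <- names(seqs)[i]
        }
    }
    reps <- sort(reps)
    out <- if (is(library, "TELibrary")) library[reps]
           else library[reps]
    attr(out, "members") <- members
    out
}

#' Filter a library on length and genomic copy support
#'
#' The copy-equivalent of a consensus is the total genomic bp aligned
#' to it divided by its length. In the default (strict) mode a
#' consensus is kept iff its length is at least \code{minLen} and its
#' copy-equivalent at least \code{minCopyEquiv}; the lenient mode
#' keeps a consensus when either condition holds (the two readings of
#' a removal rule phrased with "and").
#'
#' @param library \code{\link{TELibrary}} or named
#'   \code{DNAStringSet}.
#' @param hits Repeat-hit \code{GRanges} computed against this
#'   library.
#' @param minLen Minimum consensus length (default 200 bp).
#' @param minCopyEquiv Minimum copy-equivalent (default 2.0).
#' @param mode \code{"strict"} (keep iff both hold; default) or
#'   \code{"lenient"} (keep iff either holds).
#' @return The filtered library, with a \code{"copyEquiv"} attribute.
#' @export
filterLibrary <- function(library, hits, minLen = 200,
                          minCopyEquiv = 2.0,
                          mode = c("strict", "lenient")) {
    mode <- match.arg(mode)
    seqs <- if (is(library, "TELibrary")) consensusSeqs(library)
            else library
    alignedBp <- tapply(width(hits), mcols(hits)$consensusId, sum)
    ce <- as.numeric(alignedBp[names(seqs)])
    ce[is.na(ce)] <- 0
    ce <- ce / width(seqs)
    names(ce) <- names(seqs)
    lenOk <- width(seqs) >= minLen
    ceOk <- ce >= minCopyEquiv
    keep <- if (mode == "strict") lenOk & ceOk else lenOk | ceOk
    out <- library[which(keep)]
    attr(out, "copyEquiv") <- ce
    out
}

#' Detect tandem repeats by k-mer periodicity
#'
#' Finds intervals where the sequence matches itself at a small
#' offset (period at most \code{maxPeriod}) for at least
#' \code{minUnits} repeat units, the signature of satellite/simple
#' tandem arrays.
#'
#' @param consensus \code{DNAString} or character sequence.
#' @param maxPeriod Largest period considered (default 12 bp).
#' @param minUnits Minimum number of tandem units (default 3).
#' @return An \code{IRanges} of masked (tandem) intervals.
#' @examples
#' tandemMask(strrep("ACGT", 100))
#' @export
tandemMask <- function(consensus, maxPeriod = 12, minUnits = 3) {
    s <- utf8ToInt(toupper(as.character(consensus)))
    n <- length(s)
    masks <- IRanges()
    for (p in seq_len(min(maxPeriod, n - 1L))) {
        eq <- s[seq_len(n - p)] == s[(p + 1L):n]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        hit <- r$values & r$lengths >= (minUnits - 1L) * p
        if (any(hit))
            masks <- c(masks, IRanges(starts[hit], ends[hit] + p))
    }
    reduce(masks)
}

#' Keep/drop decision of the tandem-repeat filter
#'
#' A consensus is dropped when more than \code{maxMasked} of its
#' length is tandem-masked or when it is shorter than \code{minLen}.
#'
#' @param consensus \code{DNAString} or character sequence.
#' @param mask Optional precomputed \code{IRanges} mask (defaults to
#'   \code{\link{tandemMask}} of the sequence).
#' @param minLen Minimum length to keep (default 100 bp).
#' @param maxMasked Maximum tolerated masked fraction (default 0.80).
#' @return List with \code{keep} (logical), \code{maskedFraction}
#'   and \code{length}.
#' @export
tandemFilter <- function(consensus, mask = NULL, minLen = 100,
                         maxMasked = 0.80) {
    len <- nchar(as.character(consensus))
    if (is.null(mask))
        mask <- tandemMask(consensus)
    if (length(mask) > 0L && max(end(mask)) > len)
        stop("mask intervals exceed consensus length")
    mf <- sum(width(reduce(mask))) / len
    list(keep = !(mf > maxMasked || len < minLen),
         maskedFraction = mf, length = len)
}

#' Extend a consensus into the genomic flanks of its instances
#'
#' Appends columns one at a time on each side of a seed alignment:
#' per column, each instance contributes its next flanking base, the
#' consensus base is the one maximizing the summed log-odds score of
#' the contributing bases (K2P model at 20\% divergence and 43\% GC
#' background, scaled so a match averages about +10), and extension
#' on a side stops as soon as the net column score does not exceed
#' \code{stopGain} (default 27, about three sequences in agreement)
#' or \code{maxExtend} is reached. Instances advance through their
#' flanks column-synchronously (no gaps are opened during
#' extension).
#'
#' @param seed A \code{\link{SeedAlignment}} with recorded flanks.
#' @param stopGain Net column score at or below which extension stops
#'   (default 27).
#' @param maxExtend Maximum extension per side in bp (default 500).
#' @param substitutionMatrix Log-odds matrix (default
#'   \code{\link{k2pLogOddsMatrix}()}).
#' @return List with \code{sequence} (extended consensus
#'   \code{DNAString}), \code{extendedLeft} and \code{extendedRight}
#'   (bp added per side).
#' @export
extendConsensus <- function(seed, stopGain = 27, maxExtend = 500,
                            substitutionMatrix = k2pLogOddsMatrix()) {
    stopifnot(is(seed, "SeedAlignment"))
    validObject(seed)
    if (length(seed) == 0L)
        stop("empty seed alignment")
    ## core consensus: majority base per alignment column
    rows <- strsplit(seed@alignment, "")
    mat <- do.call(rbind, rows)
    core <- apply(mat, 2L, function(col) {
        col <- col[col %in% DNA_BASES4]
        if (length(col) == 0L) return(NA_character_)
        names(which.max(table(col)))
    })
    core <- paste(core[!is.na(core)], collapse = "")
    extendSide <- function(flanks, fromRight) {
        ext <- character(0)
        offs <- integer(length(flanks))
        lens <- nchar(flanks)
        while (length(ext) < maxExtend) {
            avail <- which(offs < lens)
            if (length(avail) == 0L)
                break
            bases <- vapply(avail, function(i) {
                pos <- if (fromRight) offs[i] + 1L else lens[i] - offs[i]
                substr(flanks[i], pos, pos)
            }, character(1L))
            contrib <- bases %in% DNA_BASES4
            if (!any(contrib))
                break
            colScores <- colSums(
                substitutionMatrix[bases[contrib], , drop = FALSE])
            if (max(colScores) <= stopGain)
                break
            ext <- c(ext, names(which.max(colScores)))
            offs[avail] <- offs[avail] + 1L
        }
        ext
    }
    rightExt <- extendSide(seed@rightFlank, fromRight = TRUE)
    leftExt <- rev(extendSide(seed@leftFlank, fromRight = FALSE))
    list(sequence = DNAString(paste0(paste(leftExt, collapse = ""),
                                     core,
                                     paste(rightExt, collapse = ""))),
         extendedLeft = length(leftExt),
         extendedRight = length(rightExt))
}

#' Build seed alignments (with flanks) from hits
#'
#' Converts the hits of one consensus into a gapped
#' \code{\link{SeedAlignment}} in consensus coordinates (insertions
#' relative to the consensus are dropped, deletions become gaps),
#' recording up to \code{flank} bp of genomic sequence on each side
#' of every instance.
#'
#' @param hits Repeat-hit \code{GRanges} produced with
#'   \code{returnAlignments = TRUE}.
#' @param genome Named \code{DNAStringSet}.
#' @param consensusId Consensus to collect instances for.
#' @param consensusLength Consensus length (bp).
#' @param flank Flank length to record per side (default 200 bp).
#' @param maxRows Use at most this many highest-scoring instances.
#' @return A \code{SeedAlignment}.
#' @export
makeSeedAlignment <- function(hits, genome, consensusId,
                              consensusLength, flank = 200,
                              maxRows = 50) {
    m <- mcols(hits)
    if (is.null(m$alignedConsensus))
        stop("hits must carry alignments (returnAlignments = TRUE)")
    sel <- which(m$consensusId == consensusId)
    if (length(sel) == 0L)
        stop("no hits for consensus ", consensusId)
    sel <- sel[order(-m$score[sel])]
    sel <- head(sel, maxRows)
    rows <- character(0); lf <- character(0); rf <- character(0)
    for (i in sel) {
        ac <- m$alignedConsensus[i]; ag <- m$alignedGenome[i]
        isMinus <- as.character(strand(hits))[i] == "-"
        if (isMinus) {
            ac <- as.character(reverseComplement(DNAString(ac)))
            ag <- as.character(reverseComplement(DNAString(ag)))
        }
        consChars <- strsplit(ac, "")[[1L]]
        genChars <- strsplit(ag, "")[[1L]]
        keep <- consChars != "-"           # drop genome insertions
        aligned <- ifelse(genChars[keep] == "-", "-", genChars[keep])
        row <- paste0(strrep("-", m$cStart[i] - 1L),
                      paste(aligned, collapse = ""),
                      strrep("-", consensusLength - m$cEnd[i]))
        scaf <- as.character(genome[[as.character(seqnames(hits))[i]]])
        gS <- start(hits)[i]; gE <- end(hits)[i]
        upstream <- substr(scaf, max(1L, gS - flank), gS - 1L)
        downstream <- substr(scaf, gE + 1L,
                             min(nchar(scaf), gE + flank))
        if (isMinus) {
            tmp <- as.character(
                reverseComplement(DNAString(downstream)))
            downstream <- as.character(
                reverseComplement(DNAString(upstream)))
            upstream <- tmp
        }
        rows <- c(rows, row); lf <- c(lf, upstream); rf <- c(rf, downstream)
    }
    names(rows) <- paste0(consensusId, ".copy", seq_along(rows))
    SeedAlignment(consensusId, rows, leftFlank = lf, rightFlank = rf)
}

#' Run the full library curation pipeline
#'
#' Quantifies a raw consensus library against a genome and applies,
#' in order: coverage-based trimming/splitting, 80/80 redundancy
#' clustering, re-quantification, the length/copy-support filter and
#' the tandem-repeat filter, optionally followed by seed-alignment
#' extension and a final 80/80 deduplication. Every decision is
#' recorded in a report.
#'
#' @param rawLibrary \code{\link{TELibrary}} or named
#'   \code{DNAStringSet} of raw consensus sequences.
#' @param genome Named \code{DNAStringSet}.
#' @param minScore,seedK Search parameters
#'   (\code{\link{naiveHomologySearch}}).
#' @param thresholdFraction,minSegment Trim/split parameters.
#' @param identity,coverage 80/80 clustering parameters.
#' @param minLen,minCopyEquiv,filterMode Support-filter parameters.
#' @param tandemMinLen,tandemMaxMasked Tandem-filter parameters.
#' @param extend Run seed-alignment extension (default \code{FALSE}).
#' @param maxExtend Maximum extension per side (bp).
#' @return List with \code{library} (curated \code{TELibrary}),
#'   \code{hits} (final hit table) and \code{report} (data.frame of
#'   decisions: step, consensus, action, detail).
#' @export
curateLibrary <- function(rawLibrary, genome, minScore = 200,
                          seedK = 11, thresholdFraction = 0.05,
                          minSegment = 50, identity = 0.80,
                          coverage = 0.80, minLen = 200,
                          minCopyEquiv = 2.0, filterMode = "strict",
                          tandemMinLen = 100, tandemMaxMasked = 0.80,
                          extend = FALSE, maxExtend = 500) {
    seqs <- if (is(rawLibrary, "TELibrary")) consensusSeqs(rawLibrary)
            else DNAStringSet(rawLibrary)
    report <- list()
    note <- function(step, consensus, action, detail = "")
        report[[length(report) + 1L]] <<- data.frame(
            step = step, consensus = consensus, action = action,
            detail = detail)
    ## 1. quantify and trim/split
    hits1 <- naiveHomologySearch(genome, seqs, minScore = minScore,
                                 seedK = seedK)
    segs <- DNAStringSet()
    rawW <- setNames(width(seqs), names(seqs))
    for (id in names(seqs)) {
        prof <- coverageProfile(hits1, id, rawW[[id]])
        out <- trimSplitConsensus(seqs[[id]], prof,
                                  thresholdFraction = thresholdFraction,
                                  minSegment = minSegment, id = id)
        if (length(out) == 0L)
            note("trim_split", id, "drop",
                 if (is.null(attr(out, "flagged"))) "below_min_segment"
                 else attr(out, "flagged"))
        else if (length(out) == 1L &&
                 width(out)[1L] == rawW[[id]])
            note("trim_split", id, "keep", "full_support")
        else
            note("trim_split", id,
                 if (length(out) > 1L) "split" else "trim",
                 paste0(length(out), " segment(s)"))
        segs <- c(segs, out)
    }
    if (length(segs) == 0L)
        stop("no consensus survived trimming")
    ## 2. cluster 80/80
    clustered <- clusterLibrary(segs, identity = identity,
                                coverage = coverage)
    members <- attr(clustered, "members")
    for (id in names(members)[members != names(members)])
        note("cluster", id, "merge", paste0("into ", members[id]))
    ## 3. re-quantify and filter on support
    hits2 <- naiveHomologySearch(genome, clustered, minScore = minScore,
                                 seedK = seedK,
                                 returnAlignments = extend)
    filtered <- filterLibrary(clustered, hits2, minLen = minLen,
                              minCopyEquiv = minCopyEquiv,
                              mode = filterMode)
    ce <- attr(filtered, "copyEquiv")
    clW <- setNames(width(clustered), names(clustered))
    for (id in setdiff(names(clustered), names(filtered)))
        note("support_filter", id, "drop",
             sprintf("len=%d copy_equiv=%.2f", clW[[id]], ce[[id]]))
    ## 4. tandem filter
    keep <- vapply(names(filtered), function(id) {
        tf <- tandemFilter(filtered[[id]], minLen = tandemMinLen,
                           maxMasked = tandemMaxMasked)
        if (!tf$keep)
            note("tandem_filter", id, "drop",
                 sprintf("masked=%.2f len=%d", tf$maskedFraction,
                         tf$length))
        tf$keep
    }, logical(1L))
    final <- filtered[which(keep)]
    ## 5. optional extension + re-deduplication
    if (extend && length(final) > 0L) {
        ext <- DNAStringSet(setNames(vapply(names(final), function(id) {
            res <- tryCatch({
                sa <- makeSeedAlignment(hits2, genome, id,
                                        nchar(as.character(final[[id]])))
                e <- extendConsensus(sa, maxExtend = maxExtend)
                if (e$extendedLeft + e$extendedRight > 0L)
                    note("extend", id, "extend",
                         sprintf("left=%d right=%d", e$extendedLeft,
                                 e$extendedRight))
                as.character(e$sequence)
            }, error = function(e) as.character(final[[id]]))
            res
        }, character(1L)), names(final)))
        final <- clusterLibrary(ext, identity = identity,
                                coverage = coverage)
        members <- attr(final, "members")
        for (id in names(members)[members != names(members)])
            note("post_extend_cluster", id, "merge",
                 paste0("into ", members[id]))
    }
    finalLib <- TELibrary(DNAStringSet(final),
                          provenance = "curated")
    hitsFinal <- naiveHomologySearch(genome, finalLib,
                                     minScore = minScore, seedK = seedK)
    list(library = finalLib, hits = hitsFinal,
         report = do.call(rbind, report))
}
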