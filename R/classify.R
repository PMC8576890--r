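## Subclass/superfamily classification: nucleotide and translated
## protein homology, TIR structure, 2-of-3 voting, MITE calling.

#' Find open reading frames in all six frames
#'
#' Scans both strands in all three frames. Within each stop-free
#' stretch, the ORF runs from the leftmost ATG to the following stop
#' (or the end of the frame), so one maximal ORF is reported per
#' stretch.
#'
#' @param seq \code{DNAString} or character sequence.
#' @param minAa Minimum ORF length in amino acids (default 100).
#' @return A data.frame with columns \code{strand}, \code{frame},
#'   \code{start}, \code{end} (nt, forward-strand coordinates,
#'   stop codon excluded), \code{lengthAa}, \code{peptide}.
#' @export
findOrfs <- function(seq, minAa = 100) {
    seqChr <- toupper(as.character(seq))
    L <- nchar(seqChr)
    empty <- data.frame(strand = character(0), frame = integer(0),
                        start = integer(0), end = integer(0),
                        lengthAa = integer(0), peptide = character(0))
    if (L < 3L)
        return(empty)
    res <- list()
    for (std in c("+", "-")) {
        s <- if (std == "+") seqChr else
            as.character(reverseComplement(DNAString(seqChr)))
        for (off in 0:2) {
            nCod <- (L - off) %/% 3L
            if (nCod < 1L)
                next
            aa <- strsplit(as.character(suppressWarnings(translate(
                DNAString(substr(s, off + 1L, off + 3L * nCod)),
                if.fuzzy.codon = "X"))), "")[[1L]]
            stops <- which(aa == "*")
            segStart <- c(1L, stops + 1L)
            segEnd <- c(stops - 1L, length(aa))
            for (k in seq_along(segStart)) {
                a <- segStart[k]; b <- segEnd[k]
                if (b < a) next
                mpos <- which(aa[a:b] == "M")[1L]
                if (is.na(mpos)) next
                stAa <- a + mpos - 1L
                lenAa <- b - stAa + 1L
                if (lenAa < minAa) next
                ntStart <- off + 3L * (stAa - 1L) + 1L
                ntEnd <- off + 3L * b
                if (std == "-") {
                    tmp <- L - ntEnd + 1L
                    ntEnd <- L - ntStart + 1L
                    ntStart <- tmp
                }
                res[[length(res) + 1L]] <- data.frame(
                    strand = std, frame = off + 1L, start = ntStart,
                    end = ntEnd, lengthAa = lenAa,
                    peptide = paste(aa[stAa:b], collapse = ""))
            }
        }
    }
    if (length(res) == 0L) empty else do.call(rbind, res)
}

#' Nucleotide-homology classification vote
#'
#' Searches the consensus against a labeled reference library.
#' Per superfamily, scores of non-overlapping hits on the consensus
#' are summed (greedy by score), so fragments of related families can
#' contribute to the same call; the best-scoring superfamily wins. A
#' call is emitted only when the combined hit length reaches
#' \code{minLengthRatio} of the consensus length (default 0.08).
#'
#' @param consensus \code{DNAString} or character sequence.
#' @param referenceLibrary Labeled \code{\link{TELibrary}}.
#' @param minLengthRatio Minimum combined hit length / consensus
#'   length (default 0.08).
#' @param minScore Minimum per-hit alignment score (default 50).
#' @return A \code{\link{HomologyCall}} or \code{NULL}.
#' @export
ntHomologyCall <- function(consensus, referenceLibrary,
                           minLengthRatio = 0.08, minScore = 50) {
    clen <- nchar(as.character(consensus))
    hits <- naiveHomologySearch(
        DNAStringSet(setNames(as.character(consensus), "query")),
        referenceLibrary, minScore = minScore)
    if (length(hits) == 0L)
        return(NULL)
    m <- mcols(hits)
    groups <- split(seq_along(hits), m$teClass)
    best <- NULL
    for (cls in names(groups)) {
        ii <- groups[[cls]][order(-m$score[groups[[cls]]])]
        chosen <- integer(0)
        for (i in ii) {
            if (length(chosen) == 0L ||
                sum(width(intersect(ranges(hits)[i],
                                    ranges(hits)[chosen]))) == 0L)
                chosen <- c(chosen, i)
        }
        cand <- list(teClass = cls,
                     score = sum(m$score[chosen]),
                     covered = sum(width(reduce(ranges(hits)[chosen]))))
        if (is.null(best) || cand$score > best$score)
            best <- cand
    }
    ratio <- min(1, best$covered / clen)
    if (ratio < minLengthRatio)
        return(NULL)
    lab <- .splitClassLabel(best$teClass)
    homologyCall("nt", lab[, "subclass"], lab[, "superfamily"],
                 score = best$score, lengthRatio = ratio)
}

## Six-frame translations of a sequence (with '*' for stops).
.sixFrameTranslations <- function(seqChr) {
    L <- nchar(seqChr)
    out <- list()
    for (std in c("+", "-")) {
        s <- if (std == "+") seqChr else
            as.character(reverseComplement(DNAString(seqChr)))
        for (off in 0:2) {
            nCod <- (L - off) %/% 3L
            if (nCod < 1L) next
            out[[paste0(std, off + 1L)]] <- as.character(
                suppressWarnings(translate(
                    DNAString(substr(s, off + 1L, off + 3L * nCod)),
                    if.fuzzy.codon = "X")))
        }
    }
    out
}

#' Translated-protein homology classification vote
#'
#' Translates the consensus in all six frames and aligns each frame
#' locally (BLOSUM62) against a labeled collection of TE proteins;
#' the best-scoring hit is kept. A call is emitted only when the hit
#' length (in aa, times 3) reaches \code{minLengthRatio} of the
#' consensus length (default 0.03).
#'
#' @param consensus \code{DNAString} or character sequence.
#' @param proteinSet Named \code{AAStringSet}; labels embedded in the
#'   names as \code{id#subclass/superfamily}.
#' @param minLengthRatio Minimum hit length ratio (default 0.03).
#' @param minScore Minimum alignment score (default 60).
#' @return A \code{\link{HomologyCall}} or \code{NULL}.
#' @export
proteinHomologyCall <- function(consensus, proteinSet,
                                minLengthRatio = 0.03, minScore = 60) {
    if (length(proteinSet) == 0L)
        return(NULL)
    clen <- nchar(as.character(consensus))
    frames <- .sixFrameTranslations(toupper(as.character(consensus)))
    data("BLOSUM62", package = "Biostrings", envir = environment())
    best <- NULL
    for (fr in frames) {
        frAA <- AAString(fr)
        for (pi in seq_along(proteinSet)) {
            aln <- pairwiseAlignment(
                proteinSet[[pi]], frAA, type = "local",
                substitutionMatrix = BLOSUM62,
                gapOpening = 10, gapExtension = 1)
            sc <- score(aln)
            if (is.null(best) || sc > best$score) {
                hitAa <- width(subject(aln)@range)
                best <- list(score = sc, name = names(proteinSet)[pi],
                             hitAa = hitAa)
            }
        }
    }
    if (best$score < minScore)
        return(NULL)
    ratio <- min(1, 3 * best$hitAa / clen)
    if (ratio < minLengthRatio)
        return(NULL)
    lab <- .splitClassLabel(sub("^[^#]*#", "", best$name))
    homologyCall("protein", lab[, "subclass"], lab[, "superfamily"],
                 score = best$score, lengthRatio = ratio)
}

#' Detect terminal inverted repeats
#'
#' Aligns the 5' window of a consensus against the reverse complement
#' of its 3' window (local dynamic programming; match +3,
#' mismatch -4, affine gaps, einverted-like defaults) and reports the
#' best-scoring arm pair whose arms start within \code{maxOffset} bp
#' of their respective termini.
#'
#' @param consensus \code{DNAString} or character sequence (length
#'   > 2 * \code{minArm}).
#' @param maxOffset Maximum distance of each arm from its terminus
#'   (default 100 bp).
#' @param minArm Minimum arm length (default 10 bp).
#' @param minIdentity Minimum fraction of identical arm columns
#'   (default 0.6).
#' @param minScore Minimum alignment score to report (default 50).
#' @param maxArmWindow Largest arm length searched for (default 600
#'   bp).
#' @return A \code{\link{TIRPair}} or \code{NULL}.
#' @export
findTIRs <- function(consensus, maxOffset = 100, minArm = 10,
                     minIdentity = 0.6, minScore = 50,
                     maxArmWindow = 600) {
    seqChr <- toupper(as.character(consensus))
    L <- nchar(seqChr)
    if (L <= 2L * minArm)
        return(NULL)
    w <- min(L %/% 2L, maxArmWindow + maxOffset)
    left <- DNAString(substr(seqChr, 1L, w))
    right <- DNAString(substr(seqChr, L - w + 1L, L))
    mat <- nucleotideSubstitutionMatrix(match = 3, mismatch = -4,
                                        baseOnly = TRUE)
    aln <- pairwiseAlignment(left, reverseComplement(right),
                             type = "local", substitutionMatrix = mat,
                             gapOpening = 12, gapExtension = 4)
    if (score(aln) < minScore)
        return(NULL)
    pr <- pattern(aln)@range
    sr <- subject(aln)@range
    leftStart <- start(pr); leftEnd <- end(pr)
    rightStart <- L - end(sr) + 1L; rightEnd <- L - start(sr) + 1L
    offset5 <- leftStart - 1L
    offset3 <- start(sr) - 1L
    armLength <- as.integer(round((width(pr) + width(sr)) / 2))
    cols <- nmatch(aln) + nmismatch(aln) +
        sum(nindel(aln)@insertion[, "WidthSum"]) +
        sum(nindel(aln)@deletion[, "WidthSum"])
    armIdentity <- nmatch(aln) / cols
    if (offset5 > maxOffset || offset3 > maxOffset ||
        armLength < minArm || armIdentity < minIdentity ||
        leftEnd >= rightStart)
        return(NULL)
    new("TIRPair", leftStart = leftStart, leftEnd = leftEnd,
        rightStart = as.integer(rightStart),
        rightEnd = as.integer(rightEnd), armLength = armLength,
        armIdentity = armIdentity, offset5 = offset5,
        offset3 = as.integer(offset3), score = score(aln))
}

#' Two-of-three classification vote
#'
#' Combines the nucleotide, protein and structural votes: the
#' subclass is the value at least two sources agree on; with no
#' majority the consensus falls back to \code{"TIR"} when a terminal
#' inverted repeat was detected, else \code{"Unknown"}. The
#' superfamily is the value at least two sources agree on, else
#' none (the structural source never names a superfamily).
#'
#' @param calls List of \code{\link{HomologyCall}} objects (at most
#'   one per source; \code{NULL} entries allowed).
#' @param tir A \code{\link{TIRPair}} or \code{NULL}. When present
#'   and no explicit structural call is given, it contributes a
#'   structural \code{"TIR"} vote.
#' @return List with \code{subclass} and \code{superfamily}
#'   (\code{NA} for none).
#' @examples
#' voteClassification(list(
#'     homologyCall("nt", "TIR", "Tc-Mar"),
#'     homologyCall("protein", "TIR", "hAT")))
#' @export
voteClassification <- function(calls, tir = NULL) {
    calls <- Filter(Negate(is.null), calls)
    sources <- vapply(calls, function(x) x@source, character(1L))
    if (anyDuplicated(sources))
        stop("at most one call per source allowed")
    if (!is.null(tir) && !"structural" %in% sources)
        calls <- c(calls, homologyCall("structural", "TIR"))
    subs <- vapply(calls, function(x) x@subclass, character(1L))
    sups <- vapply(calls, function(x) x@superfamily, character(1L))
    subclass <- NA_character_
    if (length(subs) > 0L) {
        tab <- sort(table(subs), decreasing = TRUE)
        if (tab[1L] >= 2L)
            subclass <- names(tab)[1L]
    }
    if (is.na(subclass))
        subclass <- if (!is.null(tir)) "TIR" else "Unknown"
    superfam <- NA_character_
    supsOk <- sups[!is.na(sups)]
    if (length(supsOk) > 0L) {
        tab <- sort(table(supsOk), decreasing = TRUE)
        if (tab[1L] >= 2L)
            superfam <- names(tab)[1L]
    }
    list(subclass = subclass, superfamily = superfam)
}

#' MITE call
#'
#' A consensus is called a MITE (miniature inverted-repeat
#' transposable element) when it carries terminal inverted repeats
#' but no coding capacity: no ORF of at least 100 aa, no
#' translated-protein homology, and a total length at most
#' \code{lengthCap} (default 1000 bp).
#'
#' @param consensus \code{DNAString} or character sequence.
#' @param tir \code{\link{TIRPair}} (required non-\code{NULL} for a
#'   positive call).
#' @param orfs ORF table from \code{\link{findOrfs}} (computed if
#'   missing).
#' @param proteinCall \code{\link{HomologyCall}} from
#'   \code{\link{proteinHomologyCall}} or \code{NULL}.
#' @param lengthCap Maximum MITE length (default 1000 bp).
#' @return Logical flag.
#' @export
callMITE <- function(consensus, tir, orfs = NULL, proteinCall = NULL,
                     lengthCap = 1000) {
    if (is.null(tir))
        return(FALSE)
    if (is.null(orfs))
        orfs <- findOrfs(consensus, minAa = 100)
    nchar(as.character(consensus)) <= lengthCap &&
        nrow(orfs) == 0L && is.null(proteinCall)
}

#' Extract peptides from an unclassified consensus
#'
#' All six-frame ORF translations of at least \code{minLenAa} amino
#' acids, deduplicated — the input for external protein-domain
#' screening of unknown repeats.
#'
#' @param consensus \code{DNAString} or character sequence.
#' @param minLenAa Minimum peptide length (default 100 aa).
#' @return An \code{AAStringSet} (possibly empty).
#' @export
extractUnknownPeptides <- function(consensus, minLenAa = 100) {
    orfs <- findOrfs(consensus, minAa = minLenAa)
    peps <- unique(orfs$peptide)
    if (length(peps) == 0L)
        return(AAStringSet())
    AAStringSet(setNames(peps, paste0("pep", seq_along(peps))))
}

#' TIR length statistics of a library
#'
#' Per consensus with a detected terminal inverted repeat: the arm
#' length and the internal region length (consensus length minus both
#' arms), with the superfamily — the inputs for TIR-length and
#' internal-length distribution plots. Consensus sequences without a
#' TIR are excluded.
#'
#' @param library A \code{\link{TELibrary}}.
#' @param ... Passed to \code{\link{findTIRs}}.
#' @return data.frame with columns \code{consensus},
#'   \code{tirLength}, \code{internalLength}, \code{superfamily}.
#' @export
tirStatistics <- function(library, ...) {
    rows <- list()
    seqs <- consensusSeqs(library)
    sup <- superfamily(library)
    for (id in names(seqs)) {
        tir <- findTIRs(seqs[[id]], ...)
        if (is.null(tir))
            next
        len <- nchar(as.character(seqs[[id]]))
        rows[[length(rows) + 1L]] <- data.frame(
            consensus = id,
            tirLength = tir@armLength,
            internalLength = len - (tir@leftEnd - tir@leftStart + 1L) -
                (tir@rightEnd - tir@rightStart + 1L),
            superfamily = unname(sup[id]))
    }
    if (length(rows) == 0L)
        data.frame(consensus = character(0), tirLength = integer(0),
                   internalLength = integer(0),
                   superfamily = character(0))
    else do.call(rbind, rows)
}

#' Classify every consensus of a library
#'
#' Runs the nucleotide, protein and structural (TIR) callers on each
#' consensus, applies the two-of-three vote, and flags MITEs.
#'
#' @param library A \code{\link{TELibrary}}.
#' @param referenceLibrary Labeled nucleotide \code{TELibrary} or
#'   \code{NULL}.
#' @param proteinSet Labeled \code{AAStringSet}
#'   (\code{id#subclass/superfamily} names) or \code{NULL}.
#' @param miteLengthCap MITE length cap (bp).
#' @param tirMaxOffset Maximum TIR arm offset from the termini (bp).
#' @return List with \code{library} (reclassified \code{TELibrary})
#'   and \code{table} (per-consensus data.frame: subclass,
#'   superfamily, isMITE, vote sources).
#' @export
classifyLibrary <- function(library, referenceLibrary = NULL,
                            proteinSet = NULL, miteLengthCap = 1000,
                            tirMaxOffset = 100) {
    seqs <- consensusSeqs(library)
    rows <- list()
    for (id in names(seqs)) {
        cons <- seqs[[id]]
        nt <- if (!is.null(referenceLibrary))
            ntHomologyCall(cons, referenceLibrary) else NULL
        prot <- if (!is.null(proteinSet))
            proteinHomologyCall(cons, proteinSet) else NULL
        tir <- findTIRs(cons, maxOffset = tirMaxOffset)
        vote <- voteClassification(list(nt, prot), tir = tir)
        mite <- callMITE(cons, tir, proteinCall = prot,
                         lengthCap = miteLengthCap)
        rows[[id]] <- data.frame(
            consensus = id, subclass = vote$subclass,
            superfamily = ifelse(is.na(vote$superfamily), NA,
                                 vote$superfamily),
            isMITE = mite,
            ntVote = if (is.null(nt)) NA_character_ else
                .pasteClassLabel(nt@subclass, nt@superfamily),
            proteinVote = if (is.null(prot)) NA_character_ else
                .pasteClassLabel(prot@subclass, prot@superfamily),
            tirFound = !is.null(tir))
    }
    tab <- do.call(rbind, rows)
    info <- library@info
    info$subclass <- tab$subclass
    info$superfamily <- tab$superfamily
    out <- library
    out@info <- info
    validObject(out)
    list(library = out, table = tab)
}
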