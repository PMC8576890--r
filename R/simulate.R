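## Synthetic genomes, TE families, gene models and count matrices
## with recorded ground truth.

#' Simulate a genomic backbone sequence
#'
#' Draws an i.i.d. DNA sequence at a given G+C content. The default GC
#' of 0.43 matches the background composition the curation stage's
#' substitution matrix is parameterized at.
#'
#' @param length Sequence length in bp (> 0).
#' @param gc Expected G+C fraction (0 < gc < 1; the degenerate values
#'   0 and 1 are allowed and yield AT-only / GC-only sequence).
#' @param seed Optional integer seed for reproducibility.
#' @return A \link[Biostrings]{DNAString}.
#' @examples
#' b <- makeBackbone(1000, gc = 0.43, seed = 1)
#' Biostrings::letterFrequency(b, "GC", as.prob = TRUE)
#' @export
makeBackbone <- function(length, gc = 0.43, seed = NULL) {
    if (length <= 0)
        stop("'length' must be positive")
    if (gc < 0 || gc > 1)
        stop("'gc' must lie in [0, 1]")
    withSeed(seed, {
        prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
        DNAString(paste(sample(DNA_BASES4, length, replace = TRUE,
                               prob = prob), collapse = ""))
    })
}

## Random non-stop codons for embedded ORFs.
.NONSTOP_CODONS <- {
    all <- as.vector(outer(outer(DNA_BASES4, DNA_BASES4, paste0),
                           DNA_BASES4, paste0))
    setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Simulate a TE family consensus with known structure
#'
#' Builds a consensus sequence for a \link{teFamilySpec}: exact
#' reverse-complement TIR arms at both termini when
#' \code{tirLength > 0}, and an embedded open reading frame of at
#' least 100 aa when \code{hasCodingRegion} is set (non-coding
#' families are rejection-sampled until no ORF of 100 aa or more
#' remains in any of the six frames).
#'
#' @param spec A \code{TEFamilySpec}.
#' @param seed Optional integer seed.
#' @param gc G+C content of the generated sequence.
#' @param cpgEnrich Enrich the internal region for CpG dinucleotides
#'   (about 3\% of positions seeded with CG; default off). Useful to
#'   exercise the CpG-adjusted divergence path.
#' @return A list with elements \code{consensus}
#'   (\code{DNAString}), \code{familyId}, \code{tirLength},
#'   \code{orfRange} (\code{IRanges} of the embedded ORF or
#'   \code{NULL}).
#' @examples
#' fam <- makeTEFamily(teFamilySpec("m1", "TIR", 400, tirLength = 150))
#' @export
makeTEFamily <- function(spec, seed = NULL, gc = 0.43,
                         cpgEnrich = FALSE) {
    stopifnot(is(spec, "TEFamilySpec"))
    validObject(spec)
    L <- spec@length
    t <- spec@tirLength
    withSeed(seed, {
        makeInternal <- function(n) {
            if (n == 0L) return("")
            s <- as.character(makeBackbone(n, gc = gc))
            if (cpgEnrich && n >= 10L) {
                at <- sample.int(n - 1L, max(1L, round(0.03 * n)))
                for (i in at)
                    s <- paste0(substr(s, 1L, i - 1L), "CG",
                                substr(s, i + 2L, n))
            }
            s
        }
        arm <- if (t > 0L) makeBackbone(t, gc = gc) else NULL
        intLen <- L - 2L * t
        orfRange <- NULL
        for (try in seq_len(200L)) {
            internal <- makeInternal(intLen)
            orfRange <- NULL
            if (spec@hasCodingRegion) {
                nAa <- max(110L, as.integer(intLen %/% 6L))
                orfNt <- 3L * nAa + 3L
                if (orfNt > intLen)
                    stop("internal region too short for a coding region ",
                         "(need >= ", orfNt, " bp)")
                codons <- c("ATG",
                            sample(.NONSTOP_CODONS, nAa - 1L, replace = TRUE),
                            sample(c("TAA", "TAG", "TGA"), 1L))
                orf <- paste(codons, collapse = "")
                pos <- sample.int(intLen - orfNt + 1L, 1L)
                internal <- paste0(substr(internal, 1L, pos - 1L), orf,
                                   substr(internal, pos + orfNt, intLen))
                orfRange <- IRanges(t + pos, t + pos + orfNt - 1L)
            }
            seq <- DNAString(paste0(
                if (t > 0L) as.character(arm) else "",
                internal,
                if (t > 0L) as.character(reverseComplement(arm)) else ""))
            if (spec@hasCodingRegion || nrow(findOrfs(seq, 100L)) == 0L)
                break
            if (try == 200L)
                stop("could not generate an ORF-free consensus")
        }
        list(consensus = seq, familyId = spec@familyId,
             tirLength = t, orfRange = orfRange)
    })
}

#' Mutate a consensus into a diverged genomic copy
#'
#' Applies per-site substitutions under a Kimura 2-parameter model
#' whose expected distance equals \code{targetDivergence}: the
#' per-site transition probability \code{p} and transversion
#' probability \code{q = p / tsTvRatio} are obtained by numerically
#' inverting the K2P closed form (\code{\link{k2pSolveRates}}).
#' Insertions and deletions (length 1-5, uniform) occur independently
#' at \code{indelRate} per site.
#'
#' @param consensus \code{DNAString} or character sequence.
#' @param targetDivergence Target K2P distance (fraction, < 0.4).
#' @param tsTvRatio Transition/transversion ratio (> 0).
#' @param indelRate Per-bp indel event rate.
#' @param seed Optional integer seed.
#' @return List with \code{sequence} (\code{DNAString}), the solved
#'   per-site \code{p} and \code{q}, realized substitution counts
#'   \code{nTransitions} / \code{nTransversions}, and
#'   \code{realizedDivergence}, the K2P distance implied by the
#'   realized substitution fractions (before indels).
#' @examples
#' cp <- mutateCopy(makeBackbone(1000, seed = 1), 0.1, seed = 2)
#' cp$realizedDivergence
#' @export
mutateCopy <- function(consensus, targetDivergence, tsTvRatio = 2,
                       indelRate = 0, seed = NULL) {
    rates <- k2pSolveRates(targetDivergence, tsTvRatio)
    s <- strsplit(toupper(as.character(consensus)), "")[[1L]]
    L <- length(s)
    if (L == 0L)
        stop("empty consensus")
    withSeed(seed, {
        TS <- c(A = "G", G = "A", C = "T", T = "C")
        TV <- list(A = c("C", "T"), G = c("C", "T"),
                   C = c("A", "G"), T = c("A", "G"))
        u <- runif(L)
        isTs <- u < rates$p
        isTv <- !isTs & u < rates$p + rates$q
        out <- s
        if (any(isTs))
            out[isTs] <- TS[s[isTs]]
        if (any(isTv)) {
            iv <- which(isTv)
            pick <- sample(2L, length(iv), replace = TRUE)
            out[iv] <- vapply(seq_along(iv), function(k)
                TV[[s[iv[k]]]][pick[k]], character(1L))
        }
        nTs <- sum(isTs); nTv <- sum(isTv)
        seqChr <- paste(out, collapse = "")
        if (indelRate > 0) {
            ev <- which(runif(L) < indelRate)
            for (i in rev(ev)) {   # right-to-left keeps positions valid
                len <- sample.int(5L, 1L)
                if (runif(1) < 0.5) {  # deletion
                    seqChr <- paste0(substr(seqChr, 1L, i - 1L),
                                     substr(seqChr, i + len, nchar(seqChr)))
                } else {               # insertion
                    ins <- paste(sample(DNA_BASES4, len, replace = TRUE),
                                 collapse = "")
                    seqChr <- paste0(substr(seqChr, 1L, i), ins,
                                     substr(seqChr, i + 1L, nchar(seqChr)))
                }
            }
        }
        list(sequence = DNAString(seqChr), p = rates$p, q = rates$q,
             nTransitions = nTs, nTransversions = nTv,
             realizedDivergence = if (nTs + nTv == 0L) 0
                 else k2pDistance(nTs / L, nTv / L))
    })
}

#' Plant TE copies into a backbone genome
#'
#' Builds family consensus sequences from their specs, mutates each
#' copy to its family's target divergence, optionally 5'-truncates
#' LINE-like copies, and inserts the copies at uniformly random
#' positions of the growing genome (never inside \code{avoid}
#' intervals, e.g. gene space, and never inside a previously planted
#' copy unless nesting is drawn). Every planted copy's exact
#' coordinates, strand and realized divergence are recorded.
#'
#' @param backbone \code{DNAString} backbone (from
#'   \code{\link{makeBackbone}}).
#' @param families List of \code{TEFamilySpec} objects (a single spec
#'   is accepted).
#' @param nestingProbability Probability that a copy is inserted
#'   inside a previously placed copy.
#' @param seed Optional integer seed.
#' @param avoid Optional \code{IRanges}/\code{GRanges} of backbone
#'   intervals (e.g. genes) that must not receive insertions.
#' @param geneModels Optional gene-model \code{GRanges} on the
#'   backbone (\code{\link{simulateGeneModels}}); gene spans are
#'   avoided (unless \code{avoid} is given explicitly) and the
#'   models are returned with coordinates shifted through the
#'   insertions.
#' @param indelRate Per-bp indel rate passed to
#'   \code{\link{mutateCopy}}.
#' @param tsTvRatio Transition/transversion ratio of the mutation
#'   model.
#' @param scaffoldName Name of the single output scaffold.
#' @return List with \code{genome} (named \code{DNAStringSet}),
#'   \code{truth} (\code{GRanges} of planted copies with
#'   \code{familyId}, \code{realizedDivergence}, \code{cStart},
#'   \code{cEnd}, \code{truncatedBp}), \code{library} (a
#'   \code{\link{TELibrary}} of the family consensi),
#'   \code{familyTruth} (per-family structure from
#'   \code{\link{makeTEFamily}}) and \code{geneModels} (input gene
#'   models in final-genome coordinates, or \code{NULL}).
#' @export
plantCopies <- function(backbone, families, nestingProbability = 0,
                        seed = NULL, avoid = NULL, geneModels = NULL,
                        indelRate = 0.002, tsTvRatio = 2,
                        scaffoldName = "scf1") {
    if (is(families, "TEFamilySpec"))
        families <- list(families)
    lapply(families, validObject)
    backboneLen <- nchar(as.character(backbone))
    totalPlanted <- sum(vapply(families, function(f)
        as.numeric(f@length) * f@copyNumber, numeric(1L)))
    if (totalPlanted >= backboneLen)
        stop("genome too small for the requested copy load")
    avoidR <- if (!is.null(avoid)) ranges(avoid)
        else if (!is.null(geneModels))
            reduce(ranges(geneModels[mcols(geneModels)$type == "gene"]))
        else IRanges()
    gmS <- if (is.null(geneModels)) integer(0) else start(geneModels)
    gmE <- if (is.null(geneModels)) integer(0) else end(geneModels)
    withSeed(seed, {
        fams <- lapply(families, makeTEFamily)
        names(fams) <- vapply(families, function(f) f@familyId, character(1L))
        genome <- as.character(backbone)
        glen <- backboneLen
        plan <- do.call(rbind, lapply(seq_along(families), function(i)
            if (families[[i]]@copyNumber > 0L)
                data.frame(fam = i, copy = seq_len(families[[i]]@copyNumber))))
        starts <- integer(0); ends <- integer(0); strands <- character(0)
        famIds <- character(0); rdiv <- numeric(0)
        cS <- integer(0); cE <- integer(0); truncBp <- integer(0)
        if (!is.null(plan)) {
            plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
            for (r in seq_len(nrow(plan))) {
                spec <- families[[plan$fam[r]]]
                cons <- fams[[spec@familyId]]$consensus
                mut <- mutateCopy(cons, spec@targetDivergence,
                                  tsTvRatio = tsTvRatio,
                                  indelRate = indelRate)
                copySeq <- as.character(mut$sequence)
                tl <- 0L
                if (spec@subclass == "LINE" &&
                    spec@truncationModel == "five_prime_exponential") {
                    tl <- as.integer(min(round(rexp(1L, 1 / spec@truncationMean)),
                                         nchar(copySeq) - 50L))
                    tl <- max(tl, 0L)
                    if (tl > 0L)
                        copySeq <- substr(copySeq, tl + 1L, nchar(copySeq))
                }
                strand <- sample(c("+", "-"), 1L)
                if (strand == "-")
                    copySeq <- as.character(reverseComplement(DNAString(copySeq)))
                w <- nchar(copySeq)
                nested <- length(starts) > 0L &&
                    runif(1L) < nestingProbability
                pos <- NA_integer_
                if (nested) {
                    h <- sample.int(length(starts), 1L)
                    if (ends[h] > starts[h])
                        pos <- starts[h] + sample.int(ends[h] - starts[h], 1L)
                    else nested <- FALSE
                }
                if (!nested) {
                    for (try in seq_len(1000L)) {
                        cand <- sample.int(glen + 1L, 1L)
                        inAvoid <- length(avoidR) > 0L &&
                            any(cand > start(avoidR) & cand <= end(avoidR))
                        inCopy <- length(starts) > 0L &&
                            any(cand > starts & cand <= ends)
                        if (!inAvoid && !inCopy) { pos <- cand; break }
                        if (try == 1000L)
                            stop("genome too small for the requested copy load")
                    }
                }
                genome <- paste0(substr(genome, 1L, pos - 1L), copySeq,
                                 substr(genome, pos, glen))
                glen <- glen + w
                ## shift or stretch existing intervals past the insertion
                stretch <- function(st, en) {
                    sh <- st >= pos
                    st[sh] <- st[sh] + w
                    sp <- en >= pos & !sh
                    en[sh] <- en[sh] + w
                    en[sp] <- en[sp] + w
                    list(st, en)
                }
                z <- stretch(starts, ends); starts <- z[[1L]]; ends <- z[[2L]]
                if (length(avoidR) > 0L) {
                    z <- stretch(start(avoidR), end(avoidR))
                    avoidR <- IRanges(z[[1L]], z[[2L]])
                }
                if (length(gmS) > 0L) {
                    z <- stretch(gmS, gmE)
                    gmS <- z[[1L]]; gmE <- z[[2L]]
                }
                starts <- c(starts, pos); ends <- c(ends, pos + w - 1L)
                strands <- c(strands, strand)
                famIds <- c(famIds, spec@familyId)
                rdiv <- c(rdiv, mut$realizedDivergence)
                cS <- c(cS, tl + 1L); cE <- c(cE, spec@length)
                truncBp <- c(truncBp, tl)
            }
        }
        truth <- GRanges(factor(rep(scaffoldName, length(starts)),
                                levels = scaffoldName),
                         IRanges(starts, ends), strand = strands)
        mcols(truth) <- DataFrame(familyId = famIds,
                                  realizedDivergence = rdiv,
                                  cStart = cS, cEnd = cE,
                                  truncatedBp = truncBp)
        seqlengths(truth) <- glen
        lib <- TELibrary(
            DNAStringSet(setNames(
                vapply(fams, function(f) as.character(f$consensus),
                       character(1L)),
                names(fams))),
            subclass = vapply(families, function(f) f@subclass,
                              character(1L)),
            provenance = "simulated")
        gmOut <- NULL
        if (!is.null(geneModels)) {
            gmOut <- GRanges(scaffoldName, IRanges(gmS, gmE),
                             strand = strand(geneModels))
            mcols(gmOut) <- mcols(geneModels)
            seqlengths(gmOut) <- glen
        }
        list(genome = DNAStringSet(setNames(genome, scaffoldName)),
             truth = truth, library = lib, familyTruth = fams,
             geneModels = gmOut)
    })
}

#' Simulate gene models as GFF3-style annotation
#'
#' Places non-overlapping gene models on both strands, each with a 5'
#' UTR, one or more exons separated by introns, and a 3' UTR. UTRs
#' occupy the outer ends of the terminal exons (exon features include
#' their UTR portion, as in standard GFF3).
#'
#' @param genomeLength Scaffold length in bp.
#' @param nGenes Number of genes to place (>= 0).
#' @param seed Optional integer seed.
#' @param scaffoldName Scaffold name.
#' @return A \code{GRanges} with GFF3-style \code{type}, \code{ID},
#'   \code{Parent} metadata (features: gene, mRNA, exon,
#'   five_prime_UTR, three_prime_UTR), with seqlengths set.
#' @examples
#' gm <- simulateGeneModels(100000, 3, seed = 1)
#' table(gm$type)
#' @export
simulateGeneModels <- function(genomeLength, nGenes, seed = NULL,
                               scaffoldName = "scf1") {
    if (nGenes < 0)
        stop("'nGenes' must be >= 0")
    emptyOut <- function() {
        gr <- GRanges(seqnames = factor(character(0), scaffoldName),
                      ranges = IRanges())
        mcols(gr) <- DataFrame(type = character(0), ID = character(0),
                               Parent = CharacterList())
        seqlengths(gr) <- genomeLength
        gr
    }
    if (nGenes == 0L)
        return(emptyOut())
    withSeed(seed, {
        rows <- list()
        placed <- IRanges()
        for (g in seq_len(nGenes)) {
            nEx <- sample.int(5L, 1L)
            exLen <- sample(150:600, nEx, replace = TRUE)
            inLen <- if (nEx > 1L) sample(300:2000, nEx - 1L, replace = TRUE)
                     else integer(0)
            utr5 <- sample(100:300, 1L)
            utr3 <- sample(100:400, 1L)
            exLen[1L] <- exLen[1L] + utr5
            exLen[nEx] <- exLen[nEx] + utr3
            geneLen <- sum(exLen) + sum(inLen)
            ok <- FALSE
            for (try in seq_len(500L)) {
                st <- sample.int(genomeLength - geneLen + 1L, 1L)
                cand <- IRanges(st, st + geneLen - 1L)
                if (length(placed) == 0L ||
                    sum(countOverlaps(cand + 200L, placed)) == 0L) {
                    ok <- TRUE; break
                }
            }
            if (!ok)
                stop("cannot place genes without overlap")
            placed <- c(placed, cand)
            strand <- sample(c("+", "-"), 1L)
            ## exon coordinates along the forward strand of the genome
            exStart <- st + cumsum(c(0L, head(exLen, -1L) + inLen))
            exEnd <- exStart + exLen - 1L
            gid <- sprintf("gene%02d", g)
            tid <- paste0(gid, ".t1")
            ## UTRs sit at the gene's 5'/3' ends, strand-aware
            if (strand == "+") {
                u5 <- IRanges(st, st + utr5 - 1L)
                u3 <- IRanges(st + geneLen - utr3, st + geneLen - 1L)
            } else {
                u5 <- IRanges(st + geneLen - utr5, st + geneLen - 1L)
                u3 <- IRanges(st, st + utr3 - 1L)
            }
            rows[[length(rows) + 1L]] <- data.frame(
                start = c(st, st, exStart, start(u5), start(u3)),
                end = c(st + geneLen - 1L, st + geneLen - 1L, exEnd,
                        end(u5), end(u3)),
                type = c("gene", "mRNA", rep("exon", nEx),
                         "five_prime_UTR", "three_prime_UTR"),
                ID = c(gid, tid, paste0(tid, ".exon", seq_len(nEx)),
                       paste0(tid, ".utr5"), paste0(tid, ".utr3")),
                parent = c("", gid, rep(tid, nEx + 2L)),
                strand = strand)
        }
        df <- do.call(rbind, rows)
        gr <- GRanges(scaffoldName, IRanges(df$start, df$end),
                      strand = df$strand)
        mcols(gr) <- DataFrame(
            type = df$type, ID = df$ID,
            Parent = CharacterList(lapply(df$parent, function(p)
                if (p == "") character(0) else p)))
        seqlengths(gr) <- genomeLength
        gr
    })
}

#' Simulate a TE family count matrix with known differential expression
#'
#' Draws family-by-sample read counts from a negative-binomial model
#' with log-normal per-family base means and per-sample size factors.
#' A fraction of families receive a true log2 fold change of
#' \code{effectLog2fc}, split evenly between directions; truth is
#' recorded.
#'
#' @param nFamilies Number of TE families.
#' @param nRepsPerGroup Replicates per condition (>= 2).
#' @param deFraction Fraction of families that are truly DE.
#' @param effectLog2fc Absolute true log2 fold change of DE families.
#' @param dispersion NB dispersion (Var = mu + dispersion * mu^2;
#'   > 0).
#' @param seed Optional integer seed.
#' @param baseMeanMeanlog,baseMeanSdlog Log-normal parameters of the
#'   per-family base means.
#' @param sizeFactorSdlog Log-normal sd of the per-sample size
#'   factors.
#' @return List with \code{counts} (integer matrix, families x
#'   samples), \code{condition} (factor \code{"A"}/\code{"B"}),
#'   \code{truthLog2fc} (named numeric) and \code{sizeFactors}.
#' @examples
#' sim <- simulateTECounts(100, 3, deFraction = 0.1, seed = 1)
#' sum(sim$truthLog2fc != 0)
#' @export
simulateTECounts <- function(nFamilies, nRepsPerGroup, deFraction = 0.1,
                             effectLog2fc = 2, dispersion = 0.1,
                             seed = NULL, baseMeanMeanlog = log(150),
                             baseMeanSdlog = 1.2,
                             sizeFactorSdlog = 0.15) {
    if (dispersion <= 0)
        stop("'dispersion' must be positive")
    if (nRepsPerGroup < 2)
        stop("need at least 2 replicates per condition")
    withSeed(seed, {
        nDE <- round(deFraction * nFamilies)
        lfc <- numeric(nFamilies)
        if (nDE > 0L) {
            de <- sample.int(nFamilies, nDE)
            sign <- rep(c(1, -1), length.out = nDE)
            lfc[de] <- sign * effectLog2fc
        }
        base <- rlnorm(nFamilies, baseMeanMeanlog, baseMeanSdlog)
        nS <- 2L * nRepsPerGroup
        sf <- rlnorm(nS, 0, sizeFactorSdlog)
        condition <- factor(rep(c("A", "B"), each = nRepsPerGroup))
        mu <- outer(base * 2^(-lfc / 2), rep(1, nS))
        mu[, condition == "B"] <- base * 2^(lfc / 2)
        mu <- sweep(mu, 2L, sf, "*")
        counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                         nrow = nFamilies)
        storage.mode(counts) <- "integer"
        rownames(counts) <- sprintf("fam%04d", seq_len(nFamilies))
        colnames(counts) <- paste0(condition, ".rep",
                                   rep(seq_len(nRepsPerGroup), 2L))
        names(lfc) <- rownames(counts)
        list(counts = counts, condition = condition, truthLog2fc = lfc,
             sizeFactors = sf)
    })
}
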