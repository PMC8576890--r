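## The standard planted-genome benchmark: fixed study conditions used
## by the acceptance checks and reproducible from a single seed.

#' Benchmark TE family panel
#'
#' The fixed 20-family panel used for end-to-end benchmarking: six
#' autonomous TIR families (coding, short arms), five MITEs (short,
#' arm-dominated, non-coding), five LINE-like families (coding,
#' 5'-truncated copies) and four LTR-like families (coding), with
#' copy divergences spanning 2-20% and superfamily labels attached
#' as the \code{"superfamily"} attribute.
#'
#' @return List of \code{\link{teFamilySpec}} objects.
#' @export
benchmarkFamilySpecs <- function() {
    tbl <- list(
        list("tirTcMar1", "TIR", 2400L, 40L, TRUE, 0.02, 12L, "Tc-Mar"),
        list("tirTcMar2", "TIR", 2200L, 35L, TRUE, 0.08, 12L, "Tc-Mar"),
        list("tirHat1", "TIR", 2800L, 30L, TRUE, 0.05, 12L, "hAT"),
        list("tirHat2", "TIR", 2000L, 45L, TRUE, 0.12, 12L, "hAT"),
        list("tirPif", "TIR", 2600L, 25L, TRUE, 0.15, 12L,
             "PIF-Harbinger"),
        list("tirCacta", "TIR", 2300L, 50L, TRUE, 0.10, 12L, "CACTA"),
        list("mite1", "TIR", 400L, 150L, FALSE, 0.03, 35L, NA),
        list("mite2", "TIR", 500L, 170L, FALSE, 0.06, 35L, NA),
        list("mite3", "TIR", 350L, 120L, FALSE, 0.09, 35L, NA),
        list("mite4", "TIR", 600L, 180L, FALSE, 0.12, 35L, NA),
        list("mite5", "TIR", 450L, 140L, FALSE, 0.05, 35L, NA),
        list("lineRte", "LINE", 3000L, 0L, TRUE, 0.05, 12L, "RTE"),
        list("lineJock", "LINE", 3400L, 0L, TRUE, 0.10, 12L, "Jockey"),
        list("lineI", "LINE", 2600L, 0L, TRUE, 0.15, 12L, "I"),
        list("lineR2", "LINE", 3200L, 0L, TRUE, 0.20, 12L, "R2"),
        list("lineCr1", "LINE", 2800L, 0L, TRUE, 0.08, 12L, "CR1"),
        list("ltrGypsy1", "LTR", 4000L, 0L, TRUE, 0.02, 8L, "Gypsy"),
        list("ltrCopia", "LTR", 3600L, 0L, TRUE, 0.04, 8L, "Copia"),
        list("ltrPao", "LTR", 4400L, 0L, TRUE, 0.06, 8L, "Pao"),
        list("ltrGypsy2", "LTR", 3800L, 0L, TRUE, 0.08, 8L, "Gypsy"))
    specs <- lapply(tbl, function(x)
        teFamilySpec(x[[1L]], x[[2L]], x[[3L]], tirLength = x[[4L]],
                     hasCodingRegion = x[[5L]],
                     targetDivergence = x[[6L]], copyNumber = x[[7L]],
                     truncationModel = if (x[[2L]] == "LINE")
                         "five_prime_exponential" else "none",
                     truncationMean = 800))
    attr(specs, "superfamily") <- setNames(
        vapply(tbl, function(x) as.character(x[[8L]]), character(1L)),
        vapply(tbl, `[[`, character(1L), 1L))
    specs
}

#' Build the benchmark planted genome and its companion inputs
#'
#' Plants the \code{\link{benchmarkFamilySpecs}} panel into a random
#' backbone and derives, from the same seed, the inputs an analysis
#' would start from: a raw (uncurated) consensus library — each true
#' consensus wrapped in unsupported junk flanks, plus redundant
#' fragments and decoys (tandem array, random sequences, an
#' undersized fragment) — and labeled reference sets for
#' classification (diverged nucleotide relatives of the autonomous
#' families and the proteins of their coding regions; MITEs get no
#' homology reference, as in real repeat databases).
#'
#' @param seed Integer seed controlling the whole scenario.
#' @param backboneLength Backbone length in bp (default 2e6).
#' @return List with \code{genome}, \code{truth}, \code{library}
#'   (true consensi), \code{familyTruth}, \code{rawLibrary},
#'   \code{referenceLibrary}, \code{proteinSet},
#'   \code{trueSubclass}, \code{trueSuperfamily}, \code{isMite}.
#' @export
benchmarkScenario <- function(seed, backboneLength = 2e6) {
    specs <- benchmarkFamilySpecs()
    sup <- attr(specs, "superfamily")
    backbone <- makeBackbone(backboneLength, gc = 0.43, seed = seed)
    pg <- plantCopies(backbone, specs, seed = seed + 1L)
    cons <- consensusSeqs(pg$library)
    withSeed(seed + 2L, {
        junk <- function(n) paste(sample(DNA_BASES4, n, TRUE,
                                         prob = c(0.285, 0.215, 0.215,
                                                  0.285)),
                                  collapse = "")
        raw <- vapply(names(cons), function(id) paste0(
            junk(sample(50:150, 1L)), as.character(cons[[id]]),
            junk(sample(50:150, 1L))), character(1L))
        names(raw) <- paste0("raw_", names(cons))
        ## redundant internal fragments of five families
        fragOf <- c("tirTcMar1", "lineRte", "ltrGypsy1", "mite2",
                    "tirHat1")
        frags <- vapply(fragOf, function(id) {
            s <- as.character(cons[[id]])
            n <- nchar(s)
            a <- sample.int(max(1L, n %/% 4L), 1L)
            substr(s, a, min(n, a + max(200L, n %/% 2L)))
        }, character(1L))
        names(frags) <- paste0("frag_", fragOf)
        decoys <- c(
            decoy_tandem = strrep("ACGGT", 90L),
            decoy_rand1 = junk(900L),
            decoy_rand2 = junk(1200L),
            decoy_short = junk(90L))
        rawLibrary <- DNAStringSet(c(raw, frags, decoys))
        ## labeled references: 12%-diverged relatives of the
        ## autonomous families only
        auto <- names(cons)[!grepl("^mite", names(cons))]
        refSeqs <- vapply(auto, function(id) as.character(
            mutateCopy(cons[[id]], 0.12, indelRate = 0.002)$sequence),
            character(1L))
        names(refSeqs) <- paste0("ref_", auto)
        refSub <- subclass(pg$library)[auto]
        referenceLibrary <- TELibrary(DNAStringSet(refSeqs),
                                      subclass = unname(refSub),
                                      superfamily = unname(sup[auto]),
                                      provenance = "benchmark reference")
        ## protein references from the embedded coding regions
        peps <- character(0)
        for (id in auto) {
            orfs <- findOrfs(cons[[id]], 100)
            if (nrow(orfs) > 0L) {
                pep <- orfs$peptide[which.max(orfs$lengthAa)]
                nm <- paste0("prot_", id, "#",
                             .pasteClassLabel(refSub[[id]], sup[[id]]))
                peps[nm] <- pep
            }
        }
        proteinSet <- AAStringSet(peps)
        list(genome = pg$genome, truth = pg$truth,
             library = pg$library, familyTruth = pg$familyTruth,
             rawLibrary = rawLibrary,
             referenceLibrary = referenceLibrary,
             proteinSet = proteinSet,
             trueSubclass = subclass(pg$library),
             trueSuperfamily = sup,
             isMite = setNames(grepl("^mite", names(cons)),
                               names(cons)))
    })
}

#' Score recovered consensus sequences against the planted families
#'
#' For every planted family, finds the best-matching curated
#' consensus (identity of the banded alignment, coverage over the
#' planted consensus) and reports whether it passes the recovery
#' thresholds.
#'
#' @param curated Curated \code{\link{TELibrary}} (or
#'   \code{DNAStringSet}).
#' @param trueLibrary The planted \code{TELibrary}.
#' @param minIdentity Identity threshold (default 0.95).
#' @param minCoverage Covered fraction of the planted consensus
#'   (default 0.90).
#' @return data.frame with one row per planted family:
#'   \code{familyId}, \code{match}, \code{identity},
#'   \code{coverage}, \code{recovered}.
#' @export
scoreRecovery <- function(curated, trueLibrary, minIdentity = 0.95,
                          minCoverage = 0.90) {
    got <- if (is(curated, "TELibrary")) consensusSeqs(curated)
           else curated
    want <- consensusSeqs(trueLibrary)
    rows <- lapply(names(want), function(fam) {
        best <- list(match = NA_character_, identity = 0, coverage = 0)
        ## name lineage narrows candidates; fall back to all
        cand <- grep(fam, names(got), value = TRUE, fixed = TRUE)
        if (length(cand) == 0L)
            cand <- names(got)
        for (id in cand) {
            st <- .pairIdentity(got[[id]], want[[fam]])
            ## .pairIdentity reports coverage over the shorter
            ## sequence; rescale to the planted consensus length
            gl <- nchar(as.character(got[[id]]))
            tl <- nchar(as.character(want[[fam]]))
            covTrue <- if (gl <= tl) st$coverage * gl / tl
                       else st$coverage
            if (st$identity > best$identity ||
                (st$identity == best$identity &&
                 covTrue > best$coverage))
                best <- list(match = id, identity = st$identity,
                             coverage = covTrue)
        }
        data.frame(familyId = fam, match = best$match,
                   identity = best$identity, coverage = best$coverage,
                   recovered = best$identity >= minIdentity &
                       best$coverage >= minCoverage)
    })
    do.call(rbind, rows)
}
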