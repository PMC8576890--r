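## Shared fixtures, built in code. Heavier objects are cached per
## test run so several test files can reuse them.

suppressPackageStartupMessages({
    library(Biostrings)
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
    if (!exists(name, envir = .fixtureCache))
        assign(name, expr, envir = .fixtureCache)
    get(name, envir = .fixtureCache)
}

## A small planted genome: one MITE-like and one LINE-like family on
## a 120 kb backbone.
smallPlantedGenome <- function() {
    cached("smallPlanted", {
        specs <- list(
            teFamilySpec("mite1", "TIR", 450, tirLength = 150,
                         targetDivergence = 0.05, copyNumber = 15),
            teFamilySpec("line1", "LINE", 2000, hasCodingRegion = TRUE,
                         targetDivergence = 0.10, copyNumber = 8,
                         truncationModel = "five_prime_exponential",
                         truncationMean = 400))
        plantCopies(makeBackbone(120000, seed = 11), specs, seed = 12)
    })
}

smallHits <- function() {
    cached("smallHits", {
        pg <- smallPlantedGenome()
        naiveHomologySearch(pg$genome, pg$library, minScore = 150,
                            returnAlignments = TRUE)
    })
}

## A hand-made hit table exercising both strands and all fields.
toyHits <- function() {
    repeatHits(
        scaffold = c("scf1", "scf1", "scf2"),
        qStart = c(101, 501, 21), qEnd = c(400, 850, 520),
        strand = c("+", "C", "+"),
        consensusId = c("famA", "famB", "famA"),
        cStart = c(1, 41, 101), cEnd = c(300, 390, 600),
        score = c(1500, 800, 900),
        pctDiv = c(5.1, 12.3, 8 + 1 / 3), pctDel = c(0.5, 1.2, 0),
        pctIns = c(0.2, 0, 2.5),
        kimuraDiv = c(5.4, 13.1, NA),
        teClass = c("TIR/Tc-Mar", "LINE/RTE", "TIR/Tc-Mar"),
        scaffoldLength = c(10000, 10000, 5000),
        consensusLength = c(600, 400, 600))
}

## Random gapped alignment pair for K2P checks.
randomAlignedPair <- function(n = 200) {
    bases <- c("A", "C", "G", "T")
    cons <- sample(bases, n, replace = TRUE)
    copy <- cons
    mut <- runif(n) < 0.15
    copy[mut] <- vapply(which(mut), function(i)
        sample(setdiff(bases, cons[i]), 1L), character(1L))
    gap <- runif(n) < 0.05
    copy[gap & runif(n) < 0.5] <- "-"
    cons[gap & runif(n) >= 0.5] <- "-"
    list(copy = paste(copy, collapse = ""),
         consensus = paste(cons, collapse = ""))
}
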