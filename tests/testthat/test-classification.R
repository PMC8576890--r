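test_that("ORF scanning finds embedded frames and respects strand", {
    ## construct: stops flanking a clean 150-aa ORF
    set.seed(90)
    orf <- paste0("ATG", paste(sample(repeatforge:::.NONSTOP_CODONS,
                                      149, TRUE), collapse = ""), "TAA")
    s <- paste0("TAATAATAA", orf, "TAATAA")
    found <- findOrfs(s, 100)
    expect_equal(nrow(found), 1L)
    expect_equal(found$lengthAa, 150L)
    expect_equal(found$start, 10L)
    expect_equal(substr(s, found$start, found$end + 3L),
                 paste0(orf))
    ## reverse-strand detection
    rc <- as.character(reverseComplement(DNAString(s)))
    foundRC <- findOrfs(rc, 100)
    expect_equal(nrow(foundRC), 1L)
    expect_equal(foundRC$strand, "-")
    expect_equal(foundRC$peptide, found$peptide)
    ## random sequences essentially never carry a long (150 aa) ORF;
    ## at 100 aa the expected rate is small but nonzero
    nOrf <- vapply(1:20, function(i)
        nrow(findOrfs(makeBackbone(1000, seed = 900 + i), 150)),
        numeric(1))
    expect_equal(sum(nOrf), 0)
})

test_that("unknown-peptide extraction recovers exactly embedded ORFs", {
    set.seed(91)
    orf <- paste0("ATG", paste(sample(repeatforge:::.NONSTOP_CODONS,
                                      149, TRUE), collapse = ""), "TGA")
    s <- paste0("TAGTAGTAG", orf, "TAGTAG")
    peps <- extractUnknownPeptides(s, 100)
    expect_length(peps, 1L)
    expect_equal(nchar(as.character(peps[[1L]])), 150L)
    ## same peptide recovered through Biostrings translation (oracle)
    expect_equal(as.character(peps[[1L]]),
                 as.character(translate(DNAString(substr(orf, 1, 450)))))
    ## stop-rich random sequence yields nothing
    expect_length(extractUnknownPeptides(
        as.character(makeBackbone(2000, seed = 92)), 100), 0L)
    ## minLenAa = 1 on a stop-free ATG-led sequence yields a peptide
    expect_gte(length(extractUnknownPeptides("ATGGCCGCAGCT", 1)), 1L)
})

test_that("TIR detection matches the simulator truth", {
    fam <- makeTEFamily(teFamilySpec("m", "TIR", 600, tirLength = 150),
                        seed = 93)
    tir <- findTIRs(fam$consensus)
    expect_false(is.null(tir))
    expect_lte(abs(tir@armLength - 150L), 5L)
    expect_gte(tir@armIdentity, 0.95)
    expect_equal(tir@offset5, 0L)
    expect_equal(tir@offset3, 0L)
    ## short perfect palindromic termini
    arm <- as.character(makeBackbone(40, seed = 94))
    s <- paste0(arm, as.character(makeBackbone(300, seed = 95)),
                as.character(reverseComplement(DNAString(arm))))
    tir2 <- findTIRs(s, minArm = 10)
    expect_false(is.null(tir2))
    expect_equal(tir2@offset5, 0L)
    ## arms offset from the ends beyond maxOffset are rejected
    far <- paste0(as.character(makeBackbone(150, seed = 96)), s,
                  as.character(makeBackbone(150, seed = 97)))
    expect_null(findTIRs(far, maxOffset = 100))
    expect_false(is.null(findTIRs(far, maxOffset = 200)))
    ## null false-positive rate below 5%
    fp <- vapply(1:60, function(i)
        !is.null(findTIRs(makeBackbone(2000, seed = 980 + i))),
        logical(1))
    expect_lt(mean(fp), 0.05)
})

test_that("the vote equals an exhaustive truth-table oracle", {
    tirPair <- new("TIRPair", leftStart = 1L, leftEnd = 20L,
                   rightStart = 101L, rightEnd = 120L,
                   armLength = 20L, armIdentity = 1,
                   offset5 = 0L, offset3 = 0L, score = 60)
    labels <- list(c("TIR", "Tc-Mar"), c("TIR", "hAT"),
                   c("LINE", "RTE"), c("LTR", "Gypsy"),
                   c(NA, NA))
    for (nt in labels) for (prot in labels) for (hasTir in c(TRUE, FALSE)) {
        calls <- list(
            if (!is.na(nt[1])) homologyCall("nt", nt[1], nt[2]),
            if (!is.na(prot[1])) homologyCall("protein", prot[1], prot[2]))
        got <- voteClassification(calls,
                                  tir = if (hasTir) tirPair else NULL)
        want <- voteOracle(nt, prot,
                           c(if (hasTir) "TIR" else NA, NA), hasTir)
        expect_equal(got$subclass, want$subclass,
                     info = paste(nt[1], prot[1], hasTir))
        expect_equal(got$superfamily, want$superfamily,
                     info = paste(nt[2], prot[2], hasTir))
    }
    ## spec rule checks
    expect_equal(voteClassification(list(
        homologyCall("nt", "TIR", "Tc-Mar"),
        homologyCall("protein", "TIR", "hAT")), tir = tirPair),
        list(subclass = "TIR", superfamily = NA_character_))
    expect_equal(voteClassification(list(), tir = tirPair)$subclass,
                 "TIR")
    expect_equal(voteClassification(list(), tir = NULL)$subclass,
                 "Unknown")
    expect_error(voteClassification(list(
        homologyCall("nt", "TIR"), homologyCall("nt", "LTR"))),
        "one call per source")
})

test_that("nt homology calls aggregate non-overlapping hits", {
    gypsy <- makeBackbone(3000, seed = 101)
    refs <- TELibrary(DNAStringSet(c(
        gypsyRef = as.character(gypsy),
        marRef = as.character(makeBackbone(2500, seed = 102)))),
        subclass = c("LTR", "TIR"),
        superfamily = c("Gypsy", "Tc-Mar"))
    ## chimeric consensus: 30% of a Gypsy reference inside random
    chimera <- paste0(as.character(makeBackbone(700, seed = 103)),
                      substr(as.character(gypsy), 1, 600),
                      as.character(makeBackbone(700, seed = 104)))
    call <- ntHomologyCall(chimera, refs)
    expect_false(is.null(call))
    expect_equal(call@subclass, "LTR")
    expect_equal(call@superfamily, "Gypsy")
    expect_gte(call@lengthRatio, 0.25)
    ## 5% coverage is below the 0.08 threshold: no call
    tiny <- paste0(as.character(makeBackbone(2000, seed = 105)),
                   substr(as.character(gypsy), 1, 110),
                   as.character(makeBackbone(2000, seed = 106)))
    expect_null(ntHomologyCall(tiny, refs, minScore = 40))
    ## two 5% fragments of the same superfamily jointly pass 0.08
    marA <- substr(as.character(consensusSeqs(refs)[["marRef"]]), 1, 130)
    marB <- substr(as.character(consensusSeqs(refs)[["marRef"]]),
                   1200, 1330)
    joint <- paste0(as.character(makeBackbone(900, seed = 107)), marA,
                    as.character(makeBackbone(500, seed = 108)), marB,
                    as.character(makeBackbone(900, seed = 109)))
    jc <- ntHomologyCall(joint, refs, minScore = 40)
    expect_false(is.null(jc))
    expect_equal(jc@superfamily, "Tc-Mar")
})

test_that("protein homology calls use six-frame translation", {
    fam <- makeTEFamily(teFamilySpec("l", "LINE", 3000,
                                     hasCodingRegion = TRUE), seed = 110)
    pep <- findOrfs(fam$consensus, 100)$peptide[1L]
    prots <- AAStringSet(setNames(pep, "rt#LINE/RTE"))
    call <- proteinHomologyCall(fam$consensus, prots)
    expect_false(is.null(call))
    expect_equal(call@subclass, "LINE")
    expect_equal(call@superfamily, "RTE")
    expect_gte(call@lengthRatio, 0.03)
    ## the ORF on the minus strand is still found
    rc <- reverseComplement(fam$consensus)
    callRC <- proteinHomologyCall(rc, prots)
    expect_false(is.null(callRC))
    ## empty protein set: no call
    expect_null(proteinHomologyCall(fam$consensus, AAStringSet()))
    ## unrelated sequence: no call
    expect_null(proteinHomologyCall(makeBackbone(2000, seed = 111),
                                    prots))
})

test_that("MITE calling requires TIRs, no coding and a length cap", {
    mite <- makeTEFamily(teFamilySpec("m", "TIR", 400, tirLength = 150),
                         seed = 112)
    tir <- findTIRs(mite$consensus)
    expect_true(callMITE(mite$consensus, tir))
    ## embedded transposase ORF vetoes the call
    auto <- makeTEFamily(teFamilySpec("a", "TIR", 2400, tirLength = 40,
                                      hasCodingRegion = TRUE), seed = 113)
    tirA <- findTIRs(auto$consensus)
    expect_false(is.null(tirA))
    expect_false(callMITE(auto$consensus, tirA))
    ## 4 kb TIR element without ORF is above the default cap
    big <- makeTEFamily(teFamilySpec("b", "TIR", 4000, tirLength = 150),
                        seed = 114)
    tirB <- findTIRs(big$consensus)
    expect_false(callMITE(big$consensus, tirB))
    expect_true(callMITE(big$consensus, tirB, lengthCap = 5000))
    expect_false(callMITE(mite$consensus, NULL))
    ## a protein call vetoes even without a local ORF
    expect_false(callMITE(mite$consensus, tir,
                          proteinCall = homologyCall("protein", "TIR")))
})

test_that("TIR statistics table matches the simulator truth", {
    lib <- TELibrary(DNAStringSet(c(
        m1 = as.character(makeTEFamily(teFamilySpec("m1", "TIR", 400,
            tirLength = 150), seed = 115)$consensus),
        m2 = as.character(makeTEFamily(teFamilySpec("m2", "TIR", 700,
            tirLength = 100), seed = 116)$consensus),
        noTir = as.character(makeBackbone(600, seed = 117)))),
        superfamily = c("Tc-Mar", "hAT", NA))
    tab <- tirStatistics(lib)
    expect_setequal(tab$consensus, c("m1", "m2"))
    m1 <- tab[tab$consensus == "m1", ]
    expect_lte(abs(m1$tirLength - 150L), 5L)
    expect_lte(abs(m1$internalLength - 100L), 10L)
    expect_equal(m1$superfamily, "Tc-Mar")
    m2 <- tab[tab$consensus == "m2", ]
    expect_lte(abs(m2$tirLength - 100L), 5L)
    expect_lte(abs(m2$internalLength - 500L), 10L)
})
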