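test_that("backbone composition, determinism and degenerate GC", {
    b <- makeBackbone(10000, gc = 0.43, seed = 1)
    gc <- letterFrequency(b, "GC", as.prob = TRUE)[[1L]]
    ## observed GC within 3 sd of the binomial expectation
    expect_lt(abs(gc - 0.43), 3 * sqrt(0.43 * 0.57 / 10000))
    expect_identical(as.character(makeBackbone(500, seed = 7)),
                     as.character(makeBackbone(500, seed = 7)))
    at <- makeBackbone(4, gc = 0, seed = 2)
    expect_equal(letterFrequency(at, "AT")[[1L]], 4L)
    expect_error(makeBackbone(0), "positive")
})

test_that("TE family construction enforces structure", {
    spec <- teFamilySpec("m1", "TIR", 400, tirLength = 150)
    fam <- makeTEFamily(spec, seed = 3)
    s <- as.character(fam$consensus)
    expect_identical(
        substr(s, 1, 150),
        as.character(reverseComplement(DNAString(substr(s, 251, 400)))))
    ## non-coding family has no >= 100 aa ORF in any frame
    expect_equal(nrow(findOrfs(fam$consensus, 100)), 0L)
    ## coding LINE carries an ORF findable by the six-frame scan
    lspec <- teFamilySpec("l1", "LINE", 3000, hasCodingRegion = TRUE)
    lfam <- makeTEFamily(lspec, seed = 4)
    orfs <- findOrfs(lfam$consensus, 100)
    expect_gte(nrow(orfs), 1L)
    expect_gte(max(orfs$lengthAa), 100L)
    ## the recorded ORF range translates to the reported peptide
    expect_true(any(orfs$start == start(lfam$orfRange)))
    expect_error(teFamilySpec("bad", "TIR", 400, tirLength = 250),
                 "tirLength")
})

test_that("mutateCopy hits its target divergence", {
    cons <- makeBackbone(10000, seed = 5)
    ## zero target, zero indels: identity
    m0 <- mutateCopy(cons, 0, indelRate = 0, seed = 6)
    expect_identical(as.character(m0$sequence), as.character(cons))
    ## out-of-domain target rejected
    expect_error(mutateCopy(cons, 0.5), "0.4")
    ## Monte-Carlo recovery: mean K2P of replicates within 0.01 of 0.10
    ks <- vapply(1:40, function(s) {
        m <- mutateCopy(cons, 0.10, tsTvRatio = 2, indelRate = 0,
                        seed = 1000 + s)
        pairwiseK2P(as.character(m$sequence), as.character(cons))
    }, numeric(1L))
    expect_lt(abs(mean(ks) - 0.10), 0.01)
    ## divergence calibration across targets (relative error <= 10%)
    short <- makeBackbone(2000, seed = 8)
    for (target in c(0.02, 0.05, 0.10, 0.20)) {
        ks <- vapply(1:100, function(s)
            mutateCopy(short, target, indelRate = 0,
                       seed = s)$realizedDivergence, numeric(1L))
        expect_lt(abs(mean(ks) - target) / target, 0.10)
    }
})

test_that("plantCopies records exact truth and conserves composition", {
    spec <- teFamilySpec("f1", "TIR", 300, tirLength = 50,
                         targetDivergence = 0.03, copyNumber = 5)
    pg <- plantCopies(makeBackbone(20000, seed = 9), spec, seed = 10,
                      indelRate = 0)
    expect_length(pg$truth, 5L)
    expect_true(all(width(pg$truth) == 300L))
    ## non-overlapping when nesting = 0
    expect_equal(sum(width(reduce(granges(pg$truth)))), 5L * 300L)
    ## composition: planted bp == genome growth
    expect_equal(sum(width(pg$genome)) - 20000L, sum(width(pg$truth)))
    ## planted sequence at the recorded coordinates matches the
    ## mutated copy of the consensus at the recorded divergence
    g <- as.character(pg$genome[[1L]])
    for (i in seq_along(pg$truth)) {
        frag <- substr(g, start(pg$truth)[i], end(pg$truth)[i])
        if (as.character(strand(pg$truth))[i] == "-")
            frag <- as.character(reverseComplement(DNAString(frag)))
        k <- pairwiseK2P(frag,
                         as.character(consensusSeqs(pg$library)[[1L]]))
        expect_lt(abs(k - mcols(pg$truth)$realizedDivergence[i]), 1e-9)
    }
    ## zero copies: genome equals backbone
    none <- plantCopies(makeBackbone(5000, seed = 13),
                        teFamilySpec("f0", "TIR", 300, copyNumber = 0),
                        seed = 14)
    expect_equal(sum(width(none$genome)), 5000L)
    expect_length(none$truth, 0L)
    ## truncated LINE copies align to a suffix of the consensus
    lspec <- teFamilySpec("l1", "LINE", 2000, targetDivergence = 0.05,
                          copyNumber = 10,
                          truncationModel = "five_prime_exponential",
                          truncationMean = 600)
    pl <- plantCopies(makeBackbone(50000, seed = 15), lspec, seed = 16,
                      indelRate = 0)
    tr <- mcols(pl$truth)
    expect_true(all(tr$cEnd == 2000L))
    expect_true(all(tr$cStart == tr$truncatedBp + 1L))
    expect_true(any(tr$truncatedBp > 0L))
    expect_true(all(width(pl$truth) == 2000L - tr$truncatedBp))
    ## overload rejected
    expect_error(
        plantCopies(makeBackbone(1000, seed = 17),
                    teFamilySpec("f", "TIR", 300, copyNumber = 10),
                    seed = 18),
        "too small")
})

test_that("nesting inserts copies inside earlier copies", {
    spec <- teFamilySpec("f1", "TIR", 400, targetDivergence = 0.02,
                         copyNumber = 30)
    pg <- plantCopies(makeBackbone(60000, seed = 19), spec, seed = 20,
                      nestingProbability = 1)
    ## with nesting forced, later copies split earlier ones: the
    ## truth spans overlap
    expect_lt(sum(width(reduce(granges(pg$truth)))),
              sum(width(pg$truth)))
})

test_that("gene models are structurally valid GFF3-style records", {
    gm <- simulateGeneModels(1e6, 10, seed = 21)
    expect_equal(sum(mcols(gm)$type == "gene"), 10L)
    genes <- gm[mcols(gm)$type == "gene"]
    exons <- gm[mcols(gm)$type == "exon"]
    expect_true(all(countOverlaps(genes, exons) >= 1L))
    ## child features lie within their gene
    for (k in seq_along(genes)) {
        gid <- mcols(genes)$ID[k]
        tid <- paste0(gid, ".t1")
        kids <- gm[vapply(mcols(gm)$Parent, function(p)
            length(p) > 0L && p[[1L]] == tid, logical(1L))]
        expect_true(all(start(kids) >= start(genes)[k]))
        expect_true(all(end(kids) <= end(genes)[k]))
    }
    ## introns recomputed independently: per gene, exon+intron bp
    ## tile the gene span exactly
    for (k in seq_along(genes)) {
        tid <- paste0(mcols(genes)$ID[k], ".t1")
        ex <- exons[vapply(mcols(exons)$Parent, function(p)
            p[[1L]] == tid, logical(1L))]
        introns <- setdiff(granges(genes[k]), granges(ex))
        expect_equal(sum(width(ex)) + sum(width(introns)),
                     width(genes)[k])
    }
    ## empty case
    g0 <- simulateGeneModels(10000, 0)
    expect_length(g0, 0L)
    expect_error(simulateGeneModels(10000, -1), ">= 0")
})

test_that("count simulation records DE truth", {
    sim <- simulateTECounts(2000, 3, deFraction = 0.1,
                            effectLog2fc = 2, seed = 22)
    expect_equal(sum(sim$truthLog2fc != 0), 200L)
    expect_equal(sum(sim$truthLog2fc > 0), 100L)
    expect_true(all(sim$counts >= 0))
    expect_true(is.integer(sim$counts))
    sim0 <- simulateTECounts(100, 2, deFraction = 0, seed = 23)
    expect_true(all(sim0$truthLog2fc == 0))
    expect_error(simulateTECounts(10, 3, dispersion = 0), "positive")
    expect_error(simulateTECounts(10, 1), "replicates")
})

test_that("simulator outputs are seed-deterministic", {
    spec <- teFamilySpec("f1", "LINE", 800, targetDivergence = 0.08,
                         copyNumber = 4)
    a <- plantCopies(makeBackbone(20000, seed = 1), spec, seed = 2)
    b <- plantCopies(makeBackbone(20000, seed = 1), spec, seed = 2)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
    expect_identical(simulateTECounts(50, 2, seed = 3)$counts,
                     simulateTECounts(50, 2, seed = 3)$counts)
    g1 <- simulateGeneModels(50000, 3, seed = 4)
    g2 <- simulateGeneModels(50000, 3, seed = 4)
    expect_identical(as.data.frame(g1)[, 1:5], as.data.frame(g2)[, 1:5])
})

test_that("CpG enrichment raises CpG density of the internal region", {
    spec <- teFamilySpec("c1", "Unknown", 2000, targetDivergence = 0.05)
    plain <- makeTEFamily(spec, seed = 24)$consensus
    rich <- makeTEFamily(spec, seed = 24, cpgEnrich = TRUE)$consensus
    nCpG <- function(s) length(gregexpr("CG", as.character(s),
                                        fixed = TRUE)[[1L]])
    expect_gt(nCpG(rich), 1.5 * nCpG(plain))
    ## enriched consensus lowers CpG-adjusted divergence of its copies
    cp <- mutateCopy(rich, 0.10, indelRate = 0, seed = 25)
    raw <- pairwiseK2P(as.character(cp$sequence), as.character(rich))
    adj <- pairwiseK2P(as.character(cp$sequence), as.character(rich),
                       cpgAdjusted = TRUE)
    expect_lt(adj, raw)
})
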