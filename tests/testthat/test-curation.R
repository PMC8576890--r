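test_that("coverage profiles count interval stabs", {
    h <- repeatHits("s", c(1, 2), c(100, 150), "+", "f",
                    c(1, 51), c(100, 150), 100)
    prof <- coverageProfile(h, "f", 150)
    expect_equal(prof, c(rep(1L, 50), rep(2L, 50), rep(1L, 50)))
    expect_equal(coverageProfile(h, "absent", 80), rep(0L, 80))
    ## uniform single full-length hit
    h1 <- repeatHits("s", 1, 60, "+", "f", 1, 60, 100)
    expect_equal(coverageProfile(h1, "f", 60), rep(1L, 60))
    expect_error(coverageProfile(h, "f", 120), "exceed")
})

test_that("trim/split matches the hand-evaluated rule and the oracle", {
    ## depth = [10 x3, 0 x2, 10 x2]: cutoff ~0.357, two segments (3, 2)
    seqChr <- "ACGTGCA"
    prof <- c(10, 10, 10, 0, 0, 10, 10)
    out <- trimSplitConsensus(seqChr, prof, minSegment = 1, id = "x")
    expect_equal(width(out), c(3L, 2L))
    expect_equal(as.character(out[[1L]]), "ACG")
    expect_equal(as.character(out[[2L]]), "CA")
    ## 3'-terminal low-support run is trimmed, not split
    s2 <- paste(rep("ACGT", 50), collapse = "")   # 200 bp
    p2 <- c(rep(10, 150), rep(0, 50))
    out2 <- trimSplitConsensus(s2, p2, minSegment = 50, id = "y")
    expect_equal(length(out2), 1L)
    expect_equal(as.character(out2[[1L]]), substr(s2, 1, 150))
    ## uniform support: identity
    out3 <- trimSplitConsensus(s2, rep(3, 200), id = "z")
    expect_equal(as.character(out3[[1L]]), s2)
    ## all-zero profile: flagged empty output
    out4 <- trimSplitConsensus(s2, rep(0, 200), id = "w")
    expect_length(out4, 0L)
    expect_match(attr(out4, "flagged"), "support")
    ## randomized agreement with the brute-force oracle
    set.seed(61)
    for (r in 1:200) {
        n <- sample(20:120, 1)
        seqChr <- paste(sample(c("A", "C", "G", "T"), n, TRUE),
                        collapse = "")
        prof <- sample(0:8, n, TRUE)
        ms <- sample(1:15, 1)
        mine <- as.character(trimSplitConsensus(seqChr, prof,
                                                minSegment = ms))
        oracle <- bruteTrimSplit(seqChr, prof, 0.05, ms)
        expect_equal(unname(mine), oracle)
    }
    ## conservation: outputs are disjoint in-order substrings
    prof <- c(rep(5, 30), 0, 0, rep(5, 40), 0, rep(5, 25))
    seqChr <- paste(sample(c("A", "C", "G", "T"), length(prof), TRUE),
                    collapse = "")
    segs <- as.character(trimSplitConsensus(seqChr, prof,
                                            minSegment = 10))
    pos <- 1L
    for (s in segs) {
        hit <- regexpr(s, substr(seqChr, pos, nchar(seqChr)),
                       fixed = TRUE)
        expect_gte(hit, 1L)
        pos <- pos + hit + nchar(s) - 1L
    }
})

test_that("80/80 clustering absorbs duplicates and is idempotent", {
    a <- as.character(makeBackbone(1000, seed = 62))
    b <- as.character(mutateCopy(a, 0.08, seed = 63)$sequence) # ~92% id
    dup <- DNAStringSet(c(A = a, B = b))
    out <- clusterLibrary(dup)
    expect_equal(names(out), "A")
    expect_equal(unname(attr(out, "members")["B"]), "A")
    ## identical sequences: one representative
    expect_length(clusterLibrary(DNAStringSet(c(x = a, y = a))), 1L)
    ## unrelated sequences both kept
    c2 <- as.character(makeBackbone(1000, seed = 64))
    expect_length(clusterLibrary(DNAStringSet(c(A = a, C = c2))), 2L)
    ## a reverse-complement duplicate is absorbed too
    expect_length(clusterLibrary(DNAStringSet(c(
        A = a, R = as.character(reverseComplement(DNAString(a)))))), 1L)
    ## coverage is over the shorter sequence: an exact fragment is
    ## absorbed, an 50%-identical sequence is not
    frag <- substr(a, 1, 490)
    expect_length(clusterLibrary(DNAStringSet(c(A = a, F = frag))), 1L)
    half <- paste0(substr(a, 1, 500),
                   as.character(makeBackbone(500, seed = 640)))
    expect_length(clusterLibrary(DNAStringSet(c(A = a, H = half))), 2L)
    ## ... but an 85% identical full-length copy is (independent
    ## cross-check of identity with Biostrings global alignment)
    b2 <- as.character(mutateCopy(a, 0.18, seed = 65)$sequence)
    aln <- pairwiseAlignment(DNAString(b2), DNAString(a),
                             type = "global")
    pidGlobal <- nmatch(aln) / nchar(aln)
    joined <- length(clusterLibrary(DNAStringSet(c(A = a, B = b2)))) == 1L
    expect_equal(joined, pidGlobal >= 0.80)
    ## idempotence
    lib <- DNAStringSet(c(A = a, B = b, C = c2, F = frag))
    once <- clusterLibrary(lib)
    twice <- clusterLibrary(DNAStringSet(once))
    expect_equal(names(twice), names(once))
})

test_that("support filter applies the length and copy-equivalent rule", {
    seqs <- DNAStringSet(c(
        short = as.character(makeBackbone(150, seed = 66)),
        wellSupported = as.character(makeBackbone(1000, seed = 67)),
        thinSupported = as.character(makeBackbone(1000, seed = 68))))
    hits <- repeatHits(
        scaffold = "s",
        qStart = c(1, 1001, 4001, 1, 2101),
        qEnd = c(150, 2050, 5050, 2100, 3600),
        strand = "+",
        consensusId = c("short", "wellSupported", "wellSupported",
                        "wellSupported", "thinSupported"),
        cStart = 1, cEnd = c(150, 1000, 1000, 1000, 1000),
        score = 500)
    ## copy-equiv: short 1.0, wellSupported (1050+1050+2100)/1000 = 4.2,
    ## thinSupported 1.5
    out <- filterLibrary(seqs, hits)
    expect_equal(names(out), "wellSupported")
    ce <- attr(out, "copyEquiv")
    expect_equal(unname(ce["wellSupported"]), 4.2)
    expect_equal(unname(ce["thinSupported"]), 1.5)
    ## exact boundary: 1000 bp consensus with 2100 aligned bp kept
    h2 <- repeatHits("s", c(1, 3001), c(1050, 4050), "+", "thinSupported",
                     1, 1000, 500)
    out2 <- filterLibrary(seqs[3], h2)
    expect_equal(names(out2), "thinSupported")
    ## lenient mode keeps length-failing but supported sequences
    h3 <- repeatHits("s", c(1, 201, 401), c(160, 360, 560), "+",
                     "short", 1, 150, 500)
    expect_length(filterLibrary(seqs[1], h3, mode = "strict"), 0L)
    expect_length(filterLibrary(seqs[1], h3, mode = "lenient"), 1L)
    ## monotone in minCopyEquiv, brute-force agreement
    set.seed(69)
    for (r in 1:50) {
        n <- sample(3:8, 1)
        lens <- sample(100:1200, n)
        lib <- DNAStringSet(setNames(
            vapply(lens, function(l) paste(
                sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
                character(1)), paste0("c", seq_len(n))))
        nh <- sample(1:12, 1)
        ids <- sample(names(lib), nh, TRUE)
        w <- sample(50:2000, nh, TRUE)
        hits <- repeatHits("s", seq_len(nh) * 3000,
                           seq_len(nh) * 3000 + w - 1, "+",
                           ids, 1, pmin(w, lens[match(ids, names(lib))]),
                           100)
        mce <- runif(1, 0.5, 3)
        mine <- names(filterLibrary(lib, hits, minCopyEquiv = mce))
        bp <- vapply(names(lib), function(id)
            sum(w[ids == id]), numeric(1))
        oracle <- names(lib)[lens >= 200 & bp / lens >= mce]
        expect_equal(mine, oracle)
        stricter <- names(filterLibrary(lib, hits,
                                        minCopyEquiv = mce + 0.5))
        expect_true(all(stricter %in% mine))
    }
})

test_that("tandem detector masks arrays and the filter drops them", {
    arr <- strrep("ACGT", 100)
    m <- tandemMask(arr)
    expect_gte(sum(width(m)) / 400, 0.99)
    tf <- tandemFilter(arr)
    expect_false(tf$keep)
    ## constructed arrays at random periods are detected
    set.seed(70)
    for (r in 1:30) {
        p <- sample(1:12, 1)
        unit <- paste(sample(c("A", "C", "G", "T"), p, TRUE),
                      collapse = "")
        units <- sample(5:20, 1)
        junk <- as.character(makeBackbone(300, seed = 700 + r))
        s <- paste0(junk, strrep(unit, units), junk)
        masked <- sum(width(tandemMask(s)))
        expect_gte(masked, 0.8 * p * units)
    }
    ## short sequence dropped on length regardless of masking
    s90 <- as.character(makeBackbone(90, seed = 71))
    expect_false(tandemFilter(s90)$keep)
    ## clean long sequence kept (random sequence rarely tandem-masked)
    s2k <- as.character(makeBackbone(2000, seed = 72))
    tf2 <- tandemFilter(s2k)
    expect_true(tf2$keep)
    expect_lt(tf2$maskedFraction, 0.5)
    ## 10%-masked long consensus kept via explicit mask
    tf3 <- tandemFilter(s2k, mask = IRanges(1, 200))
    expect_true(tf3$keep)
    expect_equal(tf3$maskedFraction, 0.1)
})

test_that("consensus extension stops at the flank agreement boundary", {
    core <- as.character(makeBackbone(300, seed = 73))
    shared <- as.character(makeBackbone(50, seed = 74))
    n <- 10L
    lf <- vapply(1:n, function(i) paste0(
        as.character(makeBackbone(100, seed = 750 + i)), shared),
        character(1))
    rf <- vapply(1:n, function(i) paste0(
        shared, as.character(makeBackbone(100, seed = 760 + i))),
        character(1))
    sa <- SeedAlignment("fam", rep(core, n), leftFlank = lf,
                        rightFlank = rf)
    ext <- extendConsensus(sa, maxExtend = 200)
    expect_lte(abs(ext$extendedRight - 50L), 5L)
    expect_lte(abs(ext$extendedLeft - 50L), 5L)
    ## extended sequence contains the shared flank
    expect_match(as.character(ext$sequence), shared, fixed = TRUE)
    ## two rows are below the ~3-agreeing-sequences stop threshold
    sa2 <- SeedAlignment("fam", rep(core, 2),
                         leftFlank = rep(shared, 2),
                         rightFlank = rep(shared, 2))
    ext2 <- extendConsensus(sa2)
    expect_equal(ext2$extendedLeft + ext2$extendedRight, 0L)
    ## rows without flanks: extension 0, no error
    sa3 <- SeedAlignment("fam", rep(core, 5))
    ext3 <- extendConsensus(sa3)
    expect_equal(ext3$extendedLeft + ext3$extendedRight, 0L)
    expect_error(extendConsensus(SeedAlignment("fam", character(0))))
})

test_that("seed alignments reconstruct instances in consensus space", {
    pg <- smallPlantedGenome()
    hits <- smallHits()
    sa <- makeSeedAlignment(hits, pg$genome, "mite1", 450)
    expect_gte(length(sa), 10L)
    expect_true(all(nchar(sa@alignment) == 450L))
    ## majority column consensus of the rows matches the family
    ext <- extendConsensus(sa, maxExtend = 0)
    id <- repeatforge:::.pairIdentity(
        ext$sequence, consensusSeqs(pg$library)[["mite1"]])
    expect_gte(id$identity, 0.97)
})

test_that("the full curation pipeline recovers planted families", {
    pg <- smallPlantedGenome()
    cons <- consensusSeqs(pg$library)
    raw <- DNAStringSet(c(
        r1 = paste0(as.character(makeBackbone(80, seed = 81)),
                    as.character(cons[["mite1"]]),
                    as.character(makeBackbone(60, seed = 82))),
        r2 = paste0(as.character(makeBackbone(100, seed = 83)),
                    as.character(cons[["line1"]])),
        r3 = substr(as.character(cons[["line1"]]), 401, 1700),
        tandem = strrep("ACGGT", 90),
        absent = as.character(makeBackbone(700, seed = 84))))
    cur <- curateLibrary(raw, pg$genome)
    lib <- consensusSeqs(cur$library)
    expect_equal(length(lib), 2L)
    for (fam in c("mite1", "line1")) {
        best <- max(vapply(seq_along(lib), function(i)
            repeatforge:::.pairIdentity(lib[[i]], cons[[fam]])$identity,
            numeric(1)))
        expect_gte(best, 0.95)
    }
    rep <- cur$report
    expect_true(any(rep$consensus == "tandem" & rep$action == "drop"))
    expect_true(any(rep$consensus == "absent" & rep$action == "drop"))
    expect_true(any(rep$consensus == "r3" & rep$action == "merge"))
})
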