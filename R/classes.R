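## Central S4 containers.

#' TELibrary: a set of TE consensus sequences with classification
#'
#' A \code{TELibrary} bundles consensus sequences (one per TE family)
#' with their classification (subclass from a closed DFAM-style
#' vocabulary, free-text superfamily) and provenance. It is the unit
#' passed between curation, classification and quantification stages.
#'
#' @slot sequences A named \link[Biostrings]{DNAStringSet}.
#' @slot info A \link[S4Vectors]{DataFrame} with columns
#'   \code{subclass}, \code{superfamily}, \code{provenance}, one row
#'   per sequence.
#'
#' @exportClass TELibrary
setClass("TELibrary",
    slots = c(sequences = "DNAStringSet", info = "DataFrame"))

setValidity("TELibrary", function(object) {
    msg <- NULL
    n <- length(object@sequences)
    if (is.null(names(object@sequences)) ||
        anyDuplicated(names(object@sequences)))
        msg <- c(msg, "sequences must have unique names")
    if (nrow(object@info) != n)
        msg <- c(msg, "info must have one row per sequence")
    if (!all(c("subclass", "superfamily", "provenance") %in%
             colnames(object@info)))
        msg <- c(msg, "info needs subclass/superfamily/provenance columns")
    else if (!all(object@info$subclass %in% TE_SUBCLASSES))
        msg <- c(msg, "subclass outside the closed vocabulary")
    if (n > 0L) {
        if (any(width(object@sequences) == 0L))
            msg <- c(msg, "empty consensus sequence")
        bad <- letterFrequency(object@sequences, "ACGTN") != width(object@sequences)
        if (any(bad))
            msg <- c(msg, "alphabet outside {A,C,G,T,N}")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a TELibrary
#'
#' @param sequences Named \code{DNAStringSet} (or named character vector)
#'   of consensus sequences.
#' @param subclass Character vector (recycled) of subclasses; must be in
#'   \code{c("LINE","SINE","LTR","DIRS","PLE","TIR","CRY","MAV","RC","Unknown")}.
#' @param superfamily Character vector (recycled); \code{NA} if unknown.
#' @param provenance Character vector (recycled) of free-text origins.
#' @return A \code{TELibrary}.
#' @examples
#' lib <- TELibrary(Biostrings::DNAStringSet(c(fam1 = "ACGTACGT")))
#' subclass(lib)
#' @export
TELibrary <- function(sequences, subclass = "Unknown",
                      superfamily = NA_character_, provenance = "") {
    if (!is(sequences, "DNAStringSet"))
        sequences <- DNAStringSet(sequences)
    n <- length(sequences)
    info <- DataFrame(
        subclass = rep_len(as.character(subclass), n),
        superfamily = rep_len(as.character(superfamily), n),
        provenance = rep_len(as.character(provenance), n),
        row.names = names(sequences))
    new("TELibrary", sequences = sequences, info = info)
}

#' @describeIn TELibrary Consensus sequences as a \code{DNAStringSet}.
#' @param x,object A \code{TELibrary}.
#' @export
consensusSeqs <- function(x) x@sequences

#' @describeIn TELibrary Classification table (\code{DataFrame}).
#' @export
teInfo <- function(x) x@info

#' Subclass accessor
#' @param x A \code{TELibrary}.
#' @return Character vector of subclasses, named by consensus id.
#' @export
subclass <- function(x) setNames(x@info$subclass, names(x@sequences))

#' Superfamily accessor
#' @param x A \code{TELibrary}.
#' @return Character vector of superfamilies, named by consensus id.
#' @export
superfamily <- function(x) setNames(x@info$superfamily, names(x@sequences))

#' @export
setMethod("length", "TELibrary", function(x) length(x@sequences))

#' @export
setMethod("names", "TELibrary", function(x) names(x@sequences))

#' @export
setMethod("[", "TELibrary", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i))
        i <- match(i, names(x@sequences))
    initialize(x, sequences = x@sequences[i], info = x@info[i, , drop = FALSE])
})

#' @export
setMethod("show", "TELibrary", function(object) {
    cat("TELibrary with", length(object), "consensus sequences\n")
    if (length(object) > 0L) {
        tab <- table(object@info$subclass)
        cat("  subclasses:",
            paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "),
            "\n")
        cat("  lengths:", min(width(object@sequences)), "-",
            max(width(object@sequences)), "bp\n")
    }
})

#' TEFamilySpec: parameters of one simulated TE family
#'
#' Describes a TE family for the synthetic-genome simulator: structure
#' (total length, terminal inverted repeat arm length, presence of a
#' coding region), evolutionary state (target K2P divergence of the
#' planted copies) and abundance (copy number, 5' truncation model for
#' LINE-like families).
#'
#' @slot familyId Character id.
#' @slot subclass One of \code{"TIR"}, \code{"LINE"}, \code{"LTR"},
#'   \code{"Unknown"}.
#' @slot length Consensus length (bp).
#' @slot tirLength TIR arm length (bp); 0 for none.
#' @slot hasCodingRegion Whether an ORF of at least 100 aa is embedded.
#' @slot targetDivergence Expected K2P distance of copies to the
#'   consensus, as a fraction in [0, 0.4).
#' @slot copyNumber Number of genomic copies to plant.
#' @slot truncationModel \code{"none"} or
#'   \code{"five_prime_exponential"} (LINE-like 5' truncation with
#'   exponentially distributed truncated length).
#' @slot truncationMean Mean truncated length (bp) for the
#'   exponential model.
#' @exportClass TEFamilySpec
setClass("TEFamilySpec",
    slots = c(familyId = "character", subclass = "character",
              length = "integer", tirLength = "integer",
              hasCodingRegion = "logical", targetDivergence = "numeric",
              copyNumber = "integer", truncationModel = "character",
              truncationMean = "numeric"))

setValidity("TEFamilySpec", function(object) {
    msg <- NULL
    if (!object@subclass %in% c("TIR", "LINE", "LTR", "Unknown"))
        msg <- c(msg, "subclass must be TIR, LINE, LTR or Unknown")
    if (object@length <= 0L)
        msg <- c(msg, "length must be positive")
    if (object@tirLength < 0L || 2L * object@tirLength > object@length)
        msg <- c(msg, "need 0 <= 2*tirLength <= length")
    if (object@targetDivergence < 0 || object@targetDivergence >= 0.4)
        msg <- c(msg, "targetDivergence must lie in [0, 0.4)")
    if (object@copyNumber < 0L)
        msg <- c(msg, "copyNumber must be >= 0")
    if (!object@truncationModel %in% c("none", "five_prime_exponential"))
        msg <- c(msg, "unknown truncationModel")
    if (object@truncationModel == "five_prime_exponential" &&
        object@truncationMean <= 0)
        msg <- c(msg, "truncationMean must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Construct a TEFamilySpec
#'
#' @param familyId Family id.
#' @param subclass \code{"TIR"}, \code{"LINE"}, \code{"LTR"} or
#'   \code{"Unknown"}.
#' @param length Consensus length in bp.
#' @param tirLength TIR arm length in bp (0 = no TIRs).
#' @param hasCodingRegion Embed an ORF of at least 100 aa?
#' @param targetDivergence Target K2P divergence of copies, in
#'   [0, 0.4).
#' @param copyNumber Number of copies to plant.
#' @param truncationModel \code{"none"} or
#'   \code{"five_prime_exponential"}.
#' @param truncationMean Mean 5'-truncated length (bp) under the
#'   exponential model.
#' @return A \code{TEFamilySpec}.
#' @examples
#' teFamilySpec("mite1", "TIR", length = 400, tirLength = 150,
#'              targetDivergence = 0.05, copyNumber = 20)
#' @export
teFamilySpec <- function(familyId, subclass, length, tirLength = 0L,
                         hasCodingRegion = FALSE, targetDivergence = 0.05,
                         copyNumber = 10L,
                         truncationModel = c("none", "five_prime_exponential"),
                         truncationMean = 500) {
    truncationModel <- match.arg(truncationModel)
    new("TEFamilySpec", familyId = as.character(familyId),
        subclass = as.character(subclass), length = as.integer(length),
        tirLength = as.integer(tirLength),
        hasCodingRegion = as.logical(hasCodingRegion),
        targetDivergence = as.numeric(targetDivergence),
        copyNumber = as.integer(copyNumber),
        truncationModel = truncationModel,
        truncationMean = as.numeric(truncationMean))
}

#' @export
setMethod("show", "TEFamilySpec", function(object) {
    cat(sprintf(
        "TEFamilySpec %s [%s] %d bp, TIR %d bp, %s, div %.3f, %d copies\n",
        object@familyId, object@subclass, object@length, object@tirLength,
        if (object@hasCodingRegion) "coding" else "non-coding",
        object@targetDivergence, object@copyNumber))
})

#' SeedAlignment: genomic instances aligned to one consensus
#'
#' A gapped multiple alignment of genomic copies of a family, with the
#' unaligned genomic sequence flanking each instance recorded so the
#' consensus can be extended into it.
#'
#' @slot consensusId Family id.
#' @slot alignment Character vector of equal-length gapped rows
#'   (\code{-} for gaps), named by instance locus.
#' @slot leftFlank,rightFlank Character vectors of genomic sequence
#'   immediately 5' / 3' of each aligned instance (possibly "").
#' @exportClass SeedAlignment
setClass("SeedAlignment",
    slots = c(consensusId = "character", alignment = "character",
              leftFlank = "character", rightFlank = "character"))

setValidity("SeedAlignment", function(object) {
    msg <- NULL
    n <- length(object@alignment)
    if (n < 1L)
        msg <- c(msg, "need at least one aligned row")
    if (n >= 1L && length(unique(nchar(object@alignment))) != 1L)
        msg <- c(msg, "aligned rows must have equal length")
    if (length(object@leftFlank) != n || length(object@rightFlank) != n)
        msg <- c(msg, "one flank pair per row required")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SeedAlignment
#'
#' @param consensusId Family id the rows belong to.
#' @param alignment Character vector of equal-length gapped rows.
#' @param leftFlank,rightFlank Per-row flanking genomic sequence
#'   (default "" = no flank recorded).
#' @return A \code{SeedAlignment}.
#' @export
SeedAlignment <- function(consensusId, alignment,
                          leftFlank = rep("", length(alignment)),
                          rightFlank = rep("", length(alignment))) {
    new("SeedAlignment", consensusId = as.character(consensusId),
        alignment = toupper(as.character(alignment)),
        leftFlank = toupper(as.character(leftFlank)),
        rightFlank = toupper(as.character(rightFlank)))
}

#' @export
setMethod("show", "SeedAlignment", function(object) {
    cat(sprintf("SeedAlignment for %s: %d rows x %d columns\n",
                object@consensusId, length(object@alignment),
                nchar(object@alignment[1L])))
})

#' @export
setMethod("length", "SeedAlignment", function(x) length(x@alignment))

#' TIRPair: a detected terminal inverted repeat
#'
#' Coordinates (on the consensus) of the two reverse-complementary
#' arms of a terminal inverted repeat, with arm alignment statistics.
#'
#' @slot leftStart,leftEnd,rightStart,rightEnd Arm coordinates (1-based
#'   inclusive, consensus forward strand).
#' @slot armLength Aligned arm length (bp).
#' @slot armIdentity Fraction of identical aligned columns.
#' @slot offset5,offset3 Distance of each arm from its terminus (bp).
#' @slot score Alignment score of the arm pair.
#' @exportClass TIRPair
setClass("TIRPair",
    slots = c(leftStart = "integer", leftEnd = "integer",
              rightStart = "integer", rightEnd = "integer",
              armLength = "integer", armIdentity = "numeric",
              offset5 = "integer", offset3 = "integer", score = "numeric"))

setValidity("TIRPair", function(object) {
    msg <- NULL
    if (object@leftEnd >= object@rightStart)
        msg <- c(msg, "TIR arms must not overlap")
    if (object@offset5 < 0L || object@offset3 < 0L)
        msg <- c(msg, "arm offsets must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("show", "TIRPair", function(object) {
    cat(sprintf(
        "TIRPair: [%d,%d] / [%d,%d], arm %d bp, id %.2f, score %.0f\n",
        object@leftStart, object@leftEnd, object@rightStart,
        object@rightEnd, object@armLength, object@armIdentity,
        object@score))
})

#' HomologyCall: one classification vote
#'
#' The result of one evidence source (nucleotide homology, translated
#' protein homology, or structure) voting on the classification of a
#' consensus.
#'
#' @slot source \code{"nt"}, \code{"protein"} or \code{"structural"}.
#' @slot subclass Voted subclass.
#' @slot superfamily Voted superfamily or \code{NA}.
#' @slot score Supporting alignment score.
#' @slot lengthRatio Hit length / consensus length (capped at 1).
#' @exportClass HomologyCall
setClass("HomologyCall",
    slots = c(source = "character", subclass = "character",
              superfamily = "character", score = "numeric",
              lengthRatio = "numeric"))

setValidity("HomologyCall", function(object) {
    msg <- NULL
    if (!object@source %in% c("nt", "protein", "structural"))
        msg <- c(msg, "source must be nt, protein or structural")
    if (object@lengthRatio < 0 || object@lengthRatio > 1)
        msg <- c(msg, "lengthRatio must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Construct a HomologyCall
#' @param source Evidence source (\code{"nt"}, \code{"protein"},
#'   \code{"structural"}).
#' @param subclass Voted subclass.
#' @param superfamily Voted superfamily (\code{NA} for none).
#' @param score Supporting score.
#' @param lengthRatio Hit length over consensus length; capped at 1.
#' @return A \code{HomologyCall}.
#' @export
homologyCall <- function(source, subclass, superfamily = NA_character_,
                         score = 0, lengthRatio = 0) {
    new("HomologyCall", source = unname(source),
        subclass = unname(as.character(subclass)),
        superfamily = unname(as.character(superfamily)),
        score = unname(as.numeric(score)),
        lengthRatio = min(1, unname(as.numeric(lengthRatio))))
}

#' @export
setMethod("show", "HomologyCall", function(object) {
    cat(sprintf("HomologyCall [%s] %s score %.1f ratio %.3f\n",
                object@source,
                .pasteClassLabel(object@subclass, object@superfamily),
                object@score, object@lengthRatio))
})

#' Construct a repeat hit table
#'
#' Repeat hits (one genome-to-consensus local alignment each) are
#' carried as a \link[GenomicRanges]{GRanges} on the genome with a
#' fixed metadata contract: \code{score}, \code{pctDiv},
#' \code{pctDel}, \code{pctIns}, \code{consensusId}, \code{cStart},
#' \code{cEnd} (consensus coordinates, always forward-strand
#' ascending), \code{cLeft} (consensus bp remaining after
#' \code{cEnd}), \code{teClass} ("subclass/superfamily" label) and
#' \code{kimuraDiv} (K2P divergence in percent, \code{NA} if not
#' computed). Minus-strand genomic hits carry strand \code{"-"}
#' (written as \code{"C"} in the RepeatMasker dialect).
#'
#' @param scaffold Character vector of scaffold names.
#' @param qStart,qEnd 1-based inclusive genomic coordinates.
#' @param strand \code{"+"} or \code{"-"} (or \code{"C"}).
#' @param consensusId Consensus (family) ids.
#' @param cStart,cEnd Consensus coordinates (forward strand,
#'   \code{cStart <= cEnd}).
#' @param score Alignment scores (>= 0).
#' @param pctDiv,pctDel,pctIns Percent mismatches / deleted bp /
#'   inserted bp per aligned column.
#' @param kimuraDiv K2P divergence in percent (\code{NA} allowed).
#' @param teClass "subclass/superfamily" labels.
#' @param scaffoldLength Optional scaffold lengths (for the
#'   \code{(left)} fields of the RepeatMasker dialect).
#' @param consensusLength Optional consensus lengths, used to compute
#'   \code{cLeft}.
#' @return A \code{GRanges} following the repeat-hit contract.
#' @examples
#' repeatHits("scf1", 101, 200, "+", "fam1", 1, 100, score = 500)
#' @export
repeatHits <- function(scaffold, qStart, qEnd, strand, consensusId,
                       cStart, cEnd, score, pctDiv = 0, pctDel = 0,
                       pctIns = 0, kimuraDiv = NA_real_,
                       teClass = "Unknown", scaffoldLength = NA_integer_,
                       consensusLength = NA_integer_) {
    n <- max(length(scaffold), length(qStart), length(qEnd),
             length(consensusId))
    scaffold <- rep_len(as.character(scaffold), n)
    strand <- rep_len(ifelse(strand == "C", "-", strand), n)
    qStart <- rep_len(as.integer(qStart), n)
    qEnd <- rep_len(as.integer(qEnd), n)
    cStart <- rep_len(as.integer(cStart), n)
    cEnd <- rep_len(as.integer(cEnd), n)
    score <- rep_len(as.numeric(score), n)
    if (any(qStart > qEnd))
        stop("repeat hit with qStart > qEnd")
    if (any(cStart < 1L) || any(cStart > cEnd))
        stop("repeat hit with invalid consensus coordinates")
    if (any(score < 0))
        stop("repeat hit with negative score")
    consensusLength <- rep_len(as.integer(consensusLength), n)
    cLeft <- ifelse(is.na(consensusLength), 0L, consensusLength - cEnd)
    if (any(!is.na(consensusLength) & cLeft < 0L))
        stop("consensus coordinates exceed consensus length")
    gr <- GRanges(seqnames = scaffold, ranges = IRanges(qStart, qEnd),
                  strand = strand)
    mcols(gr) <- DataFrame(
        score = score,
        pctDiv = rep_len(as.numeric(pctDiv), n),
        pctDel = rep_len(as.numeric(pctDel), n),
        pctIns = rep_len(as.numeric(pctIns), n),
        consensusId = rep_len(as.character(consensusId), n),
        cStart = cStart, cEnd = cEnd, cLeft = as.integer(cLeft),
        teClass = rep_len(as.character(teClass), n),
        kimuraDiv = rep_len(as.numeric(kimuraDiv), n))
    sl <- rep_len(as.integer(scaffoldLength), n)
    if (any(!is.na(sl))) {
        lens <- tapply(pmax(sl, qEnd, na.rm = TRUE),
                       as.character(scaffold), max, na.rm = TRUE)
        seqlengths(gr)[names(lens)] <- as.integer(lens)
    }
    gr
}
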