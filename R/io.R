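## Interchange formats: RepeatMasker-style hit tables, FASTA, GFF3,
## BED, Stockholm seed alignments.

.HIT_HEADER <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)     ID",
    "")

#' Read a RepeatMasker-style hit table
#'
#' Parses the whitespace-separated \code{.out} dialect: 15 standard
#' columns (score, \%div, \%del, \%ins, query coordinates with
#' \code{(left)}, strand \code{+}/\code{C}, repeat name,
#' class/family, strand-aware consensus coordinates, id) plus an
#' optional 16th Kimura-divergence column. For \code{C} (minus
#' strand) hits the consensus coordinate field order is
#' \code{(left) end begin}, i.e. the left coordinate is the
#' parenthesised remainder. Header lines are tolerated.
#'
#' @param path File path.
#' @return A \code{GRanges} repeat-hit table (see
#'   \code{\link{repeatHits}}).
#' @export
readRepeatHits <- function(path) {
    lines <- readLines(path)
    recs <- list()
    for (ln in seq_along(lines)) {
        line <- trimws(lines[ln])
        if (line == "" || !grepl("^[0-9]", line))
            next
        f <- strsplit(line, "[[:space:]]+")[[1L]]
        if (length(f) < 15L)
            stop("malformed hit-table row at line ", ln,
                 ": expected >= 15 fields, got ", length(f))
        num <- function(x, what) {
            v <- suppressWarnings(as.numeric(gsub("[()]", "", x)))
            if (is.na(v))
                stop("malformed hit-table row at line ", ln,
                     ": bad ", what, " field '", x, "'")
            v
        }
        strand <- f[9L]
        if (!strand %in% c("+", "C"))
            stop("malformed hit-table row at line ", ln,
                 ": bad strand '", strand, "'")
        qStart <- num(f[6L], "query begin"); qEnd <- num(f[7L], "query end")
        if (qStart > qEnd)
            stop("malformed hit-table row at line ", ln,
                 ": query begin > end")
        if (strand == "+") {
            cStart <- num(f[12L], "repeat begin")
            cEnd <- num(f[13L], "repeat end")
            cLeft <- num(f[14L], "repeat left")
        } else {
            cLeft <- num(f[12L], "repeat left")
            cEnd <- num(f[13L], "repeat end")
            cStart <- num(f[14L], "repeat begin")
        }
        if (cStart > cEnd || cStart < 1)
            stop("malformed hit-table row at line ", ln,
                 ": bad consensus coordinates")
        recs[[length(recs) + 1L]] <- list(
            score = num(f[1L], "score"), pctDiv = num(f[2L], "div"),
            pctDel = num(f[3L], "del"), pctIns = num(f[4L], "ins"),
            scaffold = f[5L], qStart = qStart, qEnd = qEnd,
            qLeft = num(f[8L], "query left"), strand = strand,
            consensusId = f[10L], teClass = f[11L],
            cStart = cStart, cEnd = cEnd, cLeft = cLeft,
            kimuraDiv = if (length(f) >= 16L && f[16L] != "NA")
                num(f[16L], "kimura") else NA_real_)
    }
    if (length(recs) == 0L)
        return(repeatHits(character(0), integer(0), integer(0),
                          character(0), character(0), integer(0),
                          integer(0), numeric(0)))
    g <- function(k) vapply(recs, function(r) r[[k]],
                            if (k %in% c("scaffold", "strand",
                                         "consensusId", "teClass"))
                                character(1L) else numeric(1L))
    hits <- repeatHits(
        scaffold = g("scaffold"), qStart = g("qStart"), qEnd = g("qEnd"),
        strand = g("strand"), consensusId = g("consensusId"),
        cStart = g("cStart"), cEnd = g("cEnd"), score = g("score"),
        pctDiv = g("pctDiv"), pctDel = g("pctDel"), pctIns = g("pctIns"),
        kimuraDiv = g("kimuraDiv"), teClass = g("teClass"),
        scaffoldLength = g("qEnd") + g("qLeft"),
        consensusLength = g("cEnd") + g("cLeft"))
    hits
}

#' Write a RepeatMasker-style hit table
#'
#' Inverse of \code{\link{readRepeatHits}}; the round trip
#' \code{readRepeatHits(writeRepeatHits(x))} is lossless for all
#' fields. A 16th Kimura column is written when any hit carries a
#' non-missing \code{kimuraDiv}.
#'
#' @param hits Repeat-hit \code{GRanges} (see \code{\link{repeatHits}}).
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeRepeatHits <- function(hits, path) {
    sl <- seqlengths(hits)[as.character(seqnames(hits))]
    qLeft <- ifelse(is.na(sl), 0L, sl - end(hits))
    m <- mcols(hits)
    strandChr <- ifelse(as.character(strand(hits)) == "-", "C", "+")
    withKimura <- any(!is.na(m$kimuraDiv))
    rows <- vapply(seq_along(hits), function(i) {
        cfields <- if (strandChr[i] == "+")
            c(m$cStart[i], m$cEnd[i], sprintf("(%d)", m$cLeft[i]))
        else
            c(sprintf("(%d)", m$cLeft[i]), m$cEnd[i], m$cStart[i])
        f <- c(format(m$score[i]), sprintf("%.1f", m$pctDiv[i]),
               sprintf("%.1f", m$pctDel[i]), sprintf("%.1f", m$pctIns[i]),
               as.character(seqnames(hits))[i], start(hits)[i],
               end(hits)[i], sprintf("(%d)", qLeft[i]), strandChr[i],
               m$consensusId[i], m$teClass[i], cfields, i)
        if (withKimura)
            f <- c(f, ifelse(is.na(m$kimuraDiv[i]), "NA",
                             sprintf("%.4f", m$kimuraDiv[i])))
        paste(f, collapse = " ")
    }, character(1L))
    writeLines(c(.HIT_HEADER, rows), path)
    invisible(path)
}

#' Read/write FASTA
#'
#' Thin wrappers over \link[Biostrings]{readDNAStringSet} and
#' \link[Biostrings]{writeXStringSet}.
#'
#' @param path File path.
#' @return \code{readFasta}: a \code{DNAStringSet}.
#' @export
readFasta <- function(path) readDNAStringSet(path)

#' @rdname readFasta
#' @param x A \code{DNAStringSet} (or \code{TELibrary}, whose
#'   classification is embedded in the headers as
#'   \code{id#subclass/superfamily}).
#' @export
writeFasta <- function(x, path) {
    if (is(x, "TELibrary")) {
        seqs <- consensusSeqs(x)
        names(seqs) <- paste0(names(seqs), "#",
                              .pasteClassLabel(x@info$subclass,
                                               x@info$superfamily))
        x <- seqs
    }
    writeXStringSet(x, path)
    invisible(path)
}

#' Read/write gene models as GFF3
#'
#' Wrappers over \link[rtracklayer]{import} / \code{export} with the
#' GFF3 convention (1-based, inclusive).
#'
#' @param path File path.
#' @return \code{readGeneModels}: a \code{GRanges} with \code{type},
#'   \code{ID}, \code{Parent} metadata.
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr
}

#' @rdname readGeneModels
#' @param gr Gene-model \code{GRanges} (as from
#'   \code{\link{simulateGeneModels}}).
#' @export
writeGeneModels <- function(gr, path) {
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Convert between GFF3 and BED interval conventions
#'
#' GFF3 intervals are 1-based inclusive; BED intervals are 0-based
#' half-open. The conversions are exact inverses.
#'
#' @param start,end GFF3 coordinates.
#' @return A two-column matrix of converted coordinates.
#' @examples
#' gffToBed(1, 100)   # 0, 100
#' bedToGff(0, 100)   # 1, 100
#' @export
gffToBed <- function(start, end) {
    if (any(end < start))
        stop("interval end before start")
    cbind(start = start - 1L, end = end)
}

#' @rdname gffToBed
#' @export
bedToGff <- function(start, end) {
    if (any(end <= start))
        stop("empty or inverted BED interval")
    cbind(start = start + 1L, end = end)
}

#' Read/write intervals as BED
#'
#' Wrappers over \link[rtracklayer]{import} / \code{export}
#' (\code{rtracklayer} performs the 0-based half-open conversion).
#'
#' @param path File path.
#' @return \code{readBedRanges}: a \code{GRanges}.
#' @export
readBedRanges <- function(path) rtracklayer::import(path, format = "bed")

#' @rdname readBedRanges
#' @param gr A \code{GRanges}.
#' @export
writeBedRanges <- function(gr, path) {
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}

#' Read a Stockholm seed alignment
#'
#' Parses a single-alignment Stockholm file into a
#' \code{\link{SeedAlignment}}. Sequence lines may be wrapped
#' (repeated row names are concatenated); rows of unequal final
#' length are a parse error. The consensus id is taken from
#' \code{#=GF ID} when present, else from the file name.
#'
#' @param path File path.
#' @return A \code{SeedAlignment} (flanks empty).
#' @export
readStockholm <- function(path) {
    lines <- readLines(path)
    if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1L]))
        stop("not a Stockholm file: missing '# STOCKHOLM' header")
    id <- sub("\\.[^.]*$", "", basename(path))
    rows <- list()
    for (ln in seq_along(lines)[-1L]) {
        line <- lines[ln]
        if (grepl("^#=GF ID", line)) {
            id <- trimws(sub("^#=GF ID", "", line))
            next
        }
        if (line == "" || grepl("^#", line) || grepl("^//", line))
            next
        f <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
        if (length(f) != 2L)
            stop("malformed Stockholm row at line ", ln)
        rows[[f[1L]]] <- paste0(if (is.null(rows[[f[1L]]])) ""
                                else rows[[f[1L]]], f[2L])
    }
    if (length(rows) == 0L)
        stop("Stockholm file contains no sequence rows")
    aln <- toupper(gsub("\\.", "-", unlist(rows)))
    if (length(unique(nchar(aln))) != 1L)
        stop("Stockholm rows have unequal aligned lengths")
    SeedAlignment(id, aln)
}

#' @rdname readStockholm
#' @param seed A \code{SeedAlignment}.
#' @export
writeStockholm <- function(seed, path) {
    nm <- names(seed@alignment)
    if (is.null(nm))
        nm <- paste0("row", seq_along(seed@alignment))
    writeLines(c("# STOCKHOLM 1.0",
                 paste0("#=GF ID ", seed@consensusId),
                 paste(format(nm), seed@alignment),
                 "//"), path)
    invisible(path)
}
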