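## Genomic distribution of TE copies: gene-anatomy partition, windowed
## coverage, metaprofiles, intron TE content.

#' Partition a genome into gene-anatomy regions
#'
#' Builds an exclusive labeled cover of the genome from gene models:
#' \code{five_utr} and \code{three_utr} take precedence over
#' \code{exon} (exon bp exclude UTR bp), \code{intron} is the
#' intra-gene space between exons, and everything unlabeled is
#' \code{intergenic}. TSS flanks (\code{tss_flank}, strand-aware
#' gene start +/- \code{tssFlank} bp, truncated at scaffold bounds)
#' are kept as a separate overlay track since they overlap the other
#' labels by construction. Per-instance intervals (each UTR, exon,
#' intron, flank, with the gene's strand) are returned alongside for
#' metaprofiles.
#'
#' @param gff Gene-model \code{GRanges} with \code{type} metadata
#'   (gene, exon, five_prime_UTR, three_prime_UTR), e.g. from
#'   \code{\link{simulateGeneModels}} or \code{\link{readGeneModels}};
#'   seqlengths must be set (or supplied via \code{seqlens}).
#' @param seqlens Optional named vector of scaffold lengths.
#' @param tssFlank TSS flank half-width (default 3000 bp).
#' @return List with \code{cover} (disjoint labeled \code{GRanges}
#'   covering the genome; label in
#'   \code{five_utr, three_utr, exon, intron, intergenic}),
#'   \code{tss} (overlay \code{GRanges}) and \code{instances}
#'   (per-instance labeled, stranded \code{GRanges}).
#' @export
partitionRegions <- function(gff, seqlens = NULL, tssFlank = 3000) {
    if (is.null(seqlens)) {
        seqlens <- seqlengths(gff)
        if (any(is.na(seqlens)))
            stop("scaffold lengths are required (seqlengths or 'seqlens')")
    }
    genomeGR <- GRanges(names(seqlens), IRanges(1L, unname(seqlens)))
    type <- mcols(gff)$type
    genes <- gff[type == "gene"]
    exons <- gff[type == "exon"]
    utr5 <- gff[type == "five_prime_UTR"]
    utr3 <- gff[type == "three_prime_UTR"]
    if (length(genes) > 0L) {
        nEx <- countOverlaps(genes, exons, type = "any")
        if (any(nEx == 0L))
            stop("gene with zero exons: ",
                 paste(mcols(genes)$ID[nEx == 0L], collapse = ", "))
    }
    u5r <- reduce(granges(utr5), ignore.strand = TRUE)
    u3r <- setdiff(reduce(granges(utr3), ignore.strand = TRUE), u5r,
                   ignore.strand = TRUE)
    exr <- setdiff(reduce(granges(exons), ignore.strand = TRUE),
                   c(u5r, u3r), ignore.strand = TRUE)
    gener <- reduce(granges(genes), ignore.strand = TRUE)
    intr <- setdiff(gener, c(u5r, u3r, exr), ignore.strand = TRUE)
    interg <- setdiff(genomeGR, c(u5r, u3r, exr, intr),
                      ignore.strand = TRUE)
    addLab <- function(gr, lab) {
        if (length(gr) > 0L) mcols(gr)$label <- lab
        else mcols(gr)$label <- character(0)
        gr
    }
    cover <- sort(c(addLab(u5r, "five_utr"), addLab(u3r, "three_utr"),
                    addLab(exr, "exon"), addLab(intr, "intron"),
                    addLab(interg, "intergenic")),
                  ignore.strand = TRUE)
    ## TSS overlay: strand-aware gene starts
    tss <- GRanges()
    if (length(genes) > 0L) {
        tssPos <- ifelse(as.character(strand(genes)) == "-",
                         end(genes), start(genes))
        tss <- GRanges(seqnames(genes),
                       IRanges(pmax(1L, tssPos - tssFlank),
                               pmin(seqlens[as.character(seqnames(genes))],
                                    tssPos + tssFlank)),
                       strand = strand(genes))
        mcols(tss)$label <- "tss_flank"
        mcols(tss)$gene <- mcols(genes)$ID
    }
    ## per-instance intervals, stranded, for metaprofiles
    inst <- list()
    if (length(genes) > 0L) {
        gid <- mcols(genes)$ID
        exParent <- .featureGene(exons, gff)
        u5Parent <- .featureGene(utr5, gff)
        u3Parent <- .featureGene(utr3, gff)
        for (k in seq_along(genes)) {
            g <- genes[k]
            std <- as.character(strand(g))
            ex <- exons[exParent == gid[k]]
            u5 <- utr5[u5Parent == gid[k]]
            u3 <- utr3[u3Parent == gid[k]]
            exCore <- setdiff(granges(ex), c(granges(u5), granges(u3)),
                              ignore.strand = TRUE)
            introns <- setdiff(granges(g), granges(ex),
                               ignore.strand = TRUE)
            mk <- function(gr, lab) {
                if (length(gr) == 0L) return(GRanges())
                out <- GRanges(seqnames(gr), ranges(gr), strand = std)
                mcols(out)$label <- lab
                mcols(out)$gene <- gid[k]
                out
            }
            inst[[length(inst) + 1L]] <- c(
                mk(exCore, "exon"), mk(introns, "intron"),
                mk(granges(u5), "five_utr"), mk(granges(u3), "three_utr"))
        }
    }
    instances <- if (length(inst)) do.call(c, inst) else GRanges()
    if (length(tss) > 0L)
        instances <- c(instances, tss)
    ## intergenic instances (unstranded)
    if (length(interg) > 0L) {
        ig <- interg
        mcols(ig)$label <- "intergenic"
        mcols(ig)$gene <- NA_character_
        instances <- c(instances, ig)
    }
    list(cover = cover, tss = tss, instances = instances)
}

## Map features to the ID of their grandparent gene (via mRNA Parent).
.featureGene <- function(features, gff) {
    if (length(features) == 0L)
        return(character(0))
    parent <- vapply(mcols(features)$Parent, function(p)
        if (length(p)) p[[1L]] else NA_character_, character(1L))
    ids <- mcols(gff)$ID
    parentOf <- setNames(vapply(mcols(gff)$Parent, function(p)
        if (length(p)) p[[1L]] else NA_character_, character(1L)), ids)
    ## a feature's Parent is usually the mRNA; walk one level up
    up <- parentOf[parent]
    ifelse(is.na(up), parent, up)
}

#' Windowed TE coverage track
#'
#' Fraction of TE bp (union of hit intervals) per fixed-width window
#' across the genome; the last partial window of each scaffold is
#' normalized by its true width.
#'
#' @param hits Repeat-hit \code{GRanges} (or any \code{GRanges} of TE
#'   intervals).
#' @param seqlens Named vector of scaffold lengths (defaults to the
#'   hits' seqlengths).
#' @param window Window width in bp (default 100).
#' @return A \code{GRanges} of windows with metadata column
#'   \code{score} (TE fraction in [0, 1]).
#' @export
windowedTECoverage <- function(hits, seqlens = NULL, window = 100) {
    if (is.null(seqlens)) {
        seqlens <- seqlengths(hits)
        if (any(is.na(seqlens)))
            stop("scaffold lengths are required")
    }
    tiles <- unlist(tileGenome(seqlens, tilewidth = window))
    te <- reduce(granges(hits), ignore.strand = TRUE)
    te <- GRanges(factor(as.character(seqnames(te)),
                         levels = names(seqlens)), ranges(te))
    cov <- coverage(te, width = seqlens)
    score <- numeric(length(tiles))
    for (sc in names(seqlens)) {
        sel <- as.character(seqnames(tiles)) == sc
        v <- Views(cov[[sc]], ranges(tiles)[sel])
        score[sel] <- viewMeans(v)
    }
    mcols(tiles)$score <- pmin(score, 1)
    tiles
}

#' Metaprofile of TE density across region instances
#'
#' Rescales every region instance to \code{nBins} bins (strand-aware,
#' 5' to 3') and averages the per-bp TE coverage track within each
#' bin, per region label.
#'
#' @param track Coverage track from \code{\link{windowedTECoverage}}
#'   (windows with \code{score}).
#' @param instances Stranded labeled instances from
#'   \code{\link{partitionRegions}} (or any labeled \code{GRanges}).
#' @param nBins Number of scaled-position bins (default 20).
#' @return A matrix of mean TE density, labels x bins.
#' @export
metaprofile <- function(track, instances, nBins = 20) {
    labs <- unique(mcols(instances)$label)
    ## per-bp value vector per scaffold from the window track
    perBp <- list()
    for (sc in unique(as.character(seqnames(track)))) {
        sel <- as.character(seqnames(track)) == sc
        t <- track[sel]
        perBp[[sc]] <- rep(mcols(t)$score, width(t))
    }
    acc <- matrix(0, length(labs), nBins,
                  dimnames = list(labs, NULL))
    cnt <- matrix(0, length(labs), nBins,
                  dimnames = list(labs, NULL))
    for (i in seq_along(instances)) {
        sc <- as.character(seqnames(instances))[i]
        v <- perBp[[sc]][start(instances)[i]:end(instances)[i]]
        if (is.null(v) || length(v) == 0L)
            next
        if (as.character(strand(instances))[i] == "-")
            v <- rev(v)
        bin <- floor((seq_along(v) - 1L) * nBins / length(v)) + 1L
        lab <- mcols(instances)$label[i]
        sums <- tapply(v, bin, sum)
        ns <- tapply(v, bin, length)
        bi <- as.integer(names(sums))
        acc[lab, bi] <- acc[lab, bi] + sums / ns
        cnt[lab, bi] <- cnt[lab, bi] + 1
    }
    out <- acc / pmax(cnt, 1)
    out[cnt == 0] <- NA
    out
}

#' Per-intron TE content
#'
#' Intersects overlap-resolved TE fragments with every intron
#' instance.
#'
#' @param partition Output of \code{\link{partitionRegions}}.
#' @param fragments Overlap-resolved fragments
#'   (\code{\link{resolveOverlaps}}); raw hits are resolved first.
#' @return data.frame with one row per intron: \code{gene},
#'   \code{length}, \code{teBp}, \code{teFraction}.
#' @export
intronTETable <- function(partition, fragments) {
    introns <- partition$instances[
        mcols(partition$instances)$label == "intron"]
    if (length(fragments) > 0L &&
        is.null(mcols(fragments)$hitIndex))
        fragments <- resolveOverlaps(fragments)
    te <- reduce(granges(fragments), ignore.strand = TRUE)
    teBp <- vapply(seq_along(introns), function(i)
        sum(width(intersect(granges(introns[i]), te,
                            ignore.strand = TRUE))), numeric(1L))
    data.frame(gene = mcols(introns)$gene,
               length = width(introns), teBp = teBp,
               teFraction = ifelse(width(introns) > 0,
                                   teBp / width(introns), 0))
}
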