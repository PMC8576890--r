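## Kimura 2-parameter divergence.

#' K2P distance from transition/transversion fractions
#'
#' Closed-form Kimura 2-parameter distance
#' \eqn{K = -\frac{1}{2}\ln((1-2p-q)\sqrt{1-2q})}
#' where \code{p} is the transition and \code{q} the transversion
#' fraction of compared sites.
#'
#' @param p Transition fraction.
#' @param q Transversion fraction.
#' @return Distance (substitutions/site), or \code{NA} when the
#'   logarithm arguments are non-positive (saturation).
#' @examples
#' k2pDistance(0.10, 0.05)
#' @export
k2pDistance <- function(p, q) {
    a <- 1 - 2 * p - q
    b <- 1 - 2 * q
    ifelse(a <= 0 | b <= 0, NA_real_, -0.5 * log(a * sqrt(b)))
}

#' Solve per-site substitution probabilities for a target K2P distance
#'
#' Finds the per-site transition probability \code{p} and transversion
#' probability \code{q = p / tsTv} whose K2P distance equals
#' \code{target}, by numerically inverting the closed form.
#'
#' @param target Target K2P distance (fraction, < 0.4).
#' @param tsTv Transition/transversion ratio (> 0).
#' @return List with elements \code{p} and \code{q}.
#' @examples
#' r <- k2pSolveRates(0.10, tsTv = 2)
#' k2pDistance(r$p, r$q)  # == 0.10
#' @export
k2pSolveRates <- function(target, tsTv = 2) {
    if (target < 0 || target >= 0.4)
        stop("target divergence must lie in [0, 0.4)")
    if (tsTv <= 0)
        stop("tsTv must be positive")
    if (target == 0)
        return(list(p = 0, q = 0))
    f <- function(p) {
        q <- p / tsTv
        k <- k2pDistance(p, q)
        if (is.na(k)) Inf else k - target
    }
    ## p + q must stay below the domain boundary 2p + q < 1
    pmax <- 1 / (2 + 1 / tsTv) - 1e-9
    sol <- tryCatch(uniroot(f, c(1e-12, pmax), tol = 1e-12),
                    error = function(e) NULL)
    if (is.null(sol) || f(sol$root) > 1e-6)
        stop("no (p, q) solution in the K2P domain for this target")
    p <- sol$root
    if (p + p / tsTv >= 0.75)
        stop("no (p, q) solution in the K2P domain for this target")
    list(p = p, q = p / tsTv)
}

#' Pairwise K2P divergence between an aligned copy and its consensus
#'
#' Computes the Kimura 2-parameter distance between two equal-length
#' gapped sequences. Columns containing a gap or a non-ACGT character
#' in either row are excluded from the site counts. With
#' \code{cpgAdjusted = TRUE}, transitions at consensus CpG dinucleotide
#' positions are down-weighted to 1/10, with the two positions of one
#' CpG contributing at most one (down-weighted) transition — the usual
#' treatment of hypermutable CpG sites in repeat divergence landscapes.
#'
#' @param copy,consensus Equal-length gapped sequences (character or
#'   \code{DNAString}); \code{consensus} defines CpG positions.
#' @param cpgAdjusted Apply the CpG down-weighting?
#' @return K2P distance as a fraction of substitutions/site, or
#'   \code{NA_real_} on saturation (log argument non-positive) or when
#'   no comparable site exists.
#' @examples
#' pairwiseK2P("ACGT", "ACGT")            # 0
#' pairwiseK2P("AAGG", "AGGG")            # one transition in 4 sites
#' @export
pairwiseK2P <- function(copy, consensus, cpgAdjusted = FALSE) {
    s1 <- strsplit(toupper(as.character(copy)), "")[[1L]]
    s2 <- strsplit(toupper(as.character(consensus)), "")[[1L]]
    if (length(s1) != length(s2))
        stop("aligned sequences must have equal length")
    ok <- s1 %in% DNA_BASES4 & s2 %in% DNA_BASES4
    if (!any(ok))
        return(NA_real_)
    n <- sum(ok)
    diff <- ok & s1 != s2
    ts <- diff & .isTransition(s1, s2)
    tv <- diff & !ts
    if (cpgAdjusted) {
        ## CpG positions on the ungapped consensus: a consensus C
        ## immediately followed (ignoring alignment gaps) by a G.
        consBase <- s2 %in% DNA_BASES4
        idx <- which(consBase)
        cpgSite <- logical(length(s2))
        if (length(idx) >= 2L) {
            isC <- s2[idx[-length(idx)]] == "C"
            isG <- s2[idx[-1L]] == "G"
            hit <- which(isC & isG)
            cpgSite[idx[hit]] <- TRUE        # the C
            cpgSite[idx[hit + 1L]] <- TRUE   # the G
            ## weighted transition count: non-CpG transitions count 1,
            ## each CpG dinucleotide contributes min(ts, 1) * 1/10
            tsCpG <- numeric(0)
            if (length(hit)) {
                tsAtC <- ts[idx[hit]]
                tsAtG <- ts[idx[hit + 1L]]
                tsCpG <- pmin(tsAtC + tsAtG, 1) / 10
            }
            nTs <- sum(ts & !cpgSite) + sum(tsCpG)
        } else {
            nTs <- sum(ts)
        }
    } else {
        nTs <- sum(ts)
    }
    k2pDistance(nTs / n, sum(tv) / n)
}

#' Log-odds nucleotide substitution matrix from a K2P model
#'
#' Builds the analytic log-odds scoring matrix used for consensus
#' extension: substitution probabilities follow a K2P model at a given
#' divergence, target frequencies follow a given GC background, and
#' the matrix is scaled so that the frequency-weighted average match
#' score equals \code{matchScale}. At the default scale a column of
#' three agreeing instances scores about +30, so the extension stop
#' threshold of 27 corresponds to roughly three sequences in
#' agreement.
#'
#' @param divergence K2P distance parameterizing the model (default
#'   0.20).
#' @param gc Background G+C fraction (default 0.43).
#' @param tsTv Transition/transversion ratio (default 2).
#' @param matchScale Average match score after scaling (default 10).
#' @return A 4x4 numeric matrix over A, C, G, T.
#' @export
k2pLogOddsMatrix <- function(divergence = 0.20, gc = 0.43, tsTv = 2,
                             matchScale = 10) {
    rt <- k2pSolveRates(divergence, tsTv)
    p <- rt$p; q <- rt$q
    pi <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    P <- matrix(q / 2, 4, 4, dimnames = list(DNA_BASES4, DNA_BASES4))
    diag(P) <- 1 - p - q
    P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- p
    s <- log2(sweep(P, 2, pi, "/"))
    lambda <- matchScale / sum(pi * diag(s))
    s * lambda
}
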