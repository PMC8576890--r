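## Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs \code{expr} with the random number generator seeded at
#' \code{seed}, restoring the caller's RNG state afterwards so that
#' seeded package functions never perturb the global random stream.
#' A \code{NULL} seed evaluates the expression with the current stream.
#'
#' @param seed Integer scalar or \code{NULL}.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

## DNA alphabet used by all simulators.
DNA_BASES4 <- c("A", "C", "G", "T")

## Closed subclass vocabulary (DFAM-style taxonomy).
TE_SUBCLASSES <- c("LINE", "SINE", "LTR", "DIRS", "PLE", "TIR",
                   "CRY", "MAV", "RC", "Unknown")

## Assert a scalar of given type; used by constructors.
.checkScalar <- function(x, what, name) {
    if (length(x) != 1L || is.na(x))
        stop("'", name, "' must be a single non-NA ", what, call. = FALSE)
    invisible(x)
}

## Is a base pair (a, b) a transition (A<->G, C<->T)?
.isTransition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

## Split "subclass/superfamily" labels into a two-column matrix.
.splitClassLabel <- function(x) {
    sub <- sub("/.*$", "", x)
    sup <- ifelse(grepl("/", x), sub("^[^/]*/", "", x), NA_character_)
    sup[sup %in% c("", "NA")] <- NA_character_
    cbind(subclass = sub, superfamily = sup)
}

.pasteClassLabel <- function(subclass, superfamily) {
    ifelse(is.na(superfamily) | superfamily == "",
           subclass, paste0(subclass, "/", superfamily))
}
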