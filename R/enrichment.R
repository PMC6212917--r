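#' Construct a TermMap
#'
#' @param terms named list of character vectors (gene ids per term).
#' @param background character vector of background gene ids (the universe).
#' @param termNames optional named character vector of readable names;
#'   missing entries default to the term id.
#' @return A \code{\link{TermMap}}. Term genes outside the background are
#'   dropped with a warning.
#' @export
termMap <- function(terms, background, termNames = NULL) {
    background <- unique(background)
    cleaned <- lapply(terms, function(g) unique(intersect(g, background)))
    dropped <- sum(lengths(lapply(terms, unique))) - sum(lengths(cleaned))
    if (dropped > 0L)
        warning(dropped, " term-gene link(s) outside the background dropped")
    nm <- setNames(names(cleaned), names(cleaned))
    if (!is.null(termNames))
        nm[names(termNames)] <- termNames
    new("TermMap", terms = cleaned, termNames = nm, background = background)
}

setMethod("show", "TermMap", function(object) {
    cat("TermMap:", length(object@terms), "terms over",
        length(object@background), "background genes\n")
})

#' Read a TermMap from TSV files
#'
#' @param mapPath 2-column TSV (gene id, term id), no header.
#' @param background character vector of background gene ids.
#' @param namesPath optional 2-column TSV (term id, term name), no header.
#' @return A \code{\link{TermMap}}.
#' @export
readTermMap <- function(mapPath, background, namesPath = NULL) {
    d <- utils::read.table(mapPath, sep = "\t", header = FALSE,
                           col.names = c("gene", "term"),
                           colClasses = "character")
    nm <- NULL
    if (!is.null(namesPath)) {
        nd <- utils::read.table(namesPath, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
        nm <- setNames(nd[[2L]], nd[[1L]])
    }
    termMap(split(d$gene, d$term), background, termNames = nm)
}

#' Hypergeometric over-representation test over a TermMap
#'
#' For a study gene set of size n drawn from a background of size N, a term
#' of size K with k study hits has upper-tail p-value P(X >= k) under
#' Hypergeometric(N, K, n). Terms are filtered to \code{sizeRange} before
#' testing and to at least \code{minK} study hits after; Benjamini-Hochberg
#' adjustment runs across the surviving terms. Raw p-values are reported
#' alongside q-values (downstream significance calls at raw p < 0.05 should
#' be interpreted with the q column in view). Study genes outside the
#' background are dropped with a warning.
#'
#' @param study character vector of study gene ids.
#' @param map a \code{\link{TermMap}}.
#' @param minK minimum study-hit count per reported term (default 3).
#' @param sizeRange numeric length-2: allowed term sizes (default c(5, 500)).
#' @return \code{DataFrame} with columns \code{term}, \code{name}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{p}, \code{q}, \code{genes}, sorted
#'   by p then term id.
#' @export
enrich <- function(study, map, minK = 3L, sizeRange = c(5L, 500L)) {
    study <- unique(study)
    outside <- setdiff(study, map@background)
    if (length(outside)) {
        warning(length(outside), " study gene(s) outside the background ",
                "dropped")
        study <- setdiff(study, outside)
    }
    empty <- DataFrame(term = character(0), name = character(0),
                       k = integer(0), K = integer(0), n = integer(0),
                       N = integer(0), p = numeric(0), q = numeric(0),
                       genes = character(0))
    if (!length(study)) {
        warning("empty study set after background intersection")
        return(empty)
    }
    N <- length(map@background)
    n <- length(study)
    K <- lengths(map@terms)
    keep <- K >= sizeRange[1L] & K <= sizeRange[2L]
    terms <- map@terms[keep]
    if (!length(terms)) return(empty)
    hits <- lapply(terms, intersect, study)
    k <- lengths(hits)
    p <- stats::phyper(k - 1L, lengths(terms), N - lengths(terms), n,
                       lower.tail = FALSE)
    sel <- k >= minK
    if (!any(sel)) return(empty)
    out <- DataFrame(term = names(terms)[sel],
                     name = unname(map@termNames[names(terms)[sel]]),
                     k = unname(k[sel]), K = unname(lengths(terms)[sel]),
                     n = n, N = N, p = unname(p[sel]),
                     q = stats::p.adjust(unname(p[sel]), method = "BH"),
                     genes = vapply(hits[sel], function(g)
                         paste(sort(g), collapse = ","), ""))
    out[order(out$p, out$term), , drop = FALSE]
}
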