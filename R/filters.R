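#' CpG dinucleotide context on the reference strand
#'
#' TRUE when the reference base at \code{pos} is a C immediately followed by
#' G, or a G immediately preceded by C. Chromosome ends have no neighbour on
#' one side; the absent neighbour never matches.
#'
#' @param genome \code{DNAStringSet} reference.
#' @param chrom chromosome name.
#' @param pos 1-based position(s).
#' @return logical vector.
#' @export
cpgContext <- function(genome, chrom, pos) {
    seqv <- genome[[chrom]]
    len <- length(seqv)
    if (any(pos < 1L | pos > len))
        stop("position outside chromosome ", chrom)
    base <- as.character(Biostrings::extractAt(
        seqv, IRanges(pos, width = 1L)))
    nxt <- ifelse(pos < len, as.character(Biostrings::extractAt(
        seqv, IRanges(pmin(pos + 1L, len), width = 1L))), "")
    prv <- ifelse(pos > 1L, as.character(Biostrings::extractAt(
        seqv, IRanges(pmax(pos - 1L, 1L), width = 1L))), "")
    (base == "C" & nxt == "G") | (base == "G" & prv == "C")
}

#' Apply conservative site filters to a merged GenotypeMatrix
#'
#' Filters run in a fixed order -- missing genotypes, triallelic sites,
#' duplication mask, CpG context, proximity to another variant -- and each
#' removed site is attributed to the first filter that rejects it, so the
#' attrition report always reconciles: input = output + sum(removed). Each
#' filter operates on the survivors of the previous one; in particular the
#' proximity filter measures distances within the surviving site set and
#' removes both members of a close pair, which makes the whole procedure
#' idempotent.
#'
#' @param m a \code{GenotypeMatrix}.
#' @param genome \code{DNAStringSet} covering all matrix chromosomes
#'   (required only when the CpG filter is on).
#' @param param a \code{\link{FilterParam}}.
#' @return list with elements \code{matrix} (filtered \code{GenotypeMatrix})
#'   and \code{report} (\code{DataFrame} of per-filter removed counts plus
#'   input/output totals).
#' @export
applyFilters <- function(m, genome = NULL, param = FilterParam()) {
    gr <- variantRanges(m)
    if (!is.null(genome)) {
        chroms <- unique(as.character(seqnames(gr)))
        miss <- setdiff(chroms, names(genome))
        if (length(miss))
            stop("genome lacks chromosome(s): ", paste(miss, collapse = ", "))
        for (ch in chroms) {
            p <- start(gr)[as.character(seqnames(gr)) == ch]
            if (length(p) && max(p) > length(genome[[ch]]))
                stop("variant position beyond end of ", ch)
        }
    }
    nIn <- nVariants(m)
    removed <- c(missing = 0L, triallelic = 0L, mask = 0L, cpg = 0L,
                 proximity = 0L)
    keep <- rep(TRUE, nIn)

    dropBy <- function(filter, bad) {
        bad <- bad & keep
        removed[[filter]] <<- sum(bad)
        keep <<- keep & !bad
    }
    if (param@dropMissing)
        dropBy("missing", rowSums(is.na(gtCodes(m))) > 0L)
    if (param@dropTriallelic)
        dropBy("triallelic", mcols(gr)$triallelic)
    if (length(param@mask))
        dropBy("mask", countOverlaps(gr, param@mask) > 0L)
    if (param@dropCpG) {
        if (is.null(genome))
            stop("CpG filter requires the reference genome")
        cpg <- logical(nIn)
        chromv <- as.character(seqnames(gr))
        for (ch in unique(chromv[keep])) {
            idx <- which(keep & chromv == ch)
            cpg[idx] <- cpgContext(genome, ch, start(gr)[idx])
        }
        dropBy("cpg", cpg)
    }
    if (param@proximityBp > 0L) {
        close <- logical(nIn)
        chromv <- as.character(seqnames(gr))
        for (ch in unique(chromv[keep])) {
            idx <- which(keep & chromv == ch)
            if (length(idx) < 2L) next
            p <- start(gr)[idx]  # sorted within chromosome
            d <- diff(p)
            hit <- d <= param@proximityBp
            close[idx[c(hit, FALSE)]] <- TRUE
            close[idx[c(FALSE, hit)]] <- TRUE
        }
        dropBy("proximity", close)
    }
    report <- DataFrame(filter = names(removed),
                        removed = unname(removed))
    metadata(report) <- list(input = nIn, output = sum(keep))
    list(matrix = m[keep], report = report)
}
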