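pct2 <- function(num, den) {
    if (den == 0) return(NA_real_)
    round(100 * num / den, 2)
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Transition/transversion ratio
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine changes
#' (A<->G, C<->T); all other single-base changes are transversions. With
#' zero transversions the ratio is undefined and \code{NA} is returned; an
#' empty input also yields \code{NA}.
#'
#' @param ref,alt character vectors of single bases.
#' @return numeric ratio.
#' @export
titvRatio <- function(ref, alt) {
    if (!length(ref)) return(NA_real_)
    ti <- sum(paste0(ref, ">", alt) %in% TRANSITIONS)
    tv <- length(ref) - ti
    if (tv == 0L) return(NA_real_)
    ti / tv
}

#' Per-sample diversity summary
#'
#' Counts over the variants the sample carries: total SNVs, homozygous and
#' heterozygous splits, heterozygosity percent, SNV density per kb, Ti/Tv,
#' and (when a specific-variant index is supplied) specific-SNV counts and
#' percentages. Percentages are reported to 2 decimals. A sample carrying no
#' variants yields zero counts with \code{NA} ratio fields rather than a
#' division error.
#'
#' @param m a \code{GenotypeMatrix}.
#' @param sample sample name in the roster.
#' @param specific optional integer index (into \code{m}) of this sample's
#'   specific variants, e.g. from \code{\link{specificSnvs}}.
#' @param denomBp denominator for the per-kb density; defaults to the sum of
#'   the reference chromosome lengths.
#' @return one-row \code{DataFrame} with columns \code{sample}, \code{nSnvs},
#'   \code{nHom}, \code{nHet}, \code{pctHet}, \code{snvPerKb}, \code{tiTv},
#'   \code{nSpecific}, \code{pctSpecific}, \code{nSpecificHet}.
#' @export
sampleSummary <- function(m, sample, specific = NULL, denomBp = NULL) {
    if (!sample %in% sampleIds(m))
        stop("unknown sample: ", sample)
    if (is.null(denomBp))
        denomBp <- sum(as.numeric(seqlengths(variantRanges(m))))
    stopifnot(denomBp > 0)
    gt <- gtCodes(m)[, sample]
    carrier <- !is.na(gt) & gt >= GT_HET
    nSnvs <- sum(carrier)
    nHet <- sum(gt[carrier] == GT_HET)
    nHom <- nSnvs - nHet
    gr <- variantRanges(m)
    tt <- titvRatio(mcols(gr)$ref[carrier], mcols(gr)$alt[carrier])
    nSpec <- nSpecHet <- NA_integer_
    pctSpec <- NA_real_
    if (!is.null(specific)) {
        nSpec <- length(specific)
        nSpecHet <- sum(gt[specific] == GT_HET, na.rm = TRUE)
        pctSpec <- pct2(nSpec, nSnvs)
    }
    DataFrame(sample = sample, nSnvs = nSnvs, nHom = nHom, nHet = nHet,
              pctHet = pct2(nHet, nSnvs),
              snvPerKb = if (nSnvs) round(nSnvs / (denomBp / 1000), 2)
                         else 0,
              tiTv = if (is.na(tt)) NA_real_ else round(tt, 2),
              nSpecific = nSpec, pctSpecific = pctSpec,
              nSpecificHet = nSpecHet)
}

#' Summaries for every sample of a matrix
#'
#' @param m a \code{GenotypeMatrix}.
#' @param specificList optional named list of specific-variant indices per
#'   sample.
#' @param denomBp see \code{\link{sampleSummary}}.
#' @return \code{DataFrame}, one row per sample.
#' @export
sampleSummaries <- function(m, specificList = NULL, denomBp = NULL) {
    rows <- lapply(sampleIds(m), function(s)
        sampleSummary(m, s, specific = specificList[[s]], denomBp = denomBp))
    do.call(rbind, rows)
}

#' Diversity percentages from count totals
#'
#' Recomputes the derived percentage columns of a per-sample diversity table
#' from its count columns: heterozygosity percent, homozygosity percent and
#' (when given) specific-SNV percent, each to 2 decimals. Useful for
#' checking or reconstituting published summary tables from their printed
#' counts.
#'
#' @param nSnvs,nHet total and heterozygous SNV counts (vectorized).
#' @param nSpecific optional specific-SNV counts.
#' @return \code{DataFrame} with \code{pctHet}, \code{pctHom} and (if
#'   requested) \code{pctSpecific}.
#' @export
diversityPercentages <- function(nSnvs, nHet, nSpecific = NULL) {
    out <- DataFrame(
        pctHet = mapply(pct2, nHet, nSnvs),
        pctHom = mapply(pct2, nSnvs - nHet, nSnvs))
    if (!is.null(nSpecific))
        out$pctSpecific <- mapply(pct2, nSpecific, nSnvs)
    out
}

#' Shared-SNV fraction of a conspecific pair
#'
#' The number of SNVs shared by two individuals as a percentage of their mean
#' total SNV count, the scale on which within-species sharing is usually
#' quoted.
#'
#' @param nShared shared-SNV count.
#' @param totalA,totalB per-individual total SNV counts.
#' @return percent, 2 decimals.
#' @export
sharedFraction <- function(nShared, totalA, totalB) {
    pct2(nShared, mean(c(totalA, totalB)))
}

#' Mutation, codon and amino-acid spectra
#'
#' Tabulates the 12 ordered single-base substitution classes over a variant
#' set and, when codon-level annotation records are supplied, the
#' codon-change and amino-acid-change spectra of the exonic variants.
#' Amino-acid changes are reported both ordered (\code{P>L}) and unordered
#' (\code{A<->T}). All tables are ranked by decreasing count with
#' lexicographic tie-breaking for determinism.
#'
#' @param ref,alt single-base character vectors (the scoped variant set).
#' @param annotation optional \code{DataFrame} of annotation records (from
#'   \code{\link{annotateVariants}}) whose exonic rows carry \code{refCodon},
#'   \code{altCodon}, \code{refAA}, \code{altAA}.
#' @return list of \code{DataFrame}s: \code{substitution}, and (if annotation
#'   given) \code{codon}, \code{aaOrdered}, \code{aaUnordered}.
#' @export
mutationSpectra <- function(ref, alt, annotation = NULL) {
    key2 <- function(a, sep, b)   # zero-length safe paste
        if (length(a)) paste0(a, sep, b) else character(0)
    rank1 <- function(keys) {
        if (!length(keys))
            return(DataFrame(change = character(0), count = integer(0)))
        tab <- table(keys)
        out <- DataFrame(change = names(tab), count = as.integer(tab))
        out[order(-out$count, out$change), , drop = FALSE]
    }
    res <- list(substitution = rank1(key2(ref, ">", alt)))
    if (!is.null(annotation)) {
        ex <- annotation[!is.na(annotation$refCodon) &
                         annotation$refCodon != "", , drop = FALSE]
        res$codon <- rank1(key2(ex$refCodon, ">", ex$altCodon))
        res$aaOrdered <- rank1(key2(ex$refAA, ">", ex$altAA))
        res$aaUnordered <- rank1(ifelse(
            ex$refAA <= ex$altAA,
            key2(ex$refAA, "<->", ex$altAA),
            key2(ex$altAA, "<->", ex$refAA)))
    }
    res
}
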