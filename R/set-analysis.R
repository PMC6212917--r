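#' Exact carrier-subset sharing counts (UpSet "distinct" mode)
#'
#' Counts each variant under the exact subset of samples that carry its
#' alternate allele, the tabular equivalent of an UpSet intersection plot.
#' Subset labels join carrier sample names in roster order with \code{"+"}.
#' Counts always sum to the number of variants.
#'
#' @param m a \code{GenotypeMatrix}.
#' @return \code{DataFrame} with columns \code{subset}, \code{nSamples},
#'   \code{count}, sorted by decreasing count then subset label.
#' @export
sharingCounts <- function(m) {
    cm <- carrierMatrix(m)
    roster <- sampleIds(m)
    labels <- apply(cm, 1L, function(r) paste(roster[r], collapse = "+"))
    tab <- table(labels)
    out <- DataFrame(subset = names(tab),
                     nSamples = lengths(strsplit(names(tab), "+",
                                                 fixed = TRUE)),
                     count = as.integer(tab))
    out[order(-out$count, out$subset), , drop = FALSE]
}

#' Species/population-specific SNVs with outgroup exclusion
#'
#' A variant is specific to \code{unit} when its carrier set equals
#' \code{unit} exactly: every unit member carries it and no other roster
#' sample does. For a single sample this yields population-specific SNVs; for
#' a conspecific pair, species-specific SNVs (both individuals must carry).
#' Sites also carried by the outgroup are then excluded -- such alleles
#' predate the split from the outgroup and are not lineage-specific. With
#' \code{outgroupMode = "any"} (default) any outgroup-carried site is
#' excluded; with \code{"sharedAll"} only sites carried by the outgroup
#' \emph{and} every roster sample are excluded (which can only matter when
#' \code{unit} is the whole roster).
#'
#' @param m a \code{GenotypeMatrix}.
#' @param unit character vector of sample names (subset of the roster).
#' @param outgroupSites \code{GRanges} (or \code{NULL}) of sites carried by
#'   the outgroup.
#' @param outgroupMode \code{"any"} or \code{"sharedAll"}.
#' @return integer vector of variant indices into \code{m}.
#' @export
specificSnvs <- function(m, unit, outgroupSites = NULL,
                         outgroupMode = c("any", "sharedAll")) {
    outgroupMode <- match.arg(outgroupMode)
    roster <- sampleIds(m)
    if (!all(unit %in% roster))
        stop("unit sample(s) not in roster: ",
             paste(setdiff(unit, roster), collapse = ", "))
    cm <- carrierMatrix(m)
    inUnit <- roster %in% unit
    hit <- rowSums(cm[, inUnit, drop = FALSE]) == sum(inUnit) &
        rowSums(cm[, !inUnit, drop = FALSE]) == 0L
    idx <- which(hit)
    if (!is.null(outgroupSites) && length(outgroupSites) && length(idx)) {
        inOut <- countOverlaps(variantRanges(m)[idx], outgroupSites) > 0L
        if (outgroupMode == "sharedAll") {
            allCarry <- rowSums(cm[idx, , drop = FALSE]) == length(roster)
            inOut <- inOut & allCarry
        }
        idx <- idx[!inOut]
    }
    idx
}

#' Shared SNVs of two conspecific individuals as one pseudo-sample
#'
#' Restricts the matrix to sites where both individuals carry the alternate
#' allele and appends a merged pseudo-sample column whose genotype is
#' homozygous alternate when both individuals are, heterozygous otherwise.
#' This lets two individuals of one species be summarized as a single sample
#' over their shared variation.
#'
#' @param m a \code{GenotypeMatrix}.
#' @param a,b distinct sample names.
#' @param name name for the merged pseudo-sample column.
#' @return A \code{GenotypeMatrix} of the shared sites with an extra column.
#' @export
sharedWithinSpecies <- function(m, a, b, name = paste0(a, "_", b, "_shared")) {
    if (a == b) stop("a and b must be distinct samples")
    cm <- carrierMatrix(m)
    shared <- cm[, a] & cm[, b]
    gt <- gtCodes(m)[shared, , drop = FALSE]
    merged <- ifelse(gt[, a] == GT_HOM_ALT & gt[, b] == GT_HOM_ALT,
                     GT_HOM_ALT, GT_HET)
    gt <- cbind(gt, matrix(as.integer(merged), ncol = 1L,
                           dimnames = list(NULL, name)))
    GenotypeMatrix(variantRanges(m)[shared], gt)
}
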