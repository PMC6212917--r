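#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @importFrom Biostrings DNAStringSet DNAString subseq reverseComplement
#'   GENETIC_CODE translate readDNAStringSet writeXStringSet extractAt
NULL

GT_HOM_REF <- 0L
GT_HET <- 1L
GT_HOM_ALT <- 2L

#' GenotypeMatrix: merged multi-sample SNV genotypes
#'
#' The pipeline's central container: a set of biallelic single-nucleotide
#' variant sites against one shared reference, with one genotype call per
#' sample at every site. Genotypes are stored as integer codes (0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, \code{NA} = missing);
#' genotypes are treated as unphased, so \code{0/1} and \code{1/0} collapse to
#' the same heterozygous state. Sites are sorted by (chromosome, position),
#' duplicates are not allowed, and per-chromosome reference lengths are carried
#' in the \code{Seqinfo} of the row ranges.
#'
#' Sites where the alternate allele conflicted across input samples (or that
#' were multi-allelic in an input) are retained with \code{triallelic = TRUE}
#' in the row metadata, so the filtering stage can remove and count them rather
#' than having them vanish silently at merge time.
#'
#' @slot rowRanges \code{GRanges} of width-1 sites with metadata columns
#'   \code{ref}, \code{alt} (single upper-case bases) and \code{triallelic}.
#' @slot genotypes integer matrix, sites x samples.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
    representation(rowRanges = "GRanges", genotypes = "matrix"))

setValidity("GenotypeMatrix", function(object) {
    gr <- object@rowRanges
    gt <- object@genotypes
    msg <- character(0)
    if (length(gr) != nrow(gt))
        msg <- c(msg, "number of sites must equal nrow(genotypes)")
    if (is.null(colnames(gt)) || anyDuplicated(colnames(gt)))
        msg <- c(msg, "genotype columns must carry unique sample names")
    need <- c("ref", "alt", "triallelic")
    if (!all(need %in% colnames(mcols(gr))))
        msg <- c(msg, "rowRanges must have mcols ref, alt, triallelic")
    if (length(gr)) {
        if (!all(width(gr) == 1L))
            msg <- c(msg, "all sites must have width 1")
        ref <- mcols(gr)$ref
        alt <- mcols(gr)$alt
        if (!all(ref %in% c("A", "C", "G", "T")) ||
            !all(alt %in% c("A", "C", "G", "T")))
            msg <- c(msg, "ref and alt must be single bases A/C/G/T")
        if (any(ref == alt))
            msg <- c(msg, "ref must differ from alt at every site")
        key <- paste(as.character(seqnames(gr)), start(gr))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (chrom, pos) sites are not allowed")
        sl <- seqlengths(gr)
        if (any(is.na(sl)))
            msg <- c(msg, "reference chromosome lengths must be set")
        else if (any(start(gr) > sl[as.character(seqnames(gr))]))
            msg <- c(msg, "site position beyond chromosome length")
        o <- order(as.integer(seqnames(gr)), start(gr))
        if (!identical(o, seq_along(gr)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
        bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
        if (any(bad))
            msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param rowRanges width-1 \code{GRanges} with mcols \code{ref}, \code{alt}
#'   and (optionally) \code{triallelic}; must carry seqlengths.
#' @param genotypes integer matrix (sites x samples) of codes 0/1/2/NA with
#'   sample names as column names.
#' @return A \code{GenotypeMatrix}, sorted by (chrom, pos).
#' @export
GenotypeMatrix <- function(rowRanges, genotypes) {
    if (is.null(mcols(rowRanges)$triallelic))
        mcols(rowRanges)$triallelic <- rep(FALSE, length(rowRanges))
    storage.mode(genotypes) <- "integer"
    o <- order(as.integer(seqnames(rowRanges)), start(rowRanges))
    new("GenotypeMatrix", rowRanges = rowRanges[o],
        genotypes = genotypes[o, , drop = FALSE])
}

#' GeneModelSet: transcript models for effect annotation
#'
#' Transcript structures parsed from GFF3: per-transcript exon and CDS
#' intervals (as \code{GRangesList} keyed by transcript id) plus a transcript
#' table linking transcripts to genes, strands and completeness. A transcript
#' is \emph{complete} when its total CDS length is divisible by 3; incomplete
#' transcripts are retained but flagged, and exonic variants falling in them
#' annotate with effect \code{"unknown"}.
#'
#' @slot txinfo \code{DataFrame} with columns \code{transcript_id},
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{coding},
#'   \code{complete}.
#' @slot exons \code{GRangesList} of exons per transcript (sorted,
#'   non-overlapping).
#' @slot cds \code{GRangesList} of CDS intervals per transcript (possibly
#'   empty for non-coding transcripts).
#'
#' @aliases GeneModelSet-class
#' @exportClass GeneModelSet
setClass("GeneModelSet",
    representation(txinfo = "DataFrame", exons = "GRangesList",
                   cds = "GRangesList"))

setValidity("GeneModelSet", function(object) {
    msg <- character(0)
    ids <- object@txinfo$transcript_id
    if (anyDuplicated(ids))
        msg <- c(msg, "duplicate transcript ids")
    if (!identical(names(object@exons), ids) ||
        !identical(names(object@cds), ids))
        msg <- c(msg, "exons/cds must be keyed by transcript_id in order")
    for (i in seq_along(ids)) {
        ex <- object@exons[[i]]
        cd <- object@cds[[i]]
        if (length(ex) > 1L) {
            if (is.unsorted(start(ex)))
                msg <- c(msg, paste0(ids[i], ": exons not sorted"))
            if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
                msg <- c(msg, paste0(ids[i], ": exons overlap"))
        }
        if (length(cd) && length(ex) &&
            !all(countOverlaps(cd, ex, type = "within") > 0L))
            msg <- c(msg, paste0(ids[i], ": CDS interval outside exons"))
    }
    if (length(msg)) msg else TRUE
})

#' Site filter configuration
#'
#' Switches and knobs for the conservative site filters applied to a merged
#' \code{GenotypeMatrix}: removal of sites with any missing genotype, of
#' triallelic/allele-conflict sites, of sites inside a duplication mask, of
#' sites in CpG dinucleotide context on the reference strand, and of sites
#' within \code{proximityBp} of another variant. The proximity default of 5 bp
#' is a conventional conservative choice; the reference studies name the
#' filter without fixing a distance, so it is configuration, not a constant.
#'
#' @slot dropMissing logical.
#' @slot dropTriallelic logical.
#' @slot dropCpG logical.
#' @slot proximityBp integer distance in bp (0 disables).
#' @slot mask \code{GRanges} of masked regions (may be empty).
#'
#' @aliases FilterParam-class
#' @exportClass FilterParam
setClass("FilterParam",
    representation(dropMissing = "logical", dropTriallelic = "logical",
                   dropCpG = "logical", proximityBp = "integer",
                   mask = "GRanges"))

setValidity("FilterParam", function(object) {
    if (object@proximityBp < 0L) "proximityBp must be >= 0" else TRUE
})

#' @param dropMissing,dropTriallelic,dropCpG logical switches.
#' @param proximityBp integer, minimum allowed distance in bp to the nearest
#'   other variant; sites closer than or at this distance are removed in
#'   symmetric pairs. 0 disables the filter.
#' @param mask \code{GRanges} of regions (e.g. known duplications) whose
#'   variants are removed; empty disables.
#' @rdname FilterParam-class
#' @export
FilterParam <- function(dropMissing = TRUE, dropTriallelic = TRUE,
                        dropCpG = TRUE, proximityBp = 5L,
                        mask = GRanges()) {
    new("FilterParam", dropMissing = dropMissing,
        dropTriallelic = dropTriallelic, dropCpG = dropCpG,
        proximityBp = as.integer(proximityBp), mask = mask)
}

#' WindowMatrix: per-chromosome windowed variant counts
#'
#' Counts of variants per sample in fixed non-overlapping windows along one
#' chromosome. Window \code{k} (1-based) covers reference positions
#' \code{(k-1)*W + 1 .. k*W}; a terminal window shorter than \code{W} is
#' retained in the counts but flagged incomplete, and influence fitting
#' excludes it (unequal exposure would mimic influence).
#'
#' @slot chrom chromosome name.
#' @slot windowSize window width in bp.
#' @slot counts integer matrix, windows x samples.
#' @slot windowStart 1-based start positions of the windows.
#' @slot windowEnd 1-based inclusive end positions (clipped at chrom end).
#' @slot complete logical per window; FALSE only for a partial last window.
#'
#' @aliases WindowMatrix-class
#' @exportClass WindowMatrix
setClass("WindowMatrix",
    representation(chrom = "character", windowSize = "integer",
                   counts = "matrix", windowStart = "integer",
                   windowEnd = "integer", complete = "logical"))

setValidity("WindowMatrix", function(object) {
    msg <- character(0)
    n <- nrow(object@counts)
    if (length(object@windowStart) != n || length(object@windowEnd) != n ||
        length(object@complete) != n)
        msg <- c(msg, "window vectors must match nrow(counts)")
    if (any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' OutlierResult: Cook's-distance window influence scan
#'
#' Result of the per-chromosome influence scan. For each chromosome and each
#' sample j, the sample's complete-window counts are regressed (ordinary least
#' squares with intercept) on the leave-one-out mean of the other samples'
#' counts, and each window's Cook's distance is computed from that fit. A
#' window is flagged when its distance exceeds \code{multiplier} times that
#' fit's mean distance in any sample's fit.
#'
#' @slot chroms chromosome names scanned.
#' @slot distances named list (per chromosome) of windows x samples Cook's
#'   distance matrices (complete windows only).
#' @slot thresholds named list of per-sample thresholds
#'   (\code{multiplier * mean(D)} of each fit).
#' @slot flagged named list of logical matrices (windows x samples).
#' @slot windowStart,windowEnd named lists of the complete windows' 1-based
#'   coordinates.
#' @slot multiplier the threshold multiplier used.
#' @slot windowSize window width in bp.
#'
#' @aliases OutlierResult-class
#' @exportClass OutlierResult
setClass("OutlierResult",
    representation(chroms = "character", distances = "list",
                   thresholds = "list", flagged = "list",
                   windowStart = "list", windowEnd = "list",
                   multiplier = "numeric", windowSize = "integer"))

#' TermMap: gene-set definitions for enrichment
#'
#' A collection of functional terms (pathways, ontology categories, disease
#' classes, ...) each mapping to a set of gene ids, plus the background gene
#' universe the hypergeometric test is computed against. Term genes outside
#' the background are dropped with a warning at construction time so the
#' subset invariant always holds.
#'
#' @slot terms named list of character vectors (gene ids per term).
#' @slot termNames named character vector of human-readable term names.
#' @slot background character vector, the gene universe.
#'
#' @aliases TermMap-class
#' @exportClass TermMap
setClass("TermMap",
    representation(terms = "list", termNames = "character",
                   background = "character"))

setValidity("TermMap", function(object) {
    msg <- character(0)
    if (anyDuplicated(object@background))
        msg <- c(msg, "background contains duplicate gene ids")
    ok <- vapply(object@terms, function(g) all(g %in% object@background),
                 logical(1))
    if (!all(ok))
        msg <- c(msg, "every term's genes must be a subset of the background")
    if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic dataset generator
#'
#' Describes a toy multi-sample dataset: a rooted tree given as a branch table
#' (each branch = the set of leaf samples below it plus an expected mutation
#' count), genome dimensions, transition/transversion bias kappa, the
#' per-carrier probability that a branch mutation is carried heterozygously,
#' gene-model geometry, optional per-sample hotspot regions, and the seed.
#' Mutations follow an infinite-sites model (no two mutations share a
#' position), so every observed carrier set is exactly a clade of the tree.
#'
#' @slot branches \code{data.frame} with columns \code{branch} (name),
#'   \code{leaves} (comma-separated sample names below the branch) and
#'   \code{mu} (expected mutation count; realized counts are Poisson).
#' @slot roster ordered ingroup sample names.
#' @slot outgroup outgroup leaf name (its carried sites are emitted as the
#'   outgroup site set, not as a roster VCF).
#' @slot nChroms,chromLength genome dimensions.
#' @slot kappa transition/transversion rate bias; a mutation is a transition
#'   with probability kappa/(kappa + 1).
#' @slot hetProb per-carrier probability of a heterozygous genotype.
#' @slot geneCount,meanCdsLen gene-model geometry (CDS length is rounded to a
#'   codon multiple).
#' @slot hotspots \code{data.frame} (possibly 0-row) with columns
#'   \code{sample}, \code{chrom}, \code{startWindow}, \code{endWindow},
#'   \code{fold}, \code{windowSize}: extra private mutations inflating that
#'   sample's count in those windows by the given fold.
#' @slot maskCount number of random duplication-mask intervals per chromosome.
#' @slot seed integer RNG seed.
#'
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
    representation(branches = "data.frame", roster = "character",
                   outgroup = "character", nChroms = "integer",
                   chromLength = "integer", kappa = "numeric",
                   hetProb = "numeric", geneCount = "integer",
                   meanCdsLen = "integer", hotspots = "data.frame",
                   maskCount = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    if (any(object@branches$mu < 0)) msg <- c(msg, "branch mu must be >= 0")
    if (object@hetProb < 0 || object@hetProb > 1)
        msg <- c(msg, "hetProb must be in [0, 1]")
    if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
    if (nrow(object@hotspots) && any(object@hotspots$fold < 1))
        msg <- c(msg, "hotspot fold must be >= 1")
    leaves <- unique(unlist(strsplit(object@branches$leaves, ",", fixed = TRUE)))
    if (!all(leaves %in% c(object@roster, object@outgroup)))
        msg <- c(msg, "branch leaves must be roster samples or the outgroup")
    if (length(msg)) msg else TRUE
})
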