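#' @rdname GenotypeMatrix-class
#' @export
setMethod("gtCodes", "GenotypeMatrix", function(x) x@genotypes)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("variantRanges", "GenotypeMatrix", function(x) x@rowRanges)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x@genotypes))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) length(x@rowRanges))

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix with", nVariants(object), "sites x",
        length(sampleIds(object)), "samples\n")
    cat("samples:", paste(sampleIds(object), collapse = ", "), "\n")
    ntri <- sum(mcols(object@rowRanges)$triallelic)
    if (ntri) cat("triallelic-flagged sites:", ntri, "\n")
    cat("chromosomes:",
        paste(seqlevels(object@rowRanges), collapse = ", "), "\n")
})

#' Subset a GenotypeMatrix by site index
#'
#' @param x a \code{GenotypeMatrix}.
#' @param i integer or logical site index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
    initialize(x, rowRanges = x@rowRanges[i],
               genotypes = x@genotypes[i, , drop = FALSE])
})

#' Carrier matrix of a GenotypeMatrix
#'
#' A sample is a \emph{carrier} at a site when its genotype contains the
#' alternate allele, i.e. is heterozygous or homozygous alternate. Missing
#' genotypes are non-carriers.
#'
#' @param m a \code{GenotypeMatrix}.
#' @return logical matrix (sites x samples).
#' @export
carrierMatrix <- function(m) {
    gt <- gtCodes(m)
    cm <- !is.na(gt) & gt >= GT_HET
    dimnames(cm) <- dimnames(gt)
    cm
}

siteKeys <- function(gr) paste0(as.character(seqnames(gr)), ":", start(gr))

#' Merge per-sample variant calls into a GenotypeMatrix
#'
#' Takes the union of all sites across samples and assembles one genotype per
#' sample per site. A sample with no record at a site is scored homozygous
#' reference if the site falls inside that sample's callable regions
#' (everything is callable when \code{callable} is \code{NULL}), otherwise
#' missing. Sites whose ref or alt allele differs between input samples, and
#' sites flagged multi-allelic in any input, are kept but flagged triallelic
#' for the filtering stage. Merging is insensitive to the order of the input
#' list; output column order follows \code{roster}.
#'
#' @param perSample named list (one element per roster sample) of variant
#'   \code{GRanges} as returned by \code{\link{readSampleVcf}}: width-1 ranges
#'   with mcols \code{ref}, \code{alt}, \code{gtCode}, \code{multiallelic}.
#' @param roster ordered character vector of sample names; must match
#'   \code{names(perSample)} as a set.
#' @param seqlen named numeric/integer vector of reference chromosome lengths.
#' @param callable optional named list of per-sample callable-region
#'   \code{GRanges}; samples absent from the list are callable everywhere.
#' @return A \code{GenotypeMatrix}.
#' @export
mergeSamples <- function(perSample, roster, seqlen, callable = NULL) {
    if (!setequal(names(perSample), roster))
        stop("names(perSample) must match the roster")
    perSample <- perSample[roster]
    badchrom <- lapply(perSample, function(gr)
        setdiff(unique(as.character(seqnames(gr))), names(seqlen)))
    off <- vapply(badchrom, length, integer(1)) > 0L
    if (any(off))
        stop("chromosome names absent from the reference in sample(s): ",
             paste0(names(perSample)[off], " (",
                    vapply(badchrom[off], paste, "", collapse = ","), ")",
                    collapse = "; "))

    keyed <- lapply(perSample, function(gr)
        data.frame(key = siteKeys(gr),
                   chrom = as.character(seqnames(gr)), pos = start(gr),
                   ref = mcols(gr)$ref, alt = mcols(gr)$alt,
                   gt = mcols(gr)$gtCode,
                   multi = mcols(gr)$multiallelic,
                   stringsAsFactors = FALSE))
    allkeys <- unique(unlist(lapply(keyed, `[[`, "key"), use.names = FALSE))
    n <- length(allkeys)
    first <- do.call(rbind, keyed)
    first <- first[!duplicated(first$key), , drop = FALSE]
    first <- first[match(allkeys, first$key), , drop = FALSE]

    gt <- matrix(NA_integer_, n, length(roster),
                 dimnames = list(NULL, roster))
    tri <- logical(n)
    ref <- first$ref
    alt <- first$alt
    for (s in roster) {
        d <- keyed[[s]]
        idx <- match(d$key, allkeys)
        gt[idx, s] <- d$gt
        tri[idx] <- tri[idx] | d$multi | d$ref != ref[idx] | d$alt != alt[idx]
    }
    gr <- GRanges(first$chrom, IRanges(first$pos, width = 1L),
                  seqinfo = Seqinfo(names(seqlen), as.integer(seqlen)))
    mcols(gr)$ref <- ref
    mcols(gr)$alt <- alt
    mcols(gr)$triallelic <- tri
    if (any(start(gr) > seqlengths(gr)[as.character(seqnames(gr))]))
        stop("variant position beyond chromosome length")

    # non-carriage: hom_ref where callable, missing otherwise
    for (s in roster) {
        absent <- is.na(gt[, s])
        if (!any(absent)) next
        if (is.null(callable) || is.null(callable[[s]])) {
            gt[absent, s] <- GT_HOM_REF
        } else {
            hit <- countOverlaps(gr[absent], callable[[s]]) > 0L
            gt[absent, s][hit] <- GT_HOM_REF
        }
    }
    GenotypeMatrix(gr, gt)
}

#' Write a merged GenotypeMatrix as a multi-sample VCF
#'
#' Emits a minimal well-formed VCFv4.2 file (GT-only FORMAT, contig header
#' lines from the matrix's reference lengths). Genotypes are written unphased
#' (\code{0/0}, \code{0/1}, \code{1/1}, \code{./.}); triallelic-flagged sites
#' carry \code{TRI=1} in INFO so a round trip preserves the flag.
#'
#' @param m a \code{GenotypeMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMergedVcf <- function(m, path) {
    gr <- variantRanges(m)
    gt <- gtCodes(m)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##fileformat=VCFv4.2", con)
    sl <- seqlengths(gr)
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(sl), sl), con)
    writeLines(paste0("##INFO=<ID=TRI,Number=0,Type=Flag,",
                      "Description=\"Triallelic or allele-conflict site\">"),
               con)
    writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"), con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds(m)), collapse = "\t"), con)
    if (nVariants(m)) {
        gtstr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
        gtstr[is.na(gt)] <- "./."
        rows <- paste(as.character(seqnames(gr)), start(gr), ".",
                      mcols(gr)$ref, mcols(gr)$alt, ".", "PASS",
                      ifelse(mcols(gr)$triallelic, "TRI", "."), "GT",
                      apply(gtstr, 1L, paste, collapse = "\t"), sep = "\t")
        writeLines(rows, con)
    }
    invisible(path)
}

#' Read a merged multi-sample VCF back into a GenotypeMatrix
#'
#' Inverse of \code{\link{writeMergedVcf}}; reference lengths are taken from
#' the VCF contig header lines.
#'
#' @param path VCF file path.
#' @return A \code{GenotypeMatrix}.
#' @export
readMergedVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    gr <- SummarizedExperiment::rowRanges(vcf)
    names(gr) <- NULL
    ref <- as.character(VariantAnnotation::ref(vcf))
    altl <- VariantAnnotation::alt(vcf)
    alt <- vapply(as.list(altl), function(a) as.character(a)[1L], "")
    gtraw <- VariantAnnotation::geno(vcf)$GT
    gt <- matrix(mapGtString(gtraw), nrow = nrow(gtraw),
                 dimnames = list(NULL, colnames(gtraw)))
    tri <- VariantAnnotation::info(vcf)$TRI
    if (is.null(tri)) tri <- rep(FALSE, length(gr))
    out <- GRanges(seqnames(gr), IRanges(start(gr), width = 1L),
                   seqinfo = seqinfo(vcf))
    mcols(out)$ref <- ref
    mcols(out)$alt <- alt
    mcols(out)$triallelic <- tri
    GenotypeMatrix(out, gt)
}
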