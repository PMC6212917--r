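mapGtString <- function(g) {
    # unphased semantics: 0/1 and 1/0 are the same het state
    out <- rep(NA_integer_, length(g))
    g <- gsub("|", "/", g, fixed = TRUE)
    out[g == "0/0"] <- GT_HOM_REF
    out[g %in% c("0/1", "1/0")] <- GT_HET
    out[g == "1/1"] <- GT_HOM_ALT
    # any allele >= 2 (multi-allelic genotype) counted as carrying an alt
    extra <- grepl("^[0-9]+/[0-9]+$", g) & is.na(out)
    out[extra] <- GT_HET
    out[extra & vapply(strsplit(g[extra], "/", fixed = TRUE),
                       function(a) a[1L] == a[2L], logical(1))] <- GT_HOM_ALT
    out
}

#' Read one sample's SNV calls from a VCF
#'
#' Parses a VCF (via \pkg{VariantAnnotation}) and returns the named sample's
#' single-nucleotide records as a width-1 \code{GRanges}. Records whose REF or
#' any ALT allele is not a single base (indels, symbolic alleles) are dropped;
#' records with more than one ALT are \emph{kept} and flagged
#' \code{multiallelic} so the downstream triallelic filter can count them
#' rather than losing them silently (the first ALT is reported as \code{alt}).
#'
#' @param path VCF file path.
#' @param sample sample name; must be present in the VCF header.
#' @return \code{GRanges} with mcols \code{ref}, \code{alt}, \code{gtCode}
#'   (0 hom-ref / 1 het / 2 hom-alt / NA missing) and \code{multiallelic}.
#' @export
readSampleVcf <- function(path, sample) {
    hdr <- tryCatch(VariantAnnotation::scanVcfHeader(path),
                    error = function(e)
        stop("failed to parse VCF header of ", path, ": ",
             conditionMessage(e)))
    if (!sample %in% VariantAnnotation::samples(hdr))
        stop("sample '", sample, "' not present in ", path,
             " (has: ", paste(VariantAnnotation::samples(hdr),
                              collapse = ", "), ")")
    validateVcfRecords(path)
    vcf <- tryCatch(VariantAnnotation::readVcf(path),
                    error = function(e) stop(vcfRecordError(path, e)))
    gr <- SummarizedExperiment::rowRanges(vcf)
    names(gr) <- NULL
    ref <- as.character(VariantAnnotation::ref(vcf))
    altl <- as.list(VariantAnnotation::alt(vcf))
    altchr <- lapply(altl, as.character)
    nalt <- lengths(altchr)
    snv <- nchar(ref) == 1L & ref %in% c("A", "C", "G", "T") &
        vapply(altchr, function(a)
            length(a) > 0L && all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")),
            logical(1))
    gt <- VariantAnnotation::geno(vcf)$GT[, sample]
    out <- GRanges(seqnames(gr)[snv], IRanges(start(gr)[snv], width = 1L))
    mcols(out)$ref <- ref[snv]
    mcols(out)$alt <- vapply(altchr[snv], `[`, "", 1L)
    mcols(out)$gtCode <- mapGtString(gt[snv])
    mcols(out)$multiallelic <- nalt[snv] > 1L
    out
}

validateVcfRecords <- function(path) {
    lines <- readLines(path)
    body <- which(!startsWith(lines, "#"))
    if (!length(body)) return(invisible(TRUE))
    bad <- body[vapply(strsplit(lines[body], "\t", fixed = TRUE),
                       function(f) length(f) < 8L ||
                           is.na(suppressWarnings(as.integer(f[2L]))),
                       logical(1))]
    if (length(bad))
        stop("malformed VCF record at line ", bad[1L], " of ", path)
    invisible(TRUE)
}

vcfRecordError <- function(path, e) {
    # try to report the offending line number for malformed records
    msg <- conditionMessage(e)
    ln <- tryCatch({
        lines <- readLines(path)
        body <- which(!startsWith(lines, "#"))
        bad <- body[vapply(strsplit(lines[body], "\t", fixed = TRUE),
                           function(f) length(f) < 8L ||
                               is.na(suppressWarnings(as.integer(f[2L]))),
                           logical(1))]
        if (length(bad)) bad[1L] else NA_integer_
    }, error = function(e2) NA_integer_)
    if (!is.na(ln))
        paste0("malformed VCF record at line ", ln, " of ", path, ": ", msg)
    else paste0("malformed VCF ", path, ": ", msg)
}
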