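#' Read an indexed reference genome
#'
#' @param path FASTA file.
#' @return A named \code{DNAStringSet}, one entry per chromosome (FASTA
#'   description lines are trimmed to the first word).
#' @export
readGenome <- function(path) {
    g <- Biostrings::readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    g
}

#' @rdname GeneModelSet-class
#' @export
setMethod("transcriptInfo", "GeneModelSet", function(x) x@txinfo)

#' @rdname GeneModelSet-class
#' @export
setMethod("exonsByTx", "GeneModelSet", function(x) x@exons)

#' @rdname GeneModelSet-class
#' @export
setMethod("cdsByTx", "GeneModelSet", function(x) x@cds)

setMethod("show", "GeneModelSet", function(object) {
    ti <- object@txinfo
    cat("GeneModelSet with", nrow(ti), "transcripts /",
        length(unique(ti$gene_id)), "genes\n")
    cat("coding:", sum(ti$coding), " complete:", sum(ti$complete), "\n")
})

#' Per-gene genomic spans of a GeneModelSet
#'
#' @param genes a \code{GeneModelSet}.
#' @return \code{GRanges}, one range per gene id spanning all its transcripts.
#' @export
geneRanges <- function(genes) {
    ti <- transcriptInfo(genes)
    spans <- unlist(range(exonsByTx(genes)))
    byGene <- split(spans, ti$gene_id)
    out <- unlist(range(byGene))
    mcols(out)$gene_id <- names(out)
    names(out) <- NULL
    out
}

#' Read gene models from GFF3
#'
#' Assembles transcripts (mRNA or other transcript-typed features with exon
#' children) from a GFF3 file. Exons are stored in genomic order; codon
#' extraction walks them strand-aware, so minus-strand codons come from the
#' reverse complement. A coding transcript whose total CDS length is not
#' divisible by 3 is retained but flagged incomplete.
#'
#' @param gffPath GFF3 file with gene/mRNA/exon/CDS features.
#' @param genome a \code{DNAStringSet} from \code{\link{readGenome}}, used to
#'   validate that every referenced chromosome exists.
#' @return A \code{GeneModelSet}.
#' @export
readGeneModels <- function(gffPath, genome) {
    gff <- rtracklayer::import(gffPath, format = "gff3")
    bad <- setdiff(unique(as.character(seqnames(gff))), names(genome))
    if (length(bad))
        stop("GFF3 references chromosome(s) absent from the genome: ",
             paste(bad, collapse = ", "))
    type <- as.character(gff$type)
    isTx <- type %in% c("mRNA", "transcript", "ncRNA", "lnc_RNA", "rRNA",
                        "tRNA")
    tx <- gff[isTx]
    txid <- as.character(tx$ID)
    parentOf <- function(x) vapply(as.list(x$Parent), function(p)
        if (length(p)) as.character(p)[1L] else NA_character_, "")
    geneid <- parentOf(tx)
    geneid[is.na(geneid)] <- txid[is.na(geneid)]

    ex <- gff[type == "exon"]
    cd <- gff[type == "CDS"]
    exParent <- parentOf(ex)
    cdParent <- parentOf(cd)
    mcols(ex) <- NULL
    mcols(cd) <- NULL
    exl <- split(ex, factor(exParent, levels = txid))
    cdl <- split(cd, factor(cdParent, levels = txid))
    exl <- GRangesList(lapply(exl, function(g) sort(g, ignore.strand = TRUE)))
    cdl <- GRangesList(lapply(cdl, function(g) sort(g, ignore.strand = TRUE)))
    cdsLen <- vapply(cdl, function(g) sum(width(g)), integer(1))
    txinfo <- DataFrame(
        transcript_id = txid,
        gene_id = geneid,
        chrom = as.character(seqnames(tx)),
        strand = as.character(strand(tx)),
        coding = cdsLen > 0L,
        complete = cdsLen > 0L & cdsLen %% 3L == 0L)
    names(exl) <- txid
    names(cdl) <- txid
    new("GeneModelSet", txinfo = txinfo, exons = exl, cds = cdl)
}

#' Read a BED interval mask
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' closed \code{GRanges} at the boundary and merged. Rows with
#' \code{start >= end} are rejected with their line number.
#'
#' @param path BED file (3+ columns); an empty file yields an empty mask.
#' @return Merged \code{GRanges}.
#' @export
readBedMask <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(GRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("BED line ", which(nf < 3L)[1L], ": fewer than 3 columns")
    chrom <- vapply(fields, `[`, "", 1L)
    s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(s) || anyNA(e))
        stop("BED line ", which(is.na(s) | is.na(e))[1L],
             ": non-numeric coordinate")
    bad <- s >= e
    if (any(bad))
        stop("BED line ", which(bad)[1L], ": start >= end")
    reduce(GRanges(chrom, IRanges(s + 1L, e)))
}
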