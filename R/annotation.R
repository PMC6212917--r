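COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
EFFECT_SEVERITY <- c(stoploss = 4L, stopgain = 4L, nonsynonymous = 3L,
                     synonymous = 2L, unknown = 1L)

aaCode <- function(aa) ifelse(aa == "*", "X", aa)

#' Effect of a single-base change within one codon
#'
#' Classifies the change of one base of a codon under the standard genetic
#' code: \code{stopgain} when the altered codon is a stop and the reference
#' codon is not, \code{stoploss} for the reverse, otherwise
#' \code{synonymous}/\code{nonsynonymous} by residue identity (a stop-to-stop
#' change is synonymous).
#'
#' @param refCodon 3-base reference codon (coding strand).
#' @param posInCodon 1, 2 or 3.
#' @param altBase replacement base (coding strand).
#' @return list with \code{effect}, \code{refAA}, \code{altAA},
#'   \code{altCodon} (amino acids in one-letter code, stop = \code{*}).
#' @export
codonEffect <- function(refCodon, posInCodon, altBase) {
    stopifnot(nchar(refCodon) == 3L, posInCodon %in% 1:3)
    altCodon <- refCodon
    substr(altCodon, posInCodon, posInCodon) <- altBase
    refAA <- unname(GENETIC_CODE[refCodon])
    altAA <- unname(GENETIC_CODE[altCodon])
    effect <- if (altAA == "*" && refAA != "*") "stopgain"
        else if (refAA == "*" && altAA != "*") "stoploss"
        else if (refAA == altAA) "synonymous"
        else "nonsynonymous"
    list(effect = effect, refAA = refAA, altAA = altAA, altCodon = altCodon)
}

# CDS-oriented coordinate of a genomic position within a transcript's CDS,
# or NA when the position is outside the CDS.
cdsPosition <- function(cds, strand, pos) {
    w <- width(cds)
    hit <- which(pos >= start(cds) & pos <= end(cds))
    if (!length(hit)) return(NA_integer_)
    hit <- hit[1L]
    if (strand == "+") {
        before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
        before + (pos - start(cds)[hit] + 1L)
    } else {
        after <- if (hit < length(cds)) sum(w[seq(hit + 1L, length(cds))])
                 else 0L
        after + (end(cds)[hit] - pos + 1L)
    }
}

codingSequence <- function(genome, cds, strand) {
    parts <- as.character(Biostrings::extractAt(
        genome[[as.character(seqnames(cds)[1L])]],
        IRanges(start(cds), end(cds))))
    s <- paste(parts, collapse = "")
    if (strand == "-")
        s <- as.character(reverseComplement(DNAString(s)))
    s
}

#' Codon-level effect of an exonic SNV in one transcript
#'
#' Builds the reference and alternate codons strand-aware from the genome and
#' the transcript's CDS intervals, translates them with the standard genetic
#' code and emits the effect plus a
#' \code{TRANSCRIPT:exonN:c.R<pos>A:p.X<pos>Y} notation string (1-based CDS
#' and protein coordinates; exon numbering follows transcription order; stop
#' written as X in the protein field). An incomplete transcript (CDS length
#' not divisible by 3) yields effect \code{"unknown"} with empty codon
#' fields.
#'
#' @param chrom,pos,alt the variant (reference-strand alt base).
#' @param txId transcript id in \code{genes}.
#' @param genes a \code{GeneModelSet}.
#' @param genome \code{DNAStringSet}.
#' @return list with \code{effect}, \code{notation}, \code{refCodon},
#'   \code{altCodon}, \code{refAA}, \code{altAA}, \code{cdsPos},
#'   \code{aaPos}.
#' @export
exonicEffect <- function(chrom, pos, alt, txId, genes, genome) {
    ti <- transcriptInfo(genes)
    i <- match(txId, ti$transcript_id)
    if (is.na(i)) stop("unknown transcript: ", txId)
    cds <- cdsByTx(genes)[[i]]
    strand <- ti$strand[i]
    blank <- list(effect = "unknown", notation = NA_character_,
                  refCodon = "", altCodon = "", refAA = "", altAA = "",
                  cdsPos = NA_integer_, aaPos = NA_integer_)
    if (!ti$coding[i] || !ti$complete[i]) return(blank)
    cp <- cdsPosition(cds, strand, pos)
    if (is.na(cp)) stop("position ", pos, " outside CDS of ", txId)
    cseq <- codingSequence(genome, cds, strand)
    ci <- (cp - 1L) %/% 3L + 1L
    off <- (cp - 1L) %% 3L + 1L
    refCodon <- substr(cseq, 3L * (ci - 1L) + 1L, 3L * ci)
    altC <- if (strand == "+") alt else unname(COMPLEMENT[alt])
    refC <- substr(refCodon, off, off)
    eff <- codonEffect(refCodon, off, altC)
    ex <- exonsByTx(genes)[[i]]
    exHit <- which(pos >= start(ex) & pos <= end(ex))[1L]
    exonN <- if (strand == "+") exHit else length(ex) - exHit + 1L
    notation <- sprintf("%s:exon%d:c.%s%d%s:p.%s%d%s", txId, exonN,
                        refC, cp, altC, aaCode(eff$refAA), ci,
                        aaCode(eff$altAA))
    list(effect = eff$effect, notation = notation, refCodon = refCodon,
         altCodon = eff$altCodon, refAA = eff$refAA, altAA = eff$altAA,
         cdsPos = cp, aaPos = ci)
}

regionSets <- function(genes, flankBp, spliceBp) {
    ti <- transcriptInfo(genes)
    exl <- exonsByTx(genes)
    cdl <- cdsByTx(genes)
    coding <- ti$coding
    emptyGr <- GRanges()
    cat_cds <- if (any(coding)) reduce(unlist(cdl[coding])) else emptyGr
    utr <- introns <- splice <- list()
    for (i in seq_len(nrow(ti))) {
        ex <- exl[[i]]
        if (!length(ex)) next
        if (!coding[i]) next   # ncRNA introns/splice collapse into ncRNA
        span <- range(ex)
        intr <- GenomicRanges::setdiff(span, ex)
        if (length(intr)) {
            introns[[length(introns) + 1L]] <- intr
            if (spliceBp > 0L) {
                donors <- GRanges(seqnames(intr),
                    IRanges(start(intr),
                            pmin(start(intr) + spliceBp - 1L, end(intr))))
                accept <- GRanges(seqnames(intr),
                    IRanges(pmax(end(intr) - spliceBp + 1L, start(intr)),
                            end(intr)))
                splice[[length(splice) + 1L]] <- c(donors, accept)
            }
        }
        u <- GenomicRanges::setdiff(ex, cdl[[i]])
        if (length(u)) utr[[length(utr) + 1L]] <- u
    }
    bindGr <- function(l) if (length(l)) reduce(do.call(c, l)) else emptyGr
    spans <- unlist(range(exl))
    ncrna <- if (any(!coding)) reduce(spans[!coding]) else emptyGr
    spansU <- spans
    strand(spansU) <- "*"
    updown <- reduce(c(
        GenomicRanges::flank(spansU, flankBp, start = TRUE),
        GenomicRanges::flank(spansU, flankBp, start = FALSE)))
    updown <- updown[start(updown) >= 1L | end(updown) >= 1L]
    start(updown) <- pmax(start(updown), 1L)
    list(exonic = cat_cds, splicing = bindGr(splice), utr = bindGr(utr),
         intronic = bindGr(introns), ncRNA = ncrna, upstream_downstream =
         updown)
}

REGION_LEVELS <- c("exonic", "splicing", "utr", "intronic", "ncRNA",
                   "upstream_downstream", "intergenic")

#' Annotate variants with region category and exonic effect
#'
#' Assigns each variant exactly one mutually exclusive region category with
#' precedence exonic > splicing > UTR > intronic > ncRNA >
#' upstream/downstream > intergenic ("exonic" means within a coding
#' transcript's CDS; splicing means within \code{spliceBp} of an exon-intron
#' boundary on the intron side; 5' and 3' UTR are collapsed into one UTR
#' category; ncRNA covers non-coding transcripts). For exonic variants the
#' codon-level effect is computed in every coding transcript whose CDS
#' contains the site, the most severe effect is reported
#' (stop changes > nonsynonymous > synonymous) and all per-transcript
#' notation strings are retained.
#'
#' @param m a \code{GenotypeMatrix}, or a width-1 \code{GRanges} with mcols
#'   \code{ref} and \code{alt}.
#' @param genes a \code{GeneModelSet}.
#' @param genome \code{DNAStringSet}.
#' @param flankBp upstream/downstream flank width (default 1000 bp).
#' @param spliceBp splice-region width inside the intron (default 2 bp).
#' @return \code{DataFrame} aligned with the variants: \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{region}, \code{effect},
#'   \code{transcript}, \code{notation} (comma-joined over transcripts),
#'   \code{refCodon}, \code{altCodon}, \code{refAA}, \code{altAA}.
#' @export
annotateVariants <- function(m, genes, genome, flankBp = 1000L,
                             spliceBp = 2L) {
    gr <- if (is(m, "GenotypeMatrix")) variantRanges(m) else m
    sets <- regionSets(genes, flankBp, spliceBp)
    n <- length(gr)
    region <- rep("intergenic", n)
    for (cat in rev(setdiff(REGION_LEVELS, "intergenic")))
        if (length(sets[[cat]]))
            region[countOverlaps(gr, sets[[cat]]) > 0L] <- cat

    effect <- rep(NA_character_, n)
    transcript <- notation <- rep(NA_character_, n)
    refCodon <- altCodon <- refAA <- altAA <- rep("", n)

    ti <- transcriptInfo(genes)
    cdl <- cdsByTx(genes)
    codingIdx <- which(ti$coding)
    if (length(codingIdx)) {
        allCds <- unlist(cdl[codingIdx])
        cdsTx <- rep(ti$transcript_id[codingIdx],
                     lengths(cdl[codingIdx]))
        exIdx <- which(region == "exonic")
        if (length(exIdx)) {
            ov <- findOverlaps(gr[exIdx], allCds)
            byVar <- split(cdsTx[S4Vectors::subjectHits(ov)],
                           S4Vectors::queryHits(ov))
            for (k in names(byVar)) {
                i <- exIdx[as.integer(k)]
                txs <- unique(byVar[[k]])
                effs <- lapply(txs, function(tx)
                    exonicEffect(as.character(seqnames(gr)[i]), start(gr)[i],
                                 mcols(gr)$alt[i], tx, genes, genome))
                sev <- EFFECT_SEVERITY[vapply(effs, `[[`, "", "effect")]
                best <- which.max(sev)
                e <- effs[[best]]
                effect[i] <- e$effect
                transcript[i] <- txs[best]
                nts <- vapply(effs, `[[`, "", "notation")
                notation[i] <- paste(nts[!is.na(nts)], collapse = ",")
                refCodon[i] <- e$refCodon
                altCodon[i] <- e$altCodon
                refAA[i] <- e$refAA
                altAA[i] <- e$altAA
            }
        }
    }
    DataFrame(chrom = as.character(seqnames(gr)), pos = start(gr),
              ref = mcols(gr)$ref, alt = mcols(gr)$alt, region = region,
              effect = effect, transcript = transcript, notation = notation,
              refCodon = refCodon, altCodon = altCodon, refAA = refAA,
              altAA = altAA)
}

#' Region and exonic-effect category tables
#'
#' Tabulates annotation records into the two standard layouts: a region table
#' (total, intergenic and genic counts with percentages of the total, and the
#' genic subcategories -- up/downstream, exonic, splicing, intronic, UTR,
#' ncRNA -- which always sum to the genic total) and an exonic-effect table
#' (synonymous / nonsynonymous / stop-gain / stop-loss counts with
#' percentages of the classified exonic total).
#'
#' @param ann \code{DataFrame} from \code{\link{annotateVariants}} (subset it
#'   first to scope the table, e.g. to one sample's carried or specific
#'   variants).
#' @return list of two \code{DataFrame}s, \code{regions} and \code{effects}.
#' @export
tabulateAnnotation <- function(ann) {
    n <- nrow(ann)
    cnt <- vapply(REGION_LEVELS, function(r) sum(ann$region == r),
                  integer(1))
    genic <- n - cnt[["intergenic"]]
    regions <- DataFrame(
        category = c("total", "intergenic", "genic", "upstream_downstream",
                     "exonic", "splicing", "intronic", "utr", "ncRNA"),
        count = c(n, cnt[["intergenic"]], genic,
                  cnt[["upstream_downstream"]], cnt[["exonic"]],
                  cnt[["splicing"]], cnt[["intronic"]], cnt[["utr"]],
                  cnt[["ncRNA"]]))
    regions$pctOfTotal <- vapply(regions$count, pct2, 0, den = n)
    effLevels <- c("synonymous", "nonsynonymous", "stopgain", "stoploss")
    ecnt <- vapply(effLevels, function(e)
        sum(!is.na(ann$effect) & ann$effect == e), integer(1))
    effects <- DataFrame(effect = effLevels, count = unname(ecnt))
    effects$pctOfExonic <- vapply(effects$count, pct2, 0, den = sum(ecnt))
    list(regions = regions, effects = effects)
}
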