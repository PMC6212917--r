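TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

defaultBranchTable <- function(roster = c("CR1", "CE1", "CE2", "SM1", "SM2",
                                          "TM1", "AM1", "PM1"),
                               outgroup = "BB") {
    all8 <- paste(roster, collapse = ",")
    data.frame(
        branch = c("ancestral", "ingroup", "fas_clade", "ce_pair",
                   "sin_clade", "tm_am", "sm_pair",
                   roster, outgroup),
        leaves = c(paste(c(roster, outgroup), collapse = ","), all8,
                   "CR1,CE1,CE2", "CE1,CE2", "SM1,SM2,TM1,AM1", "TM1,AM1",
                   "SM1,SM2", roster, outgroup),
        mu = c(200, 300, 150, 150, 150, 200, 250,
               400, 350, 380, 120, 110, 150, 300, 700, 200),
        stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Defaults emulate the structure of an eight-sample macaque-style panel with
#' an outgroup: a species tree whose clades (a rhesus/cynomolgus clade, a
#' sinica-group clade with a conspecific pair, a divergent pig-tailed-like
#' terminal carrying the largest specific load) shape the allele-sharing
#' pattern, transition bias kappa in the empirically observed 2.17-2.25
#' band, and a per-carrier heterozygote probability producing intermediate
#' heterozygosity levels.
#'
#' @param branches branch table (\code{branch}, \code{leaves}, \code{mu});
#'   see \code{\link{SimConfig}}.
#' @param roster ingroup sample names.
#' @param outgroup outgroup leaf name.
#' @param nChroms,chromLength genome dimensions.
#' @param kappa transition/transversion rate bias.
#' @param hetProb per-carrier heterozygote probability.
#' @param geneCount,meanCdsLen gene-model geometry.
#' @param hotspots hotspot table (may be 0-row); columns \code{sample},
#'   \code{chrom}, \code{startWindow}, \code{endWindow}, \code{fold},
#'   \code{windowSize}.
#' @param maskCount duplication-mask intervals per chromosome.
#' @param seed RNG seed.
#' @return A \code{\link{SimConfig}}.
#' @export
simConfig <- function(branches = defaultBranchTable(),
                      roster = c("CR1", "CE1", "CE2", "SM1", "SM2", "TM1",
                                 "AM1", "PM1"),
                      outgroup = "BB", nChroms = 2L, chromLength = 500000L,
                      kappa = 2.2, hetProb = 0.45, geneCount = 40L,
                      meanCdsLen = 300L,
                      hotspots = data.frame(sample = character(0),
                                            chrom = character(0),
                                            startWindow = integer(0),
                                            endWindow = integer(0),
                                            fold = numeric(0),
                                            windowSize = integer(0)),
                      maskCount = 2L, seed = 1L) {
    new("SimConfig", branches = branches, roster = roster,
        outgroup = outgroup, nChroms = as.integer(nChroms),
        chromLength = as.integer(chromLength), kappa = kappa,
        hetProb = hetProb, geneCount = as.integer(geneCount),
        meanCdsLen = as.integer(meanCdsLen), hotspots = hotspots,
        maskCount = as.integer(maskCount), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", length(object@roster), "samples + outgroup",
        object@outgroup, "|", object@nChroms, "x", object@chromLength,
        "bp | kappa =", object@kappa, "| seed =", object@seed, "\n")
})

# amino-acid lookup for generation-time truth, built by direct translation
# (independent of the annotator's code path)
simAaTable <- local({
    tab <- NULL
    function() {
        if (is.null(tab)) {
            bases <- c("A", "C", "G", "T")
            codons <- apply(expand.grid(bases, bases, bases), 1L, paste,
                            collapse = "")
            aa <- suppressWarnings(as.character(Biostrings::translate(
                DNAStringSet(codons), no.init.codon = TRUE)))
            tab <<- setNames(aa, codons)
        }
        tab
    }
})

simRevComp <- function(s)
    paste(rev(unname(COMPLEMENT[strsplit(s, "")[[1L]]])), collapse = "")

# transcription-ordered genomic positions of a CDS
simCdsGenomicPositions <- function(cds, strand) {
    p <- unlist(lapply(seq_along(cds), function(i)
        seq(start(cds)[i], end(cds)[i])))
    if (strand == "-") rev(p) else p
}

simEffectClass <- function(codingSeq, cdsPos, altCoding) {
    aa <- simAaTable()
    ci <- (cdsPos - 1L) %/% 3L + 1L
    off <- (cdsPos - 1L) %% 3L + 1L
    refCodon <- substr(codingSeq, 3L * (ci - 1L) + 1L, 3L * ci)
    altCodon <- refCodon
    substr(altCodon, off, off) <- altCoding
    refAA <- aa[[refCodon]]
    altAA <- aa[[altCodon]]
    if (altAA == "*" && refAA != "*") "stopgain"
    else if (refAA == "*" && altAA != "*") "stoploss"
    else if (refAA == altAA) "synonymous"
    else "nonsynonymous"
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

designCds <- function(len) {
    # ATG start, one terminal stop, no internal stops
    stopifnot(len %% 3L == 0L, len >= 9L)
    nmid <- len / 3L - 2L
    aa <- simAaTable()
    nonStop <- names(aa)[aa != "*"]
    mid <- sample(nonStop, nmid, replace = TRUE)
    paste(c("ATG", mid, sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

simGeneModels <- function(cfg, chromNames) {
    perChrom <- ceiling(cfg@geneCount / cfg@nChroms)
    rows <- list()
    gidx <- 0L
    for (ch in chromNames) {
        spacing <- cfg@chromLength %/% (perChrom + 1L)
        for (g in seq_len(perChrom)) {
            if (gidx >= cfg@geneCount) break
            gidx <- gidx + 1L
            L <- max(9L, 3L * round(cfg@meanCdsLen / 3))
            L1 <- (L %/% 2L) + ((L %/% 2L) %% 2L)  # arbitrary split
            L2 <- L - L1
            utr <- 30L
            intron <- 100L
            margin <- max(50L, min(2000L, spacing %/% 5L))
            s <- (g - 1L) * spacing + margin
            if (s + 2L * 30L + L + 100L > cfg@chromLength)
                stop("chromosome too short for the configured gene models")
            strand <- if (gidx %% 2L) "+" else "-"
            # plus-strand-style genomic layout; transcription order flips
            # on the minus strand
            ex1 <- c(s, s + utr + L1 - 1L)
            cd1 <- c(s + utr, s + utr + L1 - 1L)
            ex2s <- ex1[2L] + intron + 1L
            ex2 <- c(ex2s, ex2s + L2 + utr - 1L)
            cd2 <- c(ex2s, ex2s + L2 - 1L)
            if (strand == "-") {  # mirror UTR placement
                cd1 <- c(ex1[1L], ex1[1L] + L1 - 1L)
                ex1 <- c(ex1[1L], ex1[1L] + L1 + utr - 1L)
                ex2s <- ex1[2L] + intron + 1L
                cd2 <- c(ex2s + utr, ex2s + utr + L2 - 1L)
                ex2 <- c(ex2s, ex2s + utr + L2 - 1L)
            }
            rows[[gidx]] <- list(chrom = ch, strand = strand,
                                 gene = sprintf("g%03d", gidx),
                                 tx = sprintf("g%03d.t1", gidx),
                                 exons = rbind(ex1, ex2),
                                 cds = rbind(cd1, cd2),
                                 cdsLen = L,
                                 coding = designCds(L))
        }
    }
    rows
}

writeSimGff3 <- function(models, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (md in models) {
        span <- range(c(md$exons, md$cds))
        ln <- function(type, s, e, attrs, phase = ".")
            sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t%s\t%s", md$chrom, type,
                    s, e, md$strand, phase, attrs)
        out <- c(ln("gene", span[1L], span[2L], paste0("ID=", md$gene)),
                 ln("mRNA", span[1L], span[2L],
                    paste0("ID=", md$tx, ";Parent=", md$gene)))
        for (i in seq_len(nrow(md$exons)))
            out <- c(out, ln("exon", md$exons[i, 1L], md$exons[i, 2L],
                             paste0("Parent=", md$tx)))
        # phase of each CDS piece in transcription order
        ord <- if (md$strand == "+") seq_len(nrow(md$cds))
               else rev(seq_len(nrow(md$cds)))
        done <- 0L
        phase <- integer(nrow(md$cds))
        for (i in ord) {
            phase[i] <- (3L - done %% 3L) %% 3L
            done <- done + (md$cds[i, 2L] - md$cds[i, 1L] + 1L)
        }
        for (i in seq_len(nrow(md$cds)))
            out <- c(out, ln("CDS", md$cds[i, 1L], md$cds[i, 2L],
                             paste0("Parent=", md$tx), phase[i]))
        writeLines(out, con)
    }
    invisible(path)
}

writeSimVcf <- function(path, sample, chrom, pos, ref, alt, gt, seqlen) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##fileformat=VCFv4.2", con)
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(seqlen),
                       as.integer(seqlen)), con)
    writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"), con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample), collapse = "\t"), con)
    if (length(pos)) {
        o <- order(match(chrom, names(seqlen)), pos)
        writeLines(paste(chrom[o], pos[o], ".", ref[o], alt[o], ".", "PASS",
                         ".", "GT", c("0/1", "1/1")[gt[o]], sep = "\t"), con)
    }
    invisible(path)
}

#' Simulate a complete toy dataset with truth
#'
#' Generates a reference genome, gene models, a duplication mask, per-sample
#' VCFs, an outgroup carrier set and a per-variant truth table. Mutations
#' are placed on the configured tree: each branch receives a
#' Poisson(\code{mu}) number of mutations at positions drawn uniformly
#' without collision across the genome (infinite sites), the alternate
#' allele is the transition partner with probability kappa/(kappa+1) and
#' one of the two transversions otherwise, and every leaf below the branch
#' carries the allele (homozygous alternate, downgraded to heterozygous per
#' carrier with probability \code{hetProb}). Hotspot rows add private
#' terminal-branch mutations for one sample inside a window range, inflating
#' its count there by the requested fold. For every mutation landing in the
#' CDS of a complete transcript the truth table records the effect class by
#' direct codon lookup at generation time, independent of the annotation
#' module. Output is byte-deterministic given the config (which includes the
#' seed).
#'
#' @param cfg a \code{\link{SimConfig}}.
#' @param dir output directory (created if needed).
#' @return list with \code{paths} (fasta, gff3, mask, per-sample vcfs,
#'   outgroup vcf, truth), \code{roster}, \code{outgroup}, \code{seqlen},
#'   \code{truth} (\code{DataFrame}), \code{outgroupSites} (\code{GRanges})
#'   and \code{branchLeaves} (named list).
#' @export
simulateDataset <- function(cfg, dir) {
    set.seed(cfg@seed)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    chromNames <- paste0("chr", seq_len(cfg@nChroms))
    seqlen <- setNames(rep(cfg@chromLength, cfg@nChroms), chromNames)

    genome <- DNAStringSet(vapply(chromNames, function(ch)
        randomDna(cfg@chromLength), ""))
    names(genome) <- chromNames

    models <- simGeneModels(cfg, chromNames)
    for (md in models) {
        # write designed coding sequence into the genome, strand-aware
        gseq <- if (md$strand == "+") md$coding else simRevComp(md$coding)
        offset <- 0L
        for (i in seq_len(nrow(md$cds))) {
            w <- md$cds[i, 2L] - md$cds[i, 1L] + 1L
            piece <- substr(gseq, offset + 1L, offset + w)
            genome[[md$chrom]] <- Biostrings::replaceAt(
                genome[[md$chrom]],
                IRanges(md$cds[i, 1L], md$cds[i, 2L]), piece)
            offset <- offset + w
        }
    }

    # duplication mask: random intervals
    maskRows <- list()
    for (ch in chromNames) {
        if (cfg@chromLength <= 3000L) break   # too short for mask intervals
        for (i in seq_len(cfg@maskCount)) {
            s0 <- sample.int(cfg@chromLength - 2500L, 1L)
            maskRows[[length(maskRows) + 1L]] <-
                sprintf("%s\t%d\t%d", ch, s0, s0 + 2000L)
        }
    }

    leaves <- strsplit(cfg@branches$leaves, ",", fixed = TRUE)
    names(leaves) <- cfg@branches$branch
    nMut <- stats::rpois(nrow(cfg@branches), cfg@branches$mu)

    # hotspot extra mutations: private to one sample, terminal-branch-like
    hs <- cfg@hotspots
    hsN <- integer(nrow(hs))
    if (nrow(hs)) {
        for (i in seq_len(nrow(hs))) {
            term <- which(vapply(leaves, function(l)
                identical(l, hs$sample[i]), logical(1)))
            if (!length(term))
                stop("hotspot sample has no terminal branch: ", hs$sample[i])
            nwin <- hs$endWindow[i] - hs$startWindow[i] + 1L
            carrying <- vapply(leaves, function(l) hs$sample[i] %in% l,
                               logical(1))
            basePerBp <- sum(cfg@branches$mu[carrying]) /
                (cfg@nChroms * as.numeric(cfg@chromLength))
            hsN[i] <- stats::rpois(1L, (hs$fold[i] - 1) * basePerBp *
                                       hs$windowSize[i] * nwin)
        }
    }

    total <- sum(nMut) + sum(hsN)
    genomeSize <- cfg@nChroms * as.numeric(cfg@chromLength)
    if (total > genomeSize)
        stop("more mutations requested than available positions")
    # one global draw without replacement guarantees infinite sites
    pool <- sample.int(genomeSize, total)
    branchOf <- rep(cfg@branches$branch, nMut)
    hotspotFlag <- rep(FALSE, total)
    if (nrow(hs) && sum(hsN)) {
        # re-draw hotspot positions inside their regions, avoiding collisions
        used <- logical(genomeSize)
        used[pool] <- TRUE
        k <- sum(nMut)
        for (i in seq_len(nrow(hs))) {
            if (!hsN[i]) next
            chOff <- (match(hs$chrom[i], chromNames) - 1L) *
                as.numeric(cfg@chromLength)
            lo <- (hs$startWindow[i] - 1L) * hs$windowSize[i] + 1L
            hi <- min(hs$endWindow[i] * hs$windowSize[i], cfg@chromLength)
            region <- chOff + seq(lo, hi)
            free <- region[!used[region]]
            if (length(free) < hsN[i])
                stop("hotspot region too small for requested mutations")
            sel <- sample(free, hsN[i])
            used[sel] <- TRUE
            pool[k + seq_len(hsN[i])] <- sel
            branchOf[k + seq_len(hsN[i])] <- hs$sample[i]
            hotspotFlag[k + seq_len(hsN[i])] <- TRUE
            k <- k + hsN[i]
        }
    }

    chromIdx <- (pool - 1L) %/% cfg@chromLength + 1L
    chrom <- chromNames[chromIdx]
    pos <- as.integer((pool - 1L) %% cfg@chromLength + 1L)
    ref <- character(total)
    for (ci in seq_len(cfg@nChroms)) {
        idx <- which(chromIdx == ci)
        if (length(idx))
            ref[idx] <- as.character(Biostrings::extractAt(
                genome[[ci]], IRanges(pos[idx], width = 1L)))
    }
    isTi <- stats::runif(total) < cfg@kappa / (cfg@kappa + 1)
    alt <- character(total)
    alt[isTi] <- unname(TRANSITION_PARTNER[ref[isTi]])
    if (any(!isTi)) {
        alt[!isTi] <- vapply(ref[!isTi], function(b)
            sample(setdiff(c("A", "C", "G", "T"),
                           c(b, TRANSITION_PARTNER[[b]])), 1L), "")
    }

    carriers <- leaves[branchOf]
    carriers[hotspotFlag] <- as.list(branchOf[hotspotFlag])
    genoList <- lapply(carriers, function(cs)
        setNames(ifelse(stats::runif(length(cs)) < cfg@hetProb, 1L, 2L), cs))

    # per-variant effect truth for CDS hits (generation-time codon lookup)
    txId <- rep(NA_character_, total)
    cdsPosv <- rep(NA_integer_, total)
    effectv <- rep(NA_character_, total)
    for (md in models) {
        gp <- simCdsGenomicPositions(GRanges(md$chrom,
            IRanges(md$cds[, 1L], md$cds[, 2L])), md$strand)
        hit <- which(chrom == md$chrom & pos %in% gp)
        for (i in hit) {
            cp <- match(pos[i], gp)
            altC <- if (md$strand == "+") alt[i]
                    else unname(COMPLEMENT[alt[i]])
            txId[i] <- md$tx
            cdsPosv[i] <- cp
            effectv[i] <- simEffectClass(md$coding, cp, altC)
        }
    }

    truth <- DataFrame(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        branch = branchOf, hotspot = hotspotFlag,
        ti = if (total) paste0(ref, ">", alt) %in% TRANSITIONS
             else logical(0),
        carriers = vapply(genoList, function(g)
            paste(names(g), collapse = ","), ""),
        genotypes = vapply(genoList, function(g)
            paste(g, collapse = ","), ""),
        transcript = txId, cdsPos = cdsPosv, effect = effectv)
    o <- order(match(chrom, chromNames), pos)
    truth <- truth[o, , drop = FALSE]
    genoList <- genoList[o]

    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gff3 = file.path(dir, "genes.gff3"),
                  mask = file.path(dir, "dups.bed"),
                  truth = file.path(dir, "truth.tsv"))
    writeXStringSet(genome, paths$fasta)
    writeSimGff3(models, paths$gff3)
    writeLines(as.character(unlist(maskRows)), paths$mask)
    utils::write.table(as.data.frame(truth), paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)

    paths$vcf <- setNames(file.path(dir, paste0(cfg@roster, ".vcf")),
                          cfg@roster)
    for (s in cfg@roster) {
        gt <- vapply(genoList, function(g)
            if (s %in% names(g)) g[[s]] else NA_integer_, integer(1))
        sel <- !is.na(gt)
        writeSimVcf(paths$vcf[[s]], s, truth$chrom[sel], truth$pos[sel],
                    truth$ref[sel], truth$alt[sel], gt[sel], seqlen)
    }
    ogCarry <- vapply(genoList, function(g) cfg@outgroup %in% names(g),
                      logical(1))
    paths$outgroupVcf <- file.path(dir, paste0(cfg@outgroup, ".vcf"))
    gtOg <- vapply(genoList[ogCarry], function(g) g[[cfg@outgroup]],
                   integer(1))
    writeSimVcf(paths$outgroupVcf, cfg@outgroup, truth$chrom[ogCarry],
                truth$pos[ogCarry], truth$ref[ogCarry], truth$alt[ogCarry],
                gtOg, seqlen)
    outgroupSites <- GRanges(truth$chrom[ogCarry],
                             IRanges(truth$pos[ogCarry], width = 1L))

    list(paths = paths, roster = cfg@roster, outgroup = cfg@outgroup,
         seqlen = seqlen, truth = truth, outgroupSites = outgroupSites,
         branchLeaves = leaves, cfg = cfg)
}

#' Plant variants of a requested effect class
#'
#' Searches the complete coding transcripts of a gene-model set for CDS
#' positions and alternate bases whose effect -- computed here by brute-force
#' codon lookup, independent of the annotation module -- equals the requested
#' class, and returns \code{n} distinct planted variants.
#'
#' @param genome \code{DNAStringSet}.
#' @param genes a \code{GeneModelSet}.
#' @param effect one of \code{"synonymous"}, \code{"nonsynonymous"},
#'   \code{"stopgain"}, \code{"stoploss"}.
#' @param n number of distinct variants to plant.
#' @return width-1 \code{GRanges} with mcols \code{ref}, \code{alt},
#'   \code{effect}, \code{transcript}, \code{cdsPos}; errors when fewer than
#'   \code{n} candidate sites exist.
#' @export
plantEffectVariants <- function(genome, genes, effect, n = 1L) {
    effect <- match.arg(effect, c("synonymous", "nonsynonymous", "stopgain",
                                  "stoploss"))
    ti <- transcriptInfo(genes)
    cand <- list()
    for (i in which(ti$coding & ti$complete)) {
        cds <- cdsByTx(genes)[[i]]
        strand <- ti$strand[i]
        gp <- simCdsGenomicPositions(cds, strand)
        parts <- as.character(Biostrings::extractAt(
            genome[[ti$chrom[i]]], IRanges(start(cds), end(cds))))
        cseq <- paste(parts, collapse = "")
        if (strand == "-") cseq <- simRevComp(cseq)
        basesC <- strsplit(cseq, "")[[1L]]
        for (cp in seq_along(basesC)) {
            for (altC in setdiff(c("A", "C", "G", "T"), basesC[cp])) {
                if (simEffectClass(cseq, cp, altC) == effect) {
                    gpos <- gp[cp]
                    altG <- if (strand == "+") altC
                            else unname(COMPLEMENT[altC])
                    refG <- as.character(subseq(genome[[ti$chrom[i]]],
                                                gpos, gpos))
                    cand[[length(cand) + 1L]] <- data.frame(
                        chrom = ti$chrom[i], pos = gpos, ref = refG,
                        alt = altG, transcript = ti$transcript_id[i],
                        cdsPos = cp, stringsAsFactors = FALSE)
                }
            }
        }
        if (length(cand) >= 50L * n) break  # enough candidates collected
    }
    if (!length(cand))
        stop("no CDS site admits effect class '", effect, "'")
    d <- do.call(rbind, cand)
    d <- d[!duplicated(paste(d$chrom, d$pos, d$alt)), , drop = FALSE]
    if (nrow(d) < n)
        stop("only ", nrow(d), " candidate sites admit effect class '",
             effect, "' (requested ", n, ")")
    d <- d[sample.int(nrow(d), n), , drop = FALSE]
    GRanges(d$chrom, IRanges(d$pos, width = 1L), ref = d$ref, alt = d$alt,
            effect = effect, transcript = d$transcript, cdsPos = d$cdsPos)
}
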