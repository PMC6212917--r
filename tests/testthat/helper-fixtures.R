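suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(S4Vectors)
})

# ---- small in-code fixtures ------------------------------------------------

writeVcfText <- function(path, sample, rows,
                         contigs = c(chr1 = 100000L, chr2 = 100000L)) {
    lines <- c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       contigs),
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sample),
                     collapse = "\t"),
               rows)
    writeLines(lines, path)
    path
}

vcfRow <- function(chrom, pos, ref, alt, gt)
    paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gt,
          sep = "\t")

# a GenotypeMatrix built directly (no files)
toyMatrix <- function(chrom, pos, ref, alt, gt, samples,
                      seqlen = c(chr1 = 100000L, chr2 = 100000L),
                      triallelic = NULL) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L),
                  seqinfo = Seqinfo(names(seqlen), unname(seqlen)))
    mcols(gr)$ref <- ref
    mcols(gr)$alt <- alt
    if (!is.null(triallelic)) mcols(gr)$triallelic <- triallelic
    GenotypeMatrix(gr, matrix(as.integer(gt), ncol = length(samples),
                              dimnames = list(NULL, samples)))
}

randomToyMatrix <- function(nSites, samples,
                            seqlen = c(chr1 = 100000L)) {
    pos <- sort(sample.int(seqlen[[1L]], nSites))
    ref <- sample(c("A", "C", "G", "T"), nSites, replace = TRUE)
    alt <- unname(vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), ""))
    gt <- matrix(sample(c(0L, 0L, 1L, 2L), nSites * length(samples),
                        replace = TRUE), nSites, length(samples),
                 dimnames = list(NULL, samples))
    # guarantee at least one carrier per site
    none <- rowSums(gt >= 1L) == 0L
    gt[none, 1L] <- 1L
    toyMatrix("chr1", pos, ref, alt, gt, samples, seqlen)
}

# a toy annotated genome: one plus-strand coding gene, one minus-strand
# coding gene, one ncRNA gene, on a 10 kb chromosome; returns genome,
# GeneModelSet (via GFF3 text -> reader) and the design info
toyGenomeBundle <- function(dir = NULL, seed = 11L) {
    if (is.null(dir)) {
        dir <- tempfile("toybundle")
        dir.create(dir)
    }
    set.seed(seed)
    n <- 10000L
    seqv <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
    # plus-strand gene gA: exon1 1001-1102 (UTR 1001-1030, CDS 1031-1102),
    # intron 1103-1200, exon2 1201-1332 (CDS 1201-1320, UTR 1321-1332);
    # CDS = 72 + 120 = 192 bp (complete)
    gff <- c("##gff-version 3",
        "chr1\ttoy\tgene\t1001\t1332\t.\t+\t.\tID=gA",
        "chr1\ttoy\tmRNA\t1001\t1332\t.\t+\t.\tID=gA.t1;Parent=gA",
        "chr1\ttoy\texon\t1001\t1102\t.\t+\t.\tParent=gA.t1",
        "chr1\ttoy\texon\t1201\t1332\t.\t+\t.\tParent=gA.t1",
        "chr1\ttoy\tCDS\t1031\t1102\t.\t+\t0\tParent=gA.t1",
        "chr1\ttoy\tCDS\t1201\t1320\t.\t+\t0\tParent=gA.t1",
        # minus-strand gene gB: CDS 3019-3100 (82) + 3201-3310 (110) = 192
        "chr1\ttoy\tgene\t3001\t3322\t.\t-\t.\tID=gB",
        "chr1\ttoy\tmRNA\t3001\t3322\t.\t-\t.\tID=gB.t1;Parent=gB",
        "chr1\ttoy\texon\t3001\t3100\t.\t-\t.\tParent=gB.t1",
        "chr1\ttoy\texon\t3201\t3322\t.\t-\t.\tParent=gB.t1",
        "chr1\ttoy\tCDS\t3019\t3100\t.\t-\t0\tParent=gB.t1",
        "chr1\ttoy\tCDS\t3201\t3310\t.\t-\t0\tParent=gB.t1",
        # ncRNA gene
        "chr1\ttoy\tgene\t6001\t6400\t.\t+\t.\tID=gC",
        "chr1\ttoy\tncRNA\t6001\t6400\t.\t+\t.\tID=gC.t1;Parent=gC",
        "chr1\ttoy\texon\t6001\t6150\t.\t+\t.\tParent=gC.t1",
        "chr1\ttoy\texon\t6301\t6400\t.\t+\t.\tParent=gC.t1")
    gffPath <- file.path(dir, "toy.gff3")
    writeLines(gff, gffPath)
    fastaPath <- file.path(dir, "toy.fa")
    genome <- DNAStringSet(c(chr1 = seqv))
    writeXStringSet(genome, fastaPath)
    genome <- readGenome(fastaPath)
    genes <- readGeneModels(gffPath, genome)
    list(genome = genome, genes = genes, gffPath = gffPath,
         fastaPath = fastaPath, seqlen = c(chr1 = n))
}

# ---- independent oracles ---------------------------------------------------

# leave-one-out refit definition of Cook's distance
looCooksOracle <- function(y, x) {
    n <- length(y)
    X <- cbind(1, x)
    fit <- stats::lm.fit(X, y)
    yhat <- fit$fitted.values
    s2 <- sum(fit$residuals^2) / (n - 2)
    vapply(seq_len(n), function(i) {
        f2 <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])
        yh2 <- drop(X %*% f2$coefficients)
        sum((yhat - yh2)^2) / (2 * s2)
    }, 0)
}

# exhaustive per-base region map for a toy genome, built from first
# principles (independent of the package's precedence machinery)
regionMapOracle <- function(genes, chromLen, flankBp = 1000L,
                            spliceBp = 2L) {
    ti <- transcriptInfo(genes)
    lab <- rep("intergenic", chromLen)
    mark <- function(cat, s, e) {
        s <- max(1L, s); e <- min(chromLen, e)
        if (s <= e) lab[s:e] <<- cat
    }
    prec <- c("upstream_downstream", "ncRNA", "intronic", "utr", "splicing",
              "exonic")  # lowest precedence painted first
    paint <- list(upstream_downstream = list(), ncRNA = list(),
                  intronic = list(), utr = list(), splicing = list(),
                  exonic = list())
    for (i in seq_len(nrow(ti))) {
        ex <- exonsByTx(genes)[[i]]
        cd <- cdsByTx(genes)[[i]]
        lo <- min(start(ex)); hi <- max(end(ex))
        paint$upstream_downstream <- c(paint$upstream_downstream,
            list(c(lo - flankBp, lo - 1L)), list(c(hi + 1L, hi + flankBp)))
        if (!ti$coding[i]) {
            paint$ncRNA <- c(paint$ncRNA, list(c(lo, hi)))
            next
        }
        if (length(ex) > 1L)
            for (k in seq_len(length(ex) - 1L)) {
                is <- end(ex)[k] + 1L; ie <- start(ex)[k + 1L] - 1L
                paint$intronic <- c(paint$intronic, list(c(is, ie)))
                paint$splicing <- c(paint$splicing,
                    list(c(is, min(is + spliceBp - 1L, ie))),
                    list(c(max(ie - spliceBp + 1L, is), ie)))
            }
        cdpos <- unlist(lapply(seq_along(cd), function(k)
            seq(start(cd)[k], end(cd)[k])))
        expos <- unlist(lapply(seq_along(ex), function(k)
            seq(start(ex)[k], end(ex)[k])))
        for (p in setdiff(expos, cdpos))
            paint$utr <- c(paint$utr, list(c(p, p)))
        for (p in cdpos) paint$exonic <- c(paint$exonic, list(c(p, p)))
    }
    for (cat in prec)
        for (iv in paint[[cat]]) mark(cat, iv[1L], iv[2L])
    lab
}

# codon effect oracle built by direct translation of full codons
codonOracle <- function(refCodon, posInCodon, altBase) {
    altCodon <- refCodon
    substr(altCodon, posInCodon, posInCodon) <- altBase
    tr <- function(cdn) as.character(suppressWarnings(
        Biostrings::translate(DNAString(cdn), no.init.codon = TRUE)))
    refAA <- tr(refCodon); altAA <- tr(altCodon)
    if (altAA == "*" && refAA != "*") "stopgain"
    else if (refAA == "*" && altAA != "*") "stoploss"
    else if (refAA == altAA) "synonymous"
    else "nonsynonymous"
}

# shared small simulation used by several suites (built once per session)
simBundleCache <- new.env()
getSimBundle <- function() {
    if (is.null(simBundleCache$sim)) {
        dir <- file.path(tempdir(), "macdiv-sim-shared")
        cfg <- simConfig(seed = 101L)
        simBundleCache$sim <- simulateDataset(cfg, dir)
    }
    simBundleCache$sim
}

getSimMerged <- function() {
    if (is.null(simBundleCache$merged)) {
        sim <- getSimBundle()
        ps <- lapply(sim$roster, function(s)
            readSampleVcf(sim$paths$vcf[[s]], s))
        names(ps) <- sim$roster
        simBundleCache$merged <- mergeSamples(ps, sim$roster, sim$seqlen)
    }
    simBundleCache$merged
}
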