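test_that("codon effects agree with the exhaustive 576-case oracle", {
    bases <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(bases, bases, bases), 1L, paste,
                    collapse = "")
    checked <- 0L
    for (cdn in codons) {
        for (p in 1:3) {
            for (a in setdiff(bases, substr(cdn, p, p))) {
                got <- codonEffect(cdn, p, a)
                expect_equal(got$effect, codonOracle(cdn, p, a),
                             info = paste(cdn, p, a))
                checked <- checked + 1L
            }
        }
    }
    expect_equal(checked, 576L)
})

test_that("region categories match a brute-force per-base label map", {
    tb <- toyGenomeBundle()
    oracle <- regionMapOracle(tb$genes, tb$seqlen[["chr1"]])
    set.seed(19)
    pos <- sample.int(tb$seqlen[["chr1"]], 200L)
    ref <- vapply(pos, function(p)
        as.character(subseq(tb$genome[["chr1"]], p, p)), "")
    alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    gr <- GRanges("chr1", IRanges(sort(pos), width = 1L))
    o <- order(pos)
    mcols(gr)$ref <- ref[o]
    mcols(gr)$alt <- alt[o]
    ann <- annotateVariants(gr, tb$genes, tb$genome)
    expect_equal(ann$region, oracle[sort(pos)])
})

test_that("splice-region calls respect the boundary distance", {
    tb <- toyGenomeBundle()
    # gA intron is 1103-1200; 2 bp into it is splicing at spliceBp = 2
    gr <- GRanges("chr1", IRanges(c(1104L, 1105L), width = 1L),
                  ref = "A", alt = "G")
    ann <- annotateVariants(gr, tb$genes, tb$genome, spliceBp = 2L)
    expect_equal(ann$region, c("splicing", "intronic"))
})

test_that("exonic effects are strand-aware with annotator-style notation", {
    # build a 4-exon plus-strand transcript whose codon 131 is GTG and
    # whose CDS base 391 (the G of that codon) mutates G>A to give V131M
    dir <- tempfile(); dir.create(dir)
    cdsSeq <- paste0("ATG", paste(rep("GCT", 129), collapse = ""),
                     "GTG", "TAA")   # 396 bases: codon 131 is GTG
    # exon/CDS layout: 4 exons of CDS lengths 100+100+100+96
    n <- 5000L
    set.seed(3)
    base <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
    starts <- c(1001L, 1301L, 1601L, 1901L)
    lens <- c(100L, 100L, 100L, 96L)
    off <- 0L
    for (k in 1:4) {
        substr(base, starts[k], starts[k] + lens[k] - 1L) <-
            substr(cdsSeq, off + 1L, off + lens[k])
        off <- off + lens[k]
    }
    fa <- file.path(dir, "g.fa")
    writeXStringSet(DNAStringSet(c(chr1 = base)), fa)
    genome <- readGenome(fa)
    gff <- c("##gff-version 3",
             "chr1\ttoy\tmRNA\t1001\t1996\t.\t+\t.\tID=tV",
             sprintf("chr1\ttoy\texon\t%d\t%d\t.\t+\t.\tParent=tV",
                     starts, starts + lens - 1L),
             sprintf("chr1\ttoy\tCDS\t%d\t%d\t.\t+\t0\tParent=tV",
                     starts, starts + lens - 1L))
    gp <- file.path(dir, "g.gff3"); writeLines(gff, gp)
    genes <- readGeneModels(gp, genome)
    # CDS position 391 = exon4 offset 90 -> genomic 1901 + 90 = 1991
    e <- exonicEffect("chr1", 1991L, "A", "tV", genes, genome)
    expect_equal(e$effect, "nonsynonymous")
    expect_equal(e$notation, "tV:exon4:c.G391A:p.V131M")
    expect_equal(e$refCodon, "GTG")
    expect_equal(e$altCodon, "ATG")
})

test_that("minus-strand transcripts mirror the plus-strand construction", {
    tb <- toyGenomeBundle()
    ti <- transcriptInfo(tb$genes)
    cds <- cdsByTx(tb$genes)[["gB.t1"]]
    # first coding base in transcription order is the genomic end of the
    # last CDS interval
    p1 <- max(end(cds))
    refG <- as.character(subseq(tb$genome[["chr1"]], p1, p1))
    altG <- setdiff(c("A", "C", "G", "T"), refG)[1L]
    e <- exonicEffect("chr1", p1, altG, "gB.t1", tb$genes, tb$genome)
    expect_equal(e$cdsPos, 1L)
    # oracle: reverse-complement arithmetic from first principles
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    gp <- rev(unlist(lapply(seq_along(cds), function(i)
        seq(start(cds)[i], end(cds)[i]))))
    codingSeq <- paste(unname(comp[vapply(gp[1:3], function(p)
        as.character(subseq(tb$genome[["chr1"]], p, p)), "")]),
        collapse = "")
    expect_equal(e$refCodon, codingSeq)
    expect_equal(e$effect,
                 codonOracle(codingSeq, 1L, unname(comp[altG])))
})

test_that("incomplete transcripts yield an unknown exonic effect", {
    dir <- tempfile(); dir.create(dir)
    set.seed(4)
    fa <- file.path(dir, "g.fa")
    writeXStringSet(DNAStringSet(c(chr1 = paste(
        sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
        collapse = ""))), fa)
    genome <- readGenome(fa)
    gff <- c("##gff-version 3",
             "chr1\ttoy\tmRNA\t101\t400\t.\t+\t.\tID=tI",
             "chr1\ttoy\texon\t101\t400\t.\t+\t.\tParent=tI",
             "chr1\ttoy\tCDS\t151\t250\t.\t+\t0\tParent=tI")  # 100 bp
    gp <- file.path(dir, "g.gff3"); writeLines(gff, gp)
    genes <- readGeneModels(gp, genome)
    gr <- GRanges("chr1", IRanges(200L, width = 1L), ref = "A", alt = "G")
    mcols(gr)$ref <- as.character(subseq(genome[["chr1"]], 200, 200))
    mcols(gr)$alt <- setdiff(c("A", "C", "G", "T"), mcols(gr)$ref)[1L]
    ann <- annotateVariants(gr, genes, genome)
    expect_equal(ann$region, "exonic")
    expect_equal(ann$effect, "unknown")
})

test_that("annotation tables partition regions and reconcile subtotals", {
    tb <- toyGenomeBundle()
    set.seed(29)
    pos <- sort(sample.int(tb$seqlen[["chr1"]], 400L))
    ref <- vapply(pos, function(p)
        as.character(subseq(tb$genome[["chr1"]], p, p)), "")
    alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    gr <- GRanges("chr1", IRanges(pos, width = 1L), ref = ref, alt = alt)
    ann <- annotateVariants(gr, tb$genes, tb$genome)
    tab <- tabulateAnnotation(ann)$regions
    cnt <- setNames(tab$count, tab$category)
    expect_equal(cnt[["intergenic"]] + cnt[["genic"]], cnt[["total"]])
    expect_equal(cnt[["genic"]],
                 sum(cnt[c("upstream_downstream", "exonic", "splicing",
                           "intronic", "utr", "ncRNA")]))
})
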