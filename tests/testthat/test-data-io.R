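test_that("readSampleVcf maps genotype states and flags multi-allelics", {
    p <- writeVcfText(tempfile(fileext = ".vcf"), "S1", c(
        vcfRow("chr1", 101, "A", "G", "0/1"),
        vcfRow("chr1", 202, "C", "T", "1/1"),
        vcfRow("chr1", 303, "G", "A", "1/0"),
        vcfRow("chr1", 404, "T", "C", "./."),
        vcfRow("chr1", 505, "A", "G,T", "1/2"),
        vcfRow("chr1", 606, "AT", "A", "0/1")))   # indel: dropped
    v <- readSampleVcf(p, "S1")
    expect_equal(start(v), c(101L, 202L, 303L, 404L, 505L))
    expect_equal(mcols(v)$gtCode, c(1L, 2L, 1L, NA, 1L))
    expect_equal(mcols(v)$multiallelic, c(FALSE, FALSE, FALSE, FALSE, TRUE))
    expect_equal(mcols(v)$alt[5L], "G")   # first ALT preserved on the flag
})

test_that("readSampleVcf rejects unknown samples and malformed records", {
    p <- writeVcfText(tempfile(fileext = ".vcf"), "S1",
                      vcfRow("chr1", 101, "A", "G", "0/1"))
    expect_error(readSampleVcf(p, "nope"), "not present")
    bad <- writeVcfText(tempfile(fileext = ".vcf"), "S1",
                        "chr1\tnotanumber\t.\tA")
    expect_error(readSampleVcf(bad, "S1"), "line")
})

test_that("mergeSamples takes the site union with hom-ref backfill", {
    a <- readSampleVcf(writeVcfText(tempfile(), "A",
        vcfRow("chr1", 100, "A", "G", "0/1")), "A")
    b <- readSampleVcf(writeVcfText(tempfile(), "B",
        vcfRow("chr1", 900, "C", "T", "1/1")), "B")
    m <- mergeSamples(list(A = a, B = b), c("A", "B"),
                      c(chr1 = 100000L, chr2 = 100000L))
    expect_equal(nVariants(m), 2L)
    expect_equal(unname(gtCodes(m)[, "A"]), c(1L, 0L))
    expect_equal(unname(gtCodes(m)[, "B"]), c(0L, 2L))
})

test_that("mergeSamples flags allele conflicts as triallelic", {
    a <- readSampleVcf(writeVcfText(tempfile(), "A",
        vcfRow("chr1", 500, "A", "G", "0/1")), "A")
    b <- readSampleVcf(writeVcfText(tempfile(), "B",
        vcfRow("chr1", 500, "A", "T", "0/1")), "B")
    m <- mergeSamples(list(A = a, B = b), c("A", "B"),
                      c(chr1 = 100000L))
    expect_equal(nVariants(m), 1L)
    expect_true(mcols(variantRanges(m))$triallelic)
})

test_that("mergeSamples respects per-sample callability", {
    a <- readSampleVcf(writeVcfText(tempfile(), "A",
        vcfRow("chr1", 700, "G", "A", "0/1")), "A")
    b <- readSampleVcf(writeVcfText(tempfile(), "B",
        vcfRow("chr1", 1700, "C", "T", "1/1")), "B")
    m <- mergeSamples(list(A = a, B = b), c("A", "B"), c(chr1 = 100000L),
        callable = list(B = GRanges("chr1", IRanges(1500, 2000))))
    # B has no call at 700 and 700 is outside B's callable track -> missing
    expect_equal(unname(gtCodes(m)[, "B"]), c(NA_integer_, 2L))
    expect_equal(unname(gtCodes(m)[, "A"]), c(1L, 0L))
})

test_that("mergeSamples is order-insensitive and checks chromosome naming", {
    set.seed(5)
    mk <- function(s, chrom, pos) readSampleVcf(writeVcfText(tempfile(), s,
        vapply(pos, function(p) vcfRow(chrom, p, "A", "G", "0/1"), ""),
        contigs = setNames(100000L, chrom)), s)
    a <- mk("A", "chr1", c(10, 50, 90))
    b <- mk("B", "chr1", c(50, 70))
    m1 <- mergeSamples(list(A = a, B = b), c("A", "B"), c(chr1 = 1000L))
    m2 <- mergeSamples(list(B = b, A = a), c("A", "B"), c(chr1 = 1000L))
    expect_identical(gtCodes(m1), gtCodes(m2))
    expect_identical(start(variantRanges(m1)), start(variantRanges(m2)))
    weird <- mk("C", "chrX", 10)
    expect_error(
        mergeSamples(list(A = a, C = weird), c("A", "C"), c(chr1 = 1000L)),
        "chrX")
})

test_that("merged VCF writing round-trips sites, alleles and genotypes", {
    set.seed(9)
    m <- randomToyMatrix(60, c("S1", "S2", "S3"))
    gt <- gtCodes(m)
    gt[c(3L, 10L)] <- NA_integer_
    mcols(m@rowRanges)$triallelic[5L] <- TRUE
    m <- GenotypeMatrix(variantRanges(m), gt)
    p <- tempfile(fileext = ".vcf")
    writeMergedVcf(m, p)
    m2 <- readMergedVcf(p)
    expect_identical(start(variantRanges(m2)), start(variantRanges(m)))
    expect_identical(mcols(variantRanges(m2))$ref,
                     mcols(variantRanges(m))$ref)
    expect_identical(mcols(variantRanges(m2))$alt,
                     mcols(variantRanges(m))$alt)
    expect_identical(mcols(variantRanges(m2))$triallelic,
                     mcols(variantRanges(m))$triallelic)
    expect_identical(gtCodes(m2), gtCodes(m))
})

test_that("gene models assemble with strand-aware completeness flags", {
    tb <- toyGenomeBundle()
    ti <- transcriptInfo(tb$genes)
    expect_setequal(ti$transcript_id, c("gA.t1", "gB.t1", "gC.t1"))
    expect_true(all(ti$complete[ti$transcript_id %in% c("gA.t1", "gB.t1")]))
    expect_false(ti$coding[ti$transcript_id == "gC.t1"])
    exA <- exonsByTx(tb$genes)[["gA.t1"]]
    expect_true(all(diff(start(exA)) > 0))   # genomic order, ascending
    # incomplete CDS (length 100) is retained but flagged
    d <- tempfile(); dir.create(d)
    gff <- c("##gff-version 3",
             "chr1\ttoy\tmRNA\t10\t400\t.\t+\t.\tID=tX",
             "chr1\ttoy\texon\t10\t400\t.\t+\t.\tParent=tX",
             "chr1\ttoy\tCDS\t101\t200\t.\t+\t0\tParent=tX")
    gp <- file.path(d, "x.gff3"); writeLines(gff, gp)
    gm <- readGeneModels(gp, tb$genome)
    expect_false(transcriptInfo(gm)$complete)
    expect_true(transcriptInfo(gm)$coding)
    # unknown chromosome -> error
    gff2 <- sub("chr1", "chr9", gff)
    gp2 <- file.path(d, "y.gff3"); writeLines(gff2, gp2)
    expect_error(readGeneModels(gp2, tb$genome), "chr9")
})

test_that("BED masks merge intervals and validate coordinates", {
    p <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t10\t20", "chr1\t15\t30"), p)
    gr <- readBedMask(p)
    expect_equal(length(gr), 1L)
    expect_equal(start(gr), 11L)   # 0-based half-open -> 1-based closed
    expect_equal(end(gr), 30L)
    writeLines(character(0), p)
    expect_equal(length(readBedMask(p)), 0L)
    writeLines("chr1\t5\t5", p)
    expect_error(readBedMask(p), "line 1")
})
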