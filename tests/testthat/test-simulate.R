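smallBranches <- function(mu) {
    data.frame(branch = c("root", "A", "B", "OG"),
               leaves = c("A,B,OG", "A", "B", "OG"),
               mu = mu, stringsAsFactors = FALSE)
}

test_that("zero intensities yield an empty but valid dataset", {
    d <- tempfile()
    cfg <- simConfig(branches = smallBranches(c(0, 0, 0, 0)),
                     roster = c("A", "B"), outgroup = "OG", nChroms = 1L,
                     chromLength = 50000L, geneCount = 4L, seed = 2L)
    sim <- simulateDataset(cfg, d)
    expect_equal(nrow(sim$truth), 0L)
    v <- readSampleVcf(sim$paths$vcf[["A"]], "A")
    expect_equal(length(v), 0L)
})

test_that("terminal-only mutations produce no shared carrier subsets", {
    d <- tempfile()
    cfg <- simConfig(branches = smallBranches(c(0, 40, 40, 0)),
                     roster = c("A", "B"), outgroup = "OG", nChroms = 1L,
                     chromLength = 100000L, geneCount = 4L, seed = 3L)
    sim <- simulateDataset(cfg, d)
    ps <- lapply(sim$roster, function(s)
        readSampleVcf(sim$paths$vcf[[s]], s))
    names(ps) <- sim$roster
    m <- mergeSamples(ps, sim$roster, sim$seqlen)
    sh <- sharingCounts(m)
    expect_setequal(sh$subset, c("A", "B"))
})

test_that("identical configs regenerate byte-identical outputs", {
    cfg <- simConfig(seed = 5L, nChroms = 1L, chromLength = 100000L,
                     geneCount = 6L)
    d1 <- tempfile(); d2 <- tempfile()
    s1 <- simulateDataset(cfg, d1)
    s2 <- simulateDataset(cfg, d2)
    for (f in c("fasta", "gff3", "mask", "truth")) {
        expect_identical(unname(tools::md5sum(s1$paths[[f]])),
                         unname(tools::md5sum(s2$paths[[f]])),
                         info = f)
    }
    expect_identical(unname(tools::md5sum(s1$paths$vcf)),
                     unname(tools::md5sum(s2$paths$vcf)))
})

test_that("carrier sets mirror the clades of the generating tree", {
    sim <- getSimBundle()
    m <- getSimMerged()
    sh <- sharingCounts(m)
    lv <- sim$branchLeaves
    ingroup <- vapply(lv, function(l)
        length(intersect(sim$roster, l)) > 0L, logical(1))
    subsetOf <- vapply(lv[ingroup], function(l)
        paste(intersect(sim$roster, l), collapse = "+"), "")
    # every observed subset is a clade...
    expect_true(all(sh$subset %in% subsetOf))
    # ...and each clade's count equals its branch mutation tallies
    tall <- table(factor(sim$truth$branch, levels = names(subsetOf)))
    agg <- tapply(as.integer(tall), subsetOf, sum)
    expect_equal(unname(sh$count[match(names(agg), sh$subset)]),
                 unname(as.integer(agg)))
    expect_equal(sum(sh$count), nVariants(m))
})

test_that("specific sets equal terminal-branch mutations after outgroup
           exclusion", {
    sim <- getSimBundle()
    m <- getSimMerged()
    for (s in c("CR1", "PM1", "TM1")) {
        spec <- specificSnvs(m, s, sim$outgroupSites)
        expect_equal(length(spec), sum(sim$truth$branch == s))
        specPos <- start(variantRanges(m))[spec]
        truthPos <- sim$truth$pos[sim$truth$branch == s]
        expect_setequal(paste(as.character(seqnames(variantRanges(m)))[spec],
                              specPos),
                        paste(sim$truth$chrom[sim$truth$branch == s],
                              truthPos))
    }
    specSm <- specificSnvs(m, c("SM1", "SM2"), sim$outgroupSites)
    expect_equal(length(specSm), sum(sim$truth$branch == "sm_pair"))
})

test_that("generated effect classes match the annotator on every CDS hit", {
    sim <- getSimBundle()
    m <- getSimMerged()
    genome <- readGenome(sim$paths$fasta)
    genes <- readGeneModels(sim$paths$gff3, genome)
    ann <- annotateVariants(m, genes, genome)
    key <- paste(ann$chrom, ann$pos)
    tkey <- paste(sim$truth$chrom, sim$truth$pos)
    tr <- sim$truth$effect[match(key, tkey)]
    cds <- which(!is.na(tr))
    expect_gt(length(cds), 20L)
    expect_equal(ann$effect[cds], tr[cds])
    expect_true(all(ann$region[cds] == "exonic"))
})

test_that("planted hotspots inflate their windows and get flagged", {
    d <- tempfile()
    hs <- data.frame(sample = "AM1", chrom = "chr1", startWindow = 11L,
                     endWindow = 11L, fold = 15, windowSize = 10000L,
                     stringsAsFactors = FALSE)
    cfg <- simConfig(seed = 7L, hotspots = hs)
    sim <- simulateDataset(cfg, d)
    ps <- lapply(sim$roster, function(s)
        readSampleVcf(sim$paths$vcf[[s]], s))
    names(ps) <- sim$roster
    m <- mergeSamples(ps, sim$roster, sim$seqlen)
    cm <- carrierMatrix(m)
    perSample <- lapply(sim$roster, function(s)
        variantRanges(m)[cm[, s]])
    names(perSample) <- sim$roster
    wm <- binCounts(perSample, sim$seqlen, windowSize = 10000L)
    inHot <- wm$chr1@counts[11L, "AM1"]
    outHot <- mean(wm$chr1@counts[-11L, "AM1"])
    expect_gt(inHot, 3 * outHot)
    res <- cooksOutliers(wm, 30)
    expect_true(res@flagged$chr1[11L, "AM1"])
})

test_that("infeasible mutation loads are rejected", {
    cfg <- simConfig(branches = smallBranches(c(0, 5000, 0, 0)),
                     roster = c("A", "B"), outgroup = "OG", nChroms = 1L,
                     chromLength = 1000L, geneCount = 1L, meanCdsLen = 60L,
                     seed = 8L)
    expect_error(simulateDataset(cfg, tempfile()), "more mutations")
})

test_that("planted effect variants satisfy their requested class by
           construction", {
    sim <- getSimBundle()
    genome <- readGenome(sim$paths$fasta)
    genes <- readGeneModels(sim$paths$gff3, genome)
    set.seed(91)
    for (cls in c("synonymous", "nonsynonymous", "stopgain", "stoploss")) {
        pv <- plantEffectVariants(genome, genes, cls, 10L)
        expect_equal(length(pv), 10L)
        expect_false(anyDuplicated(paste(seqnames(pv), start(pv),
                                         mcols(pv)$alt)) > 0L)
        ann <- annotateVariants(pv, genes, genome)
        expect_equal(ann$effect, rep(cls, 10L))
    }
})
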