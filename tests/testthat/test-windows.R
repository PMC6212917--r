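mkWindowMatrix <- function(counts, windowSize = 50000L, chrom = "chr1",
                           complete = NULL) {
    nw <- nrow(counts)
    if (is.null(complete)) complete <- rep(TRUE, nw)
    new("WindowMatrix", chrom = chrom, windowSize = as.integer(windowSize),
        counts = counts,
        windowStart = as.integer((seq_len(nw) - 1L) * windowSize + 1L),
        windowEnd = as.integer(seq_len(nw) * windowSize),
        complete = complete)
}

test_that("window binning fixes the grid and flags the partial tail", {
    ps <- list(S1 = GRanges("chr1", IRanges(c(1L, 50000L, 50001L, 110000L),
                                            width = 1L)))
    wm <- binCounts(ps, c(chr1 = 120000L), windowSize = 50000L)$chr1
    expect_equal(nrow(wm@counts), 3L)
    expect_equal(wm@complete, c(TRUE, TRUE, FALSE))
    expect_equal(wm@windowEnd[3L], 120000L)
    # positions 1 and 50000 share window 1; 50001 starts window 2
    expect_equal(unname(wm@counts[, "S1"]), c(2L, 1L, 1L))
})

test_that("window column sums conserve per-sample counts", {
    set.seed(41)
    for (i in 1:5) {
        ps <- lapply(1:3, function(k)
            GRanges("chr1", IRanges(sample.int(222000L, 150L), width = 1L)))
        names(ps) <- paste0("S", 1:3)
        wm <- binCounts(ps, c(chr1 = 222000L), windowSize = 50000L)$chr1
        expect_equal(unname(colSums(wm@counts)), rep(150L, 3L))
    }
    expect_error(binCounts(list(S1 = GRanges("chr1",
        IRanges(500L, width = 1L))), c(chr1 = 100L)), "beyond")
})

test_that("density outliers use the effective window length", {
    counts <- matrix(c(500L, 100L), 2L, 1L, dimnames = list(NULL, "S1"))
    wm <- mkWindowMatrix(counts, complete = c(TRUE, FALSE))
    wm@windowEnd[2L] <- wm@windowStart[2L] + 20000L - 1L   # 20 kb tail
    hits <- densityOutliers(list(chr1 = wm), 9.5)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$window, 1L)
    expect_equal(hits$ratePerKb, 10.0)    # 500 / 50 kb
    # partial window: 100 / 20 kb = 5.0, below threshold
    expect_equal(nrow(densityOutliers(list(chr1 = wm), 4.9)), 2L)
})

test_that("hat-matrix Cook's distances equal the leave-one-out refit", {
    set.seed(53)
    for (i in 1:200) {
        n <- sample(5:20, 1L)
        x <- rnorm(n)
        y <- 1 + 2 * x + rnorm(n)
        d1 <- cooksDistance(y, x)
        d2 <- looCooksOracle(y, x)
        expect_lt(max(abs(d1 - d2) / pmax(abs(d2), 1e-12)), 1e-9)
    }
})

test_that("Cook's distances cross-check against stats::cooks.distance", {
    set.seed(59)
    x <- rnorm(15); y <- 3 - x + rnorm(15)
    expect_equal(cooksDistance(y, x),
                 unname(stats::cooks.distance(stats::lm(y ~ x))),
                 tolerance = 1e-12)
})

test_that("a single-sample count spike is flagged against the consensus", {
    set.seed(61)
    counts <- matrix(rpois(40L * 4L, 20), 40L, 4L,
                     dimnames = list(NULL, c("S1", "S2", "S3", "S4")))
    counts[4L, 2L] <- counts[4L, 2L] + 200L
    res <- cooksOutliers(list(chr1 = mkWindowMatrix(counts)), 30)
    D <- res@distances$chr1
    # the spiked window dominates the spiked sample's fit...
    expect_true(res@flagged$chr1[4L, "S2"])
    # ...its distance equals the LOO-refit oracle value...
    x <- rowMeans(counts[, -2L]); y <- counts[, 2L]
    expect_equal(unname(D[4L, "S2"]), looCooksOracle(y, x)[4L],
                 tolerance = 1e-9)
    # ...and it alone exceeds 30x the mean in that fit
    expect_equal(unname(which(res@flagged$chr1[, "S2"])), 4L)
    fw <- flaggedWindows(res)
    expect_true(res@windowStart$chr1[4L] %in% start(fw))
})

test_that("degenerate fits and infinite multipliers flag nothing", {
    counts <- matrix(rep(c(5L, 7L, 9L, 11L, 13L), 3L), 5L, 3L,
                     dimnames = list(NULL, c("S1", "S2", "S3")))
    res <- cooksOutliers(list(chr1 = mkWindowMatrix(counts)), 30)
    expect_true(all(res@distances$chr1 == 0))
    expect_equal(length(flaggedWindows(res)), 0L)
    set.seed(67)
    counts2 <- matrix(rpois(24L, 30), 8L, 3L,
                      dimnames = list(NULL, c("S1", "S2", "S3")))
    counts2[2L, 1L] <- 300L
    res2 <- cooksOutliers(list(chr1 = mkWindowMatrix(counts2)), Inf)
    expect_equal(length(flaggedWindows(res2)), 0L)
})

test_that("flags are invariant under window order relabeling", {
    set.seed(71)
    counts <- matrix(rpois(30L, 25), 10L, 3L,
                     dimnames = list(NULL, c("S1", "S2", "S3")))
    counts[7L, 3L] <- 250L
    perm <- sample(10L)
    r1 <- cooksOutliers(list(chr1 = mkWindowMatrix(counts)), 30)
    r2 <- cooksOutliers(list(chr1 = mkWindowMatrix(
        counts[perm, , drop = FALSE])), 30)
    expect_equal(r1@flagged$chr1[perm, ], r2@flagged$chr1)
    expect_equal(r1@distances$chr1[perm, ], r2@distances$chr1,
                 tolerance = 1e-12)
})

test_that("short chromosomes are skipped with a warning", {
    counts <- matrix(1L, 3L, 2L, dimnames = list(NULL, c("S1", "S2")))
    expect_warning(res <- cooksOutliers(list(chr1 = mkWindowMatrix(counts)),
                                        30),
                   "fewer than 4")
    expect_equal(length(res@chroms), 0L)
})

test_that("outlier genes match a brute-force overlap oracle", {
    set.seed(73)
    tb <- toyGenomeBundle()
    counts <- matrix(rpois(40L * 4L, 15), 40L, 4L,
                     dimnames = list(NULL, c("S1", "S2", "S3", "S4")))
    counts[5L, 1L] <- 180L    # window 5 covers 1001-1250, inside gene gA
    res <- cooksOutliers(list(chr1 = mkWindowMatrix(counts, 250L)), 30)
    fw <- flaggedWindows(res)
    expect_gt(length(fw), 0L)
    nsPerSample <- list(
        S1 = GRanges("chr1", IRanges(c(1050L, 3050L), width = 1L)),
        S2 = GRanges("chr1", IRanges(6100L, width = 1L)),
        S3 = GRanges())
    og <- outlierGenes(res, tb$genes, nsPerSample)
    # naive O(n*m) oracle
    gr <- geneRanges(tb$genes)
    ns <- sort(unique(c(1050L, 3050L, 6100L)))
    expected <- character(0)
    for (i in seq_along(gr)) {
        hasNs <- any(ns >= start(gr)[i] & ns <= end(gr)[i])
        inWin <- any(start(fw) <= end(gr)[i] & end(fw) >= start(gr)[i])
        if (hasNs && inWin)
            expected <- c(expected, mcols(gr)$gene_id[i])
    }
    expect_setequal(og$gene_id, expected)
})
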