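#' Bin per-sample variant positions into non-overlapping windows
#'
#' Fixed, chromosome-anchored grid: window k (1-based) covers positions
#' \code{(k-1)*W + 1 .. k*W}; a chromosome whose length is not a multiple of
#' W gets a shorter terminal window flagged incomplete. Per-sample column
#' sums over a chromosome's windows equal that sample's variant count there.
#'
#' @param perSample named list of width-1 \code{GRanges} (one per sample),
#'   e.g. each sample's carried nsSNV positions.
#' @param seqlen named vector of chromosome lengths.
#' @param windowSize window width in bp (default 50000).
#' @return named list of \code{\link{WindowMatrix}}, one per chromosome.
#' @export
binCounts <- function(perSample, seqlen, windowSize = 50000L) {
    stopifnot(windowSize > 0L)
    windowSize <- as.integer(windowSize)
    samples <- names(perSample)
    out <- list()
    for (ch in names(seqlen)) {
        len <- as.integer(seqlen[[ch]])
        nw <- as.integer(ceiling(len / windowSize))
        ws <- (seq_len(nw) - 1L) * windowSize + 1L
        we <- pmin(seq_len(nw) * windowSize, len)
        counts <- matrix(0L, nw, length(samples),
                         dimnames = list(NULL, samples))
        for (s in samples) {
            gr <- perSample[[s]]
            p <- start(gr)[as.character(seqnames(gr)) == ch]
            if (length(p)) {
                if (max(p) > len)
                    stop("variant beyond length of ", ch)
                counts[, s] <- tabulate((p - 1L) %/% windowSize + 1L, nw)
            }
        }
        out[[ch]] <- new("WindowMatrix", chrom = ch,
                         windowSize = windowSize, counts = counts,
                         windowStart = ws, windowEnd = we,
                         complete = we - ws + 1L == windowSize)
    }
    out
}

#' Windows exceeding a per-kb variant density threshold
#'
#' Density uses the effective window length (a partial terminal window is
#' judged on its real width, not the nominal window size).
#'
#' @param wmList list of \code{WindowMatrix} from \code{\link{binCounts}}.
#' @param ratePerKb threshold in variants per kb.
#' @return \code{DataFrame} of (chrom, window, start, end, sample, count,
#'   ratePerKb) rows over the threshold.
#' @export
densityOutliers <- function(wmList, ratePerKb) {
    rows <- list()
    for (wm in wmList) {
        kb <- (wm@windowEnd - wm@windowStart + 1L) / 1000
        rate <- wm@counts / kb
        hit <- which(rate > ratePerKb, arr.ind = TRUE)
        if (nrow(hit))
            rows[[length(rows) + 1L]] <- DataFrame(
                chrom = wm@chrom, window = as.integer(hit[, 1L]),
                start = wm@windowStart[hit[, 1L]],
                end = wm@windowEnd[hit[, 1L]],
                sample = colnames(wm@counts)[hit[, 2L]],
                count = as.integer(wm@counts[hit]),
                ratePerKb = unname(round(rate[hit], 2)))
    }
    if (!length(rows))
        return(DataFrame(chrom = character(0), window = integer(0),
                         start = integer(0), end = integer(0),
                         sample = character(0), count = integer(0),
                         ratePerKb = numeric(0)))
    out <- do.call(rbind, rows)
    out[order(out$chrom, out$window, out$sample), , drop = FALSE]
}

#' Cook's distances of a simple linear regression
#'
#' Ordinary least squares of y on an intercept plus x, with each
#' observation's Cook's distance computed from the hat-matrix form
#' \code{D_i = e_i^2 / (p s^2) * h_ii / (1 - h_ii)^2}, p = 2. A perfect fit
#' (residual variance 0) makes the distances 0 by convention; a degenerate
#' predictor (zero spread in x) falls back to the intercept-only hat values.
#'
#' @param y response vector.
#' @param x predictor vector.
#' @return numeric vector of Cook's distances.
#' @export
cooksDistance <- function(y, x) {
    n <- length(y)
    p <- 2
    xbar <- mean(x)
    sxx <- sum((x - xbar)^2)
    if (sxx > 0) {
        beta <- sum((x - xbar) * (y - mean(y))) / sxx
        fit <- mean(y) + beta * (x - xbar)
        h <- 1 / n + (x - xbar)^2 / sxx
    } else {
        fit <- rep(mean(y), n)
        h <- rep(1 / n, n)
    }
    e <- y - fit
    s2 <- sum(e^2) / (n - p)
    if (!is.finite(s2) || s2 <= 0) return(rep(0, n))
    e^2 / (p * s2) * h / (1 - h)^2
}

#' Cook's-distance outlier windows
#'
#' Per chromosome and per sample j, regresses sample j's complete-window
#' counts on the leave-one-out mean of the other samples' counts (ordinary
#' least squares with intercept) and computes each window's Cook's distance;
#' a window is influential in that fit exactly when the sample's count there
#' departs from the cross-sample consensus. A window is flagged when its
#' distance exceeds \code{multiplier} times the mean distance of its fit;
#' the mean (hence the threshold) is per fit per chromosome. Chromosomes
#' with fewer than 4 complete windows are skipped with a warning; partial
#' terminal windows never enter the fits. A perfect fit (zero residual
#' variance) produces zero distances and no flags.
#'
#' @param wmList list of \code{WindowMatrix} from \code{\link{binCounts}};
#'   needs at least 2 samples.
#' @param multiplier threshold multiplier (default 30).
#' @return An \code{\link{OutlierResult}}.
#' @export
cooksOutliers <- function(wmList, multiplier = 30) {
    chroms <- distances <- thresholds <- flagged <- ws <- we <- list()
    wsize <- NA_integer_
    for (wm in wmList) {
        wsize <- wm@windowSize
        samples <- colnames(wm@counts)
        if (length(samples) < 2L)
            stop("Cook's-distance scan needs at least 2 samples")
        keep <- wm@complete
        cnt <- wm@counts[keep, , drop = FALSE]
        if (nrow(cnt) < 4L) {
            warning("skipping ", wm@chrom, ": fewer than 4 complete windows")
            next
        }
        D <- matrix(0, nrow(cnt), length(samples),
                    dimnames = list(NULL, samples))
        for (j in seq_along(samples)) {
            x <- rowMeans(cnt[, -j, drop = FALSE])
            D[, j] <- cooksDistance(cnt[, j], x)
        }
        thr <- multiplier * colMeans(D)
        fl <- sweep(D, 2L, thr, ">")
        fl[, colMeans(D) == 0] <- FALSE
        k <- length(chroms) + 1L
        chroms[[k]] <- wm@chrom
        distances[[k]] <- D
        thresholds[[k]] <- thr
        flagged[[k]] <- fl
        ws[[k]] <- wm@windowStart[keep]
        we[[k]] <- wm@windowEnd[keep]
    }
    nm <- unlist(chroms)
    names(distances) <- names(thresholds) <- names(flagged) <-
        names(ws) <- names(we) <- nm
    new("OutlierResult", chroms = as.character(nm), distances = distances,
        thresholds = thresholds, flagged = flagged, windowStart = ws,
        windowEnd = we, multiplier = multiplier,
        windowSize = if (is.na(wsize)) 50000L else wsize)
}

#' @rdname OutlierResult-class
#' @export
setMethod("flaggedWindows", "OutlierResult", function(x) {
    rows <- lapply(x@chroms, function(ch) {
        fl <- x@flagged[[ch]]
        any_fl <- rowSums(fl) > 0L
        if (!any(any_fl)) return(NULL)
        i <- which(any_fl)
        GRanges(ch, IRanges(x@windowStart[[ch]][i], x@windowEnd[[ch]][i]),
                maxD = apply(x@distances[[ch]][i, , drop = FALSE], 1L, max),
                samples = vapply(i, function(w)
                    paste(colnames(fl)[fl[w, ]], collapse = "+"), ""))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(GRanges(maxD = numeric(0),
                                      samples = character(0)))
    do.call(c, rows)
})

setMethod("show", "OutlierResult", function(object) {
    fw <- flaggedWindows(object)
    cat("OutlierResult over", length(object@chroms),
        "chromosome(s); multiplier =", object@multiplier, "\n")
    cat("flagged windows:", length(fw), "\n")
})

#' Write flagged outlier windows as BED
#'
#' BED is 0-based half-open; the score column carries the window's maximum
#' Cook's distance over the per-sample fits.
#'
#' @param res an \code{OutlierResult}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOutlierBed <- function(res, path) {
    fw <- flaggedWindows(res)
    lines <- sprintf("%s\t%d\t%d\t%s\t%.6g", as.character(seqnames(fw)),
                     start(fw) - 1L, end(fw), mcols(fw)$samples,
                     mcols(fw)$maxD)
    writeLines(lines, path)
    invisible(path)
}

#' Genes with nsSNVs in flagged outlier windows
#'
#' Reports each gene overlapping at least one flagged window and containing
#' at least one nonsynonymous SNV in at least one sample, with the flagged
#' windows it touches. A gene spanning several flagged windows is reported
#' once.
#'
#' @param res an \code{OutlierResult}.
#' @param genes a \code{GeneModelSet}.
#' @param nsPerSample named list of per-sample nsSNV position \code{GRanges}.
#' @return \code{DataFrame} with \code{gene_id} and comma-joined
#'   \code{windows}.
#' @export
outlierGenes <- function(res, genes, nsPerSample) {
    fw <- flaggedWindows(res)
    if (!length(fw))
        return(DataFrame(gene_id = character(0), windows = character(0)))
    gr <- geneRanges(genes)
    nsAll <- reduce(do.call(c, unname(lapply(nsPerSample, granges))))
    hasNs <- countOverlaps(gr, nsAll) > 0L
    ov <- findOverlaps(gr[hasNs], fw)
    if (!length(ov))
        return(DataFrame(gene_id = character(0), windows = character(0)))
    gid <- mcols(gr)$gene_id[hasNs][S4Vectors::queryHits(ov)]
    win <- paste0(as.character(seqnames(fw)), ":",
                  start(fw), "-", end(fw))[S4Vectors::subjectHits(ov)]
    byGene <- split(win, gid)
    DataFrame(gene_id = names(byGene),
              windows = vapply(byGene, function(w)
                  paste(unique(w), collapse = ","), ""))
}
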