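#' Read and validate a pipeline run configuration
#'
#' Configuration is a YAML file (or an equivalent named list) with fields:
#' \code{samples} (named map sample -> VCF path), \code{reference} (FASTA),
#' \code{gff3}, optional \code{outgroup_vcf} + \code{outgroup_sample},
#' optional \code{mask} (BED), \code{filters} (switches and
#' \code{proximity_bp}), \code{species_pairs} (list of 2-vectors of samples
#' summarized jointly), \code{window_size}, \code{multiplier},
#' \code{flank_bp}, \code{splice_bp}, optional \code{enrichment}
#' (\code{term_map}, optional \code{term_names}, \code{min_k},
#' \code{size_range}), \code{out_dir} and \code{seed}. Referenced paths are
#' checked at validation time, before any compute.
#'
#' @param config YAML path or named list.
#' @return validated config list with defaults filled in.
#' @export
readRunConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    need <- c("samples", "reference", "gff3", "out_dir")
    miss <- setdiff(need, names(config))
    if (length(miss))
        stop("config missing field(s): ", paste(miss, collapse = ", "))
    if (is.null(names(config$samples)) ||
        anyDuplicated(names(config$samples)))
        stop("config samples must be a uniquely named sample -> VCF map")
    defaults <- list(window_size = 50000L, multiplier = 30,
                     flank_bp = 1000L, splice_bp = 2L, seed = 1L,
                     filters = list())
    for (f in names(defaults))
        if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
    fdef <- list(drop_missing = TRUE, drop_triallelic = TRUE,
                 drop_cpg = TRUE, proximity_bp = 5L)
    for (f in names(fdef))
        if (is.null(config$filters[[f]])) config$filters[[f]] <- fdef[[f]]
    paths <- c(unlist(config$samples), config$reference, config$gff3,
               config$mask, config$outgroup_vcf,
               config$enrichment$term_map, config$enrichment$term_names)
    absent <- paths[!file.exists(paths)]
    if (length(absent))
        stop("config references missing file(s): ",
             paste(absent, collapse = ", "))
    config
}

writeTsv <- function(d, path) {
    utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full comparative SNV pipeline
#'
#' Orchestrates merge, filtering, carrier-set analysis, per-sample
#' summaries, functional annotation, windowed nsSNV outlier detection and
#' (when a term map is configured) enrichment of the outlier genes, writing
#' one TSV/BED per stage plus a machine-readable \code{manifest.json} with
#' per-stage counts, the echoed configuration and its hash. Outputs are pure
#' functions of (inputs, config, seed).
#'
#' @param config YAML path or list; see \code{\link{readRunConfig}}.
#' @return invisible list with the in-memory stage results and the manifest.
#' @export
runPipeline <- function(config) {
    cfg <- readRunConfig(config)
    outDir <- cfg$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(cfg$seed)
    stage <- function(name) message("[macdiv] stage: ", name)

    stage("load inputs")
    genome <- readGenome(cfg$reference)
    seqlen <- setNames(Biostrings::width(genome), names(genome))
    genes <- readGeneModels(cfg$gff3, genome)
    mask <- if (!is.null(cfg$mask)) readBedMask(cfg$mask) else GRanges()
    roster <- names(cfg$samples)
    perSample <- lapply(roster, function(s)
        readSampleVcf(cfg$samples[[s]], s))
    names(perSample) <- roster
    outgroupSites <- NULL
    if (!is.null(cfg$outgroup_vcf)) {
        ogv <- readSampleVcf(cfg$outgroup_vcf,
                             cfg$outgroup_sample %||% "outgroup")
        outgroupSites <- ogv[which(mcols(ogv)$gtCode >= GT_HET)]
    }

    stage("merge")
    merged <- mergeSamples(perSample, roster, seqlen)

    stage("filter")
    fp <- FilterParam(dropMissing = isTRUE(cfg$filters$drop_missing),
                      dropTriallelic = isTRUE(cfg$filters$drop_triallelic),
                      dropCpG = isTRUE(cfg$filters$drop_cpg),
                      proximityBp = cfg$filters$proximity_bp, mask = mask)
    filt <- applyFilters(merged, genome, fp)
    m <- filt$matrix
    writeTsv(filt$report, file.path(outDir, "filter_report.tsv"))

    stage("carrier sets")
    sharing <- sharingCounts(m)
    writeTsv(sharing, file.path(outDir, "sharing.tsv"))
    units <- c(as.list(roster), cfg$species_pairs)
    names(units) <- vapply(units, paste, "", collapse = "+")
    specific <- lapply(units, function(u)
        specificSnvs(m, unlist(u), outgroupSites))
    specificBySample <- specific[roster]

    stage("summaries")
    summ <- sampleSummaries(m, specificList = specificBySample)
    for (pr in cfg$species_pairs) {
        sh <- sharedWithinSpecies(m, pr[[1]], pr[[2]])
        ps <- sampleIds(sh)[length(sampleIds(sh))]
        summ <- rbind(summ, sampleSummary(sh, ps))
    }
    writeTsv(summ, file.path(outDir, "sample_summary.tsv"))

    stage("annotation")
    ann <- annotateVariants(m, genes, genome, flankBp = cfg$flank_bp,
                            spliceBp = cfg$splice_bp)
    tabs <- tabulateAnnotation(ann)
    writeTsv(tabs$regions, file.path(outDir, "annotation_regions.tsv"))
    writeTsv(tabs$effects, file.path(outDir, "annotation_effects.tsv"))

    stage("window outliers")
    cm <- carrierMatrix(m)
    nsIdx <- which(!is.na(ann$effect) & ann$effect == "nonsynonymous")
    nsPerSample <- lapply(roster, function(s)
        variantRanges(m)[nsIdx[cm[nsIdx, s]]])
    names(nsPerSample) <- roster
    wm <- binCounts(nsPerSample, seqlen, windowSize = cfg$window_size)
    outl <- withCallingHandlers(
        cooksOutliers(wm, multiplier = cfg$multiplier),
        warning = function(w) {
            message("[macdiv] ", conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    writeOutlierBed(outl, file.path(outDir, "outlier_windows.bed"))
    og <- outlierGenes(outl, genes, nsPerSample)
    writeTsv(og, file.path(outDir, "outlier_genes.tsv"))

    enr <- NULL
    if (!is.null(cfg$enrichment)) {
        stage("enrichment")
        tm <- readTermMap(cfg$enrichment$term_map,
                          unique(transcriptInfo(genes)$gene_id),
                          cfg$enrichment$term_names)
        enr <- enrich(og$gene_id, tm,
                      minK = cfg$enrichment$min_k %||% 3L,
                      sizeRange = unlist(cfg$enrichment$size_range %||%
                                         c(5L, 500L)))
        writeTsv(enr, file.path(outDir, "enrichment.tsv"))
    }

    stage("manifest")
    manifest <- list(
        package = "macdiv",
        version = as.character(utils::packageVersion("macdiv")),
        config = cfg,
        counts = list(
            input_sites = metadata(filt$report)$input,
            filtered_sites = metadata(filt$report)$output,
            removed = setNames(as.list(filt$report$removed),
                               filt$report$filter),
            sharing_subsets = nrow(sharing),
            specific = lapply(specific, length),
            nsSNVs = length(nsIdx),
            flagged_windows = length(flaggedWindows(outl)),
            outlier_genes = nrow(og),
            enriched_terms = if (is.null(enr)) NA else nrow(enr)))
    mpath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    manifest$hash <- unname(tools::md5sum(mpath))
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")

    invisible(list(matrix = m, report = filt$report, sharing = sharing,
                   specific = specific, summary = summ, annotation = ann,
                   tables = tabs, windows = wm, outliers = outl,
                   outlierGenes = og, enrichment = enr,
                   manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
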