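#' @include AllClasses.R AllGenerics.R utils.R io.R simulate.R
#' @include expression-stats.R popgen.R phasing.R effects.R
NULL

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Exactly one of
#' `input` (paths to expression/metadata/VCF files) or `simulation`
#' (arguments for [simulationConfig()]) must be given. All randomised
#' steps derive their seeds from the single `seed`.
#'
#' @param input `list(expression =, metadata =, vcf =, geneLengths = NULL,
#'   phased = NULL)` of file paths; `geneLengths` may be omitted when the
#'   VCF carries `##contig` lengths; `phased` supplies an externally
#'   phased table instead of the EM phaser.
#' @param simulation named list of [simulationConfig()] arguments.
#' @param nativeEnv native environment label (default `"JH"`).
#' @param edMetric Ed metric (default `"shannon"`).
#' @param ratioBand,edBand conservation bands (defaults `c(0.5, 2)`,
#'   `c(-0.25, 0.25)`).
#' @param minQual,maxMissing,minMaf SNP filter thresholds (defaults 10,
#'   0.10, 0.05; kept sites must be strictly beyond each threshold).
#' @param filterScope SNP filtering per environment (default) or joint.
#' @param maxSnps phasing SNP ceiling (default 9).
#' @param fdrMethod,alpha multiple-testing control (defaults `"storey"`,
#'   0.05).
#' @param significanceUse `"q"` (default) or `"p"` for effect flags and
#'   the eight-group classification.
#' @param epBins,piBins equal-count group counts (defaults 5, 4).
#' @param seed integer seed (default 1).
#' @param outputDir where [runPipeline()] writes results.
#' @return validated `PipelineConfig` (a classed list).
#' @export
pipelineConfig <- function(input = NULL, simulation = NULL,
                           nativeEnv = "JH", edMetric = "shannon",
                           ratioBand = c(0.5, 2), edBand = c(-0.25, 0.25),
                           minQual = 10, maxMissing = 0.10, minMaf = 0.05,
                           filterScope = "per_env", maxSnps = 9L,
                           fdrMethod = "storey", alpha = 0.05,
                           significanceUse = "q", epBins = 5L, piBins = 4L,
                           seed = 1L, outputDir = "popexpvar_results") {
    cfg <- list(input = input, simulation = simulation,
                nativeEnv = nativeEnv, edMetric = edMetric,
                ratioBand = ratioBand, edBand = edBand, minQual = minQual,
                maxMissing = maxMissing, minMaf = minMaf,
                filterScope = filterScope, maxSnps = as.integer(maxSnps),
                fdrMethod = fdrMethod, alpha = alpha,
                significanceUse = significanceUse,
                epBins = as.integer(epBins), piBins = as.integer(piBins),
                seed = as.integer(seed), outputDir = outputDir)
    class(cfg) <- "PipelineConfig"
    validatePipelineConfig(cfg)
    cfg
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @export
validatePipelineConfig <- function(config) {
    if (is.null(config$input) == is.null(config$simulation))
        stop("exactly one of 'input' and 'simulation' must be given")
    if (!is.null(config$input)) {
        need <- c("expression", "metadata", "vcf")
        miss <- setdiff(need, names(config$input))
        if (length(miss))
            stop("input lacks path(s): ", paste(miss, collapse = ", "))
        for (p in unlist(config$input[need]))
            if (!file.exists(p)) stop("input file not found: ", p)
    }
    stopifnot(config$minQual >= 0, config$maxMissing > 0,
              config$maxMissing <= 1, config$minMaf >= 0,
              config$minMaf < 0.5, config$alpha > 0, config$alpha < 1,
              config$maxSnps >= 1, config$epBins >= 2, config$piBins >= 2,
              length(config$ratioBand) == 2, diff(config$ratioBand) > 0,
              config$ratioBand[1] > 0,
              length(config$edBand) == 2, diff(config$edBand) > 0,
              config$filterScope %in% c("per_env", "joint"),
              config$fdrMethod %in% c("storey", "bh"),
              config$significanceUse %in% c("q", "p"),
              config$edMetric %in% c("shannon", "gini_simpson", "cv"))
    invisible(config)
}

#' Read a PipelineConfig from a YAML file
#'
#' Top-level keys are [pipelineConfig()] arguments; `input:` and
#' `simulation:` are nested mappings.
#'
#' @param path YAML file.
#' @return `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(y), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(pipelineConfig, y)
}

.logLine <- function(log, fmt, ...) {
    line <- sprintf(fmt, ...)
    message("popExpVar | ", line)
    c(log, line)
}

# ---------------------------------------------------------------------------
# stages: each consumes/produces the TSV/VCF interfaces so the pipeline is
# runnable piecewise; runPipeline() chains them in memory for speed but
# writes the identical tables
# ---------------------------------------------------------------------------

#' Pipeline stages
#'
#' Stage functions mirroring the subcommand layout of the analysis:
#' `simulateStage` writes a simulated dataset to disk;
#' `statsStage`, `diversityStage`, `phaseStage`, `effectsStage` and
#' `classifyStage` each read the standard file formats, run one analysis
#' step and write its result table. [runPipeline()] composes the same
#' computations end-to-end.
#'
#' @param config `PipelineConfig` (with a `simulation` block for
#'   `simulateStage`).
#' @param outDir output directory.
#' @return named list of written file paths (invisibly for stages).
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
simulateStage <- function(config, outDir = config$outputDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    simCfg <- do.call(simulationConfig,
                      c(config$simulation,
                        if (is.null(config$simulation$seed))
                            list(seed = deriveSeed(config$seed, 1L))))
    sim <- simulateDataset(simCfg)
    paths <- list(
        expression = file.path(outDir, "expression.tsv"),
        metadata = file.path(outDir, "metadata.tsv"),
        vcf = file.path(outDir, "snps.vcf"),
        truth = file.path(outDir, "truth.tsv"))
    writeExpressionMatrix(sim$expr, paths$expression)
    cd <- as.data.frame(colData(sim$expr))
    writeSampleMetadata(data.frame(sample_id = colnames(sim$expr),
                                   cd[c("population", "environment",
                                        "individual")],
                                   stringsAsFactors = FALSE),
                        paths$metadata)
    writeSNPVcf(sim$snps, paths$vcf)
    writeTsv(sim$truth, paths$truth, what = "simulation_truth", config = simCfg)
    invisible(c(paths, list(sim = sim)))
}

#' @rdname pipeline-stages
#' @param exprPath,metaPath,vcfPath,phasedPath input file paths.
#' @export
statsStage <- function(exprPath, metaPath, config,
                       outDir = config$outputDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    x <- readExpressionSet(exprPath, metaPath, config$nativeEnv)
    stats <- geneExpressionStats(x, edMetric = config$edMetric,
                                 ratioBand = config$ratioBand,
                                 edBand = config$edBand)
    out <- file.path(outDir, "gene_stats.tsv")
    writeTsv(as.data.frame(stats), out, what = "gene_stats", config = config)
    invisible(out)
}

#' @rdname pipeline-stages
#' @export
diversityStage <- function(exprPath, metaPath, vcfPath, config,
                           outDir = config$outputDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    x <- readExpressionSet(exprPath, metaPath, config$nativeEnv)
    snps <- readSNPVcf(vcfPath, config$input$geneLengths)
    div <- geneDiversity(snps, x, filterScope = config$filterScope,
                         minQual = config$minQual,
                         maxMissing = config$maxMissing,
                         minMaf = config$minMaf)
    out <- file.path(outDir, "gene_diversity.tsv")
    writeTsv(as.data.frame(div), out, what = "gene_diversity", config = config)
    invisible(out)
}

#' @rdname pipeline-stages
#' @export
phaseStage <- function(exprPath, metaPath, vcfPath, config,
                       outDir = config$outputDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    x <- readExpressionSet(exprPath, metaPath, config$nativeEnv)
    snps <- readSNPVcf(vcfPath, config$input$geneLengths)
    filtered <- filterSnps(snps, minQual = config$minQual,
                           maxMissing = config$maxMissing,
                           minMaf = config$minMaf)
    dip <- phaseAllGenes(filtered, individualId = individualId(x),
                         maxSnps = config$maxSnps,
                         seed = deriveSeed(config$seed, 4L))
    out <- file.path(outDir, "phased_haplotypes.tsv")
    writePhasedHaplotypes(dip, out, config = config)
    invisible(out)
}

#' Run the full analysis pipeline
#'
#' Executes (optional) simulation, expression filtering and statistics,
#' per-environment nucleotide diversity, phasing, the two ANOVA models
#' with FDR control, the nine- and eight-group classifications, and the
#' bin-comparison Wilcoxon tables; writes every result TSV, a run log with
#' before/after gene counts, and a machine-readable `summary.json` to
#' `config$outputDir`. Identical config + seed produces byte-identical
#' outputs.
#'
#' @param config `PipelineConfig`.
#' @return (invisibly) list with the in-memory results and the summary
#'   list.
#' @export
runPipeline <- function(config) {
    validatePipelineConfig(config)
    outDir <- config$outputDir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    log <- character(0)
    set.seed(config$seed)

    # --- inputs -----------------------------------------------------------
    if (!is.null(config$simulation)) {
        st <- simulateStage(config, outDir)
        x <- st$sim$expr
        snps <- st$sim$snps
        truth <- st$sim$truth
        phasedExternal <- NULL
        log <- .logLine(log, "simulated dataset: %d genes, %d samples",
                        nrow(x), ncol(x))
    } else {
        x <- readExpressionSet(config$input$expression, config$input$metadata,
                               config$nativeEnv)
        snps <- readSNPVcf(config$input$vcf, config$input$geneLengths)
        truth <- NULL
        phasedExternal <- config$input$phased
        log <- .logLine(log, "read dataset: %d genes, %d samples",
                        nrow(x), ncol(x))
    }

    # --- expression stats -------------------------------------------------
    nAll <- nrow(x)
    stats <- geneExpressionStats(x, edMetric = config$edMetric,
                                 ratioBand = config$ratioBand,
                                 edBand = config$edBand)
    log <- .logLine(log, "expression filter: %d -> %d genes (>= half expressed per env)",
                    nAll, nrow(stats))
    xKept <- x[stats$gene_id, ]
    writeTsv(as.data.frame(stats), file.path(outDir, "gene_stats.tsv"),
             what = "gene_stats", config = config)

    epCor <- correlateEp(stats$ep_native, stats$ep_new)
    nineCounts <- table(factor(stats$nine_group))

    # --- diversity --------------------------------------------------------
    snpsKept <- snps[intersect(stats$gene_id, geneIds(snps))]
    div <- geneDiversity(snpsKept, x, filterScope = config$filterScope,
                         minQual = config$minQual,
                         maxMissing = config$maxMissing,
                         minMaf = config$minMaf)
    writeTsv(as.data.frame(div), file.path(outDir, "gene_diversity.tsv"),
             what = "gene_diversity", config = config)
    nWith <- vapply(split(div$has_snp, div$environment), sum, numeric(1))
    log <- .logLine(log, "SNP filter (quality > %g, missing < %g, MAF > %g): genes with SNP per env: %s",
                    config$minQual, config$maxMissing, config$minMaf,
                    paste(names(nWith), nWith, sep = "=", collapse = ", "))

    # --- phasing ----------------------------------------------------------
    filtered <- filterSnps(snpsKept, minQual = config$minQual,
                           maxMissing = config$maxMissing,
                           minMaf = config$minMaf)
    ns <- nSnps(filtered)
    eligible <- sum(ns >= 1 & ns <= config$maxSnps)
    dip <- if (!is.null(phasedExternal)) {
        readPhasedHaplotypes(phasedExternal, filtered)
    } else if (eligible > 0L) {
        phaseAllGenes(filtered, individualId = individualId(x),
                      maxSnps = config$maxSnps,
                      seed = deriveSeed(config$seed, 4L))
    } else NULL
    nPhased <- if (is.null(dip)) 0L else length(dip)
    log <- .logLine(log, "phasing: %d genes eligible (1..%d SNPs), %d phased",
                    eligible, config$maxSnps, nPhased)
    if (!is.null(dip))
        writePhasedHaplotypes(dip, file.path(outDir, "phased_haplotypes.tsv"),
                              config = config)

    # --- effects ----------------------------------------------------------
    effPop <- fitAllGenes(xKept, model = "pop_env",
                          fdrMethod = config$fdrMethod, alpha = config$alpha)
    effHap <- if (!is.null(dip))
        tryCatch(fitAllGenes(xKept, diplotypes = dip, model = "hap_env",
                             fdrMethod = config$fdrMethod,
                             alpha = config$alpha),
                 error = function(e) NULL) else NULL
    writeTsv(as.data.frame(effPop), file.path(outDir, "effects_pop_env.tsv"),
             what = "effects_pop_env", config = config)
    if (!is.null(effHap))
        writeTsv(as.data.frame(effHap),
                 file.path(outDir, "effects_hap_env.tsv"),
                 what = "effects_hap_env", config = config)

    flagCol <- if (config$significanceUse == "q") "flag" else "flag_p"
    effCount <- function(eff, term) {
        if (is.null(eff)) return(NA_integer_)
        sum(eff[[flagCol]][eff$term == term])
    }
    nTested <- length(unique(effPop$gene_id))
    nTestedHap <- if (is.null(effHap)) 0L else length(unique(effHap$gene_id))
    log <- .logLine(log, "ANOVA pop_env: %d genes; hap_env: %d genes",
                    nTested, nTestedHap)

    # --- classifications --------------------------------------------------
    eight <- if (!is.null(effHap))
        classifyEightGroups(effHap, alpha = config$alpha,
                            use = config$significanceUse) else NULL
    cls <- data.frame(gene_id = stats$gene_id,
                      nine_group = stats$nine_group,
                      stringsAsFactors = FALSE)
    if (!is.null(eight))
        cls$eight_group <- eight$eight_group[match(cls$gene_id, eight$gene_id)]
    writeTsv(cls, file.path(outDir, "classifications.tsv"),
             what = "classifications", config = config)

    # --- bin-comparison Wilcoxon tables ----------------------------------
    wilcoxTables <- .binComparisons(stats, div, config)

    # --- summary ----------------------------------------------------------
    nativeE <- levels(envFactor(x))[1]; newE <- levels(envFactor(x))[2]
    divNat <- div[div$environment == nativeE, ]
    divNew <- div[div$environment == newE, ]
    summary <- list(
        n_genes_input = nAll,
        n_genes_filtered = nrow(stats),
        ep_correlation_r = epCor$r,
        ep_correlation_p = epCor$p,
        conserved_ep_percent = 100 * mean(stats$ep_class == "conserved",
                                          na.rm = TRUE),
        conserved_ed_percent = 100 * mean(stats$ed_class == "conserved",
                                          na.rm = TRUE),
        nine_group_counts = as.list(nineCounts),
        genes_with_snp = as.list(nWith),
        pi_range_native = if (any(divNat$has_snp))
            range(divNat$pi[divNat$has_snp]) else c(NA, NA),
        pi_mean_native = if (any(divNat$has_snp))
            mean(divNat$pi[divNat$has_snp]) else NA,
        pi_mean_new = if (any(divNew$has_snp))
            mean(divNew$pi[divNew$has_snp]) else NA,
        n_genes_phased = nPhased,
        effect_counts_pop_env = list(
            environment = effCount(effPop, "environment"),
            population = effCount(effPop, "population"),
            interaction = effCount(effPop, "interaction")),
        effect_counts_hap_env = list(
            environment = effCount(effHap, "environment"),
            haplotype = effCount(effHap, "haplotype"),
            interaction = effCount(effHap, "interaction")),
        eight_group_counts = if (!is.null(eight))
            as.list(table(eight$eight_group)) else NULL,
        wilcoxon_bin_tests = wilcoxTables,
        config_hash = configHash(config),
        seed = config$seed)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log, file.path(outDir, "run.log"))
    invisible(list(expr = x, stats = stats, diversity = div, diplotypes = dip,
                   effectsPop = effPop, effectsHap = effHap, eight = eight,
                   truth = truth, summary = summary))
}

# Wilcoxon comparisons across equal-count bins and SNP-presence groups
.binComparisons <- function(stats, div, config) {
    out <- list()
    ok <- !is.na(stats$ep_ratio)
    if (sum(ok) >= config$epBins * 2) {
        bins <- binEqualCount(stats$ep_native[ok], config$epBins)
        ratio <- stats$ep_ratio[ok]
        cmp <- list()
        for (i in seq_len(config$epBins - 1)) for (j in (i + 1):config$epBins) {
            w <- wilcoxonRankSum(ratio[bins == i], ratio[bins == j])
            cmp[[sprintf("ep_bin%d_vs_bin%d", i, j)]] <- w$p
        }
        out$ep_ratio_across_ep_bins <- cmp
    }
    nativeE <- unique(div$environment)[1]
    d <- div[div$environment == nativeE, ]
    m <- match(d$gene_id, stats$gene_id)
    epNat <- stats$ep_native[m]; edNat <- stats$ed_native[m]
    ratio <- stats$ep_ratio[m]
    if (any(d$has_snp) && any(!d$has_snp)) {
        out$snp_presence <- list(
            ep = wilcoxonRankSum(epNat[d$has_snp], epNat[!d$has_snp])$p,
            ed = wilcoxonRankSum(edNat[d$has_snp], edNat[!d$has_snp])$p,
            ep_ratio = wilcoxonRankSum(ratio[d$has_snp & !is.na(ratio)],
                                       ratio[!d$has_snp & !is.na(ratio)])$p)
    }
    withSnp <- which(d$has_snp)
    if (length(withSnp) >= config$piBins * 2) {
        piBins <- binEqualCount(d$pi[withSnp], config$piBins)
        cmp <- list()
        for (i in seq_len(config$piBins - 1)) for (j in (i + 1):config$piBins) {
            sel1 <- withSnp[piBins == i]; sel2 <- withSnp[piBins == j]
            cmp[[sprintf("pi_bin%d_vs_bin%d", i, j)]] <- list(
                ep = wilcoxonRankSum(epNat[sel1], epNat[sel2])$p,
                ed = wilcoxonRankSum(edNat[sel1], edNat[sel2])$p,
                ep_ratio = wilcoxonRankSum(ratio[sel1][!is.na(ratio[sel1])],
                                           ratio[sel2][!is.na(ratio[sel2])])$p)
        }
        out$across_pi_bins <- cmp
    }
    out
}
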