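#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Configuration of the synthetic transplant-design generator
#'
#' Holds every knob of the generative model behind [simulateDataset()]:
#' a balanced common-garden design of `nPopulations` source populations
#' with `indPerPop` genets each, every genet grown as one ramet per
#' environment (so genotype is identical across environments), expression
#' simulated on the log scale
#' `log(FPKM + 1) = mu_g + env + pop + hap(diplotype) + interaction + eps`,
#' and biallelic SNP haplotypes drawn under Hardy-Weinberg equilibrium.
#'
#' Defaults reproduce the 14-population x 2-environment design with 3
#' genets per population and effect prevalences matching a field
#' transplant experiment (environment 15.4\% of genes, population 3\%,
#' haplotype 19.9\% of SNP-bearing genes); effect sizes are expressed in
#' units of the residual log-scale SD.
#'
#' @slot nGenes number of genes.
#' @slot nPopulations source populations (default 14).
#' @slot indPerPop genets per population, each sampled in both
#'   environments (default 3).
#' @slot dropoutPerEnv samples discarded at random per environment
#'   (default 0; the field design lost 2 per site).
#' @slot envNames two environment labels, native first.
#' @slot baselineLogMean,baselineLogSd gene baseline `mu_g` distribution
#'   on the `log(FPKM+1)` scale.
#' @slot fracEnvEffect,fracPopEffect,fracInteraction fractions of genes
#'   carrying each planted effect.
#' @slot fracHapEffect fraction of SNP-bearing genes with a haplotype
#'   effect.
#' @slot effectSizeSdUnits planted shift in units of `residualLogSd`.
#' @slot residualLogSd residual SD of `log(FPKM+1)`.
#' @slot fracGenesWithSnps fraction of genes carrying SNPs.
#' @slot snpCountProbs probabilities of 1..9 SNPs for SNP-bearing genes.
#' @slot alleleFreqRange range the per-site minor-ish allele frequency is
#'   drawn from.
#' @slot geneLengthRange transcript length range (bp).
#' @slot missingRate per-genotype missingness in the emitted VCF.
#' @slot seed integer seed; the whole dataset is a pure function of the
#'   config.
#' @seealso [simulationConfig()], [simulateDataset()]
#' @export
setClass("SimulationConfig", representation(
    nGenes = "integer", nPopulations = "integer", indPerPop = "integer",
    dropoutPerEnv = "integer", envNames = "character",
    baselineLogMean = "numeric", baselineLogSd = "numeric",
    fracEnvEffect = "numeric", fracPopEffect = "numeric",
    fracHapEffect = "numeric", fracInteraction = "numeric",
    effectSizeSdUnits = "numeric", residualLogSd = "numeric",
    fracGenesWithSnps = "numeric", snpCountProbs = "numeric",
    alleleFreqRange = "numeric", geneLengthRange = "numeric",
    missingRate = "numeric", seed = "integer"
))

.validSimulationConfig <- function(object) {
    msg <- character()
    fr <- c(object@fracEnvEffect, object@fracPopEffect, object@fracHapEffect,
            object@fracInteraction, object@fracGenesWithSnps,
            object@missingRate)
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must be in [0, 1]")
    if (object@effectSizeSdUnits < 0) msg <- c(msg, "effect size must be >= 0")
    if (object@residualLogSd < 0) msg <- c(msg, "residual SD must be >= 0")
    if (length(object@envNames) != 2L || anyDuplicated(object@envNames))
        msg <- c(msg, "envNames must be two distinct labels")
    if (length(object@snpCountProbs) != 9L || any(object@snpCountProbs < 0) ||
        abs(sum(object@snpCountProbs) - 1) > 1e-9)
        msg <- c(msg, "snpCountProbs must be 9 probabilities summing to 1 (1..9 SNPs)")
    if (length(object@alleleFreqRange) != 2L ||
        any(object@alleleFreqRange <= 0 | object@alleleFreqRange >= 1) ||
        diff(object@alleleFreqRange) < 0)
        msg <- c(msg, "alleleFreqRange must be an increasing range inside (0, 1)")
    if (length(object@geneLengthRange) != 2L || any(object@geneLengthRange < 1))
        msg <- c(msg, "geneLengthRange must be positive")
    if (object@nGenes < 1L || object@nPopulations < 2L || object@indPerPop < 1L)
        msg <- c(msg, "need nGenes >= 1, nPopulations >= 2, indPerPop >= 1")
    if (object@dropoutPerEnv >= object@nPopulations * object@indPerPop)
        msg <- c(msg, "dropout would empty an environment")
    if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)

#' Build a SimulationConfig
#'
#' See [SimulationConfig-class] for the meaning of every field; arguments
#' not supplied take the study-design defaults documented there.
#'
#' @param nGenes,nPopulations,indPerPop,dropoutPerEnv design sizes.
#' @param envNames two environment labels, native first.
#' @param baselineLogMean,baselineLogSd baseline distribution.
#' @param fracEnvEffect,fracPopEffect,fracHapEffect,fracInteraction planted
#'   effect prevalences.
#' @param effectSizeSdUnits,residualLogSd effect scale and noise.
#' @param fracGenesWithSnps,snpCountProbs,alleleFreqRange,geneLengthRange,missingRate
#'   genetic architecture.
#' @param seed integer seed.
#' @return validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nGenes = 100, seed = 1)
#' sim <- simulateDataset(cfg)
#' sim$expr
#' @export
simulationConfig <- function(nGenes = 2000L, nPopulations = 14L,
                             indPerPop = 3L, dropoutPerEnv = 0L,
                             envNames = c("JH", "QG"),
                             baselineLogMean = 3, baselineLogSd = 1.5,
                             fracEnvEffect = 0.154, fracPopEffect = 0.030,
                             fracHapEffect = 0.199, fracInteraction = 0.05,
                             effectSizeSdUnits = 2, residualLogSd = 0.5,
                             fracGenesWithSnps = 0.47,
                             snpCountProbs = c(0.30, 0.20, 0.14, 0.10, 0.08,
                                               0.06, 0.05, 0.04, 0.03),
                             alleleFreqRange = c(0.05, 0.5),
                             geneLengthRange = c(300, 3000),
                             missingRate = 0.02, seed = 1L) {
    new("SimulationConfig",
        nGenes = as.integer(nGenes), nPopulations = as.integer(nPopulations),
        indPerPop = as.integer(indPerPop),
        dropoutPerEnv = as.integer(dropoutPerEnv),
        envNames = as.character(envNames),
        baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
        fracEnvEffect = fracEnvEffect, fracPopEffect = fracPopEffect,
        fracHapEffect = fracHapEffect, fracInteraction = fracInteraction,
        effectSizeSdUnits = effectSizeSdUnits, residualLogSd = residualLogSd,
        fracGenesWithSnps = fracGenesWithSnps,
        snpCountProbs = snpCountProbs / sum(snpCountProbs),
        alleleFreqRange = as.numeric(alleleFreqRange),
        geneLengthRange = as.numeric(geneLengthRange),
        missingRate = missingRate, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf("SimulationConfig: %d genes, %d pops x %d ind x 2 envs (%s), seed %d\n",
                object@nGenes, object@nPopulations, object@indPerPop,
                paste(object@envNames, collapse = "/"), object@seed))
})

# ---------------------------------------------------------------------------
# genotype simulation under HWE
# ---------------------------------------------------------------------------

#' Draw diplotypes and genotype codes under Hardy-Weinberg equilibrium
#'
#' Each individual receives two haplotypes drawn independently from
#' `hapFreqs` (HWE); the genotype code at each site is the sum of the two
#' haplotype alleles.
#'
#' @param hapFreqs named probability vector; names are haplotype strings
#'   over \{0,1\}, all of one length; must sum to 1 within 1e-9.
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return list with `hap1`, `hap2` (character vectors, canonical order
#'   `hap1 <= hap2`) and `geno` (sites x n integer matrix).
#' @examples
#' g <- simulateGenotypes(c(`0` = 0.5, `1` = 0.5), n = 10, seed = 1)
#' g$geno
#' @export
simulateGenotypes <- function(hapFreqs, n, seed = NULL) {
    if (!length(hapFreqs)) stop("empty haplotype pool")
    if (abs(sum(hapFreqs) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
    haps <- names(hapFreqs)
    if (is.null(haps) || any(grepl("[^01]", haps)) ||
        length(unique(nchar(haps))) != 1L)
        stop("haplotype names must be equal-length strings over {0,1}")
    if (!is.null(seed)) set.seed(seed)
    i1 <- sample.int(length(haps), n, replace = TRUE, prob = hapFreqs)
    i2 <- sample.int(length(haps), n, replace = TRUE, prob = hapFreqs)
    hapMat <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
    geno <- t(hapMat[i1, , drop = FALSE] + hapMat[i2, , drop = FALSE])
    h1 <- haps[i1]; h2 <- haps[i2]
    swap <- h1 > h2
    tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
    list(hap1 = h1, hap2 = h2, geno = geno)
}

# random haplotype pool for one gene: per-site allele frequencies drawn
# from `freqRange`, pool of K distinct haplotypes with Dirichlet(1) freqs
.randomHapPool <- function(nSites, freqRange, maxHaps = 4L) {
    K <- sample(2:maxHaps, 1L)
    p <- stats::runif(nSites, freqRange[1], freqRange[2])
    pool <- character(0)
    for (tries in 1:50) {
        h <- paste(stats::rbinom(nSites, 1L, p), collapse = "")
        pool <- unique(c(pool, h))
        if (length(pool) >= K) break
    }
    f <- stats::rexp(length(pool))
    stats::setNames(f / sum(f), pool)
}

# ---------------------------------------------------------------------------
# full dataset
# ---------------------------------------------------------------------------

#' Simulate a full common-garden population-transcriptome dataset
#'
#' Generates expression, metadata, per-gene SNP genotypes and a ground-truth
#' table under the model described in [SimulationConfig-class]. The same
#' genet keeps its genotype in both environments (ramets of one genet);
#' planted interaction effects act on environment x haplotype for
#' SNP-bearing genes and environment x population otherwise. FPKM is
#' `exp(y) - 1` truncated at zero, so low-baseline genes naturally produce
#' unexpressed (zero) cells for the expression filter to act on.
#'
#' @param config [SimulationConfig-class].
#' @return list with components
#'   \describe{
#'     \item{expr}{[PopExpressionSet-class]}
#'     \item{snps}{[SNPSet-class] (all simulated genes; zero-row tables for
#'       genes without SNPs)}
#'     \item{truth}{data.frame: per gene, planted-effect flags and sizes,
#'       SNP count, gene length, interaction type}
#'     \item{diplotypes}{[DiplotypeSet-class] of the true per-genet
#'       diplotypes for SNP-bearing genes}
#'     \item{hapPools}{named list of true haplotype frequency vectors}
#'   }
#' @export
simulateDataset <- function(config) {
    validObject(config)
    set.seed(config@seed)
    nP <- config@nPopulations; nI <- config@indPerPop
    envs <- config@envNames
    pops <- sprintf("P%02d", seq_len(nP))
    genets <- as.vector(outer(paste0(pops, "_I"), seq_len(nI), paste0))
    genetPop <- rep(pops, times = nI)
    meta <- data.frame(
        sample_id = as.vector(outer(genets, envs, paste, sep = "_")),
        population = rep(genetPop, 2L),
        environment = rep(envs, each = length(genets)),
        individual = rep(genets, 2L),
        stringsAsFactors = FALSE)
    if (config@dropoutPerEnv > 0L) {
        drop <- unlist(lapply(envs, function(e)
            sample(which(meta$environment == e), config@dropoutPerEnv)))
        meta <- meta[-drop, , drop = FALSE]
    }
    nSamp <- nrow(meta)
    genes <- sprintf("g%05d", seq_len(config@nGenes))
    sdE <- config@effectSizeSdUnits * config@residualLogSd

    # which genes carry what
    nG <- config@nGenes
    pick <- function(frac, from = genes) {
        k <- round(frac * length(from))
        if (k == 0L) character(0) else sample(from, k)
    }
    snpGenes <- pick(config@fracGenesWithSnps)
    envGenes <- pick(config@fracEnvEffect)
    popGenes <- pick(config@fracPopEffect)
    hapGenes <- pick(config@fracHapEffect, from = snpGenes)
    intGenes <- pick(config@fracInteraction)

    # genetic architecture
    hapPools <- list(); trueDip <- list(); snpData <- list()
    geneLen <- stats::setNames(
        as.integer(round(stats::runif(nG, config@geneLengthRange[1],
                                      config@geneLengthRange[2]))), genes)
    nSnpVec <- stats::setNames(integer(nG), genes)
    for (g in snpGenes) {
        s <- sample.int(9L, 1L, prob = config@snpCountProbs)
        nSnpVec[g] <- s
        pool <- .randomHapPool(s, config@alleleFreqRange)
        hapPools[[g]] <- pool
        gt <- simulateGenotypes(pool, length(genets))
        trueDip[[g]] <- data.frame(sample_id = genets, hap1 = gt$hap1,
                                   hap2 = gt$hap2, posterior = 1,
                                   stringsAsFactors = FALSE)
        geno <- gt$geno  # sites x genets; same genet in both envs
        genoSamp <- geno[, match(meta$individual, genets), drop = FALSE]
        if (config@missingRate > 0) {
            miss <- matrix(stats::runif(length(genoSamp)) < config@missingRate,
                           nrow(genoSamp))
            genoSamp[miss] <- NA_integer_
        }
        pos <- sort(sample.int(geneLen[[g]], s))
        snpData[[g]] <- list(position = pos,
                             quality = round(stats::runif(s, 25, 60), 1),
                             geno = genoSamp)
    }
    for (g in setdiff(genes, snpGenes))
        snpData[[g]] <- list(position = integer(0), quality = numeric(0),
                             geno = matrix(integer(0), 0L, nSamp))
    snpData <- snpData[genes]
    snps <- SNPSet(snpData, geneLen, meta$sample_id)

    # expression model
    mu <- stats::rnorm(nG, config@baselineLogMean, config@baselineLogSd)
    names(mu) <- genes
    envBeta <- stats::setNames(numeric(nG), genes)
    envBeta[envGenes] <- sample(c(-1, 1), length(envGenes), TRUE) * sdE
    popEff <- matrix(0, nG, nP, dimnames = list(genes, pops))
    popEff[popGenes, ] <- stats::rnorm(length(popGenes) * nP, 0, sdE)
    hapEff <- list()
    for (g in hapGenes) {
        haps <- names(hapPools[[g]])
        hapEff[[g]] <- stats::setNames(stats::rnorm(length(haps), 0, sdE / sqrt(2)),
                                       haps)
    }
    intType <- stats::setNames(rep("none", nG), genes)
    intEff <- list()
    for (g in intGenes) {
        if (g %in% snpGenes) {
            intType[g] <- "env_x_hap"
            haps <- names(hapPools[[g]])
            e <- stats::rnorm(length(haps), 0, sdE / sqrt(2))
            intEff[[g]] <- stats::setNames(e - mean(e), haps)
        } else {
            intType[g] <- "env_x_pop"
            e <- stats::rnorm(nP, 0, sdE)
            intEff[[g]] <- stats::setNames(e - mean(e), pops)
        }
    }

    isNew <- as.numeric(meta$environment == envs[2])
    popIdx <- match(meta$population, pops)
    y <- matrix(0, nG, nSamp, dimnames = list(genes, meta$sample_id))
    y <- y + mu + outer(envBeta, isNew) + popEff[, popIdx, drop = FALSE]
    for (g in names(hapEff)) {
        d <- trueDip[[g]][match(meta$individual, genets), ]
        y[g, ] <- y[g, ] + hapEff[[g]][d$hap1] + hapEff[[g]][d$hap2]
    }
    for (g in intGenes) {
        if (intType[g] == "env_x_hap" && g %in% names(trueDip)) {
            d <- trueDip[[g]][match(meta$individual, genets), ]
            y[g, ] <- y[g, ] + isNew * (intEff[[g]][d$hap1] + intEff[[g]][d$hap2])
        } else if (intType[g] == "env_x_pop") {
            y[g, ] <- y[g, ] + isNew * intEff[[g]][popIdx]
        }
    }
    if (config@residualLogSd > 0)
        y <- y + matrix(stats::rnorm(nG * nSamp, 0, config@residualLogSd),
                        nG, nSamp)
    fpkmMat <- pmax(exp(y) - 1, 0)

    expr <- PopExpressionSet(fpkmMat, population = meta$population,
                             environment = meta$environment,
                             individual = meta$individual,
                             nativeEnv = envs[1])
    truth <- data.frame(
        gene_id = genes,
        has_env_effect = genes %in% envGenes,
        has_pop_effect = genes %in% popGenes,
        has_hap_effect = genes %in% hapGenes,
        has_interaction = genes %in% intGenes,
        interaction_type = unname(intType),
        env_beta = unname(envBeta),
        n_snps = unname(nSnpVec),
        gene_length = unname(geneLen),
        stringsAsFactors = FALSE)
    dipSet <- if (length(trueDip)) DiplotypeSet(trueDip, hapFreqs = hapPools)
              else NULL
    list(expr = expr, snps = snps, truth = truth, diplotypes = dipSet,
         hapPools = hapPools)
}
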