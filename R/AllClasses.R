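#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

# ---------------------------------------------------------------------------
# PopExpressionSet
# ---------------------------------------------------------------------------

#' Population expression experiment across two common-garden environments
#'
#' `PopExpressionSet` extends [SummarizedExperiment::SummarizedExperiment]
#' for a genes-by-samples FPKM matrix from a reciprocal/common-garden
#' transplant design: every sample carries a source population, a growth
#' environment (exactly two levels, one designated *native* — the
#' denominator of cross-environment ratios), and an individual (genet)
#' identifier linking the ramets of the same plant grown in both
#' environments.
#'
#' @slot (inherited) assays a single assay named `"fpkm"`, non-negative.
#'
#' @section Validity:
#' * one assay named `"fpkm"`, all values finite and `>= 0`;
#' * no duplicated gene or sample identifiers;
#' * `colData` columns `population`, `environment`, `individual`;
#' * exactly two environment levels, both non-empty;
#' * `metadata(x)$nativeEnv` is one of the two environment levels.
#'
#' @seealso [PopExpressionSet()] (constructor), [fpkm()], [envFactor()],
#'   [popFactor()], [nativeEnv()]
#' @export
setClass("PopExpressionSet", contains = "SummarizedExperiment")

.validPopExpressionSet <- function(object) {
    msg <- character()
    if (!identical(assayNames(object), "fpkm"))
        msg <- c(msg, "must have exactly one assay, named 'fpkm'")
    else {
        v <- assay(object, "fpkm")
        if (anyNA(v) || any(!is.finite(v)))
            msg <- c(msg, "FPKM values must be finite and non-missing")
        else if (any(v < 0))
            msg <- c(msg, "FPKM values must be non-negative")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicated gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample identifiers")
    cd <- colData(object)
    need <- c("population", "environment", "individual")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        envs <- unique(as.character(cd$environment))
        if (length(envs) != 2L)
            msg <- c(msg, sprintf("need exactly 2 environment levels, found %d",
                                  length(envs)))
        ne <- metadata(object)$nativeEnv
        if (is.null(ne) || length(ne) != 1L || !(ne %in% envs))
            msg <- c(msg, "metadata(x)$nativeEnv must name one of the environment levels")
    }
    if (length(msg)) msg else TRUE
}
setValidity("PopExpressionSet", .validPopExpressionSet)

#' Construct a PopExpressionSet
#'
#' @param fpkm numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs); non-negative FPKM.
#' @param population character/factor of source populations, one per sample.
#' @param environment character/factor of growth environments, one per
#'   sample; exactly two levels.
#' @param individual identifier linking the two ramets of one genet across
#'   environments; defaults to the sample names.
#' @param nativeEnv which environment level is the native habitat (ratio
#'   denominator).
#' @return A validated [PopExpressionSet-class] object.
#' @examples
#' m <- matrix(rexp(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' pes <- PopExpressionSet(m, population = c("P1", "P1", "P2", "P2"),
#'                         environment = c("JH", "QG", "JH", "QG"),
#'                         individual = c("i1", "i1", "i2", "i2"),
#'                         nativeEnv = "JH")
#' nativeEnv(pes)
#' @export
PopExpressionSet <- function(fpkm, population, environment,
                             individual = colnames(fpkm), nativeEnv) {
    fpkm <- as.matrix(fpkm)
    storage.mode(fpkm) <- "double"
    cd <- DataFrame(population = as.character(population),
                    environment = as.character(environment),
                    individual = as.character(individual),
                    row.names = colnames(fpkm))
    se <- SummarizedExperiment(assays = list(fpkm = fpkm), colData = cd)
    metadata(se)$nativeEnv <- nativeEnv
    new("PopExpressionSet", se)
}

#' @rdname popExpVar-generics
#' @export
setMethod("fpkm", "PopExpressionSet", function(x, ...) assay(x, "fpkm"))

#' @rdname popExpVar-generics
#' @export
setMethod("popFactor", "PopExpressionSet", function(x, ...)
    factor(colData(x)$population))

#' @rdname popExpVar-generics
#' @export
setMethod("envFactor", "PopExpressionSet", function(x, ...) {
    e <- as.character(colData(x)$environment)
    # native level first so the second level is the transplant environment
    factor(e, levels = c(nativeEnv(x), setdiff(unique(e), nativeEnv(x))))
})

#' @rdname popExpVar-generics
#' @export
setMethod("individualId", "PopExpressionSet", function(x, ...)
    as.character(colData(x)$individual))

#' @rdname popExpVar-generics
#' @export
setMethod("nativeEnv", "PopExpressionSet", function(x, ...)
    metadata(x)$nativeEnv)

#' @rdname popExpVar-generics
#' @export
setMethod("newEnv", "PopExpressionSet", function(x, ...) {
    setdiff(unique(as.character(colData(x)$environment)), nativeEnv(x))
})

setMethod("show", "PopExpressionSet", function(object) {
    ef <- envFactor(object)
    cat("PopExpressionSet:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  environments:", paste(levels(ef), table(ef), sep = "=", collapse = ", "),
        " (native:", nativeEnv(object), ")\n")
    cat("  populations:", nlevels(popFactor(object)), "\n")
})

# ---------------------------------------------------------------------------
# SNPSet
# ---------------------------------------------------------------------------

#' Per-gene biallelic SNP genotypes in transcript coordinates
#'
#' Container for filtered or unfiltered SNP genotype tables, one per gene.
#' Genotypes are diploid allele-dosage codes: 0 and 2 homozygous reference /
#' alternate, 1 heterozygous, `NA` missing. Positions are 1-based transcript
#' coordinates; `geneLengths` holds the transcript length used as the
#' denominator of nucleotide diversity.
#'
#' @slot geneIds character, one per gene.
#' @slot geneLengths integer, named by gene, all `> 0`.
#' @slot sampleIds character, the common sample ordering of all genotype
#'   matrices.
#' @slot snpData named list, one entry per gene: `list(position, quality,
#'   geno)` with `geno` a sites x samples integer matrix.
#' @export
setClass("SNPSet", representation(
    geneIds = "character",
    geneLengths = "integer",
    sampleIds = "character",
    snpData = "list"
))

.validSNPSet <- function(object) {
    msg <- character()
    g <- object@geneIds
    if (anyDuplicated(g)) msg <- c(msg, "duplicated gene IDs")
    if (!identical(sort(names(object@geneLengths)), sort(g)) ||
        !identical(sort(names(object@snpData)), sort(g)))
        msg <- c(msg, "geneLengths/snpData names must match geneIds")
    if (any(object@geneLengths <= 0L, na.rm = TRUE))
        msg <- c(msg, "gene lengths must be positive")
    ns <- length(object@sampleIds)
    for (gid in g) {
        d <- object@snpData[[gid]]
        L <- object@geneLengths[[gid]]
        s <- length(d$position)
        if (length(d$quality) != s || !identical(dim(d$geno), c(s, ns))) {
            msg <- c(msg, sprintf("gene %s: inconsistent SNP table shape", gid))
            next
        }
        if (s > 0L) {
            if (any(d$position < 1L | d$position > L))
                msg <- c(msg, sprintf("gene %s: SNP position outside [1, length]", gid))
            if (s > 1L && any(diff(d$position) <= 0L))
                msg <- c(msg, sprintf("gene %s: positions not strictly increasing", gid))
            if (!all(d$geno %in% c(0L, 1L, 2L, NA)))
                msg <- c(msg, sprintf("gene %s: invalid genotype code", gid))
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("SNPSet", .validSNPSet)

#' Construct an SNPSet
#'
#' @param snpData named list (by gene) of `list(position, quality, geno)`;
#'   `geno` is a sites x samples matrix of codes in \{0, 1, 2, NA\}. Genes
#'   without SNPs use zero-row matrices.
#' @param geneLengths named integer/numeric vector of transcript lengths
#'   covering every gene in `snpData`.
#' @param sampleIds sample ordering shared by all genotype matrices.
#' @return A validated [SNPSet-class].
#' @export
SNPSet <- function(snpData, geneLengths, sampleIds) {
    geneIds <- names(snpData)
    gl <- geneLengths[geneIds]
    storage.mode(gl) <- "integer"
    names(gl) <- geneIds
    snpData <- lapply(snpData, function(d) {
        d$position <- as.integer(d$position)
        d$quality <- as.numeric(d$quality)
        geno <- d$geno
        storage.mode(geno) <- "integer"
        dimnames(geno) <- list(NULL, sampleIds)
        list(position = d$position, quality = d$quality, geno = geno)
    })
    new("SNPSet", geneIds = geneIds, geneLengths = gl,
        sampleIds = as.character(sampleIds), snpData = snpData)
}

#' @rdname popExpVar-generics
#' @export
setMethod("geneIds", "SNPSet", function(x, ...) x@geneIds)

#' @rdname popExpVar-generics
#' @export
setMethod("geneLengths", "SNPSet", function(x, ...) x@geneLengths)

#' @rdname popExpVar-generics
#' @export
setMethod("nSnps", "SNPSet", function(x, ...)
    vapply(x@snpData, function(d) length(d$position), integer(1)))

#' @rdname popExpVar-generics
#' @export
setMethod("snpGenotypes", "SNPSet", function(x, gene, ...) x@snpData[[gene]]$geno)

#' @rdname popExpVar-generics
#' @export
setMethod("snpPositions", "SNPSet", function(x, gene, ...) x@snpData[[gene]]$position)

#' @rdname popExpVar-generics
#' @export
setMethod("snpQuality", "SNPSet", function(x, gene, ...) x@snpData[[gene]]$quality)

#' @export
setMethod("length", "SNPSet", function(x) length(x@geneIds))

#' Subset an SNPSet by gene
#' @param x An [SNPSet-class].
#' @param i gene IDs or indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SNPSet", function(x, i, j, ..., drop = FALSE) {
    ids <- if (is.character(i)) i else x@geneIds[i]
    new("SNPSet", geneIds = ids, geneLengths = x@geneLengths[ids],
        sampleIds = x@sampleIds, snpData = x@snpData[ids])
})

setMethod("show", "SNPSet", function(object) {
    ns <- nSnps(object)
    cat("SNPSet:", length(object), "genes,", length(object@sampleIds),
        "samples,", sum(ns), "SNPs\n")
    if (length(ns))
        cat("  SNPs/gene: min", min(ns), "median", stats::median(ns),
            "max", max(ns), "\n")
})

# ---------------------------------------------------------------------------
# DiplotypeSet
# ---------------------------------------------------------------------------

#' Per-gene haplotype-pair (diplotype) reconstructions
#'
#' Result of EM phasing ([phaseAllGenes()]) or of reading an externally
#' phased best-guess table ([readPhasedHaplotypes()]). Haplotypes are
#' strings over \{0, 1\} across a gene's (filtered) SNP sites; each
#' individual carries an unordered pair, stored in canonical
#' (lexicographically sorted) order.
#'
#' @slot geneIds character.
#' @slot assignments named list of per-gene data.frames with columns
#'   `sample_id`, `hap1`, `hap2`, `posterior`.
#' @slot hapFreqs named list of per-gene named frequency vectors
#'   (sum to 1 within 1e-9).
#' @slot logLik named numeric, per-gene reconstruction log-likelihood
#'   (`NA` for externally phased input).
#' @export
setClass("DiplotypeSet", representation(
    geneIds = "character",
    assignments = "list",
    hapFreqs = "list",
    logLik = "numeric"
))

.validDiplotypeSet <- function(object) {
    msg <- character()
    g <- object@geneIds
    if (anyDuplicated(g)) msg <- c(msg, "duplicated gene IDs")
    if (!identical(sort(names(object@assignments)), sort(g)))
        msg <- c(msg, "assignments names must match geneIds")
    for (gid in g) {
        a <- object@assignments[[gid]]
        if (!all(c("sample_id", "hap1", "hap2") %in% colnames(a))) {
            msg <- c(msg, sprintf("gene %s: assignment lacks required columns", gid))
            next
        }
        if (any(grepl("[^01]", c(a$hap1, a$hap2))))
            msg <- c(msg, sprintf("gene %s: haplotype alleles must be 0/1", gid))
        if (any(a$hap1 > a$hap2))
            msg <- c(msg, sprintf("gene %s: haplotype pairs not in canonical order", gid))
        f <- object@hapFreqs[[gid]]
        if (!is.null(f) && abs(sum(f) - 1) > 1e-9)
            msg <- c(msg, sprintf("gene %s: haplotype frequencies do not sum to 1", gid))
    }
    if (length(msg)) msg else TRUE
}
setValidity("DiplotypeSet", .validDiplotypeSet)

#' Construct a DiplotypeSet
#'
#' @param assignments named list (by gene) of data.frames with columns
#'   `sample_id`, `hap1`, `hap2` and optionally `posterior`; pairs are
#'   canonicalised (sorted) here.
#' @param hapFreqs named list of per-gene named haplotype frequency vectors;
#'   estimated from the assignments when omitted.
#' @param logLik named numeric of per-gene log-likelihoods (`NA` allowed).
#' @return A validated [DiplotypeSet-class].
#' @export
DiplotypeSet <- function(assignments, hapFreqs = NULL, logLik = NULL) {
    geneIds <- names(assignments)
    assignments <- lapply(assignments, function(a) {
        a <- as.data.frame(a, stringsAsFactors = FALSE)
        swap <- a$hap1 > a$hap2
        tmp <- a$hap1[swap]; a$hap1[swap] <- a$hap2[swap]; a$hap2[swap] <- tmp
        if (is.null(a$posterior)) a$posterior <- NA_real_
        rownames(a) <- NULL
        a[c("sample_id", "hap1", "hap2", "posterior")]
    })
    if (is.null(hapFreqs)) {
        hapFreqs <- lapply(assignments, function(a) {
            tab <- table(c(a$hap1, a$hap2))
            f <- as.numeric(tab) / sum(tab)
            names(f) <- names(tab)
            f
        })
    }
    if (is.null(logLik)) {
        logLik <- rep(NA_real_, length(geneIds))
        names(logLik) <- geneIds
    }
    new("DiplotypeSet", geneIds = geneIds, assignments = assignments,
        hapFreqs = hapFreqs[geneIds], logLik = logLik[geneIds])
}

#' @rdname popExpVar-generics
#' @export
setMethod("geneIds", "DiplotypeSet", function(x, ...) x@geneIds)

#' @rdname popExpVar-generics
#' @export
setMethod("assignments", "DiplotypeSet", function(x, ...) x@assignments)

#' @rdname popExpVar-generics
#' @export
setMethod("hapFreqs", "DiplotypeSet", function(x, ...) x@hapFreqs)

#' @export
setMethod("length", "DiplotypeSet", function(x) length(x@geneIds))

setMethod("show", "DiplotypeSet", function(object) {
    cat("DiplotypeSet:", length(object), "phased genes\n")
})
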