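#' @include AllClasses.R AllGenerics.R utils.R
NULL

# per-site summaries over a sample subset
.siteStats <- function(geno) {
    nInd <- ncol(geno)
    missing <- rowSums(is.na(geno)) / nInd
    m <- 2 * rowSums(!is.na(geno))          # non-missing allele count
    alt <- rowSums(geno, na.rm = TRUE)      # alternate allele count
    p <- ifelse(m > 0, alt / m, NA_real_)
    maf <- pmin(p, 1 - p)
    list(missing = missing, m = m, p = p, maf = maf)
}

#' Filter SNPs on quality, missingness and minor allele frequency
#'
#' Keeps a SNP iff quality `> minQual`, missing-genotype fraction
#' `< maxMissing`, and minor allele frequency `> minMaf`; i.e. sites *at*
#' any threshold are excluded. MAF is computed over the non-missing
#' alleles (two per diploid) of the samples in `sampleIds`; a site with
#' all genotypes missing is excluded (missing fraction 1).
#'
#' @param snps [SNPSet-class].
#' @param sampleIds samples whose genotypes define missingness and MAF
#'   (default all samples in `snps`).
#' @param minQual quality threshold (default 10).
#' @param maxMissing missing-fraction threshold (default 0.10).
#' @param minMaf MAF threshold (default 0.05).
#' @return [SNPSet-class] restricted to the passing sites of every gene
#'   (all samples retained).
#' @export
filterSnps <- function(snps, sampleIds = NULL, minQual = 10,
                       maxMissing = 0.10, minMaf = 0.05) {
    if (is.null(sampleIds)) sampleIds <- snps@sampleIds
    idx <- match(sampleIds, snps@sampleIds)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(sampleIds[is.na(idx)], collapse = ", "))
    snpData <- lapply(snps@snpData, function(d) {
        if (!length(d$position)) return(d)
        st <- .siteStats(d$geno[, idx, drop = FALSE])
        pass <- !is.na(d$quality) & d$quality > minQual &
            st$missing < maxMissing &
            !is.na(st$maf) & st$maf > minMaf
        list(position = d$position[pass], quality = d$quality[pass],
             geno = d$geno[pass, , drop = FALSE])
    })
    out <- SNPSet(snpData, geneLengths(snps), snps@sampleIds)
    out
}

#' Per-gene nucleotide diversity from genotype codes
#'
#' Nei's per-site nucleotide diversity summed over a gene's SNP sites and
#' divided by the transcript length `L`: at site `j` with `m_j` non-missing
#' alleles and alternate-allele frequency `p_j`,
#' `pi = (1/L) * sum_j (m_j / (m_j - 1)) * 2 * p_j * (1 - p_j)`.
#' This equals the average pairwise allele difference over all `C(m_j, 2)`
#' allele pairs at each site. Sites with fewer than 2 non-missing diploids
#' are skipped; a gene with no (remaining) SNPs has `pi = 0`.
#'
#' @param geno sites x samples genotype-code matrix (\{0, 1, 2, NA\}).
#' @param geneLength transcript length in bp (`> 0`).
#' @return scalar pi.
#' @examples
#' # one site, two diploids both heterozygous, L = 100:
#' computePi(matrix(c(1L, 1L), 1), 100)  # (4/3 * 0.5) / 100 = 1/150
#' @export
computePi <- function(geno, geneLength) {
    if (geneLength <= 0) stop("gene length must be positive")
    if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L)
    if (!nrow(geno)) return(0)
    st <- .siteStats(geno)
    use <- st$m >= 4  # at least two non-missing diploids
    if (!any(use)) return(0)
    m <- st$m[use]; p <- st$p[use]
    sum(m / (m - 1) * 2 * p * (1 - p)) / geneLength
}

#' Per-gene, per-environment diversity table
#'
#' Applies the SNP filter within each environment's samples (the
#' transplant design genotypes the same genets at both sites, but
#' filtering is per environment so each site's own missingness and MAF
#' decide; set `filterScope = "joint"` to filter once on all samples) and
#' computes pi per environment.
#'
#' @param snps unfiltered [SNPSet-class].
#' @param x [PopExpressionSet-class] supplying the sample-to-environment
#'   mapping.
#' @param genes genes to report (default all genes in `snps`).
#' @param filterScope `"per_env"` (default) or `"joint"`.
#' @param minQual,maxMissing,minMaf passed to [filterSnps()].
#' @return [S4Vectors::DataFrame]: `gene_id`, `environment`, `n_snps`,
#'   `has_snp`, `pi`.
#' @export
geneDiversity <- function(snps, x, genes = geneIds(snps),
                          filterScope = c("per_env", "joint"),
                          minQual = 10, maxMissing = 0.10, minMaf = 0.05) {
    filterScope <- match.arg(filterScope)
    ef <- envFactor(x)
    sampleByEnv <- split(colnames(x), ef)
    gl <- geneLengths(snps)
    if (filterScope == "joint")
        joint <- filterSnps(snps, minQual = minQual, maxMissing = maxMissing,
                            minMaf = minMaf)
    rows <- lapply(levels(ef), function(e) {
        ids <- sampleByEnv[[e]]
        f <- if (filterScope == "per_env")
            filterSnps(snps, sampleIds = ids, minQual = minQual,
                       maxMissing = maxMissing, minMaf = minMaf)
        else joint
        idx <- match(ids, f@sampleIds)
        ns <- nSnps(f)[genes]
        pi <- vapply(genes, function(g)
            computePi(f@snpData[[g]]$geno[, idx, drop = FALSE], gl[[g]]),
            numeric(1))
        DataFrame(gene_id = genes, environment = e,
                  n_snps = unname(ns), has_snp = unname(ns) > 0L,
                  pi = unname(pi))
    })
    do.call(rbind, rows)
}

#' Partition genes by SNP presence within each environment
#'
#' @param div [S4Vectors::DataFrame] from [geneDiversity()].
#' @return named list (one entry per environment) of
#'   `list(with_snp = ..., without_snp = ...)` gene-ID sets; within each
#'   environment the two sets are disjoint and exhaustive.
#' @export
groupBySnpPresence <- function(div) {
    envs <- unique(div$environment)
    out <- lapply(envs, function(e) {
        d <- div[div$environment == e, ]
        list(with_snp = d$gene_id[d$has_snp],
             without_snp = d$gene_id[!d$has_snp])
    })
    names(out) <- envs
    out
}
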