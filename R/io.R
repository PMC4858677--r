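#' @include AllClasses.R AllGenerics.R utils.R
NULL

# ---------------------------------------------------------------------------
# expression matrix + sample metadata
# ---------------------------------------------------------------------------

#' Read a genes-by-samples FPKM matrix from TSV
#'
#' Expects gene identifiers in the first column and sample identifiers in
#' the header row; the body must be numeric, non-missing and non-negative.
#'
#' @param path TSV file (first column gene IDs, remaining columns FPKM).
#' @return numeric matrix, genes in rows.
#' @export
readExpressionMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("expression TSV needs a gene-ID column plus at least one sample")
    gid <- as.character(df[[1L]])
    if (anyDuplicated(gid))
        stop("duplicated gene IDs in expression matrix: ",
             paste(unique(gid[duplicated(gid)]), collapse = ", "))
    if (anyDuplicated(colnames(df)[-1L]))
        stop("duplicated sample IDs in expression matrix header")
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m)) stop("expression matrix contains missing/non-numeric cells")
    if (any(m < 0)) stop("expression matrix contains negative FPKM values")
    rownames(m) <- gid
    m
}

#' Write an FPKM matrix (or the assay of a PopExpressionSet) to TSV
#'
#' @param x matrix or [PopExpressionSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
    m <- if (is(x, "PopExpressionSet")) fpkm(x) else x
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read per-sample metadata (population, environment, individual)
#'
#' @param path TSV with columns `sample_id`, `population`, `environment`
#'   and optionally `individual` (defaults to `sample_id`).
#' @param nativeEnv the environment level to treat as native habitat; must
#'   be present in the file.
#' @return data.frame with the four columns above.
#' @export
readSampleMetadata <- function(path, nativeEnv) {
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("sample_id", "population", "environment")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id in metadata")
    envs <- unique(df$environment)
    if (length(envs) != 2L)
        stop(sprintf("need exactly 2 environment levels, found %d (%s)",
                     length(envs), paste(envs, collapse = ", ")))
    if (!nativeEnv %in% envs)
        stop(sprintf("nativeEnv '%s' not among environment levels (%s)",
                     nativeEnv, paste(envs, collapse = ", ")))
    if (any(table(df$environment) == 0L))
        stop("an environment level has no samples")
    if (is.null(df$individual)) df$individual <- df$sample_id
    df[c("sample_id", "population", "environment", "individual")]
}

#' @rdname readSampleMetadata
#' @param meta data.frame as returned by `readSampleMetadata`.
#' @export
writeSampleMetadata <- function(meta, path) {
    utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Assemble a PopExpressionSet from matrix + metadata
#'
#' Every sample (column) of the matrix must appear exactly once in the
#' metadata; the error names any sample that does not.
#'
#' @param m FPKM matrix from [readExpressionMatrix()].
#' @param meta data.frame from [readSampleMetadata()].
#' @param nativeEnv native environment level.
#' @return [PopExpressionSet-class].
#' @export
makePopExpressionSet <- function(m, meta, nativeEnv) {
    missing <- setdiff(colnames(m), meta$sample_id)
    if (length(missing))
        stop("sample(s) in expression matrix missing from metadata: ",
             paste(missing, collapse = ", "))
    meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
    PopExpressionSet(m, population = meta$population,
                     environment = meta$environment,
                     individual = meta$individual, nativeEnv = nativeEnv)
}

#' Read expression matrix + metadata straight into a PopExpressionSet
#'
#' @param exprPath expression TSV (see [readExpressionMatrix()]).
#' @param metaPath metadata TSV (see [readSampleMetadata()]).
#' @param nativeEnv native environment level.
#' @return [PopExpressionSet-class].
#' @export
readExpressionSet <- function(exprPath, metaPath, nativeEnv) {
    makePopExpressionSet(readExpressionMatrix(exprPath),
                         readSampleMetadata(metaPath, nativeEnv),
                         nativeEnv)
}

# ---------------------------------------------------------------------------
# VCF
# ---------------------------------------------------------------------------

.gtToCode <- function(gt) {
    # 0/1, 1/0, 0|1, 1|0 all count one alternate allele; input phase is
    # discarded because phasing is re-estimated downstream
    out <- rep(NA_integer_, length(gt))
    gt <- sub(":.*$", "", gt)
    ok <- !is.na(gt)
    code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
              "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_)
    known <- gt[ok] %in% names(code)
    if (any(!known))
        stop("malformed GT field(s): ",
             paste(unique(gt[ok][!known]), collapse = ", "))
    out[ok] <- code[gt[ok]]
    out
}

#' Read per-gene SNP genotypes from a VCF
#'
#' CHROM is interpreted as the transcript/gene identifier (reads are mapped
#' to a reference transcriptome), POS as the 1-based transcript coordinate.
#' Only biallelic SNP records are kept; multiallelic records are skipped and
#' counted. Genotypes are collapsed to allele-dosage codes \{0, 1, 2, NA\}.
#'
#' @param path VCF v4.x file (uncompressed or gzipped).
#' @param geneLengths named vector of transcript lengths. If `NULL`, lengths
#'   are taken from `##contig=<ID=...,length=...>` header lines. Genes in
#'   the VCF without a known length are skipped with a warning.
#' @return [SNPSet-class]; the number of skipped multiallelic records is in
#'   `metadata`-style attribute `nMultiallelic`.
#' @export
readSNPVcf <- function(path, geneLengths = NULL) {
    if (!file.exists(path)) stop("VCF not found: ", path)
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    if (is.null(geneLengths)) {
        meta <- vcf@meta
        contig <- grep("^##contig=", meta, value = TRUE)
        ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
        lens <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", contig)))
        geneLengths <- stats::setNames(lens, ids)
        if (!length(geneLengths))
            stop("no geneLengths given and no ##contig header lines in VCF")
    }
    samples <- colnames(vcf@gt)[-1L]
    nrec <- nrow(fix)
    keep <- rep(TRUE, nrec)
    alt <- fix[, "ALT"]
    ref <- fix[, "REF"]
    multi <- grepl(",", alt) | is.na(alt) | nchar(ref) != 1L |
        (nchar(alt) != 1L & !grepl(",", alt))
    nMulti <- sum(grepl(",", alt))
    keep[multi] <- FALSE
    chrom <- fix[, "CHROM"]
    unknown <- setdiff(unique(chrom[keep]), names(geneLengths))
    if (length(unknown)) {
        warning("skipping gene(s) absent from gene lengths: ",
                paste(unknown, collapse = ", "))
        keep[chrom %in% unknown] <- FALSE
    }
    gt <- vcf@gt[, -1L, drop = FALSE]
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    pos <- as.integer(fix[, "POS"])
    # genes with a known length but no surviving record get an empty table
    snpData <- lapply(names(geneLengths), function(g) {
        idx <- which(keep & chrom == g)
        idx <- idx[order(pos[idx])]
        geno <- if (length(idx)) {
            matrix(.gtToCode(t(gt[idx, , drop = FALSE])),
                   nrow = length(idx), byrow = TRUE)
        } else matrix(integer(0), 0L, length(samples))
        list(position = pos[idx], quality = qual[idx], geno = geno)
    })
    names(snpData) <- names(geneLengths)
    out <- SNPSet(snpData, geneLengths, samples)
    attr(out, "nMultiallelic") <- nMulti
    if (nMulti > 0L)
        message(sprintf("readSNPVcf: skipped %d multiallelic record(s)", nMulti))
    out
}

#' Write an SNPSet as a minimal VCF v4.2
#'
#' Emits one biallelic record per SNP with `GT`-only genotype fields and a
#' `##contig` header line per gene carrying the transcript length, so the
#' file round-trips through [readSNPVcf()] without an external length table.
#'
#' @param snps [SNPSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSNPVcf <- function(snps, path) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("##fileformat=VCFv4.2", con)
    writeLines(sprintf("##source=popExpVar_%s", pkgVersionString()), con)
    gl <- geneLengths(snps)
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(gl), gl), con)
    writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", snps@sampleIds), collapse = "\t"), con)
    gtStr <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    for (g in geneIds(snps)) {
        d <- snps@snpData[[g]]
        s <- length(d$position)
        if (!s) next
        for (j in seq_len(s)) {
            codes <- d$geno[j, ]
            gt <- ifelse(is.na(codes), "./.", gtStr[as.character(codes)])
            writeLines(paste(c(g, d$position[j], ".", "A", "T",
                               format(d$quality[j], trim = TRUE), ".", ".",
                               "GT", gt), collapse = "\t"), con)
        }
    }
    invisible(path)
}

# ---------------------------------------------------------------------------
# phased haplotypes (PHASE-style best-guess table)
# ---------------------------------------------------------------------------

#' Read externally phased best-guess haplotypes
#'
#' Accepts a TSV of per-individual haplotype pairs (the shape PHASE-style
#' best reconstructions are exported in, and the shape
#' [writePhasedHaplotypes()] emits): columns `gene_id`, `sample_id`,
#' `hap1`, `hap2` (strings over \{0,1\}) and optionally `posterior`.
#' Pairs are unordered; they are canonicalised so that `hap1 <= hap2`.
#'
#' @param path TSV file.
#' @param snps [SNPSet-class] of the *filtered* SNPs the haplotypes refer
#'   to; haplotype string lengths must equal each gene's SNP count.
#' @return [DiplotypeSet-class].
#' @export
readPhasedHaplotypes <- function(path, snps) {
    # hap columns must stay character: "01" is a haplotype, not the number 1
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = c(hap1 = "character",
                                           hap2 = "character"))
    need <- c("gene_id", "sample_id", "hap1", "hap2")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("phased TSV lacks column(s): ", paste(miss, collapse = ", "))
    df$hap1 <- as.character(df$hap1)
    df$hap2 <- as.character(df$hap2)
    if (any(grepl("[^01]", c(df$hap1, df$hap2))))
        stop("haplotype strings must be over alleles {0,1}")
    ns <- nSnps(snps)
    for (g in unique(df$gene_id)) {
        if (!g %in% geneIds(snps))
            stop("phased gene absent from SNP set: ", g)
        len <- unique(nchar(c(df$hap1[df$gene_id == g],
                              df$hap2[df$gene_id == g])))
        if (!identical(len, unname(ns[g])))
            stop(sprintf("gene %s: haplotype length %s != %d filtered SNPs",
                         g, paste(len, collapse = "/"), ns[g]))
    }
    DiplotypeSet(split(df[setdiff(colnames(df), "gene_id")], df$gene_id))
}

#' Write a DiplotypeSet as a phased TSV
#'
#' Same shape [readPhasedHaplotypes()] accepts, so the phaser's output
#' round-trips.
#'
#' @param dip [DiplotypeSet-class].
#' @param path output file.
#' @param config optional config object for the provenance header.
#' @return `path`, invisibly.
#' @export
writePhasedHaplotypes <- function(dip, path, config = NULL) {
    rows <- lapply(geneIds(dip), function(g) {
        a <- assignments(dip)[[g]]
        data.frame(gene_id = g, a, stringsAsFactors = FALSE)
    })
    writeTsv(do.call(rbind, rows), path, what = "phased_haplotypes",
             config = config)
}
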