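#' @include AllClasses.R AllGenerics.R utils.R
NULL

# haplotypes are bit codes: site j allele in bit j-1; string form "010..."
.hapToString <- function(code, s)
    vapply(code, function(h)
        paste(bitwAnd(bitwShiftR(h, seq_len(s) - 1L), 1L), collapse = ""),
        character(1))

# all unordered haplotype pairs compatible with one genotype vector.
# het sites split the two haplotypes; missing sites are marginalised
# (both haplotypes free). Returns a 2-column matrix of hap codes (a <= b).
.compatiblePairs <- function(g) {
    s <- length(g)
    base <- 0L
    hom <- which(!is.na(g) & g == 2L)
    if (length(hom)) base <- sum(bitwShiftL(1L, hom - 1L))
    het <- which(!is.na(g) & g == 1L)
    mis <- which(is.na(g))
    a <- base; b <- base
    # het sites: the first het is fixed to hap2 so unordered pairs are not
    # generated twice; remaining het sites branch
    if (length(het)) {
        b <- b + bitwShiftL(1L, het[1] - 1L)
        for (j in het[-1]) {
            bit <- bitwShiftL(1L, j - 1L)
            a <- c(a + bit, a); b <- c(b, b + bit)
        }
    }
    # missing sites: both haplotypes free -> 4 combinations per site
    for (j in mis) {
        bit <- bitwShiftL(1L, j - 1L)
        a <- c(a, a + bit, a, a + bit)
        b <- c(b, b, b + bit, b + bit)
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    unique(cbind(lo, hi))
}

#' Phase one gene by EM over haplotype frequencies
#'
#' Excoffier-Slatkin EM for genes with few SNPs, substituting for an
#' external coalescent-based phaser: the E-step distributes each
#' individual's genotype probability over its compatible (unordered)
#' haplotype pairs under the current frequencies, assuming Hardy-Weinberg
#' (`P\{a, b\} = 2 f_a f_b`, `P\{a, a\} = f_a^2`); the M-step re-estimates
#' frequencies from the expected haplotype counts. Missing genotypes are
#' marginalised over. The best of `nRestarts` runs (by log-likelihood)
#' is kept, and each individual is assigned its maximum-posterior
#' compatible pair, ties broken by lexicographically smallest pair.
#'
#' @param geno sites x individuals genotype-code matrix with 1 to
#'   `maxSnps` rows; column names are the individual IDs.
#' @param maxSnps refuse genes with more SNPs than this (default 9,
#'   matching the accuracy limit of transcriptome phasing).
#' @param nRestarts EM restarts from random frequency starts after the
#'   uniform start (default 5).
#' @param seed optional integer seed for the restarts.
#' @param maxIter,tol convergence controls: stop when the largest
#'   frequency change is `< tol` (default 1e-8) or after `maxIter`
#'   (default 500) iterations.
#' @return list with `assignment` (data.frame `sample_id`, `hap1`, `hap2`,
#'   `posterior`), `hapFreqs` (named, string haplotypes), `logLik`, and
#'   `llTrace` (per-restart iteration log-likelihoods; non-decreasing).
#' @export
phaseGeneEM <- function(geno, maxSnps = 9L, nRestarts = 5L, seed = NULL,
                        maxIter = 500L, tol = 1e-8) {
    if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L,
                                           dimnames = list(NULL, names(geno)))
    s <- nrow(geno); n <- ncol(geno)
    if (s < 1L) stop("gene has no SNPs to phase")
    if (s > maxSnps) stop(sprintf("gene has %d SNPs; phasing restricted to <= %d",
                                  s, maxSnps))
    if (!is.null(seed)) set.seed(seed)
    ids <- colnames(geno)
    if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(n))
    pairList <- lapply(seq_len(n), function(i) .compatiblePairs(geno[, i]))
    hapUniverse <- sort(unique(unlist(pairList)))
    H <- length(hapUniverse)
    hidx <- function(code) match(code, hapUniverse)
    pairIdx <- lapply(pairList, function(p) cbind(hidx(p[, 1]), hidx(p[, 2])))

    runEM <- function(f) {
        ll <- -Inf; trace <- numeric(0)
        for (it in seq_len(maxIter)) {
            counts <- numeric(H)
            llNew <- 0
            for (i in seq_len(n)) {
                p <- pairIdx[[i]]
                w <- f[p[, 1]] * f[p[, 2]] * ifelse(p[, 1] == p[, 2], 1, 2)
                tw <- sum(w)
                if (tw <= 0) { w <- rep(1 / nrow(p), nrow(p)); tw <- 1
                               llNew <- -Inf } else {
                    llNew <- llNew + log(tw)
                    w <- w / tw
                }
                counts[p[, 1]] <- counts[p[, 1]] + w
                counts[p[, 2]] <- counts[p[, 2]] + w
            }
            fNew <- counts / (2 * n)
            trace <- c(trace, llNew)
            delta <- max(abs(fNew - f))
            f <- fNew
            ll <- llNew
            if (delta < tol) break
        }
        list(f = f, ll = ll, trace = trace)
    }

    starts <- c(list(rep(1 / H, H)),
                lapply(seq_len(max(0L, nRestarts - 1L)), function(k) {
                    r <- stats::rexp(H); r / sum(r)
                }))
    runs <- lapply(starts, runEM)
    best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "ll"))]]
    f <- best$f

    hapStr <- .hapToString(hapUniverse, s)
    assignOne <- function(i) {
        p <- pairIdx[[i]]
        w <- f[p[, 1]] * f[p[, 2]] * ifelse(p[, 1] == p[, 2], 1, 2)
        tw <- sum(w)
        post <- if (tw > 0) w / tw else rep(1 / nrow(p), nrow(p))
        # max posterior; ties -> lexicographically smallest pair label
        lab1 <- hapStr[p[, 1]]; lab2 <- hapStr[p[, 2]]
        ord <- order(-post, pmin(lab1, lab2), pmax(lab1, lab2))
        k <- ord[1]
        c(sort(c(lab1[k], lab2[k])), format(post[k], digits = 10))
    }
    am <- vapply(seq_len(n), assignOne, character(3))
    assignment <- data.frame(sample_id = ids, hap1 = am[1, ], hap2 = am[2, ],
                             posterior = as.numeric(am[3, ]),
                             stringsAsFactors = FALSE)
    keep <- f > 1e-12
    hapFreqs <- stats::setNames(f[keep] / sum(f[keep]), hapStr[keep])
    list(assignment = assignment, hapFreqs = hapFreqs, logLik = best$ll,
         llTrace = lapply(runs, `[[`, "trace"))
}

#' Phase every eligible gene of an SNPSet
#'
#' Runs [phaseGeneEM()] on each gene with 1 to `maxSnps` (filtered) SNPs,
#' pooling the samples of both environments. When the transplant design
#' genotypes the same genet in both environments, pass `individualId` so
#' each genet is counted once; its diplotype is then shared by both
#' ramets.
#'
#' @param snps filtered [SNPSet-class].
#' @param individualId optional character vector (parallel to the SNPSet
#'   samples) of genet IDs; duplicate genets are collapsed before EM.
#' @param maxSnps,nRestarts,maxIter,tol passed to [phaseGeneEM()].
#' @param seed integer seed; per-gene seeds are derived from it.
#' @return [DiplotypeSet-class] over the phased genes (per genet when
#'   `individualId` is given).
#' @export
phaseAllGenes <- function(snps, individualId = NULL, maxSnps = 9L,
                          nRestarts = 5L, seed = 1L, maxIter = 500L,
                          tol = 1e-8) {
    ns <- nSnps(snps)
    todo <- geneIds(snps)[ns >= 1L & ns <= maxSnps]
    if (!length(todo)) stop("no genes with 1..maxSnps SNPs to phase")
    assignments <- list(); freqs <- list(); lls <- numeric(0)
    for (k in seq_along(todo)) {
        g <- todo[k]
        geno <- snpGenotypes(snps, g)
        colnames(geno) <- snps@sampleIds
        if (!is.null(individualId)) {
            first <- !duplicated(individualId)
            geno <- geno[, first, drop = FALSE]
            colnames(geno) <- individualId[first]
        }
        res <- phaseGeneEM(geno, maxSnps = maxSnps, nRestarts = nRestarts,
                           seed = deriveSeed(seed, k), maxIter = maxIter,
                           tol = tol)
        assignments[[g]] <- res$assignment
        freqs[[g]] <- res$hapFreqs
        lls[g] <- res$logLik
    }
    DiplotypeSet(assignments, hapFreqs = freqs, logLik = lls)
}

#' Diplotype factor for haplotype-effect ANOVA
#'
#' Turns one gene's phased assignment into the categorical "haplotype"
#' factor: level = canonical unordered pair label `hap1|hap2`; levels
#' carried by fewer than `minGroupSize` individuals are merged into a
#' `"rare"` level so the ANOVA stays estimable. Returns `NULL` (gene
#' dropped) when fewer than 2 levels remain.
#'
#' @param assignment data.frame (`sample_id`, `hap1`, `hap2`) for one
#'   gene, as stored in a [DiplotypeSet-class].
#' @param minGroupSize merge threshold (default 2).
#' @return named factor (names = sample IDs) or `NULL`.
#' @export
diplotypeFactor <- function(assignment, minGroupSize = 2L) {
    lab <- paste(pmin(assignment$hap1, assignment$hap2),
                 pmax(assignment$hap1, assignment$hap2), sep = "|")
    tab <- table(lab)
    rare <- names(tab)[tab < minGroupSize]
    if (length(rare)) lab[lab %in% rare] <- "rare"
    if (length(unique(lab)) < 2L) return(NULL)
    stats::setNames(factor(lab), assignment$sample_id)
}
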