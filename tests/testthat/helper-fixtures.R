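# in-code fixtures and independent oracles shared across test files

# tiny balanced two-environment expression set: nPop populations x nInd
# genets, each genet sampled in both environments
makeTinyExpr <- function(fpkm, nPop = 2, nInd = 2, envs = c("JH", "QG")) {
    nSamp <- ncol(fpkm)
    stopifnot(nSamp == nPop * nInd * 2)
    genets <- as.vector(outer(sprintf("P%d", seq_len(nPop)),
                              sprintf("_I%d", seq_len(nInd)), paste0))
    pop <- rep(sprintf("P%d", seq_len(nPop)), times = nInd)
    colnames(fpkm) <- paste(rep(genets, 2), rep(envs, each = length(genets)),
                            sep = "_")
    PopExpressionSet(fpkm,
                     population = rep(pop, 2),
                     environment = rep(envs, each = length(genets)),
                     individual = rep(genets, 2),
                     nativeEnv = envs[1])
}

# brute-force nucleotide diversity: average pairwise allele difference over
# all C(m, 2) sampled allele pairs at each site, / L (the independent
# oracle for computePi)
piBruteForce <- function(geno, L) {
    if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
    tot <- 0
    for (j in seq_len(nrow(geno))) {
        g <- geno[j, ]
        g <- g[!is.na(g)]
        if (length(g) < 2) next
        alleles <- unlist(lapply(g, function(x) c(rep(1L, x), rep(0L, 2L - x))))
        pr <- utils::combn(length(alleles), 2)
        tot <- tot + mean(alleles[pr[1, ]] != alleles[pr[2, ]])
    }
    tot / L
}

# full-enumeration two-sided Mann-Whitney p-value (oracle for the exact
# branch of wilcoxonRankSum); mirrors the doubled-tail convention
wilcoxExactOracle <- function(x, y) {
    m <- length(x); n <- length(y)
    vals <- c(x, y)
    stopifnot(!anyDuplicated(vals))
    idx <- utils::combn(m + n, m)
    r <- rank(vals)
    Uall <- apply(idx, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
    Uobs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    mid <- m * n / 2
    p <- if (Uobs > mid) 2 * mean(Uall >= Uobs) else 2 * mean(Uall <= Uobs)
    min(1, p)
}

# exhaustive-ML haplotype frequencies on tiny instances: enumerate every
# haplotype of the full 2^s universe and maximise the multinomial-pair
# likelihood directly over the simplex with multi-start BFGS on softmax
# coordinates, using the analytic gradient (independent of the EM updates)
exhaustiveMLFreqs <- function(geno, nStarts = 30, seed = 1) {
    if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
    s <- nrow(geno); n <- ncol(geno)
    hapsAll <- as.matrix(expand.grid(rep(list(0:1), s)))
    hapStrAll <- apply(hapsAll, 1, paste, collapse = "")
    fitOnUniverse <- function(universe, nStarts, seed) {
    haps <- hapsAll[universe, , drop = FALSE]
    hapStr <- hapStrAll[universe]
    H <- nrow(haps)
    compat <- lapply(seq_len(n), function(i) {
        g <- geno[, i]
        out <- NULL
        for (a in seq_len(H)) for (b in a:H) {
            gsum <- haps[a, ] + haps[b, ]
            if (all(is.na(g) | gsum == g)) out <- rbind(out, c(a, b))
        }
        out
    })
    if (any(vapply(compat, is.null, logical(1)))) return(NULL)
    toFreq <- function(theta) {
        v <- c(theta, 0)
        e <- exp(v - max(v))
        e / sum(e)
    }
    negll <- function(theta) {
        f <- toFreq(theta)
        ll <- 0
        for (i in seq_len(n)) {
            p <- compat[[i]]
            w <- f[p[, 1]] * f[p[, 2]] * ifelse(p[, 1] == p[, 2], 1, 2)
            tw <- sum(w)
            if (tw <= 1e-300) return(1e10)
            ll <- ll + log(tw)
        }
        -ll
    }
    gradNegll <- function(theta) {
        f <- toFreq(theta)
        dllf <- numeric(H)
        for (i in seq_len(n)) {
            p <- compat[[i]]
            mult <- ifelse(p[, 1] == p[, 2], 1, 2)
            w <- f[p[, 1]] * f[p[, 2]] * mult
            tw <- sum(w)
            if (tw <= 1e-300) return(rep(0, H - 1))
            for (r in seq_len(nrow(p))) {
                a <- p[r, 1]; b <- p[r, 2]
                dllf[a] <- dllf[a] + mult[r] * f[b] / tw
                dllf[b] <- dllf[b] + mult[r] * f[a] / tw
            }
        }
        # chain rule through softmax: d ll / d theta_k
        dtheta <- f * (dllf - sum(dllf * f))
        -dtheta[seq_len(H - 1)]
    }
    set.seed(seed)
    best <- NULL
    for (k in seq_len(nStarts)) {
        th0 <- if (k == 1) rep(0, H - 1) else rnorm(H - 1, 0, 2)
        fit <- tryCatch(
            stats::optim(th0, negll, gradNegll, method = "BFGS",
                         control = list(maxit = 2000, reltol = 1e-16)),
            error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value))
            best <- fit
    }
    f <- toFreq(best$par)
    names(f) <- hapStr
    list(freqs = f, logLik = -best$value)
    }
    first <- fitOnUniverse(seq_len(nrow(hapsAll)), nStarts, seed)
    # active-set polish: boundary zeros slow softmax convergence, so
    # re-optimise restricted to the support of the first pass
    support <- which(hapStrAll %in% names(first$freqs)[first$freqs > 1e-5])
    second <- if (length(support) >= 2 && length(support) < nrow(hapsAll))
        fitOnUniverse(support, nStarts, seed + 1) else NULL
    out <- if (!is.null(second) && second$logLik >= first$logLik) {
        f <- stats::setNames(numeric(nrow(hapsAll)), hapStrAll)
        f[names(second$freqs)] <- second$freqs
        list(freqs = f, logLik = second$logLik)
    } else first
    out
}
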