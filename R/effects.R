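#' @include AllClasses.R AllGenerics.R utils.R
NULL

# RSS of every row of Y regressed on design matrix X (rank-safe)
.rssAll <- function(Y, X) {
    q <- qr(X)
    res <- t(qr.resid(q, t(Y)))
    list(rss = rowSums(res * res), rank = q$rank)
}

#' Two-way fixed-effects ANOVA with Type II sums of squares
#'
#' Fits `y ~ A * B` and partitions the variation with marginality-
#' respecting Type II sums of squares (each main effect adjusted for the
#' other, the interaction adjusted for both), which reduce to the
#' classical sequential decomposition on balanced designs. F statistics
#' use the full-model residual mean square.
#'
#' Degenerate situations are flagged rather than fatal: an inestimable
#' interaction (empty factor-level combination) gets `df = 0` and
#' `interaction_dropped = TRUE`; a zero residual variance reports `p = 0`
#' for terms with positive SS and sets `degenerate = TRUE` (a constant
#' response has all SS zero, `F = NA`).
#'
#' @param y numeric response vector.
#' @param A,B factors (>= 2 levels each, no empty level).
#' @return data.frame with rows `factorA`, `factorB`, `interaction`,
#'   `residuals` and columns `term`, `ss`, `df`, `f`, `p`, plus attributes
#'   `interaction_dropped` and `degenerate`.
#' @export
anovaTwoWay <- function(y, A, B) {
    res <- anovaTwoWayMatrix(matrix(y, nrow = 1), A, B)
    out <- data.frame(
        term = c("factorA", "factorB", "interaction", "residuals"),
        ss = c(res$ss[1, ], res$ssRes[1]),
        df = c(res$df, res$dfRes),
        f = c(res$f[1, ], NA),
        p = c(res$p[1, ], NA))
    attr(out, "interaction_dropped") <- res$interactionDropped
    attr(out, "degenerate") <- res$degenerate[1]
    out
}

#' Vectorised two-way Type II ANOVA across genes
#'
#' Same model as [anovaTwoWay()] applied to every row of `Y` at once (the
#' design is shared, so each nested model is fit once via QR and reused
#' for all genes).
#'
#' @param Y genes x samples response matrix.
#' @param A,B factors of length `ncol(Y)`.
#' @return list: `ss`, `f`, `p` (genes x 3 matrices: factorA, factorB,
#'   interaction), `ssRes`, `dfRes`, `df` (length-3), `degenerate`
#'   (logical per gene), `interactionDropped` (scalar).
#' @export
anovaTwoWayMatrix <- function(Y, A, B) {
    A <- droplevels(as.factor(A)); B <- droplevels(as.factor(B))
    if (nlevels(A) < 2L || nlevels(B) < 2L)
        stop("both factors need >= 2 non-empty levels")
    if (length(A) != ncol(Y) || length(B) != ncol(Y))
        stop("factor length must match number of samples")
    n <- ncol(Y)
    Xa <- stats::model.matrix(~A)
    Xb <- stats::model.matrix(~B)
    Xab <- stats::model.matrix(~A + B)
    Xfull <- stats::model.matrix(~A * B)
    fa <- .rssAll(Y, Xa); fb <- .rssAll(Y, Xb)
    fab <- .rssAll(Y, Xab); ffull <- .rssAll(Y, Xfull)
    dfA <- fab$rank - fb$rank
    dfB <- fab$rank - fa$rank
    dfAB <- ffull$rank - fab$rank
    dfRes <- n - ffull$rank
    if (dfRes < 1L) stop("no residual degrees of freedom")
    interactionDropped <- dfAB == 0L
    ssA <- pmax(fb$rss - fab$rss, 0)
    ssB <- pmax(fa$rss - fab$rss, 0)
    ssAB <- pmax(fab$rss - ffull$rss, 0)
    ssRes <- ffull$rss
    # floor numerically-zero SS (QR roundoff on constant/noise-free rows)
    eps <- pmax(rowSums(Y * Y), 1) * 1e-14
    ssA[ssA < eps] <- 0; ssB[ssB < eps] <- 0; ssAB[ssAB < eps] <- 0
    ssRes[ssRes < eps] <- 0
    msRes <- ssRes / dfRes
    degenerate <- ssRes == 0
    fstat <- function(ss, df) {
        f <- if (df > 0) (ss / df) / msRes else rep(NA_real_, length(ss))
        # zero residual variance: report p = 0 for terms with signal
        f[degenerate & ss > 0] <- Inf
        f[degenerate & ss == 0] <- NA_real_
        f
    }
    fA <- fstat(ssA, dfA); fB <- fstat(ssB, dfB); fAB <- fstat(ssAB, dfAB)
    pval <- function(f, df) {
        p <- rep(NA_real_, length(f))
        fin <- !is.na(f) & is.finite(f)
        p[fin] <- stats::pf(f[fin], max(df, 1), dfRes, lower.tail = FALSE)
        p[!is.na(f) & is.infinite(f)] <- 0
        p
    }
    gnames <- rownames(Y)
    mk <- function(a, b, ab) {
        m <- cbind(factorA = a, factorB = b, interaction = ab)
        rownames(m) <- gnames
        m
    }
    list(ss = mk(ssA, ssB, ssAB), f = mk(fA, fB, fAB),
         p = mk(pval(fA, dfA), pval(fB, dfB), pval(fAB, dfAB)),
         ssRes = ssRes, dfRes = dfRes, df = c(factorA = dfA, factorB = dfB,
                                              interaction = dfAB),
         degenerate = degenerate, interactionDropped = interactionDropped)
}

#' Per-gene ANOVA over the whole experiment
#'
#' `model = "pop_env"` fits environment x population on every gene of `x`;
#' `model = "hap_env"` fits environment x diplotype on the genes whose
#' [diplotypeFactor()] has at least two levels (each genet's diplotype is
#' shared by its ramets in both environments). The response is
#' `log2(FPKM + 1)` by default. Per-term p-value vectors are passed
#' jointly (across genes, within term) to [controlFdr()].
#'
#' @param x [PopExpressionSet-class] (pre-filtered to the analysis genes).
#' @param diplotypes [DiplotypeSet-class]; required for `"hap_env"`.
#' @param model `"pop_env"` or `"hap_env"`.
#' @param response `"log2"` (default) or `"raw"` FPKM.
#' @param fdrMethod,alpha passed to [controlFdr()].
#' @param minGroupSize passed to [diplotypeFactor()] for `"hap_env"`.
#' @return [S4Vectors::DataFrame] in long form: `gene_id`, `model`,
#'   `term` (`environment`, `population`/`haplotype`, `interaction`),
#'   `ss`, `df`, `f`, `p`, `q`, `flag` (q < alpha), `flag_p` (p < alpha),
#'   `degenerate`.
#' @export
fitAllGenes <- function(x, diplotypes = NULL,
                        model = c("pop_env", "hap_env"),
                        response = c("log2", "raw"),
                        fdrMethod = c("storey", "bh"), alpha = 0.05,
                        minGroupSize = 2L) {
    model <- match.arg(model)
    response <- match.arg(response)
    fdrMethod <- match.arg(fdrMethod)
    Y <- fpkm(x)
    if (response == "log2") Y <- log2(Y + 1)
    env <- envFactor(x)
    termB <- if (model == "pop_env") "population" else "haplotype"

    if (model == "pop_env") {
        res <- anovaTwoWayMatrix(Y, env, popFactor(x))
        genes <- rownames(Y)
        pMat <- res$p; fMat <- res$f; ssMat <- res$ss
        dfMat <- matrix(res$df, nrow(Y), 3, byrow = TRUE)
        degenerate <- res$degenerate
    } else {
        if (is.null(diplotypes))
            stop("model 'hap_env' requires a DiplotypeSet")
        ind <- individualId(x)
        genes <- intersect(rownames(Y), geneIds(diplotypes))
        keep <- logical(length(genes))
        pMat <- fMat <- ssMat <- dfMat <-
            matrix(NA_real_, length(genes), 3,
                   dimnames = list(genes, c("factorA", "factorB", "interaction")))
        degenerate <- logical(length(genes))
        for (k in seq_along(genes)) {
            g <- genes[k]
            fac <- diplotypeFactor(assignments(diplotypes)[[g]],
                                   minGroupSize = minGroupSize)
            if (is.null(fac)) next
            hap <- fac[ind]
            if (anyNA(hap) || nlevels(droplevels(hap)) < 2L) next
            res <- tryCatch(anovaTwoWayMatrix(Y[g, , drop = FALSE], env, hap),
                            error = function(e) NULL)
            if (is.null(res)) next
            keep[k] <- TRUE
            pMat[k, ] <- res$p; fMat[k, ] <- res$f; ssMat[k, ] <- res$ss
            dfMat[k, ] <- res$df
            degenerate[k] <- res$degenerate
        }
        genes <- genes[keep]
        pMat <- pMat[keep, , drop = FALSE]; fMat <- fMat[keep, , drop = FALSE]
        ssMat <- ssMat[keep, , drop = FALSE]; dfMat <- dfMat[keep, , drop = FALSE]
        degenerate <- degenerate[keep]
        if (!length(genes)) stop("no gene with an estimable haplotype factor")
    }

    terms <- c("environment", termB, "interaction")
    rows <- lapply(1:3, function(j) {
        p <- pMat[, j]
        q <- rep(NA_real_, length(p))
        ok <- !is.na(p)
        if (any(ok)) q[ok] <- controlFdr(p[ok], method = fdrMethod,
                                         alpha = alpha)$qvalues
        DataFrame(gene_id = genes, model = model, term = terms[j],
                  ss = unname(ssMat[, j]), df = unname(dfMat[, j]),
                  f = unname(fMat[, j]), p = unname(p), q = q,
                  flag = !is.na(q) & q < alpha,
                  flag_p = !is.na(p) & p < alpha,
                  degenerate = unname(degenerate))
    })
    do.call(rbind, rows)
}

#' Positive-FDR (Storey) or Benjamini-Hochberg q-values
#'
#' `method = "storey"` estimates the null proportion with the fixed-lambda
#' estimator `pi0 = #\{p > lambda\} / ((1 - lambda) m)` (capped to
#' \[1/m, 1\]) and computes step-up q-values
#' `q_(i) = min_(j >= i) pi0 m p_(j) / j`; `method = "bh"` is the
#' `pi0 = 1` special case, delegated to [stats::p.adjust()].
#'
#' @param pvals p-values in \[0, 1\].
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda Storey tuning parameter (default 0.5).
#' @param alpha rejection threshold for the returned flags (default 0.05).
#' @return list: `qvalues`, `rejected` (q < alpha), `pi0`.
#' @export
controlFdr <- function(pvals, method = c("storey", "bh"), lambda = 0.5,
                       alpha = 0.05) {
    method <- match.arg(method)
    if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0, 1] with no NA")
    m <- length(pvals)
    if (method == "bh") {
        q <- stats::p.adjust(pvals, method = "BH")
        pi0 <- 1
    } else {
        pi0 <- min(1, max(mean(pvals > lambda) / (1 - lambda), 1 / m))
        o <- order(pvals, decreasing = TRUE)
        q <- numeric(m)
        q[o] <- cummin(pi0 * m * pvals[o] / (m:1))
        q <- pmin(q, 1)
    }
    list(qvalues = q, rejected = q < alpha, pi0 = pi0)
}

#' Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Thin wrapper over [stats::wilcox.test()] enforcing a fixed policy:
#' exact enumeration when `length(x) + length(y) <= 12` and there are no
#' ties, otherwise the normal approximation with midrank tie correction
#' and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list: `U` (Mann-Whitney statistic for `x`), `p`.
#' @export
wilcoxonRankSum <- function(x, y, alternative = "two.sided") {
    if (!length(x) || !length(y)) stop("empty group")
    exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                              exact = exact, correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value)
}

#' Eight-group effect classification
#'
#' Labels each gene of the environment x haplotype model by the subset of
#' \{E, H, HxE\} whose effects are significant — q-based by default,
#' switchable to raw p (`use = "p"`). The 2^3 = 8 possible labels include
#' `"none"`.
#'
#' @param effects long-form [S4Vectors::DataFrame] from
#'   [fitAllGenes()] with `model == "hap_env"`.
#' @param alpha significance threshold (default 0.05).
#' @param use `"q"` (default) or `"p"`.
#' @return data.frame: `gene_id`, `eight_group`.
#' @export
classifyEightGroups <- function(effects, alpha = 0.05, use = c("q", "p")) {
    use <- match.arg(use)
    eff <- as.data.frame(effects[effects$model == "hap_env", ])
    if (!nrow(eff)) stop("no hap_env effect records")
    need <- c("environment", "haplotype", "interaction")
    wide <- lapply(need, function(tm) {
        d <- eff[eff$term == tm, c("gene_id", use)]
        stats::setNames(d[[use]], d$gene_id)
    })
    genes <- sort(unique(eff$gene_id))
    sig <- vapply(wide, function(v) {
        s <- v[genes]
        !is.na(s) & s < alpha
    }, logical(length(genes)))
    if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1)
    part <- c("E", "H", "HxE")
    lab <- apply(sig, 1L, function(b)
        if (!any(b)) "none" else paste(part[b], collapse = "+"))
    data.frame(gene_id = genes, eight_group = unname(lab),
               stringsAsFactors = FALSE)
}
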