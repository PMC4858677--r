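#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Filter genes expressed in at least half of the individuals per environment
#'
#' A gene is kept iff, in *each* environment separately, it has nonzero
#' FPKM in at least `ceiling(n_env / 2)` individuals.
#'
#' @param x [PopExpressionSet-class].
#' @return character vector of kept gene IDs.
#' @export
filterExpressedGenes <- function(x) {
    ef <- envFactor(x)
    if (any(table(ef) == 0L)) stop("an environment group is empty")
    m <- fpkm(x)
    keep <- rep(TRUE, nrow(m))
    for (e in levels(ef)) {
        cols <- which(ef == e)
        keep <- keep & rowSums(m[, cols, drop = FALSE] > 0) >=
            ceiling(length(cols) / 2)
    }
    rownames(m)[keep]
}

#' Population expression level Ep
#'
#' The arithmetic mean FPKM of a gene over the individuals sampled in one
#' environment.
#'
#' @param values FPKM vector for one gene in one environment (length >= 2).
#' @return scalar Ep.
#' @export
computeEp <- function(values) {
    if (!length(values)) stop("empty expression vector")
    if (length(values) < 2L) stop("Ep needs at least 2 individuals")
    mean(values)
}

#' Population expression diversity Ed
#'
#' A bounded \[0, 1\] index of how unevenly a gene's expression is spread
#' across individuals. The default (`shannon`) is one minus the evenness of
#' the expression shares: with `p_i = E_i / sum(E)`,
#' `Ed = 1 - H(p) / log(n)`, so `Ed = 0` when all individuals express the
#' gene equally and `Ed -> 1` as a single individual dominates.
#' `gini_simpson` substitutes the Gini-Simpson index normalised by its
#' maximum `1 - 1/n`; `cv` uses the coefficient of variation rescaled to
#' `cv / (1 + cv)`.
#'
#' @param values non-negative FPKM vector, length >= 2, positive sum.
#' @param metric one of `"shannon"` (default), `"gini_simpson"`, `"cv"`.
#' @return scalar Ed in \[0, 1\].
#' @examples
#' computeEd(c(1, 1))  # 0: maximal evenness
#' computeEd(c(1, 0))  # 1: one individual holds everything
#' @export
computeEd <- function(values, metric = c("shannon", "gini_simpson", "cv")) {
    metric <- match.arg(metric)
    n <- length(values)
    if (n < 2L) stop("Ed needs at least 2 individuals")
    if (any(values < 0)) stop("negative expression values")
    tot <- sum(values)
    if (tot <= 0) stop("Ed undefined for an all-zero vector")
    p <- values / tot
    switch(metric,
        shannon = {
            pp <- p[p > 0]
            1 - (-sum(pp * log(pp))) / log(n)
        },
        gini_simpson = 1 - (1 - sum(p^2)) / (1 - 1 / n),
        cv = {
            cv <- stats::sd(values) / mean(values)
            cv / (1 + cv)
        })
}

#' Cross-environment expression ratio Ep(new) / Ep(native)
#'
#' Vectorised; the native environment is always the denominator. Genes
#' with `epNative == 0` get `NA` (undefined ratio, excluded from
#' ratio-based analyses).
#'
#' @param epNew,epNative Ep vectors of equal length.
#' @return numeric vector of ratios.
#' @export
epRatio <- function(epNew, epNative) {
    if (length(epNew) != length(epNative)) stop("length mismatch")
    if (any(epNative < 0 | epNew < 0, na.rm = TRUE)) stop("negative Ep")
    ifelse(epNative > 0, epNew / epNative, NA_real_)
}

#' Conservation classes and nine-group labels
#'
#' `ep_class` is `"conserved"` iff the Ep ratio lies inside
#' `ratioBand` (band endpoints inclusive), `"up"` above, `"down"` below;
#' `ed_class` analogously from the Ed change (new minus native) against
#' `edBand`. The nine-group label is the ordered pair `ep_class:ed_class`.
#'
#' @param ratio Ep ratio vector (`NA` allowed; propagates).
#' @param edChange Ed(new) - Ed(native) vector.
#' @param ratioBand inclusive conserved band for the ratio, default
#'   `c(0.5, 2)`.
#' @param edBand inclusive conserved band for the Ed change, default
#'   `c(-0.25, 0.25)`.
#' @return data.frame with `ep_class`, `ed_class`, `nine_group`.
#' @export
classifyConservation <- function(ratio, edChange, ratioBand = c(0.5, 2),
                                 edBand = c(-0.25, 0.25)) {
    if (length(ratio) != length(edChange)) stop("length mismatch")
    epc <- ifelse(is.na(ratio), NA_character_,
           ifelse(ratio < ratioBand[1], "down",
           ifelse(ratio > ratioBand[2], "up", "conserved")))
    edc <- ifelse(is.na(edChange), NA_character_,
           ifelse(edChange < edBand[1], "shrunk",
           ifelse(edChange > edBand[2], "enlarged", "conserved")))
    nine <- ifelse(is.na(epc) | is.na(edc), NA_character_,
                   paste(epc, edc, sep = ":"))
    data.frame(ep_class = epc, ed_class = edc, nine_group = nine,
               stringsAsFactors = FALSE)
}

#' Split a statistic into k equal-count (quantile) groups
#'
#' Rank-based: values are ordered (ties broken by stable input order) and
#' cut into `k` contiguous groups whose sizes differ by at most one; when
#' `length(values)` is not divisible by `k`, the lower-statistic groups
#' take the extra members. Labels `1..k` follow increasing statistic, so
#' the labelling is invariant under any strictly monotone transform of the
#' values.
#'
#' @param values numeric vector, no NA.
#' @param k number of groups, `2 <= k <= length(values)`.
#' @return integer vector of group labels in `1..k`.
#' @export
binEqualCount <- function(values, k) {
    n <- length(values)
    if (k < 2L) stop("k must be >= 2")
    if (k > n) stop("more groups than values")
    if (anyNA(values)) stop("NA in values")
    sizes <- rep(n %/% k, k)
    r <- n %% k
    if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
    labels <- integer(n)
    labels[order(values)] <- rep(seq_len(k), times = sizes)
    labels
}

#' Pearson correlation of Ep between environments
#'
#' @param epNative,epNew Ep vectors (equal length >= 3).
#' @param log2Transform correlate `log2(Ep + 1)` instead of raw Ep
#'   (display-scale parity; default FALSE).
#' @return list with `r` and `p` (t-distribution, n - 2 df).
#' @export
correlateEp <- function(epNative, epNew, log2Transform = FALSE) {
    if (length(epNative) != length(epNew)) stop("length mismatch")
    if (length(epNative) < 3L) stop("need at least 3 genes")
    x <- epNative; y <- epNew
    if (log2Transform) { x <- log2(x + 1); y <- log2(y + 1) }
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance: correlation undefined")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Per-gene expression statistics across both environments
#'
#' Applies the expression filter, then computes Ep and Ed per environment,
#' the Ep ratio (native denominator), the Ed change, and conservation /
#' nine-group classes for every kept gene.
#'
#' @param x [PopExpressionSet-class].
#' @param edMetric passed to [computeEd()].
#' @param ratioBand,edBand passed to [classifyConservation()].
#' @return [S4Vectors::DataFrame] with one row per kept gene: `gene_id`,
#'   `ep_native`, `ep_new`, `ed_native`, `ed_new`, `ep_ratio`, `ed_change`,
#'   `ep_class`, `ed_class`, `nine_group`.
#' @export
geneExpressionStats <- function(x, edMetric = "shannon",
                                ratioBand = c(0.5, 2),
                                edBand = c(-0.25, 0.25)) {
    keep <- filterExpressedGenes(x)
    m <- fpkm(x)[keep, , drop = FALSE]
    ef <- envFactor(x)
    natCols <- ef == levels(ef)[1]
    newCols <- ef == levels(ef)[2]
    epNat <- rowMeans(m[, natCols, drop = FALSE])
    epNew <- rowMeans(m[, newCols, drop = FALSE])
    edNat <- apply(m[, natCols, drop = FALSE], 1L, computeEd, metric = edMetric)
    edNew <- apply(m[, newCols, drop = FALSE], 1L, computeEd, metric = edMetric)
    ratio <- epRatio(epNew, epNat)
    dEd <- edNew - edNat
    cls <- classifyConservation(ratio, dEd, ratioBand, edBand)
    DataFrame(gene_id = keep, ep_native = unname(epNat),
              ep_new = unname(epNew), ed_native = unname(edNat),
              ed_new = unname(edNew), ep_ratio = unname(ratio),
              ed_change = unname(dEd), ep_class = cls$ep_class,
              ed_class = cls$ed_class, nine_group = cls$nine_group)
}
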