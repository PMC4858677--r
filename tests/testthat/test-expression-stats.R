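test_that("expression filter keeps genes expressed in >= half of each env", {
    # 2 pops x 2 genets x 2 envs = 8 samples, 4 per environment
    m <- rbind(
        g1 = c(1, 0, 0, 0,  1, 1, 1, 1),   # 1/4 in env1 -> excluded
        g2 = c(1, 1, 0, 0,  0, 0, 2, 2),   # exactly half in both -> kept
        g3 = rep(2, 8),                     # everywhere -> kept
        g4 = c(0, 0, 0, 0,  1, 1, 1, 1))   # absent in env1 -> excluded
    x <- makeTinyExpr(m)
    expect_identical(filterExpressedGenes(x), c("g2", "g3"))

    # brute-force recount on a random sparse matrix
    set.seed(11)
    ms <- matrix(rbinom(500 * 8, 1, 0.5) * rexp(500 * 8), 500, 8,
                 dimnames = list(sprintf("g%03d", 1:500), NULL))
    xs <- makeTinyExpr(ms)
    ef <- envFactor(xs)
    expected <- rownames(ms)[vapply(seq_len(500), function(i) {
        all(vapply(levels(ef), function(e) {
            v <- ms[i, ef == e]
            sum(v > 0) >= ceiling(length(v) / 2)
        }, logical(1)))
    }, logical(1))]
    expect_identical(filterExpressedGenes(xs), expected)
})

test_that("Ep is the arithmetic mean and its ratio uses the native denominator", {
    expect_equal(computeEp(rep(3.7, 9)), 3.7)
    expect_equal(computeEp(c(0, 0, 4)), 4 / 3)
    expect_error(computeEp(numeric(0)), "empty")
    # mean of a lognormal sample approaches exp(mu + sigma^2/2)
    set.seed(2); v <- rlnorm(1e5, 1, 0.5)
    expect_equal(computeEp(v), exp(1 + 0.125), tolerance = 0.02)

    expect_equal(epRatio(10, 5), 2)
    expect_equal(epRatio(5, 5), 1)
    expect_true(is.na(epRatio(3, 0)))

    # planted log(2) environment shift in the zero-noise limit -> ratio 2:
    # log(FPKM+1) shifts by +-log 2, and at a high baseline the +1 is
    # negligible, so Ep_new / Ep_native ~ 2 or 1/2
    cfg0 <- simulationConfig(nGenes = 50, fracEnvEffect = 1, fracPopEffect = 0,
                             fracHapEffect = 0, fracInteraction = 0,
                             effectSizeSdUnits = 1e9 * log(2),
                             residualLogSd = 1e-9, baselineLogMean = 12,
                             baselineLogSd = 0.2, seed = 6)
    sim <- simulateDataset(cfg0)
    st <- geneExpressionStats(sim$expr)
    up <- st$ep_ratio[st$ep_ratio > 1]
    down <- st$ep_ratio[st$ep_ratio < 1]
    expect_equal(unname(up), rep(2, length(up)), tolerance = 1e-4)
    expect_equal(unname(down), rep(0.5, length(down)), tolerance = 1e-4)
})

test_that("Ed identities, bounds and alternate metrics behave", {
    expect_equal(computeEd(c(1, 1)), 0)
    expect_equal(computeEd(c(1, 0)), 1)
    # hand-computed: 1 - (-(0.75 log 0.75 + 0.25 log 0.25)) / log 2
    expect_lt(abs(computeEd(c(3, 1)) - 0.1887), 1e-4)
    expect_error(computeEd(c(0, 0)), "all-zero")
    expect_error(computeEd(5), "at least 2")

    expect_equal(computeEd(c(1, 1, 1), metric = "gini_simpson"), 0)
    expect_equal(computeEd(c(1, 0, 0), metric = "gini_simpson"), 1)
    expect_equal(computeEd(c(2, 2, 2), metric = "cv"), 0)

    # scale- and permutation-invariance; spread monotonicity
    set.seed(13)
    for (k in 1:200) {
        v <- rexp(sample(3:12, 1)) * 10
        c1 <- runif(1, 0.01, 100)
        for (metric in c("shannon", "gini_simpson", "cv")) {
            e <- computeEd(v, metric = metric)
            expect_equal(computeEd(c1 * v, metric = metric), e,
                         tolerance = 1e-12)
            expect_equal(computeEd(sample(v), metric = metric), e,
                         tolerance = 1e-12)
            expect_gte(e, 0); expect_lte(e, 1)
        }
    }
    deltas <- seq(0.1, 0.9, by = 0.1)
    eds <- vapply(deltas, function(d) computeEd(c(1 + d, 1 - d)), numeric(1))
    expect_true(all(diff(eds) > 0))
})

test_that("conservation classification uses inclusive bands (boundary grid)", {
    ratios <- c(0.4, 0.5, 2, 2.1)
    deltas <- c(-0.3, -0.25, 0.25, 0.3)
    grid <- expand.grid(ratio = ratios, delta = deltas)
    got <- classifyConservation(grid$ratio, grid$delta)
    expEp <- c("down", "conserved", "conserved", "up")[match(grid$ratio, ratios)]
    expEd <- c("shrunk", "conserved", "conserved",
               "enlarged")[match(grid$delta, deltas)]
    expect_identical(got$ep_class, expEp)
    expect_identical(got$ed_class, expEd)
    expect_identical(got$nine_group, paste(expEp, expEd, sep = ":"))

    expect_identical(classifyConservation(1, 0)$nine_group,
                     "conserved:conserved")
    expect_identical(classifyConservation(3, 0.3)$nine_group, "up:enlarged")
    expect_true(is.na(classifyConservation(NA, 0)$nine_group))
})

test_that("equal-count binning follows the remainder and tie rules", {
    expect_equal(as.vector(table(binEqualCount(rnorm(10), 5))), rep(2L, 5))
    b11 <- binEqualCount(seq_len(11), 5)
    expect_equal(as.vector(table(b11)), c(3L, 2L, 2L, 2L, 2L))
    # labels ordered by increasing statistic
    expect_true(all(diff(b11[order(seq_len(11))]) >= 0))

    tied <- binEqualCount(rep(1, 9), 4)
    expect_true(max(table(tied)) - min(table(tied)) <= 1)
    expect_identical(tied, binEqualCount(rep(1, 9), 4))  # deterministic

    # invariance under strictly monotone transforms
    set.seed(21)
    v <- rexp(57)
    expect_identical(binEqualCount(v, 5), binEqualCount(log(v), 5))
    expect_identical(binEqualCount(v, 5), binEqualCount(v^3, 5))

    expect_error(binEqualCount(1:3, 5), "more groups")
})

test_that("Ep correlation matches hand-computed Pearson values", {
    x <- c(1, 2, 3, 4)
    expect_equal(correlateEp(x, 2 * x)$r, 1)
    expect_equal(correlateEp(x, rev(x))$r, -1)
    # hand computation: cross-deviations sum 3, each SS 5 -> r = 3/5
    expect_equal(correlateEp(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
    expect_error(correlateEp(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("nine-group labels partition every gene with a defined ratio", {
    sim <- simulateDataset(simulationConfig(nGenes = 400, seed = 23))
    st <- geneExpressionStats(sim$expr)
    ok <- !is.na(st$ep_ratio)
    expect_true(all(!is.na(st$nine_group[ok])))
    counts <- table(st$nine_group[ok])
    expect_equal(sum(counts), sum(ok))
    expect_true(all(names(counts) %in% as.vector(outer(
        c("down", "conserved", "up"), c("shrunk", "conserved", "enlarged"),
        paste, sep = ":"))))
})
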