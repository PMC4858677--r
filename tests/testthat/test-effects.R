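test_that("two-way Type II ANOVA agrees with the car oracle", {
    skip_if_not_installed("car")
    set.seed(61)
    # balanced and unbalanced random designs
    for (k in 1:10) {
        nA <- 2; nB <- sample(3:5, 1)
        reps <- sample(2:4, 1)
        A <- factor(rep(rep(letters[1:nA], each = nB), reps))
        B <- factor(rep(rep(LETTERS[1:nB], nA), reps))
        if (k > 5) {  # unbalance by dropping a few observations
            dropIdx <- sample(length(A), 3)
            A <- A[-dropIdx]; B <- B[-dropIdx]
        }
        y <- rnorm(length(A)) + as.integer(A) * 0.5 +
            (as.integer(B) == 2) * 0.7
        mine <- anovaTwoWay(y, A, B)
        oracle <- car::Anova(stats::lm(y ~ A * B), type = 2)
        expect_equal(mine$ss[1:3], oracle$`Sum Sq`[1:3], tolerance = 1e-9)
        expect_equal(mine$df[1:3], oracle$Df[1:3])
        expect_equal(mine$p[1:3], oracle$`Pr(>F)`[1:3], tolerance = 1e-9)
        expect_equal(mine$ss[4], oracle$`Sum Sq`[4], tolerance = 1e-9)
    }
})

test_that("balanced-design identities hold: SS additivity and closed forms", {
    set.seed(62)
    # SS_A + SS_B + SS_AB + SS_res = SS_total on balanced designs
    for (k in 1:10) {
        A <- factor(rep(rep(c("e1", "e2"), each = 7), 3))
        B <- factor(rep(rep(sprintf("p%d", 1:7), 2), 3))
        y <- rnorm(length(A))
        res <- anovaTwoWay(y, A, B)
        expect_equal(sum(res$ss), sum((y - mean(y))^2), tolerance = 1e-9)
    }
    # balanced 2x2 with n=2/cell, cell means (0,0,0,delta), no noise:
    # each factorial contrast is delta/4 on average -> every SS = n*delta^2/4
    delta <- 3
    A <- factor(rep(c("a1", "a2"), each = 4))
    B <- factor(rep(c("b1", "b2", "b1", "b2"), each = 2))
    y <- ifelse(A == "a2" & B == "b2", delta, 0)
    res <- anovaTwoWay(y, A, B)
    expect_equal(res$ss[1:3], rep(2 * delta^2 / 4, 3), tolerance = 1e-12)
    expect_true(attr(res, "degenerate"))  # zero residual variance
    expect_equal(res$p[1:3], rep(0, 3))

    # constant response: all SS zero, flagged, F undefined
    resC <- anovaTwoWay(rep(5, 8), A, B)
    expect_true(attr(resC, "degenerate"))
    expect_true(all(resC$ss == 0))
    expect_true(all(is.na(resC$f[1:3])))
})

test_that("confounded designs drop the interaction with a flag", {
    # B nested in A: no cell for (a1, b3) etc -> interaction inestimable
    A <- factor(c("a1", "a1", "a1", "a1", "a2", "a2", "a2", "a2"))
    B <- factor(c("b1", "b1", "b2", "b2", "b3", "b3", "b4", "b4"))
    res <- anovaTwoWay(rnorm(8), A, B)
    expect_true(attr(res, "interaction_dropped"))
    expect_equal(res$df[3], 0)
    expect_true(is.na(res$f[3]))
})

test_that("matrix and single-gene ANOVA paths give identical answers", {
    set.seed(63)
    A <- factor(rep(c("JH", "QG"), each = 21))
    B <- factor(rep(sprintf("P%02d", 1:7), 6))
    Y <- matrix(rnorm(5 * 42), 5, 42,
                dimnames = list(sprintf("g%d", 1:5), NULL))
    mat <- anovaTwoWayMatrix(Y, A, B)
    for (i in 1:5) {
        single <- anovaTwoWay(Y[i, ], A, B)
        expect_equal(unname(mat$p[i, ]), single$p[1:3], tolerance = 1e-12)
        expect_equal(unname(mat$ss[i, ]), single$ss[1:3], tolerance = 1e-12)
    }
})

test_that("fitAllGenes covers every eligible gene and controls q per term", {
    sim <- simulateDataset(simulationConfig(nGenes = 150, seed = 64))
    keep <- filterExpressedGenes(sim$expr)
    x <- sim$expr[keep, ]
    eff <- fitAllGenes(x, model = "pop_env")
    expect_equal(length(unique(eff$gene_id)), length(keep))
    expect_setequal(unique(eff$term),
                    c("environment", "population", "interaction"))
    expect_true(all(eff$q >= eff$p * 0 , na.rm = TRUE))

    expect_error(fitAllGenes(x, model = "hap_env"), "DiplotypeSet")
})

test_that("Storey and BH q-values behave per the step-up arithmetic", {
    # BH on (0.01, 0.02, 0.03, 0.04): q = m p / i cummin-ed = 0.04 each
    bh <- controlFdr(c(0.01, 0.02, 0.03, 0.04), method = "bh")
    expect_equal(bh$qvalues, rep(0.04, 4))
    expect_identical(bh$qvalues, stats::p.adjust(c(0.01, 0.02, 0.03, 0.04),
                                                 "BH"))

    allOne <- controlFdr(rep(1, 20), method = "storey")
    expect_true(all(allOne$qvalues == 1))
    expect_false(any(allOne$rejected))

    # q monotone in p, q <= 1, pi0 in [0, 1]
    set.seed(65)
    p <- c(runif(300), rbeta(100, 0.2, 5))
    st <- controlFdr(p, method = "storey")
    o <- order(p)
    expect_true(all(diff(st$qvalues[o]) >= -1e-12))
    expect_true(all(st$qvalues <= 1 & st$qvalues >= 0))
    expect_true(st$pi0 > 0 && st$pi0 <= 1)
    # Storey q = pi0 * BH q
    expect_equal(st$qvalues, st$pi0 * stats::p.adjust(p, "BH"),
                 tolerance = 1e-12)

    expect_error(controlFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Storey pFDR controls the realized FDR on mixture simulations", {
    set.seed(66)
    fdrs <- replicate(50, {
        p <- c(runif(160), pmin(1, rbeta(40, 0.05, 8)))
        isNull <- c(rep(TRUE, 160), rep(FALSE, 40))
        st <- controlFdr(p, method = "storey", alpha = 0.05)
        if (!any(st$rejected)) 0 else mean(isNull[st$rejected])
    })
    expect_lte(mean(fdrs), 0.075)
})

test_that("Wilcoxon wrapper: exact branch matches enumeration, ties fall back", {
    w <- wilcoxonRankSum(c(1, 2), c(3, 4))
    expect_equal(w$p, 1 / 3)  # 2 of C(4,2)=6 assignments as extreme
    expect_equal(wilcoxonRankSum(1:4, 1:4 + 0.5)$p,
                 wilcoxExactOracle(1:4, 1:4 + 0.5))
    # identical samples -> tie fallback, p near 1 (not exact branch)
    expect_gt(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p, 0.9)
    expect_error(wilcoxonRankSum(numeric(0), 1:3), "empty")
})

test_that("effect recovery and eight-group classification on planted data", {
    cfg <- simulationConfig(nGenes = 400, fracEnvEffect = 0.5,
                            fracPopEffect = 0, fracHapEffect = 0,
                            fracInteraction = 0, seed = 67)
    sim <- simulateDataset(cfg)
    keep <- filterExpressedGenes(sim$expr)
    eff <- fitAllGenes(sim$expr[keep, ], model = "pop_env")
    pe <- eff[eff$term == "environment", ]
    tr <- sim$truth[match(pe$gene_id, sim$truth$gene_id), ]
    expect_gte(mean(pe$flag[tr$has_env_effect]), 0.95)

    # hap_env model end-to-end on a hap-effect-rich simulation
    cfgH <- simulationConfig(nGenes = 200, fracGenesWithSnps = 0.9,
                             fracHapEffect = 0.5, fracEnvEffect = 0.2,
                             fracInteraction = 0, missingRate = 0, seed = 68)
    simH <- simulateDataset(cfgH)
    keepH <- filterExpressedGenes(simH$expr)
    filt <- filterSnps(simH$snps[intersect(keepH, geneIds(simH$snps))])
    dip <- phaseAllGenes(filt, individualId = individualId(simH$expr),
                         seed = 2)
    effH <- fitAllGenes(simH$expr[keepH, ], diplotypes = dip,
                        model = "hap_env")
    eight <- classifyEightGroups(effH)
    # partition: one label per tested gene, all labels from the 8 subsets
    expect_equal(nrow(eight), length(unique(effH$gene_id)))
    valid <- c("none", "E", "H", "HxE", "E+H", "E+HxE", "H+HxE", "E+H+HxE")
    expect_true(all(eight$eight_group %in% valid))
    # planted haplotype effects enrich H-containing labels
    trH <- simH$truth[match(eight$gene_id, simH$truth$gene_id), ]
    hsens <- mean(grepl("H", sub("HxE", "", eight$eight_group))[
        trH$has_hap_effect & !trH$has_env_effect])
    expect_gt(hsens, 0.5)
})
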