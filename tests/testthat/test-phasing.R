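test_that("single-SNP genes phase unambiguously", {
    geno <- matrix(c(1L, 2L, 0L), 1,
                   dimnames = list(NULL, c("a", "b", "c")))
    ph <- phaseGeneEM(geno, seed = 1)
    a <- ph$assignment
    expect_identical(a$hap1[a$sample_id == "a"], "0")
    expect_identical(a$hap2[a$sample_id == "a"], "1")
    expect_identical(a$hap1[a$sample_id == "b"], "1")
    expect_identical(a$hap2[a$sample_id == "b"], "1")
    expect_identical(a$hap1[a$sample_id == "c"], "0")
})

test_that("homozygotes anchor the phase of a double heterozygote", {
    # genotypes over 2 sites: (0,0), (2,2), (1,1): the double het must be
    # 00|11 because those two haplotypes are forced by the homozygotes
    geno <- matrix(c(0L, 0L, 2L, 2L, 1L, 1L), nrow = 2,
                   dimnames = list(NULL, c("a", "b", "c")))
    ph <- phaseGeneEM(geno, nRestarts = 10, seed = 2)
    a <- ph$assignment
    expect_identical(c(a$hap1[3], a$hap2[3]), c("00", "11"))
    # EM optimum agrees with exhaustive ML over the full simplex
    ora <- exhaustiveMLFreqs(geno, seed = 5)
    expect_equal(ph$logLik, ora$logLik, tolerance = 1e-6)
})

test_that("EM log-likelihood never decreases within any restart", {
    set.seed(91)
    for (k in 1:20) {
        s <- sample(1:5, 1)
        pool <- local({
            h <- unique(replicate(sample(2:4, 1),
                paste(sample(0:1, s, TRUE), collapse = "")))
            f <- rexp(length(h)); names(f) <- h; f / sum(f)
        })
        g <- simulateGenotypes(pool, n = 20)
        colnames(g$geno) <- sprintf("i%02d", 1:20)
        ph <- phaseGeneEM(g$geno, nRestarts = 3, seed = k)
        for (tr in ph$llTrace)
            expect_true(all(diff(tr) >= -1e-9))
    }
})

test_that("EM equals combinatorial phasing when <= 1 het site per individual", {
    # with at most one het site, each individual's pair is unique
    pool <- c(`000` = 0.5, `100` = 0.3, `001` = 0.2)
    g <- simulateGenotypes(pool, 40, seed = 12)
    colnames(g$geno) <- sprintf("i%02d", 1:40)
    oneHet <- colSums(g$geno == 1L) <= 1
    ph <- phaseGeneEM(g$geno, seed = 3)
    for (i in which(oneHet)) {
        expect_identical(ph$assignment$hap1[i], g$hap1[i])
        expect_identical(ph$assignment$hap2[i], g$hap2[i])
    }
})

test_that("EM frequencies match exhaustive ML on tiny instances", {
    # fixed instances with homozygote anchors so the ML optimum is unique
    instances <- list(
        matrix(c(0L, 0L,  2L, 2L,  1L, 1L,  0L, 0L), nrow = 2),
        matrix(c(0L, 0L, 0L,  2L, 2L, 2L,  1L, 1L, 1L,  2L, 0L, 2L,
                 0L, 0L, 2L), nrow = 3),
        matrix(c(0L, 2L,  2L, 0L,  1L, 1L,  1L, 1L,  0L, 2L,  2L, 2L),
               nrow = 2))
    for (k in seq_along(instances)) {
        geno <- instances[[k]]
        colnames(geno) <- sprintf("i%d", seq_len(ncol(geno)))
        ph <- phaseGeneEM(geno, nRestarts = 25, seed = k, tol = 1e-12)
        ora <- exhaustiveMLFreqs(geno, seed = k)
        expect_equal(ph$logLik, ora$logLik, tolerance = 1e-9)
        oraTop <- ora$freqs[ora$freqs > 1e-6]
        emTop <- ph$hapFreqs[ph$hapFreqs > 1e-6]
        expect_setequal(names(emTop), names(oraTop))
        expect_lt(max(abs(emTop[names(oraTop)] - oraTop / sum(oraTop))),
                  1e-6)
    }

    # and on random HWE draws the attained maxima agree
    set.seed(55)
    for (k in 1:5) {
        s <- sample(2:3, 1); n <- sample(4:6, 1)
        pool <- local({
            h <- unique(replicate(3, paste(sample(0:1, s, TRUE),
                                           collapse = "")))
            f <- rexp(length(h)); names(f) <- h; f / sum(f)
        })
        g <- simulateGenotypes(pool, n)
        colnames(g$geno) <- sprintf("i%d", seq_len(n))
        ph <- phaseGeneEM(g$geno, nRestarts = 20, seed = k)
        ora <- exhaustiveMLFreqs(g$geno, seed = k)
        expect_equal(ph$logLik, ora$logLik, tolerance = 1e-6)
    }
})

test_that("recovery on a 4-SNP gene with three haplotypes is near-perfect", {
    pool <- c(`0000` = 0.5, `0110` = 0.3, `1011` = 0.2)
    g <- simulateGenotypes(pool, 80, seed = 42)
    colnames(g$geno) <- sprintf("i%02d", 1:80)
    ph <- phaseGeneEM(g$geno, nRestarts = 5, seed = 9)
    recovered <- mean(paste(g$hap1, g$hap2) ==
                      paste(ph$assignment$hap1, ph$assignment$hap2))
    expect_gte(recovered, 0.95)
})

test_that("missing genotypes are marginalised, not fatal", {
    pool <- c(`00` = 0.6, `11` = 0.4)
    g <- simulateGenotypes(pool, 30, seed = 8)
    colnames(g$geno) <- sprintf("i%02d", 1:30)
    g$geno[1, 3] <- NA; g$geno[2, 7] <- NA
    ph <- phaseGeneEM(g$geno, seed = 4)
    expect_equal(nrow(ph$assignment), 30)
    expect_true(all(nchar(c(ph$assignment$hap1, ph$assignment$hap2)) == 2))
    expect_lt(abs(sum(ph$hapFreqs) - 1), 1e-9)
})

test_that("SNP-count limits are enforced", {
    geno <- matrix(sample(0:2, 10 * 4, TRUE), 10)
    expect_error(phaseGeneEM(geno), "restricted")
    expect_error(phaseGeneEM(matrix(integer(0), 0, 4)), "no SNPs")
})

test_that("diplotype factor canonicalises pairs and merges rare levels", {
    a <- data.frame(sample_id = sprintf("s%d", 1:7),
                    hap1 = c("00", "00", "11", "11", "01", "00", "00"),
                    hap2 = c("11", "11", "00", "00", "10", "00", "00"))
    f <- diplotypeFactor(a)
    # 00|11 from either order is one level
    expect_equal(unname(f["s1"]), unname(f["s3"]))
    # the singleton 01|10 is merged into "rare"
    expect_equal(as.character(f["s5"]), "rare")
    expect_equal(nlevels(f), 3)

    # all-identical diplotypes -> gene dropped
    b <- data.frame(sample_id = c("s1", "s2"), hap1 = c("0", "0"),
                    hap2 = c("1", "1"))
    expect_null(diplotypeFactor(b))
})

test_that("phaseAllGenes phases eligible genes per genet", {
    sim <- simulateDataset(simulationConfig(nGenes = 60,
                                            fracGenesWithSnps = 0.8,
                                            missingRate = 0, seed = 77))
    filt <- filterSnps(sim$snps)
    ns <- nSnps(filt)
    dip <- phaseAllGenes(filt, individualId = individualId(sim$expr),
                         seed = 5)
    expect_setequal(geneIds(dip), names(ns)[ns >= 1 & ns <= 9])
    # per-genet: one row per genet, shared across environments
    nGenet <- length(unique(individualId(sim$expr)))
    for (g in geneIds(dip))
        expect_equal(nrow(assignments(dip)[[g]]), nGenet)
    # haplotype pairs are consistent with the genotype codes at every site
    ind <- individualId(sim$expr)
    first <- !duplicated(ind)
    for (g in geneIds(dip)[1:5]) {
        a <- assignments(dip)[[g]]
        geno <- snpGenotypes(filt, g)[, first, drop = FALSE]
        h1 <- do.call(rbind, lapply(strsplit(a$hap1, ""), as.integer))
        h2 <- do.call(rbind, lapply(strsplit(a$hap2, ""), as.integer))
        implied <- t(h1 + h2)
        obs <- geno
        ok <- is.na(obs) | obs == implied
        expect_true(all(ok))
    }
})
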