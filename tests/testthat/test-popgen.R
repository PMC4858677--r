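test_that("SNP filter excludes sites at each threshold boundary", {
    # 40 diploids; site layout:
    #  1: fine on all counts           -> kept
    #  2: quality exactly 10           -> excluded
    #  3: MAF exactly 0.05 (4/80)      -> excluded
    #  4: 4 missing genotypes = 10%    -> excluded
    #  5: MAF just above 0.05 (5/80)   -> kept
    n <- 40
    mk <- function(nAlt1, nMissing = 0) {
        g <- rep(0L, n)
        if (nAlt1 > 0) g[seq_len(nAlt1)] <- 1L
        if (nMissing > 0) g[(n - nMissing + 1):n] <- NA_integer_
        g
    }
    geno <- rbind(mk(20), mk(20), mk(4), mk(20, 4), mk(5))
    snps <- SNPSet(list(g1 = list(position = c(10L, 20L, 30L, 40L, 50L),
                                  quality = c(50, 10, 50, 50, 50),
                                  geno = geno)),
                   c(g1 = 1000L), sprintf("s%02d", 1:n))
    kept <- filterSnps(snps)
    expect_identical(snpPositions(kept, "g1"), c(10L, 50L))

    # an all-missing site is excluded (missing fraction 1)
    snps2 <- SNPSet(list(g1 = list(position = 1L, quality = 50,
                                   geno = matrix(NA_integer_, 1, n))),
                    c(g1 = 1000L), sprintf("s%02d", 1:n))
    expect_identical(unname(nSnps(filterSnps(snps2))["g1"]), 0L)
})

test_that("pi matches its hand example and the pairwise-difference oracle", {
    # one site, 2 diploids both 0/1, L = 100: mean pairwise difference over
    # C(4,2)=6 allele pairs is 4/6 -> pi = (4/3 * 1/2)/100
    expect_equal(computePi(matrix(c(1L, 1L), 1), 100), (4 / 3 * 0.5) / 100)
    expect_equal(computePi(matrix(c(1L, 1L), 1), 100),
                 piBruteForce(matrix(c(1L, 1L), 1), 100))
    expect_equal(computePi(matrix(integer(0), 0, 5), 100), 0)

    set.seed(301)
    for (k in 1:250) {
        n <- sample(2:10, 1); s <- sample(1:5, 1)
        geno <- matrix(sample(c(0:2, NA), s * n, TRUE,
                              prob = c(0.3, 0.3, 0.3, 0.1)), s, n)
        L <- sample(50:500, 1)
        expect_equal(computePi(geno, L), piBruteForce(geno, L),
                     tolerance = 1e-12)
    }
})

test_that("pi is invariant under reference-allele relabeling", {
    set.seed(33)
    for (k in 1:50) {
        n <- sample(3:10, 1); s <- sample(1:4, 1)
        geno <- matrix(sample(0:2, s * n, TRUE), s, n)
        expect_equal(computePi(geno, 100), computePi(2L - geno, 100),
                     tolerance = 1e-14)
    }
})

test_that("pi converges to Nei heterozygosity under HWE", {
    p <- 0.3; n <- 10000
    g <- simulateGenotypes(c(`0` = 1 - p, `1` = p), n, seed = 7)
    # per-site pi * L equals ~ 2p(1-p) (correction ~ 1 at this n)
    expect_equal(computePi(g$geno, 1) ,
                 2 * p * (1 - p), tolerance = 0.02)
})

test_that("per-environment diversity table partitions genes by SNP presence", {
    sim <- simulateDataset(simulationConfig(nGenes = 120, seed = 15))
    div <- geneDiversity(sim$snps, sim$expr)
    expect_equal(nrow(div), 2 * length(geneIds(sim$snps)))
    expect_true(all(div$pi >= 0))
    expect_true(all(div$pi[!div$has_snp] == 0))
    expect_true(all(div$n_snps[div$has_snp] > 0))

    groups <- groupBySnpPresence(div)
    for (e in names(groups)) {
        expect_length(intersect(groups[[e]]$with_snp,
                                groups[[e]]$without_snp), 0)
        expect_setequal(c(groups[[e]]$with_snp, groups[[e]]$without_snp),
                        geneIds(sim$snps))
    }

    # frequency bound: pi <= 0.5 * (2n/(2n-1)) * n_snps / L
    gl <- geneLengths(sim$snps)
    nEnv <- table(envFactor(sim$expr))
    for (i in which(div$has_snp)) {
        nAll <- 2 * nEnv[[div$environment[i]]]
        bound <- 0.5 * (nAll / (nAll - 1)) * div$n_snps[i] /
            gl[[div$gene_id[i]]]
        expect_lte(div$pi[i], bound + 1e-12)
    }
})
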