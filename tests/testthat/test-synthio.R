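# Synthetic cohort generator: LD structure, marginal MAF, planted effects,
# fixture round trips and determinism.

test_that("configuration invariants are enforced", {
    expect_error(simConfig(nSamples = 5), "nSamples")
    expect_error(simConfig(mafRange = c(0, 0.5)), "mafRange")
    expect_error(simConfig(mafRange = c(0.1, 0.6)), "mafRange")
    expect_error(simConfig(noiseSd = 0), "noiseSd")
    expect_error(simConfig(nLoci = 1, effectSizes = c(0.5, 0.5)),
                 "absent locus")
})

test_that("perfect copying gives identical dosage columns with r2 = 1", {
    cfg <- simConfig(nSamples = 200, nLoci = 1, snpsPerLocus = 2,
                     mafRange = c(0.3, 0.3), ldDecay = 1, seed = 42)
    d <- dosages(simulateGenotypes(cfg))
    expect_identical(d[1, ], d[2, ])
    expect_equal(computeLDr2(d[1, ], d[2, ]), 1)
})

test_that("independent variants are uncorrelated at large n", {
    cfg <- simConfig(nSamples = 5000, nLoci = 1, snpsPerLocus = 2,
                     mafRange = c(0.3, 0.3), ldDecay = 0, seed = 7)
    d <- dosages(simulateGenotypes(cfg))
    expect_lt(computeLDr2(d[1, ], d[2, ]), 0.01)
})

test_that("adjacent-pair r2 matches a forward haplotype simulation oracle", {
    # oracle: independent re-implementation of the copying chain for two
    # variants at equal MAF, measuring dosage r^2 directly
    oracle <- function(t, p, nhap, seed) {
        set.seed(seed)
        u1 <- runif(nhap)
        copy <- runif(nhap) < t
        u2 <- ifelse(copy, u1, runif(nhap))
        a1 <- as.numeric(u1 < p); a2 <- as.numeric(u2 < p)
        o <- seq(1, nhap, by = 2); e <- seq(2, nhap, by = 2)
        cor(a1[o] + a1[e], a2[o] + a2[e])^2
    }
    oracleVals <- vapply(1:40, function(s) oracle(0.9, 0.3, 10000, s),
                         numeric(1))
    cfg <- lapply(1:40, function(s)
        simConfig(nSamples = 5000, nLoci = 1, snpsPerLocus = 2,
                  mafRange = c(0.3, 0.3), ldDecay = 0.9, seed = 100 + s))
    pkgVals <- vapply(cfg, function(cf) {
        d <- dosages(simulateGenotypes(cf))
        computeLDr2(d[1, ], d[2, ])
    }, numeric(1))
    # means agree within 3 combined Monte-Carlo standard errors
    se <- sqrt(var(oracleVals) / 40 + var(pkgVals) / 40)
    expect_lt(abs(mean(oracleVals) - mean(pkgVals)), 3 * se)
})

test_that("realized MAF tracks the target within 3 binomial SE", {
    cfg <- simConfig(nSamples = 400, nLoci = 2, snpsPerLocus = 15,
                     ldDecay = 0.5, seed = 9)
    ge <- simulateGenotypes(cfg)
    vi <- as.data.frame(SummarizedExperiment::rowData(ge))
    d <- dosages(ge)
    realized <- rowMeans(d) / 2
    target <- vi$maf_target
    se <- sqrt(target * (1 - target) / (2 * cfg@nSamples))
    expect_true(all(abs(realized - target) <= 3.5 * se))
    # and essentially no r2 >= 0.8 pairs under ld_decay = 0
    cfg0 <- simConfig(nSamples = 1000, nLoci = 1, snpsPerLocus = 12,
                      ldDecay = 0, seed = 10)
    d0 <- dosages(simulateGenotypes(cfg0))
    r2 <- cor(t(d0))^2
    expect_equal(sum(r2[upper.tri(r2)] >= 0.8), 0)
})

test_that("null cohorts give slope estimates centered on zero and the
           noiseless limit recovers the planted slope exactly", {
    cfg <- simConfig(nSamples = 150, nLoci = 1, snpsPerLocus = 2,
                     probesPerLocus = 2, seed = 11)
    ge <- simulateGenotypes(cfg)
    slopes <- vapply(1:60, function(s) {
        cf <- simConfig(nSamples = 150, nLoci = 1, snpsPerLocus = 2,
                        probesPerLocus = 2, seed = 1000 + s)
        g <- simulateGenotypes(cf)
        sim <- simulateExpression(g, cf)
        fitSnpProbe(dosages(g)[1, ], exprValues(sim$expr)[1, ])$slope
    }, numeric(1))
    expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))

    cfgN <- simConfig(nSamples = 100, nLoci = 1, snpsPerLocus = 3,
                      probesPerLocus = 1, effectSizes = 1,
                      noiseSd = 1e-9, seed = 12)
    gN <- simulateGenotypes(cfgN)
    simN <- simulateExpression(gN, cfgN)
    fit <- fitSnpProbe(dosages(gN)[simN$truth$rsid, ],
                       exprValues(simN$expr)[simN$truth$probe_id, ])
    expect_equal(fit$slope, 1, tolerance = 1e-6)
})

test_that("truth ledger cis labels agree with classifyProbes", {
    sc <- smallCohort(effectSizes = 0.5, seed = 21)
    lab <- merge(sc$truth, sc$assignments,
                 by = "probe_id")
    expect_true(all(lab$class.x == lab$class.y))
})

test_that("fixtures round-trip bit-identically and rewrite byte-identically", {
    sc <- smallCohort(nSamples = 30, snpsPerLocus = 4, probesPerLocus = 3,
                      seed = 31)
    dir1 <- file.path(tempdir(), "fx1")
    paths <- writeFixture(sc$geno, sc$expr, sc$truth, dir1)
    ge2 <- readGenotypes(paths[["genotypes"]])
    ee2 <- readExpression(paths[["expression"]], paths[["probes"]],
                          state = "normalized")
    expect_identical(unname(dosages(ge2)), unname(dosages(sc$geno)))
    expect_identical(unname(exprValues(ee2)), unname(exprValues(sc$expr)))

    dir2 <- file.path(tempdir(), "fx2")
    paths2 <- writeFixture(sc$geno, sc$expr, sc$truth, dir2)
    for (k in names(paths))
        expect_identical(unname(tools::md5sum(paths[[k]])),
                         unname(tools::md5sum(paths2[[k]])))

    empty <- sc$geno[, integer(0)]
    expect_error(writeFixture(empty, sc$expr, sc$truth,
                              file.path(tempdir(), "fx3")), "empty cohort")
})

test_that("a fixed seed reproduces the whole cohort bit-identically", {
    a <- smallCohort(seed = 55, effectSizes = 0.3)
    b <- smallCohort(seed = 55, effectSizes = 0.3)
    expect_identical(dosages(a$geno), dosages(b$geno))
    expect_identical(exprValues(a$expr), exprValues(b$expr))
    expect_identical(a$meta, b$meta)
})

test_that("softened genotypes carry valid posteriors and matching dosages", {
    cfg <- simConfig(nSamples = 80, nLoci = 1, snpsPerLocus = 5,
                     imputationCertainty = 0.9, seed = 61)
    ge <- simulateGenotypes(cfg)
    expect_true(all(c("gpAA", "gpAB", "gpBB") %in%
                        SummarizedExperiment::assayNames(ge)))
    gpSum <- SummarizedExperiment::assay(ge, "gpAA") +
        SummarizedExperiment::assay(ge, "gpAB") +
        SummarizedExperiment::assay(ge, "gpBB")
    expect_equal(max(abs(gpSum - 1)), 0, tolerance = 1e-12)
    expd <- SummarizedExperiment::assay(ge, "gpAB") +
        2 * SummarizedExperiment::assay(ge, "gpBB")
    expect_equal(unname(dosages(ge)), unname(expd), tolerance = 1e-12)
})
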