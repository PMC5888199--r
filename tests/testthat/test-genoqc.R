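# Genotype QC: MAF and INFO statistics, strict-threshold filters and
# first-failing-rule accounting.

test_that("computeMAF folds the mean dosage and survives relabeling", {
    expect_equal(computeMAF(c(0, 0, 0, 0)), 0)
    expect_equal(computeMAF(c(2, 2, 2, 2)), 0)
    expect_equal(computeMAF(c(0, 1, 1, 2)), 0.5)
    expect_equal(computeMAF(c(0, 1, NA, 2, 1)), computeMAF(c(0, 1, 2, 1)))
    for (s in 1:20) {
        set.seed(s)
        d <- sample(0:2, 30, replace = TRUE)
        expect_equal(computeMAF(d), computeMAF(2 - d))
    }
    expect_error(computeMAF(c(NA_real_, NA_real_)), "all dosages missing")
})

test_that("computeINFO matches its defining formula and boundary conventions", {
    certain <- matrix(0, 10, 3); certain[, 2] <- 1
    expect_equal(computeINFO(certain), 1)
    # monomorphic certain calls: pbar in {0, 1} convention
    mono <- matrix(0, 10, 3); mono[, 1] <- 1
    expect_equal(computeINFO(mono), 1)
    # uniform posteriors at pbar = 0.5: direct evaluation of the ratio,
    # computed here from first principles, then clamped into [0, 1]
    unif <- matrix(1 / 3, 8, 3)
    eg <- 1 / 3 + 2 / 3; varg <- (1 / 3 + 4 / 3) - eg^2
    pbar <- eg / 2
    expected <- max(0, 1 - varg / (2 * pbar * (1 - pbar)))
    expect_equal(computeINFO(unif), expected)
    # partially certain heterozygotes: again direct formula evaluation
    gp <- matrix(c(0.1, 0.8, 0.1), 6, 3, byrow = TRUE)
    eg <- 0.8 + 0.2; varg <- (0.8 + 0.4) - eg^2
    expect_equal(computeINFO(gp), 1 - varg / (2 * 0.5 * 0.5))
    expect_error(computeINFO(matrix(c(0.5, 0.2, 0.2), 3, 3, byrow = TRUE)),
                 "malformed")
})

test_that("filters use strict inequalities and account for every exclusion", {
    # 10 variants: 2 fail call rate, 1 fails MAF, 1 sits in a blacklisted
    # region; 6 survive
    set.seed(5)
    n <- 100
    d <- matrix(rbinom(10 * n, 2, 0.3), 10, n,
                dimnames = list(sprintf("v%02d", 1:10),
                                sprintf("S%03d", 1:n)))
    d[1, 1:5] <- NA  # call rate 0.95
    d[2, 1:3] <- NA  # call rate 0.97
    d[3, ] <- c(rep(1, 1), rep(0, n - 1))  # MAF 0.005
    ge <- GenotypeExperiment(d, data.frame(
        rsid = rownames(d), chrom = c(rep("1", 9), "6"),
        pos = c(1:9 * 1000, 30e6), ref = "A", alt = "G"))
    # with few variants a handful of missing calls also dents sample call
    # rates; disable the sample filter to isolate the variant rules
    out <- applyGenotypeFilters(ge, minSampleCallRate = 0)
    expect_equal(out$report@nVariantsOut, 6L)
    expect_equal(sum(out$report@variantsRemoved), 4L)
    expect_equal(unname(out$report@variantsRemoved[c(
        "call_rate", "maf", "region_blacklist")]), c(2L, 1L, 1L))
    expect_equal(out$report@nVariantsIn,
                 out$report@nVariantsOut + sum(out$report@variantsRemoved))

    # boundary: MAF exactly at threshold survives; INFO exactly 0.8 survives
    nb <- 200
    db <- rbind(v1 = c(rep(1, 4), rep(0, nb - 4)),      # MAF exactly 0.01
                v2 = rbinom(nb, 2, 0.4))
    colnames(db) <- sprintf("S%03d", 1:nb)
    geb <- toyGeno(db)
    outb <- applyGenotypeFilters(geb, regionBlacklist = NULL)
    expect_equal(outb$report@nVariantsOut, 2L)
    expect_equal(computeMAF(db[1, ]), 0.01)
})

test_that("filtering is idempotent and quality blacklists attribute first", {
    sc <- smallCohort(seed = 77)
    once <- applyGenotypeFilters(sc$geno)
    twice <- applyGenotypeFilters(once$genotypes)
    expect_identical(dosages(once$genotypes), dosages(twice$genotypes))
    expect_equal(sum(twice$report@variantsRemoved), 0L)

    rsids <- as.data.frame(SummarizedExperiment::rowData(sc$geno))$rsid
    out <- applyGenotypeFilters(sc$geno, qualityBlacklist = rsids[1:2])
    expect_equal(unname(out$report@variantsRemoved[["quality_blacklist"]]), 2L)
})

test_that("INFO filter acts on stored posteriors", {
    cfg <- simConfig(nSamples = 200, nLoci = 1, snpsPerLocus = 10,
                     imputationCertainty = 0.55, seed = 91)
    ge <- simulateGenotypes(cfg)
    vi <- as.data.frame(variantInfo(ge))
    expect_true(any(vi$info < 0.8))
    # heavy softening can exclude everything: the empty survivor set is an
    # explicit flagged status, not a silent empty matrix
    if (all(vi$info < 0.8 | vi$call_rate < 0.98 | vi$maf < 0.01)) {
        expect_warning(out <- applyGenotypeFilters(ge, regionBlacklist = NULL),
                       "empty result")
    } else {
        out <- applyGenotypeFilters(ge, regionBlacklist = NULL)
    }
    expect_equal(unname(out$report@variantsRemoved[["info"]]),
                 sum(vi$info < 0.8 & vi$call_rate >= 0.98 & vi$maf >= 0.01))
})
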