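# Covariate-adjusted models, robustness sweeps and stratified rescans.

test_that("orthogonal covariates leave the slope unchanged; collinearity
           errors", {
    set.seed(53)
    n <- 200
    x <- rbinom(n, 2, 0.3)
    z <- rnorm(n)
    z <- residuals(lm(z ~ x))  # exactly orthogonal to dosage
    y <- 1 + 0.5 * x + rnorm(n)
    yperp <- residuals(lm(y ~ z)) # expression orthogonal to covariate
    base <- fitSnpProbe(x, yperp)
    adj <- fitAdjusted(x, yperp, data.frame(z = z))
    expect_equal(adj$slope, base$slope, tolerance = 1e-10)
    expect_error(fitAdjusted(x, y, data.frame(z = 2 * x)), "collinear")

    # a covariate equal to the noise reduces the slope's standard error
    noise <- rnorm(n)
    y2 <- 0.5 * x + noise
    expect_lt(fitAdjusted(x, y2, data.frame(noise = noise))$se,
              fitSnpProbe(x, y2)$se)

    # Frisch-Waugh: adjusted slope equals the double-residualized slope
    w <- 0.3 * x + rnorm(n)
    y3 <- 0.5 * x + 0.8 * w + rnorm(n)
    adj3 <- fitAdjusted(x, y3, data.frame(w = w))
    fw <- lm(residuals(lm(y3 ~ w)) ~ residuals(lm(x ~ w)))
    expect_equal(adj3$slope, unname(coef(fw)[2]), tolerance = 1e-8)

    # complete-case accounting
    w2 <- w; w2[1:7] <- NA
    adjNA <- fitAdjusted(x, y3, data.frame(w = w2))
    expect_equal(adjNA$n, n - 7L)
    expect_equal(adjNA$n_dropped, 7L)
})

test_that("left-censored CRP markers are encoded at the interval midpoint", {
    set.seed(57)
    n <- 120
    x <- rbinom(n, 2, 0.4)
    y <- 0.5 * x + rnorm(n)
    crpNum <- round(rlnorm(n, log(8), 0.5), 1)
    crpChar <- as.character(crpNum)
    crpChar[crpNum < 5] <- "<5"
    crpMid <- crpNum; crpMid[crpNum < 5] <- 2.5
    a <- fitAdjusted(x, y, data.frame(crp = crpChar))
    b <- fitAdjusted(x, y, data.frame(crp = crpMid))
    expect_equal(a$slope, b$slope, tolerance = 1e-12)
})

test_that("robustness sweep flags null-covariate cohorts unchanged and
           detects planted interactions", {
    sc <- smallCohort(nSamples = 250, snpsPerLocus = 2, probesPerLocus = 2,
                      effectSizes = 0.6, seed = 59)
    res <- scanAssociations(sc$geno, sc$expr, sc$blocks, sc$assignments,
                            mode = "cis")
    eqtl <- res[res$rsid == sc$truth$rsid &
                res$probe_id == sc$truth$probe_id, ]
    sweep <- robustnessSweep(eqtl, sc$geno, sc$expr, sc$meta,
                             covariates = c("age", "sex", "crp", "sjc"))
    expect_equal(nrow(sweep), 4L)
    expect_true(all(sweep$flag == "unchanged"))
    expect_true(all(is.finite(sweep$delta)))

    expect_message(
        skipSweep <- robustnessSweep(eqtl, sc$geno, sc$expr, sc$meta,
                                     covariates = c("age", "nonesuch")),
        "skipped")
    expect_equal(unique(skipSweep$covariate), "age")
    expect_equal(nrow(robustnessSweep(eqtl, sc$geno, sc$expr, sc$meta,
                                      covariates = character(0))), 0L)

    # planted SNP x covariate interaction is detected
    set.seed(61)
    n <- 300
    x <- rbinom(n, 2, 0.3)
    cv <- rnorm(n)
    y <- 0.5 * x + 0.4 * x * cv + rnorm(n)
    expect_lt(riskQTL:::.interactionP(x, y, cv), 0.05)
    yNull <- 0.5 * x + rnorm(n)
    pNull <- vapply(1:50, function(i) {
        set.seed(1000 + i)
        riskQTL:::.interactionP(rbinom(n, 2, 0.3), rnorm(n), rnorm(n))
    }, numeric(1))
    expect_lt(abs(mean(pNull < 0.05) - 0.05), 0.15)
})

test_that("stratified scans reproduce the full scan and respect the floor", {
    sc <- smallCohort(nSamples = 120, snpsPerLocus = 3, probesPerLocus = 2,
                      effectSizes = 0.5, seed = 67)
    full <- scanAssociations(sc$geno, sc$expr, sc$blocks, sc$assignments,
                             mode = "cis")
    all1 <- stratifiedScan(sc$geno, sc$expr, sc$blocks, sc$assignments,
                           sc$meta, stratum = NULL)
    expect_equal(all1, full)
    ra <- stratifiedScan(sc$geno, sc$expr, sc$blocks, sc$assignments,
                         sc$meta, stratum = "RA")
    expect_equal(unique(ra$n), sum(sc$meta$diagnosis == "RA"))
    expect_error(stratifiedScan(sc$geno, sc$expr, sc$blocks,
                                sc$assignments, sc$meta,
                                stratum = "no-such-diagnosis"),
                 "below the floor")
})

test_that("strata with identical planted effects agree on the lead SNP", {
    agree <- vapply(1:20, function(s) {
        cfg <- simConfig(nSamples = 240, nLoci = 1, snpsPerLocus = 4,
                         probesPerLocus = 1, effectSizes = 0.8,
                         seed = 7000 + s)
        ge <- simulateGenotypes(cfg)
        sim <- simulateExpression(ge, cfg)
        vann <- as.data.frame(SummarizedExperiment::rowData(ge))
        idx <- data.frame(rsid = vann$rsid[1], chrom = vann$chrom[1],
                          pos = vann$pos[1], locus_label = "L1")
        blocks <- buildLDBlocks(idx, ge, r2Min = 0)
        asg <- classifyProbes(blocks, sim$expr)
        half <- sim$meta
        half$diagnosis <- rep(c("A", "B"), length.out = nrow(half))
        lead <- function(st) {
            r <- stratifiedScan(ge, sim$expr, blocks, asg, half,
                                stratum = st)
            r$rsid[which.min(r$p_nominal)]
        }
        lead("A") == lead("B")
    }, logical(1))
    expect_gte(mean(agree), 0.9)
})
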