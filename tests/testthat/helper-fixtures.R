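# Shared fixtures: small simulated cohorts and independent oracles.

# One-locus cohort with every SNP admitted to the test family (r2Min = 0)
# and all probes cis; returns the pieces every scan-level test needs.
smallCohort <- function(nSamples = 100, snpsPerLocus = 8, probesPerLocus = 4,
                        ldDecay = 0.7, probeCor = 0, effectSizes = numeric(0),
                        noiseSd = 1, seed = 1, nLoci = 1) {
    cfg <- simConfig(nSamples = nSamples, nLoci = nLoci,
                     snpsPerLocus = snpsPerLocus,
                     probesPerLocus = probesPerLocus, ldDecay = ldDecay,
                     probeCor = probeCor, effectSizes = effectSizes,
                     noiseSd = noiseSd, seed = seed)
    ge <- simulateGenotypes(cfg)
    sim <- simulateExpression(ge, cfg)
    vann <- as.data.frame(SummarizedExperiment::rowData(ge))
    first <- vann[!duplicated(vann$locus), ]
    idx <- data.frame(rsid = first$rsid, chrom = first$chrom,
                      pos = first$pos,
                      locus_label = paste0("L", first$locus),
                      stringsAsFactors = FALSE)
    blocks <- buildLDBlocks(idx, ge, r2Min = 0, searchWindowBp = 1e6)
    asg <- classifyProbes(blocks, sim$expr)
    list(cfg = cfg, geno = ge, expr = sim$expr, truth = sim$truth,
         meta = sim$meta, blocks = blocks, assignments = asg)
}

# Independent OLS oracle: stats::lm + summary (a different code path from
# the package's closed-form arithmetic).
lmOracle <- function(x, y) {
    fit <- stats::lm(y ~ x)
    s <- summary(fit)
    list(slope = unname(coef(fit)[2]), se = s$coefficients[2, 2],
         r2 = s$r.squared, p = s$coefficients[2, 4])
}

# Hand-rolled genotype matrix wrapped in the package container.
toyGeno <- function(dosage, chrom = "1", posStart = 1000, by = 100) {
    n <- nrow(dosage)
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("S%03d", seq_len(ncol(dosage)))
    GenotypeExperiment(dosage,
        data.frame(rsid = rownames(dosage), chrom = chrom,
                   pos = posStart + (seq_len(n) - 1) * by,
                   ref = "A", alt = "G", stringsAsFactors = FALSE))
}
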