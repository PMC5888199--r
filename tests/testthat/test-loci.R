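# LD r-squared, block expansion and the 4-Mb cis/trans window rule.

test_that("dosage r2 matches a brute-force Pearson oracle and is symmetric", {
    expect_equal(computeLDr2(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)), 1)
    expect_equal(computeLDr2(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0)), 1)
    a <- c(0, 1, 2, 0, 1, 2, 0, 1)
    b <- c(0, 1, 2, 0, 1, 2, 2, 1)
    # brute-force: explicit moment arithmetic, no cor()
    n <- length(a)
    num <- sum(a * b) - n * mean(a) * mean(b)
    den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
    expect_equal(computeLDr2(a, b), (num / den)^2, tolerance = 1e-12)
    for (s in 1:10) {
        set.seed(s)
        x <- rbinom(20, 2, 0.4); y <- rbinom(20, 2, 0.3)
        if (sd(x) == 0 || sd(y) == 0) next
        expect_equal(computeLDr2(x, y), computeLDr2(y, x),
                     tolerance = 1e-12)
    }
    expect_error(computeLDr2(rep(1, 10), rbinom(10, 2, 0.5)),
                 "monomorphic")
    expect_error(computeLDr2(c(0, 1), c(1, 0)), "3 complete pairs")
})

test_that("block membership equals exhaustive all-pairs thresholding", {
    sc <- smallCohort(nSamples = 300, snpsPerLocus = 12, ldDecay = 0.9,
                      seed = 13)
    vann <- as.data.frame(SummarizedExperiment::rowData(sc$geno))
    d <- dosages(sc$geno)
    idx <- data.frame(rsid = vann$rsid[1], chrom = vann$chrom[1],
                      pos = vann$pos[1], locus_label = "L1")
    blocks <- buildLDBlocks(idx, sc$geno, r2Min = 0.8,
                            searchWindowBp = 1e6)
    mem <- ldMembers(blocks)
    # oracle: brute-force r2 of every variant against the index
    oracleIn <- vann$rsid[vapply(seq_len(nrow(vann)), function(j) {
        if (j == 1) return(TRUE)
        cor(d[1, ], d[j, ])^2 >= 0.8
    }, logical(1))]
    expect_setequal(mem$rsid, oracleIn)
    expect_equal(mem$r2[mem$rsid == vann$rsid[1]], 1)
    bl <- ldBlocks(blocks)
    expect_equal(bl$span_start, min(mem$pos))
    expect_equal(bl$span_end, max(mem$pos))
})

test_that("perfect LD yields full-locus blocks; absent index SNPs skip", {
    cfg <- simConfig(nSamples = 200, nLoci = 1, snpsPerLocus = 6,
                     mafRange = c(0.3, 0.3), ldDecay = 1, seed = 14)
    ge <- simulateGenotypes(cfg)
    vann <- as.data.frame(SummarizedExperiment::rowData(ge))
    idx <- data.frame(rsid = c(vann$rsid[1], "rs_missing"),
                      chrom = vann$chrom[1], pos = vann$pos[1],
                      locus_label = c("L1", "L2"))
    expect_message(blocks <- buildLDBlocks(idx, ge), "skipped")
    expect_equal(length(blocks), 1L)
    expect_equal(blocks@skipped, "rs_missing")
    expect_equal(nrow(ldMembers(blocks)), 6L)
    expect_true(all(ldMembers(blocks)$r2 == 1))

    # index with no proxies: block of size 1, span collapses to a point
    d <- rbind(v1 = rbinom(100, 2, 0.5))
    colnames(d) <- sprintf("S%03d", 1:100)
    solo <- buildLDBlocks(data.frame(rsid = "v1", chrom = "1", pos = 500),
                          toyGeno(d, posStart = 500))
    expect_equal(ldBlocks(solo)$span_start, ldBlocks(solo)$span_end)
    expect_equal(ldBlocks(solo)$n_members, 1L)
})

test_that("the 4-Mb window boundary is inclusive and chromosome-aware", {
    blocks <- new("LDBlockSet",
        blocks = data.frame(index_rsid = "rsX", chrom = "2",
                            index_pos = 10e6, locus_label = "2p11",
                            span_start = 10e6, span_end = 11e6,
                            n_members = 1L),
        members = data.frame(index_rsid = "rsX", rsid = "rsX",
                             chrom = "2", pos = 10e6, r2 = 1),
        r2Min = 0.8, skipped = character(0))
    probes <- data.frame(
        probe_id = c("inside", "atEdge", "justBeyond", "otherChrom",
                     "leftEdge"),
        gene_symbol = "G", chrom = c("2", "2", "2", "3", "2"),
        start_pos = c(10.5e6, 11e6 + 4e6, 11e6 + 4e6 + 1, 10.5e6,
                      10e6 - 4e6))
    asg <- classifyProbes(blocks, probes)
    cls <- setNames(asg$class, asg$probe_id)
    expect_equal(cls[["inside"]], "cis")
    expect_equal(asg$distance_bp[asg$probe_id == "inside"], 0)
    expect_equal(cls[["atEdge"]], "cis")
    expect_equal(cls[["justBeyond"]], "trans")
    expect_equal(cls[["otherChrom"]], "trans")
    expect_equal(cls[["leftEdge"]], "cis")

    # cis and trans partition the placed probes; unplaced ones are dropped
    probes2 <- rbind(probes, data.frame(probe_id = "unplaced",
                                        gene_symbol = "G",
                                        chrom = NA, start_pos = NA))
    expect_message(asg2 <- classifyProbes(blocks, probes2),
                   "without coordinates")
    expect_equal(nrow(asg2), 5L)
    expect_true(all(asg2$class %in% c("cis", "trans")))

    # widening the window never demotes cis to trans
    wide <- classifyProbes(blocks, probes, windowBp = 8e6)
    wasCis <- asg$probe_id[asg$class == "cis"]
    expect_true(all(wide$class[wide$probe_id %in% wasCis] == "cis"))
})
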