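# Expression preparation: quantile normalization, batch regression, PCA
# diagnostics and probe exclusion.

rawExpr <- function(values, ids = sprintf("P%02d", seq_len(nrow(values)))) {
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
    ExpressionExperiment(values, data.frame(
        probe_id = ids, gene_symbol = ids, chrom = "1",
        start_pos = seq_len(nrow(values)) * 1000), state = "raw")
}

test_that("quantile normalization matches the hand computation and is a
           fixed point", {
    # 4 probes x 3 samples: rank, average the order statistics, map back
    m <- cbind(s1 = c(2, 6, 4, 8), s2 = c(1, 3, 5, 7),
               s3 = c(10, 20, 40, 30))
    means <- rowMeans(cbind(sort(m[, 1]), sort(m[, 2]), sort(m[, 3])))
    byHand <- apply(m, 2, function(col) means[rank(col)])
    qn <- quantileNormalize(m)
    expect_equal(unname(qn), unname(byHand))
    expect_equal(quantileNormalize(qn), qn)
    # permutation invariance: same multiset in different order -> equal
    # columns after normalization
    m2 <- cbind(a = c(5, 1, 3, 2), b = c(2, 3, 5, 1))
    qn2 <- quantileNormalize(m2)
    expect_equal(sort(qn2[, 1]), sort(qn2[, 2]))
    expect_identical(sum(duplicated(t(apply(qn2, 2, sort)))), 1L)
})

test_that("normalizeExpression validates input and advances state", {
    set.seed(2)
    ee <- rawExpr(matrix(rexp(40, 0.2), 8, 5))
    out <- normalizeExpression(ee)
    expect_equal(normState(out), "normalized")
    v <- exprValues(out)
    sorted <- apply(v, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
    expect_error(normalizeExpression(out), "states only move forward")

    neg <- rawExpr(matrix(c(-1, -2, 1, 2, 3, 4), 3, 2))
    expect_error(normalizeExpression(neg), "2 offending")

    rin <- normalizeExpression(ee, method = "rank-inverse-normal")
    z <- exprValues(rin)[1, ]
    expect_equal(unname(sort(z)), qnorm((seq_len(5) - 0.5) / 5))
})

test_that("batch regression removes batch means exactly and preserves the
           grand mean", {
    batch <- rep(c("b1", "b2", "b3"), each = 4)
    # pure batch-shift data: probe = mu + batch offset, no noise
    mu <- c(5, 8)
    off <- c(b1 = -1, b2 = 0.5, b3 = 2)
    vals <- rbind(mu[1] + off[batch], mu[2] + off[batch])
    ee <- rawExpr(vals)
    ee <- normalizeExpression(ee, method = "none")
    out <- regressOutBatch(ee, batch)
    expect_equal(normState(out), "batch_corrected")
    v <- exprValues(out)
    expect_true(all(apply(v, 1, function(x) diff(range(x))) < 1e-12))
    expect_equal(unname(rowMeans(v)), rowMeans(vals), tolerance = 1e-10)

    # noisy case: per-probe batch means coincide afterwards
    set.seed(3)
    vals2 <- matrix(rnorm(5 * 12, 8), 5, 12) +
        matrix(rep(off[batch], each = 5), 5, 12)
    ee2 <- normalizeExpression(rawExpr(vals2), method = "none")
    out2 <- regressOutBatch(ee2, batch)
    bm <- sapply(unique(batch), function(b)
        rowMeans(exprValues(out2)[, batch == b]))
    expect_lt(max(abs(bm - bm[, 1])), 1e-8)
    expect_equal(unname(rowMeans(exprValues(out2))), rowMeans(vals2),
                 tolerance = 1e-10)

    # single batch: no-op on the values
    one <- regressOutBatch(ee2, rep("b1", 12))
    expect_identical(exprValues(one), exprValues(ee2))
    # singleton batch: warning, excluded from estimation
    expect_warning(regressOutBatch(ee2, c("b1", rep(c("b2", "b3"),
                                                    length.out = 11))),
                   "single sample")
})

test_that("PCA diagnostics capture rank structure and batch correction", {
    # rank-1 matrix: first component takes essentially all variance
    u <- rnorm(20); v <- rnorm(15)
    ee <- rawExpr(outer(u, v))
    ee <- normalizeExpression(ee, method = "none")
    pc <- pcaCheck(ee, k = 3)
    expect_gt(pc$varianceFraction[1], 0.999)
    expect_lt(sum(pc$varianceFraction), 1 + 1e-12)
    # scores orthogonal
    cp <- crossprod(pc$scores)
    expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
    expect_error(pcaCheck(ee, k = 100), "exceeds")

    # batch-structured cohort: PC1 ~ batch R2 collapses after correction
    cfg <- simConfig(nSamples = 60, nLoci = 1, snpsPerLocus = 2,
                     probesPerLocus = 10, batchEffectSd = 2,
                     nBatches = 3, seed = 4)
    sim <- simulateExpression(simulateGenotypes(cfg), cfg)
    before <- pcaCheck(sim$expr, k = 3)
    corrected <- regressOutBatch(sim$expr)
    after <- pcaCheck(corrected, k = 3)
    expect_gt(before$batchR2[1], after$batchR2[1])
    expect_lt(after$batchR2[1], 0.01)
})

test_that("probe exclusion drops exactly the blacklist and logs unknowns", {
    ee <- rawExpr(matrix(rnorm(50), 10, 5))
    out <- excludeProbes(ee, character(0))
    expect_equal(nrow(out), 10L)
    out3 <- excludeProbes(ee, c("P01", "P05", "P09"))
    expect_equal(nrow(out3), 7L)
    expect_message(excludeProbes(ee, c("P01", "nope")), "not present")
    expect_warning(excludeProbes(ee, sprintf("P%02d", 1:10)),
                   "all probes excluded")
})

test_that("cohort merging intersects probes and labels batches", {
    e1 <- rawExpr(matrix(rnorm(12), 3, 4), ids = c("A", "B", "C"))
    e2 <- rawExpr(matrix(rnorm(8), 2, 4), ids = c("B", "C"))
    merged <- mergeCohorts(list(x = e1, y = e2))
    expect_equal(sort(as.character(
        SummarizedExperiment::rowData(merged)$probe_id)), c("B", "C"))
    expect_equal(ncol(merged), 8L)
    expect_equal(as.character(SummarizedExperiment::colData(merged)$batch),
                 rep(c("x", "y"), each = 4))
})
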