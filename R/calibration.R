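# Family-wise error rate calibration of the min-P permutation procedure on
# global-null synthetic cohorts.

#' Calibrate the family-wise error rate of the permutation thresholds
#'
#' Simulates \code{nCohorts} independent global-null cohorts (one risk
#' locus of LD-correlated SNPs, co-expressed probes, no planted effects),
#' derives per-cohort experiment-wide thresholds from the min-P
#' permutation null, and records for each level whether any observed
#' nominal P falls at or below its threshold.  Under the global null the
#' rejection fraction estimates the family-wise error rate, which the
#' procedure controls at the nominal level.
#'
#' The single locus is expanded with \code{r2Min = 0} so that every
#' simulated SNP enters the test family (the harness fixes the family
#' size at \code{snpsPerLocus x probesPerLocus} tests irrespective of the
#' LD grading), and all probes sit within the cis window.
#'
#' @param nCohorts number of simulated cohorts (default 400).
#' @param alphas nominal levels (default the study's 5\% and 10\%).
#' @param R permutation replicates per cohort (default 199).
#' @param seed integer base seed; per-cohort generation and permutation
#'   seeds are drawn from a stream initialized with it, so different base
#'   seeds give fully independent cohort sets.
#' @param nSamples,snpsPerLocus,probesPerLocus,ldDecay,probeCor,noiseSd
#'   cohort generator settings (defaults: 100 samples, 20 SNPs, 10
#'   probes, copying probability 0.7, probe correlation 0.3, unit noise).
#' @return list with \code{rate} (named rejection fractions, one per
#'   alpha), \code{se} (binomial standard errors), \code{rejections}
#'   (nCohorts x alphas logical matrix) and \code{nCohorts}.
#' @examples
#' \donttest{
#' cal <- calibrateFWER(nCohorts = 20, R = 199, seed = 1)
#' cal$rate
#' }
#' @export
calibrateFWER <- function(nCohorts = 400L, alphas = c(0.05, 0.10),
                          R = 199L, seed = 1L, nSamples = 100L,
                          snpsPerLocus = 20L, probesPerLocus = 10L,
                          ldDecay = 0.7, probeCor = 0.3, noiseSd = 1) {
    nCohorts <- as.integer(nCohorts)
    rejections <- matrix(NA, nCohorts, length(alphas),
                         dimnames = list(NULL, as.character(alphas)))
    set.seed(seed)
    cohortSeeds <- sample.int(2147483646L, nCohorts)
    permSeeds <- sample.int(2147483646L, nCohorts)
    for (i in seq_len(nCohorts)) {
        cfg <- simConfig(nSamples = nSamples, nLoci = 1L,
                         snpsPerLocus = snpsPerLocus,
                         probesPerLocus = probesPerLocus,
                         ldDecay = ldDecay, probeCor = probeCor,
                         noiseSd = noiseSd, seed = cohortSeeds[i])
        ge <- simulateGenotypes(cfg)
        sim <- simulateExpression(ge, cfg)
        vann <- as.data.frame(rowData(ge))
        idx <- data.frame(rsid = vann$rsid[1L], chrom = vann$chrom[1L],
                          pos = vann$pos[1L], locus_label = "L1",
                          stringsAsFactors = FALSE)
        blocks <- buildLDBlocks(idx, ge, r2Min = 0, searchWindowBp = 1e6)
        assignments <- classifyProbes(blocks, sim$expr)
        null <- permuteScan(ge, sim$expr, blocks, assignments, R = R,
                            seed = permSeeds[i], mode = "cis")
        thr <- deriveThresholds(null, alphas)
        rejections[i, ] <- null@observedMinP <= thr
    }
    rate <- colMeans(rejections)
    list(rate = rate,
         se = sqrt(rate * (1 - rate) / nCohorts),
         rejections = rejections, nCohorts = nCohorts)
}
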