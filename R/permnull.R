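# Experiment-wide significance by the min-P permutation procedure: permute
# the genotype-expression sample linkage once per replicate (jointly for
# the whole test family), rescan, record the minimum nominal P value, and
# derive order-statistic thresholds and empirical adjusted P values.

# Standardize columns to unit variance/zero mean; n-1 denominator so that
# crossprod(Zg, Ze)/(n-1) is the Pearson correlation matrix.
.standardize <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    sds <- sqrt(colSums(m^2) / (nrow(m) - 1L))
    if (any(sds == 0))
        stop("monomorphic/constant column in permutation family")
    sweep(m, 2L, sds, `/`)
}

# Convert the maximum |r| over a family into the minimum two-sided P of
# the corresponding t tests on df degrees of freedom.
.minPfromMaxR <- function(maxAbsR, df) {
    maxAbsR <- min(maxAbsR, 1)
    if (maxAbsR >= 1) return(.Machine$double.xmin)
    tval <- maxAbsR * sqrt(df / (1 - maxAbsR^2))
    max(2 * stats::pt(-tval, df), .Machine$double.xmin)
}

#' Minimum-P permutation scan
#'
#' For each of \code{R} replicates, one random permutation of the sample
#' linkage between the genotype matrix and the whole expression matrix is
#' drawn -- a single permutation shared by every SNP and probe in the
#' family, which preserves LD among SNPs and co-expression among probes --
#' the full scan is repeated, and the minimum nominal P value across all
#' tests is recorded.  Deterministic given \code{seed}.
#'
#' The test family is the same set of (block member SNP x probe of the
#' requested class) pairs that [scanAssociations()] would fit.  Samples
#' with any missing value in the family's dosage or expression rows are
#' dropped with a message: the joint permutation requires one complete
#' sample set so that the number of tests is identical in every replicate.
#'
#' @param geno a [GenotypeExperiment-class].
#' @param expr an [ExpressionExperiment-class].
#' @param blocks an [LDBlockSet-class].
#' @param assignments output of [classifyProbes()].
#' @param R number of permutation replicates (at least 100; the study
#'   design value is 10,000).
#' @param seed integer seed.
#' @param mode \code{"cis"} or \code{"trans"}.
#' @return a [PermutationNull-class]; its \code{observedMinP} slot holds
#'   the unpermuted scan's minimum nominal P.
#' @export
permuteScan <- function(geno, expr, blocks, assignments, R = 10000L,
                        seed = 1L, mode = c("cis", "trans")) {
    mode <- match.arg(mode)
    R <- as.integer(R)
    if (R < 100L)
        stop("R < 100 refused: threshold quantiles are unstable")
    sf <- .scanFamily(geno, expr, blocks, assignments, mode)
    if (!length(sf$fam))
        stop("empty test family: no (SNP, ", mode, " probe) pairs")
    samples <- sf$samples
    d <- dosages(geno)[, samples, drop = FALSE]
    e <- exprValues(expr)[, samples, drop = FALSE]
    snpRows <- unique(unlist(lapply(sf$fam, function(f) f$snps$rsid)))
    prbRows <- unique(unlist(lapply(sf$fam, function(f) f$probes$probe_id)))
    ok <- colSums(is.na(d[snpRows, , drop = FALSE])) == 0L &
          colSums(is.na(e[prbRows, , drop = FALSE])) == 0L
    if (!all(ok))
        message("dropping ", sum(!ok),
                " sample(s) with missing values from the permutation family")
    d <- d[, ok, drop = FALSE]
    e <- e[, ok, drop = FALSE]
    n <- ncol(d)
    if (n < 3L)
        stop("fewer than 3 complete samples")
    df <- n - 2L

    # per-block standardized matrices; the family's test count
    fams <- lapply(sf$fam, function(f) list(
        Zg = .standardize(t(d[f$snps$rsid, , drop = FALSE])),
        Ze = .standardize(t(e[f$probes$probe_id, , drop = FALSE]))))
    m <- sum(vapply(sf$fam, function(f)
        nrow(f$snps) * nrow(f$probes), numeric(1)))

    famMaxR <- function(perm) {
        mx <- 0
        for (f in fams) {
            r <- crossprod(f$Zg, f$Ze[perm, , drop = FALSE]) / (n - 1L)
            mx <- max(mx, max(abs(r)))
        }
        mx
    }

    observed <- .minPfromMaxR(famMaxR(seq_len(n)), df)
    set.seed(seed)
    minp <- vapply(seq_len(R), function(i)
        .minPfromMaxR(famMaxR(sample.int(n)), df), numeric(1))
    new("PermutationNull", minP = minp, nTests = as.integer(m), R = R,
        seed = as.integer(seed), observedMinP = observed)
}

#' Experiment-wide thresholds from a permutation null
#'
#' The threshold at level alpha is the k-th smallest replicate minimum
#' nominal P with \code{k = floor(alpha * (R + 1))} -- a conservative,
#' integer-deterministic order-statistic convention.  A nominal P is
#' experiment-wide significant at alpha iff it is at or below the
#' threshold.
#'
#' @param null a [PermutationNull-class].
#' @param alphas numeric levels in (0, 1]; defaults to the two
#'   predetermined study levels, 5\% and 10\%.
#' @return named numeric vector of thresholds (names = alphas),
#'   nondecreasing in alpha.
#' @examples
#' null <- new("PermutationNull", minP = runif(999)^10, nTests = 10L,
#'             R = 999L, seed = 1L, observedMinP = 1e-4)
#' deriveThresholds(null)
#' @export
deriveThresholds <- function(null, alphas = c(0.05, 0.10)) {
    stopifnot(is(null, "PermutationNull"))
    k <- pmin(floor(alphas * (null@R + 1L)), null@R)
    if (any(k < 1L))
        stop("R = ", null@R, " too small for alpha = ",
             paste(alphas[k < 1L], collapse = ", "))
    s <- sort(null@minP)
    stats::setNames(s[k], as.character(alphas))
}

#' Empirical experiment-wide adjusted P value
#'
#' Single-step min-P adjustment: the fraction (with add-one smoothing) of
#' permutation replicates whose minimum nominal P is at or below the
#' observed one, \code{(1 + #{minP <= p}) / (R + 1)}.  Monotone
#' nondecreasing in the input with floor \code{1/(R+1)}.
#'
#' @param pObserved numeric vector of nominal P values in (0, 1].
#' @param null a [PermutationNull-class].
#' @return adjusted P values in (0, 1], same length.
#' @export
empiricalAdjustedP <- function(pObserved, null) {
    stopifnot(is(null, "PermutationNull"))
    if (any(pObserved <= 0 | pObserved > 1, na.rm = TRUE))
        stop("p values must lie in (0, 1]")
    s <- sort(null@minP)
    (1 + findInterval(pObserved, s)) / (null@R + 1L)
}
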