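# Post-imputation genotype quality control: per-variant statistics and the
# standard exclusion filters (call rate, MAF, INFO, region/quality
# blacklists) with first-failing-rule accounting.

#' Minor allele frequency from additive dosages
#'
#' MAF is the folded mean dosage: with \eqn{\bar p = \mathrm{mean}(d)/2}
#' over non-missing entries, \eqn{\mathrm{MAF} = \min(\bar p, 1-\bar p)}.
#' Invariant under allele relabeling (\eqn{d \to 2 - d}).
#'
#' @param dosages numeric vector in [0, 2], \code{NA} allowed.
#' @return frequency in [0, 0.5].
#' @examples
#' computeMAF(c(0, 1, 1, 2))  # 0.5
#' @export
computeMAF <- function(dosages) {
    d <- dosages[!is.na(dosages)]
    if (!length(d))
        stop("MAF undefined: all dosages missing")
    p <- mean(d) / 2
    min(p, 1 - p)
}

#' IMPUTE-style INFO imputation-quality score
#'
#' The measured-information ratio
#' \deqn{\mathrm{INFO} = 1 - \frac{\mathrm{mean}_i(v_i)}{2\bar p(1-\bar p)}}
#' where \eqn{v_i} is sample i's genotype posterior variance and
#' \eqn{\bar p} the mean posterior allele frequency; defined as 1 when
#' \eqn{\bar p \in \{0, 1\}} and clamped to [0, 1].
#'
#' @param posteriors numeric matrix, samples x 3, the genotype posterior
#'   probabilities of carrying 0, 1 or 2 alternate alleles; each row must
#'   sum to 1 within 1e-6.
#' @return quality score in [0, 1].
#' @examples
#' computeINFO(matrix(c(1, 0, 0), 10, 3, byrow = TRUE))  # certain: 1
#' @export
computeINFO <- function(posteriors) {
    gp <- as.matrix(posteriors)
    if (ncol(gp) != 3L)
        stop("posteriors must have three columns (genotypes 0/1/2)")
    if (any(abs(rowSums(gp) - 1) > 1e-6) || any(gp < -1e-9))
        stop("malformed posterior triple: rows must be probabilities summing to 1")
    eg <- gp[, 2L] + 2 * gp[, 3L]
    eg2 <- gp[, 2L] + 4 * gp[, 3L]
    v <- eg2 - eg^2
    pbar <- mean(eg) / 2
    if (pbar <= 0 || pbar >= 1)
        return(1)
    min(1, max(0, 1 - mean(v) / (2 * pbar * (1 - pbar))))
}

# Dosage-variance fallback when no posteriors are stored:
# var(dosage) / (2 p (1-p)), clamped to [0, 1].
.infoFromDosage <- function(dosages) {
    d <- dosages[!is.na(dosages)]
    if (length(d) < 2L) return(NA_real_)
    p <- mean(d) / 2
    if (p <= 0 || p >= 1) return(1)
    min(1, max(0, stats::var(d) / (2 * p * (1 - p))))
}

#' Default HLA-region blacklist
#'
#' The extended HLA region on chromosome 6 (25-35 Mb, 1-based inclusive),
#' used to exclude variants whose expression probes suffer abundant
#' cross-hybridization and copy-number confounding.
#'
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
hlaRegion <- function() {
    data.frame(chrom = "6", start = 25e6, end = 35e6,
               stringsAsFactors = FALSE)
}

#' Apply genotype quality-control filters
#'
#' Exclusion thresholds follow the strict-inequality convention: samples
#' and variants with call rate < \code{minCallRate}, variants with
#' MAF < \code{minMAF} or INFO < \code{minINFO} are excluded (a variant
#' sitting exactly on a threshold survives).  Rules run in a fixed order --
#' sample call rate, variant call rate, MAF, INFO, region blacklist,
#' quality blacklist -- and each excluded variant is attributed to the
#' first rule it fails, so the [QCReport-class] accounting always balances.
#' Variant statistics are computed on the samples surviving the sample
#' filter.  INFO uses stored genotype posteriors when present and the
#' dosage-variance form otherwise.
#'
#' @param geno a [GenotypeExperiment-class].
#' @param minCallRate minimum variant call rate (default 0.98).
#' @param minSampleCallRate minimum sample call rate (default 0.98).
#' @param minMAF minimum minor allele frequency (default 0.01).
#' @param minINFO minimum INFO score (default 0.8).
#' @param regionBlacklist data.frame of 1-based inclusive intervals
#'   (\code{chrom}, \code{start}, \code{end}); defaults to [hlaRegion()].
#'   \code{NULL} disables the rule.
#' @param qualityBlacklist character vector of rsids failing an external
#'   (e.g. array cluster-quality) check.
#' @return list with elements \code{genotypes} (filtered
#'   [GenotypeExperiment-class]) and \code{report} ([QCReport-class]).  If
#'   no variant survives, the report flags it and a zero-row container is
#'   returned with a warning.
#' @export
applyGenotypeFilters <- function(geno, minCallRate = 0.98,
                                 minSampleCallRate = 0.98, minMAF = 0.01,
                                 minINFO = 0.8,
                                 regionBlacklist = hlaRegion(),
                                 qualityBlacklist = character(0)) {
    stopifnot(is(geno, "GenotypeExperiment"))
    nVin <- nrow(geno)
    nSin <- ncol(geno)
    d <- dosages(geno)

    sampleCR <- colMeans(!is.na(d))
    keepS <- sampleCR >= minSampleCallRate
    geno <- geno[, keepS]
    samplesRemoved <- c(call_rate = sum(!keepS))

    vi <- variantInfo(geno)
    fail <- rep(NA_character_, nrow(geno))
    fail[is.na(fail) & vi$call_rate < minCallRate] <- "call_rate"
    fail[is.na(fail) & vi$maf < minMAF] <- "maf"
    fail[is.na(fail) & !is.na(vi$info) & vi$info < minINFO] <- "info"
    if (!is.null(regionBlacklist) && nrow(regionBlacklist)) {
        inRegion <- rep(FALSE, nrow(geno))
        for (k in seq_len(nrow(regionBlacklist))) {
            inRegion <- inRegion |
                (as.character(vi$chrom) ==
                     as.character(regionBlacklist$chrom[k]) &
                 vi$pos >= regionBlacklist$start[k] &
                 vi$pos <= regionBlacklist$end[k])
        }
        fail[is.na(fail) & inRegion] <- "region_blacklist"
    }
    fail[is.na(fail) & vi$rsid %in% qualityBlacklist] <- "quality_blacklist"

    rules <- c("call_rate", "maf", "info", "region_blacklist",
               "quality_blacklist")
    variantsRemoved <- vapply(rules, function(r) sum(fail == r, na.rm = TRUE),
                              integer(1))
    keepV <- is.na(fail)
    out <- geno[keepV, ]
    report <- new("QCReport",
                  nVariantsIn = nVin, nSamplesIn = nSin,
                  samplesRemoved = samplesRemoved,
                  variantsRemoved = variantsRemoved,
                  nVariantsOut = sum(keepV), nSamplesOut = ncol(out))
    if (nrow(out) == 0L)
        warning("no variants survive quality control: empty result")
    list(genotypes = out, report = report)
}
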