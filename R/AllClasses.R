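#' @import methods
#' @import S4Vectors
#' @import SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Simulation configuration for synthetic eQTL cohorts
#'
#' Parameters of the synthetic cohort generator: cohort size, locus layout,
#' minor allele frequency spectrum, haplotype linkage-disequilibrium decay,
#' planted per-allele effect sizes, expression noise, batch structure and the
#' clinical covariate effects.  All randomness is governed by \code{seed};
#' a fixed seed reproduces every simulated object bit-identically.
#'
#' @slot nSamples number of individuals (>= 10).
#' @slot nLoci number of independent risk loci, each on its own chromosome.
#' @slot snpsPerLocus number of variants per locus.
#' @slot probesPerLocus number of expression probes placed near each locus.
#' @slot mafRange length-2 numeric in (0, 0.5]; per-variant target minor
#'   allele frequencies are drawn uniformly from this interval.
#' @slot ldDecay haplotype copying probability in [0, 1) between adjacent
#'   variants (1 is accepted for the degenerate perfect-copying case);
#'   adjacent-variant haplotype correlation equals \code{ldDecay} when the
#'   two variants share a MAF, so dosage r-squared decays geometrically
#'   with marker distance.
#' @slot effectSizes planted per-allele slopes (expression units per dosage
#'   unit), one per locus in order; loci beyond its length carry no effect.
#'   \code{numeric(0)} gives a global-null cohort.
#' @slot noiseSd standard deviation of the Gaussian expression noise (> 0).
#' @slot probeCor pairwise correlation in [0, 1) of the noise among probes of
#'   one locus (equicorrelated co-expression); 0 gives independent probes.
#' @slot batchEffectSd standard deviation of additive per-batch, per-probe
#'   offsets; 0 disables batch structure.
#' @slot nBatches number of processing batches.
#' @slot covariateEffects named numeric vector of per-unit effects of the
#'   standardized clinical covariates (\code{age}, \code{sex}, \code{crp},
#'   \code{sjc}) on all probes; defaults to all zero so covariate-robustness
#'   nulls are recoverable.
#' @slot imputationCertainty mean posterior weight on the true genotype in
#'   (0, 1]; 1 emits hard calls without genotype posteriors, values below 1
#'   emit softened genotype posterior triples (Beta-distributed per-sample
#'   certainty) plus the matching expected dosages, so INFO filtering can be
#'   exercised.
#' @slot seed integer seed fixing all generator output.
#'
#' @seealso [simConfig()], [simulateGenotypes()], [simulateExpression()]
#' @export
setClass("SimConfig",
    representation(
        nSamples = "integer",
        nLoci = "integer",
        snpsPerLocus = "integer",
        probesPerLocus = "integer",
        mafRange = "numeric",
        ldDecay = "numeric",
        effectSizes = "numeric",
        noiseSd = "numeric",
        probeCor = "numeric",
        batchEffectSd = "numeric",
        nBatches = "integer",
        covariateEffects = "numeric",
        imputationCertainty = "numeric",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character(0)
    if (object@nSamples < 10L)
        msg <- c(msg, "nSamples must be >= 10")
    if (object@nLoci < 1L || object@snpsPerLocus < 1L ||
        object@probesPerLocus < 1L)
        msg <- c(msg, "nLoci, snpsPerLocus and probesPerLocus must be >= 1")
    if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
        any(object@mafRange > 0.5) || object@mafRange[1] > object@mafRange[2])
        msg <- c(msg, "mafRange must be an ordered pair within (0, 0.5]")
    if (object@ldDecay < 0 || object@ldDecay > 1)
        msg <- c(msg, "ldDecay must lie in [0, 1]")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (object@probeCor < 0 || object@probeCor >= 1)
        msg <- c(msg, "probeCor must lie in [0, 1)")
    if (object@batchEffectSd < 0)
        msg <- c(msg, "batchEffectSd must be >= 0")
    if (object@nBatches < 1L)
        msg <- c(msg, "nBatches must be >= 1")
    if (length(object@effectSizes) > object@nLoci)
        msg <- c(msg, "more effectSizes than loci: planted effect on absent locus")
    if (object@imputationCertainty <= 0 || object@imputationCertainty > 1)
        msg <- c(msg, "imputationCertainty must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe an early-arthritis-like cohort: 250 individuals, five
#' independent non-HLA risk loci of 20 genotyped variants each with graded
#' LD (copying probability 0.7), ten microarray probes per locus, unit
#' expression noise, three processing batches and null clinical covariate
#' effects.  By default no eQTL effects are planted (global null).
#'
#' @param nSamples,nLoci,snpsPerLocus,probesPerLocus cohort layout counts.
#' @param mafRange,ldDecay,effectSizes,noiseSd,probeCor,batchEffectSd,nBatches
#'   generator parameters; see [SimConfig-class].
#' @param covariateEffects named numeric vector over
#'   \code{c("age","sex","crp","sjc")}.
#' @param imputationCertainty mean posterior mass on the true genotype; 1
#'   emits hard calls.
#' @param seed integer seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSamples = 50, nLoci = 1, seed = 7)
#' cfg
#' @export
simConfig <- function(nSamples = 250L, nLoci = 5L, snpsPerLocus = 20L,
                      probesPerLocus = 10L, mafRange = c(0.05, 0.5),
                      ldDecay = 0.7, effectSizes = numeric(0), noiseSd = 1,
                      probeCor = 0, batchEffectSd = 0, nBatches = 3L,
                      covariateEffects = c(age = 0, sex = 0, crp = 0, sjc = 0),
                      imputationCertainty = 1, seed = 1L) {
    full <- c(age = 0, sex = 0, crp = 0, sjc = 0)
    if (length(covariateEffects)) {
        bad <- setdiff(names(covariateEffects), names(full))
        if (length(bad))
            stop("unknown covariate effect(s): ", paste(bad, collapse = ", "))
        full[names(covariateEffects)] <- covariateEffects
    }
    new("SimConfig",
        nSamples = as.integer(nSamples), nLoci = as.integer(nLoci),
        snpsPerLocus = as.integer(snpsPerLocus),
        probesPerLocus = as.integer(probesPerLocus),
        mafRange = as.numeric(mafRange), ldDecay = as.numeric(ldDecay),
        effectSizes = as.numeric(effectSizes), noiseSd = as.numeric(noiseSd),
        probeCor = as.numeric(probeCor),
        batchEffectSd = as.numeric(batchEffectSd),
        nBatches = as.integer(nBatches), covariateEffects = full,
        imputationCertainty = as.numeric(imputationCertainty),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nSamples, "samples,", object@nLoci, "loci x",
        object@snpsPerLocus, "SNPs x", object@probesPerLocus, "probes\n")
    cat("  mafRange [", object@mafRange[1], ",", object@mafRange[2],
        "], ldDecay ", object@ldDecay, ", noiseSd ", object@noiseSd,
        ", probeCor ", object@probeCor, "\n", sep = "")
    cat("  planted effects:",
        if (length(object@effectSizes))
            paste(signif(object@effectSizes, 3), collapse = ", ")
        else "none (global null)", "\n")
    cat("  batches:", object@nBatches, "(sd", object@batchEffectSd,
        "), seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# GenotypeExperiment / ExpressionExperiment
# ---------------------------------------------------------------------------

#' Genotype dosage container
#'
#' A \linkS4class{SummarizedExperiment} holding additive allele dosages
#' (variants x samples, assay \code{"dosage"}, values in [0, 2] with
#' \code{NA} for missing calls) and per-variant metadata in \code{rowData}
#' (\code{rsid}, \code{chrom}, 1-based \code{pos}, \code{ref}, \code{alt}).
#' When genotype posteriors are available they are carried as assays
#' \code{"gpAA"}, \code{"gpAB"}, \code{"gpBB"} (probabilities of 0, 1 and 2
#' alternate alleles, each triple summing to 1).
#'
#' @seealso [GenotypeExperiment()], [dosages()], [variantInfo()]
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- character(0)
    if (!"dosage" %in% assayNames(object))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
        msg <- c(msg, "dosages must lie in [0, 2]")
    need <- c("rsid", "chrom", "pos")
    miss <- setdiff(need, colnames(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste("rowData lacks:", paste(miss, collapse = ", ")))
    gp <- intersect(c("gpAA", "gpAB", "gpBB"), assayNames(object))
    if (length(gp) > 0L && length(gp) != 3L)
        msg <- c(msg, "genotype posteriors need all of gpAA, gpAB, gpBB")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param dosage numeric matrix, variants x samples, values in [0, 2]
#'   (\code{NA} allowed); column names are sample ids.
#' @param variants data.frame or DataFrame with one row per variant and at
#'   least \code{rsid}, \code{chrom}, \code{pos} (1-based).
#' @param posteriors optional list of three matrices \code{gpAA},
#'   \code{gpAB}, \code{gpBB} conformable with \code{dosage}.
#' @return a [GenotypeExperiment-class].
#' @examples
#' d <- rbind(rs1 = c(0, 1, 2), rs2 = c(2, 1, 0))
#' colnames(d) <- paste0("S", 1:3)
#' ge <- GenotypeExperiment(d, data.frame(rsid = c("rs1", "rs2"),
#'                                        chrom = "1", pos = c(100, 200)))
#' dosages(ge)
#' @export
GenotypeExperiment <- function(dosage, variants, posteriors = NULL) {
    dosage <- as.matrix(dosage)
    variants <- as(variants, "DataFrame")
    rownames(dosage) <- variants$rsid
    assays <- list(dosage = dosage)
    if (!is.null(posteriors)) {
        stopifnot(all(c("gpAA", "gpAB", "gpBB") %in% names(posteriors)))
        assays <- c(assays, lapply(posteriors[c("gpAA", "gpAB", "gpBB")],
                                   function(m) {
                                       m <- as.matrix(m)
                                       dimnames(m) <- dimnames(dosage)
                                       m
                                   }))
    }
    new("GenotypeExperiment",
        SummarizedExperiment(assays = assays, rowData = variants))
}

setMethod("show", "GenotypeExperiment", function(object) {
    cat("GenotypeExperiment:", nrow(object), "variants x", ncol(object),
        "samples\n")
    cat("  chromosomes:",
        paste(unique(as.character(rowData(object)$chrom)), collapse = ", "),
        "\n")
    cat("  posteriors:",
        if (all(c("gpAA", "gpAB", "gpBB") %in% assayNames(object)))
            "present" else "absent", "\n")
})

#' Expression matrix container
#'
#' A \linkS4class{SummarizedExperiment} holding expression intensities
#' (probes x samples, assay \code{"exprs"}), probe annotation in
#' \code{rowData} (\code{probe_id}, \code{gene_symbol}, \code{chrom},
#' 1-based \code{start_pos}, logical \code{blacklisted}) and sample metadata
#' in \code{colData}.  The normalization state is tracked in
#' \code{metadata(x)$state} and moves only forward through
#' \code{raw -> normalized -> batch_corrected}.
#'
#' @seealso [ExpressionExperiment()], [exprValues()], [probeInfo()],
#'   [normState()]
#' @export
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

.EXPR_STATES <- c("raw", "normalized", "batch_corrected")

setValidity("ExpressionExperiment", function(object) {
    msg <- character(0)
    if (!"exprs" %in% assayNames(object))
        return("assay 'exprs' is required")
    st <- metadata(object)$state
    if (is.null(st) || !st %in% .EXPR_STATES)
        msg <- c(msg, "metadata(x)$state must be raw/normalized/batch_corrected")
    if (!"probe_id" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData lacks probe_id")
    if (anyDuplicated(rowData(object)$probe_id))
        msg <- c(msg, "probe_id must be unique")
    if (!is.null(st) && identical(st, "normalized") &&
        anyNA(assay(object, "exprs")))
        msg <- c(msg, "normalized expression must have no missing values")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionExperiment
#'
#' @param values numeric matrix, probes x samples; column names are sample
#'   ids.
#' @param probes data.frame/DataFrame with \code{probe_id} and, for probes
#'   usable in cis/trans classification, \code{gene_symbol}, \code{chrom}
#'   and \code{start_pos} (1-based).
#' @param samples optional data.frame of sample metadata (one row per
#'   column of \code{values}).
#' @param state normalization state, one of \code{"raw"},
#'   \code{"normalized"}, \code{"batch_corrected"}.
#' @return an [ExpressionExperiment-class].
#' @export
ExpressionExperiment <- function(values, probes, samples = NULL,
                                 state = c("raw", "normalized",
                                           "batch_corrected")) {
    state <- match.arg(state)
    values <- as.matrix(values)
    probes <- as(probes, "DataFrame")
    if (!"blacklisted" %in% colnames(probes))
        probes$blacklisted <- FALSE
    rownames(values) <- probes$probe_id
    cd <- if (is.null(samples)) {
        make.row.names <- colnames(values)
        DataFrame(row.names = make.row.names)
    } else {
        as(samples, "DataFrame")
    }
    se <- SummarizedExperiment(assays = list(exprs = values),
                               rowData = probes, colData = cd)
    metadata(se)$state <- state
    new("ExpressionExperiment", se)
}

setMethod("show", "ExpressionExperiment", function(object) {
    cat("ExpressionExperiment: ", nrow(object), " probes x ", ncol(object),
        " samples (state: ", metadata(object)$state, ")\n", sep = "")
    ann <- sum(!is.na(rowData(object)$chrom) &
               !is.na(rowData(object)$start_pos))
    cat("  probes with genomic annotation:", ann, "\n")
})

# ---------------------------------------------------------------------------
# QCReport
# ---------------------------------------------------------------------------

#' Genotype quality-control accounting report
#'
#' Per-rule exclusion counts from [applyGenotypeFilters()].  Rules are
#' applied in a fixed order (sample call rate, then variant call rate, MAF,
#' INFO, region blacklist, quality blacklist) and every excluded variant is
#' attributed to the first rule it fails, so the counts and the survivor
#' total always sum to the input total.
#'
#' @slot nVariantsIn,nSamplesIn input dimensions.
#' @slot samplesRemoved named integer vector of per-rule sample exclusions.
#' @slot variantsRemoved named integer vector of per-rule variant exclusions.
#' @slot nVariantsOut,nSamplesOut surviving dimensions.
#' @export
setClass("QCReport",
    representation(
        nVariantsIn = "integer", nSamplesIn = "integer",
        samplesRemoved = "integer", variantsRemoved = "integer",
        nVariantsOut = "integer", nSamplesOut = "integer"
    )
)

setValidity("QCReport", function(object) {
    msg <- character(0)
    if (object@nVariantsIn != object@nVariantsOut + sum(object@variantsRemoved))
        msg <- c(msg, "variant accounting does not balance")
    if (object@nSamplesIn != object@nSamplesOut + sum(object@samplesRemoved))
        msg <- c(msg, "sample accounting does not balance")
    if (length(msg)) msg else TRUE
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport\n  samples: ", object@nSamplesIn, " in -> ",
        object@nSamplesOut, " kept\n", sep = "")
    for (nm in names(object@samplesRemoved))
        if (object@samplesRemoved[[nm]] > 0L)
            cat("    removed (", nm, "): ", object@samplesRemoved[[nm]],
                "\n", sep = "")
    cat("  variants: ", object@nVariantsIn, " in -> ", object@nVariantsOut,
        " kept\n", sep = "")
    for (nm in names(object@variantsRemoved))
        cat("    removed (", nm, "): ", object@variantsRemoved[[nm]],
            "\n", sep = "")
})

# ---------------------------------------------------------------------------
# LDBlockSet
# ---------------------------------------------------------------------------

#' Set of LD blocks anchored at index SNPs
#'
#' One block per resolvable index SNP: all genotyped variants within the
#' search window whose dosage r-squared with the index meets the proxy
#' threshold (inclusive), plus the genomic span those members cover.  The
#' index SNP itself is always a member with r-squared 1.
#'
#' @slot blocks data.frame: \code{index_rsid}, \code{chrom},
#'   \code{index_pos}, \code{locus_label}, \code{span_start},
#'   \code{span_end}, \code{n_members}.
#' @slot members data.frame: \code{index_rsid}, \code{rsid}, \code{chrom},
#'   \code{pos}, \code{r2}.
#' @slot r2Min proxy threshold used.
#' @slot skipped index rsids absent from the genotype matrix.
#' @export
setClass("LDBlockSet",
    representation(blocks = "data.frame", members = "data.frame",
                   r2Min = "numeric", skipped = "character")
)

setValidity("LDBlockSet", function(object) {
    msg <- character(0)
    if (nrow(object@members)) {
        if (any(object@members$r2 < object@r2Min - 1e-12))
            msg <- c(msg, "member below the r2 threshold")
        m <- merge(object@members, object@blocks, by = "index_rsid")
        if (any(m$pos < m$span_start | m$pos > m$span_end))
            msg <- c(msg, "member outside its block span")
        if (any(as.character(m$chrom.x) != as.character(m$chrom.y)))
            msg <- c(msg, "member off the index chromosome")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "LDBlockSet", function(object) {
    cat("LDBlockSet:", nrow(object@blocks), "blocks,",
        nrow(object@members), "member variants (r2 >=", object@r2Min, ")\n")
    if (length(object@skipped))
        cat("  unresolved index SNPs:",
            paste(object@skipped, collapse = ", "), "\n")
})

#' @describeIn LDBlockSet-class number of blocks.
#' @param x an \code{LDBlockSet}.
#' @export
setMethod("length", "LDBlockSet", function(x) nrow(x@blocks))

# ---------------------------------------------------------------------------
# PermutationNull
# ---------------------------------------------------------------------------

#' Permutation null distribution of the minimum nominal P value
#'
#' Result of [permuteScan()]: per permutation replicate, the sample linkage
#' between the genotype and expression matrices is shuffled once (jointly
#' for every SNP-probe pair in the family, preserving LD among SNPs and
#' co-expression among probes), the full association scan is repeated, and
#' the minimum nominal P value across all tests is recorded.
#'
#' @slot minP per-replicate minimum nominal P values (length \code{R}).
#' @slot nTests number of SNP-probe pairs in the family (m).
#' @slot R number of permutation replicates.
#' @slot seed integer seed that produced the replicates.
#' @slot observedMinP minimum nominal P of the unpermuted scan.
#' @seealso [deriveThresholds()], [empiricalAdjustedP()]
#' @export
setClass("PermutationNull",
    representation(minP = "numeric", nTests = "integer", R = "integer",
                   seed = "integer", observedMinP = "numeric")
)

setValidity("PermutationNull", function(object) {
    msg <- character(0)
    if (length(object@minP) != object@R)
        msg <- c(msg, "length(minP) must equal R")
    if (any(object@minP <= 0 | object@minP > 1))
        msg <- c(msg, "minP values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationNull", function(object) {
    cat("PermutationNull: R =", object@R, "replicates over m =",
        object@nTests, "tests (seed", object@seed, ")\n")
    q <- stats::quantile(object@minP, c(0.05, 0.5))
    cat("  min-P 5% quantile ", signif(q[1], 4), ", median ",
        signif(q[2], 4), "\n", sep = "")
    if (length(object@observedMinP))
        cat("  observed scan min P:", signif(object@observedMinP, 4), "\n")
})
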