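# Accessor generics for the package's containers.

#' Extract the dosage matrix
#'
#' @param x a [GenotypeExperiment-class].
#' @return numeric matrix, variants x samples, in [0, 2].
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeExperiment",
          function(x) assay(x, "dosage"))

#' Per-variant metadata with QC statistics
#'
#' Returns the variant annotation together with the QC statistics the
#' genotype filters consume: minor allele frequency (dosage mean halved,
#' folded to at most 0.5), call rate (non-missing fraction) and the INFO
#' imputation-quality score (posterior-variance form when genotype
#' posteriors are stored, dosage-variance form otherwise).
#'
#' @param x a [GenotypeExperiment-class].
#' @return a [S4Vectors::DataFrame] with one row per variant.
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname variantInfo
#' @export
setMethod("variantInfo", "GenotypeExperiment", function(x) {
    out <- rowData(x)
    d <- dosages(x)
    out$maf <- apply(d, 1L, function(v)
        if (all(is.na(v))) NA_real_ else computeMAF(v))
    out$call_rate <- rowMeans(!is.na(d))
    if (all(c("gpAA", "gpAB", "gpBB") %in% assayNames(x))) {
        gpAA <- assay(x, "gpAA"); gpAB <- assay(x, "gpAB")
        gpBB <- assay(x, "gpBB")
        out$info <- vapply(seq_len(nrow(d)), function(i)
            computeINFO(cbind(gpAA[i, ], gpAB[i, ], gpBB[i, ])),
            numeric(1))
    } else {
        out$info <- apply(d, 1L, .infoFromDosage)
    }
    out
})

#' Extract the expression matrix
#'
#' @param x an [ExpressionExperiment-class].
#' @return numeric matrix, probes x samples.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionExperiment",
          function(x) assay(x, "exprs"))

#' Probe annotation
#'
#' @param x an [ExpressionExperiment-class].
#' @return a [S4Vectors::DataFrame] of probe metadata.
#' @export
setGeneric("probeInfo", function(x) standardGeneric("probeInfo"))

#' @rdname probeInfo
#' @export
setMethod("probeInfo", "ExpressionExperiment", function(x) rowData(x))

#' Normalization state of an expression container
#'
#' @param x an [ExpressionExperiment-class].
#' @return one of \code{"raw"}, \code{"normalized"},
#'   \code{"batch_corrected"}.
#' @export
setGeneric("normState", function(x) standardGeneric("normState"))

#' @rdname normState
#' @export
setMethod("normState", "ExpressionExperiment",
          function(x) metadata(x)$state)

#' Per-replicate minimum nominal P values of a permutation null
#'
#' @param x a [PermutationNull-class].
#' @return numeric vector of length \code{R}.
#' @export
setGeneric("minP", function(x) standardGeneric("minP"))

#' @rdname minP
#' @export
setMethod("minP", "PermutationNull", function(x) x@minP)

#' Block and member tables of an LD block set
#'
#' @param x an [LDBlockSet-class].
#' @return \code{ldBlocks}: one row per block; \code{ldMembers}: one row
#'   per (block, proxy variant) pair with its r-squared to the index SNP.
#' @export
setGeneric("ldBlocks", function(x) standardGeneric("ldBlocks"))

#' @rdname ldBlocks
#' @export
setMethod("ldBlocks", "LDBlockSet", function(x) x@blocks)

#' @rdname ldBlocks
#' @export
setGeneric("ldMembers", function(x) standardGeneric("ldMembers"))

#' @rdname ldBlocks
#' @export
setMethod("ldMembers", "LDBlockSet", function(x) x@members)
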