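# Expression preparation: variance-stabilizing normalization, linear-model
# batch correction, PCA diagnostics, probe blacklisting and cohort merging.

#' Quantile-normalize a matrix across samples
#'
#' Thin wrapper over [limma::normalizeQuantiles()]: after normalization
#' every sample (column) shares one value multiset, so the operation is a
#' fixed point (idempotent) and invariant to within-column permutations.
#'
#' @param m numeric matrix, features x samples.
#' @return matrix of the same shape.
#' @export
quantileNormalize <- function(m) {
    out <- limma::normalizeQuantiles(as.matrix(m))
    dimnames(out) <- dimnames(m)
    out
}

#' Normalize an expression matrix
#'
#' The default pipeline applies the variance-stabilizing transform
#' \code{log2(x + 1)} followed by quantile normalization across samples.
#' \code{"rank-inverse-normal"} maps each probe's values to normal scores
#' \code{qnorm((rank - 0.5)/n)}, which makes downstream linear-model P
#' values robust to heavy tails.  \code{"none"} only advances the state.
#' Input must be in the \code{"raw"} state; the result is
#' \code{"normalized"} (states only move forward).
#'
#' @param expr an [ExpressionExperiment-class] in state \code{"raw"}.
#' @param method \code{"log-quantile"} (default),
#'   \code{"rank-inverse-normal"} or \code{"none"}.
#' @return a normalized [ExpressionExperiment-class].
#' @export
normalizeExpression <- function(expr, method = c("log-quantile",
                                                 "rank-inverse-normal",
                                                 "none")) {
    stopifnot(is(expr, "ExpressionExperiment"))
    method <- match.arg(method)
    if (normState(expr) != "raw")
        stop("normalization requires state 'raw' (got '", normState(expr),
             "'): states only move forward")
    x <- exprValues(expr)
    if (anyNA(x))
        stop("missing expression values: ", sum(is.na(x)), " entries")
    out <- switch(method,
        "log-quantile" = {
            nbad <- sum(x < 0)
            if (nbad > 0)
                stop("log2(x+1) transform requires nonnegative values: ",
                     nbad, " offending entries")
            quantileNormalize(log2(x + 1))
        },
        "rank-inverse-normal" = {
            t(apply(x, 1L, function(v)
                stats::qnorm((rank(v) - 0.5) / length(v))))
        },
        "none" = x)
    dimnames(out) <- dimnames(x)
    se <- expr
    assay(se, "exprs") <- out
    metadata(se)$state <- "normalized"
    metadata(se)$normalization_method <- method
    se
}

#' Remove batch effects by per-probe linear modeling
#'
#' For each probe, expression is regressed on batch indicators and
#' replaced by the residuals plus the probe's grand mean, so after
#' correction every batch mean equals the grand mean (to machine
#' precision) and the per-probe grand mean is preserved.  Batches with a
#' single sample cannot be estimated; they are excluded from estimation
#' with a warning and their values pass through unchanged.  With a single
#' batch the input is returned unchanged.
#'
#' @param expr a normalized [ExpressionExperiment-class].
#' @param batch batch labels, one per sample; defaults to
#'   \code{colData(expr)$batch}.
#' @return an [ExpressionExperiment-class] in state
#'   \code{"batch_corrected"}.
#' @export
regressOutBatch <- function(expr, batch = NULL) {
    stopifnot(is(expr, "ExpressionExperiment"))
    if (is.null(batch)) batch <- colData(expr)$batch
    if (is.null(batch))
        stop("no batch labels supplied and none in colData")
    batch <- as.factor(batch)
    if (length(batch) != ncol(expr))
        stop("one batch label per sample required")
    x <- exprValues(expr)
    se <- expr
    if (nlevels(batch) >= 2L) {
        tab <- table(batch)
        singletons <- names(tab)[tab < 2L]
        if (length(singletons))
            warning("batch(es) with a single sample excluded from ",
                    "estimation: ", paste(singletons, collapse = ", "))
        grand <- rowMeans(x)
        out <- x
        for (b in setdiff(levels(batch), singletons)) {
            idx <- which(batch == b)
            out[, idx] <- x[, idx, drop = FALSE] -
                rowMeans(x[, idx, drop = FALSE]) + grand
        }
        assay(se, "exprs") <- out
    }
    metadata(se)$state <- "batch_corrected"
    se
}

#' Principal component diagnostics of an expression matrix
#'
#' Computes the top-k principal components of the sample x probe matrix
#' (probes centered), the fraction of total variance each explains, and --
#' when batch labels are available -- the R-squared of each component
#' regressed on batch, the diagnostic used to confirm that technical batch
#' structure has been removed.
#'
#' @param expr a normalized or batch-corrected
#'   [ExpressionExperiment-class].
#' @param k number of components (at most \code{min(n samples, n probes)}).
#' @param batch optional batch labels; defaults to
#'   \code{colData(expr)$batch}.
#' @return list with \code{scores} (samples x k), \code{varianceFraction}
#'   (length k, sums to at most 1) and \code{batchR2} (length k, or
#'   \code{NULL} without batch labels).
#' @export
pcaCheck <- function(expr, k = 5L, batch = NULL) {
    stopifnot(is(expr, "ExpressionExperiment"))
    if (normState(expr) == "raw")
        stop("PCA diagnostics require normalized expression")
    x <- t(exprValues(expr))
    if (k > min(dim(x)))
        stop("k exceeds min(n samples, n probes) = ", min(dim(x)))
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    scores <- pc$x[, seq_len(k), drop = FALSE]
    varFrac <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
    if (is.null(batch)) batch <- colData(expr)$batch
    batchR2 <- NULL
    if (!is.null(batch)) {
        bf <- as.factor(batch)
        batchR2 <- apply(scores, 2L, function(s)
            summary(stats::lm(s ~ bf))$r.squared)
    }
    list(scores = scores, varianceFraction = varFrac, batchR2 = batchR2)
}

#' Exclude blacklisted probes
#'
#' Removes probes liable to cross-hybridization (or otherwise flagged) by
#' id.  Unknown ids are reported and ignored.
#'
#' @param expr an [ExpressionExperiment-class].
#' @param blacklist character vector of probe ids; defaults to probes with
#'   \code{rowData(expr)$blacklisted == TRUE}.
#' @return the [ExpressionExperiment-class] without the blacklisted
#'   probes.  Removing every probe yields a zero-row container with a
#'   warning.
#' @export
excludeProbes <- function(expr, blacklist = NULL) {
    stopifnot(is(expr, "ExpressionExperiment"))
    ids <- rowData(expr)$probe_id
    if (is.null(blacklist))
        blacklist <- ids[isTRUE_vec(rowData(expr)$blacklisted)]
    unknown <- setdiff(blacklist, ids)
    if (length(unknown))
        message(length(unknown), " blacklist id(s) not present; ignored")
    drop <- ids %in% blacklist
    message("excluding ", sum(drop), " of ", length(ids), " probes")
    out <- expr[!drop, ]
    if (nrow(out) == 0L)
        warning("all probes excluded: empty result")
    out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Merge expression cohorts by column-aligned concatenation
#'
#' Restricts each cohort to the probes common to all (id intersection,
#' standing in for cross-platform probe matching), concatenates samples
#' and records the cohort of origin as a batch label.
#'
#' @param exprs list of [ExpressionExperiment-class] objects in the same
#'   state.
#' @param labels cohort labels (default: list names or seq).
#' @return an [ExpressionExperiment-class] with \code{colData$batch} set
#'   to the cohort label.
#' @export
mergeCohorts <- function(exprs, labels = NULL) {
    stopifnot(length(exprs) >= 2L)
    if (is.null(labels))
        labels <- if (!is.null(names(exprs))) names(exprs)
                  else as.character(seq_along(exprs))
    states <- vapply(exprs, normState, character(1))
    if (length(unique(states)) != 1L)
        stop("cohorts are in different normalization states")
    common <- Reduce(intersect, lapply(exprs, function(e)
        rowData(e)$probe_id))
    if (!length(common))
        stop("no probes common to all cohorts")
    mats <- lapply(exprs, function(e)
        exprValues(e)[match(common, rowData(e)$probe_id), , drop = FALSE])
    values <- do.call(cbind, mats)
    probes <- rowData(exprs[[1L]])[match(common,
                                         rowData(exprs[[1L]])$probe_id), ]
    batch <- rep(labels, vapply(exprs, ncol, integer(1)))
    samples <- data.frame(sample_id = colnames(values), batch = batch,
                          stringsAsFactors = FALSE)
    ExpressionExperiment(values, probes, samples = samples,
                         state = states[1L])
}
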