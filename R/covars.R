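# Covariate robustness: covariate-adjusted general linear models,
# one-at-a-time robustness sweeps with interaction tests, and
# diagnosis-stratified rescans.

# Build a numeric model frame from a covariate data.frame: factors/character
# become one-hot indicator columns with a reference level; a left-censored
# CRP marker "<5" is encoded at the interval midpoint 2.5.
.covariateMatrix <- function(covariates) {
    covariates <- as.data.frame(covariates)
    for (nm in colnames(covariates)) {
        v <- covariates[[nm]]
        if (is.character(v) && any(grepl("^<", v))) {
            num <- suppressWarnings(as.numeric(v))
            cens <- grepl("^<", v)
            bound <- suppressWarnings(as.numeric(sub("^<", "", v[cens])))
            num[cens] <- bound / 2
            covariates[[nm]] <- num
        }
    }
    chr <- vapply(covariates, function(v) is.character(v) || is.factor(v),
                  logical(1))
    for (nm in colnames(covariates)[chr])
        covariates[[nm]] <- factor(covariates[[nm]])
    mf <- stats::model.frame(~ ., data = covariates,
                             na.action = stats::na.pass)
    mm <- stats::model.matrix(~ ., data = mf)
    mm[, -1L, drop = FALSE]
}

#' Covariate-adjusted SNP-probe association
#'
#' Ordinary least squares of expression on additive dosage plus the
#' supplied covariates (categorical covariates one-hot encoded against a
#' reference level).  Reports the dosage slope with its standard error and
#' marginal two-sided P.  Complete cases across dosage, expression and all
#' covariates are used; the reduction is reported via the \code{n} column.
#' Collinear designs (rank-deficient, or condition number above
#' \code{kappaMax}) are an error naming the offending columns.
#'
#' @param dosage numeric vector in [0, 2].
#' @param expression numeric vector, same length.
#' @param covariates data.frame of covariates (one row per sample).
#' @param kappaMax condition-number bound for the design matrix
#'   (default 1e8).
#' @return one-row data.frame: \code{n}, \code{slope}, \code{se},
#'   \code{p_nominal}, \code{r_squared} (full-model), \code{n_dropped}.
#' @export
fitAdjusted <- function(dosage, expression, covariates,
                        kappaMax = 1e8) {
    covariates <- as.data.frame(covariates)
    stopifnot(length(dosage) == length(expression),
              nrow(covariates) == length(dosage))
    mm <- .covariateMatrix(covariates)
    ok <- !is.na(dosage) & !is.na(expression) &
        stats::complete.cases(mm)
    nDropped <- sum(!ok)
    x <- dosage[ok]; y <- expression[ok]
    mm <- mm[ok, , drop = FALSE]
    if (length(x) < ncol(mm) + 3L)
        stop("too few complete cases for the adjusted model")
    if (stats::sd(x) == 0)
        stop("monomorphic dosage: association undefined")
    X <- cbind(`(Intercept)` = 1, dosage = x, mm)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
        stop("collinear design: ", paste(aliased, collapse = ", "))
    }
    Xs <- scale(X[, -1L, drop = FALSE])
    kap <- kappa(Xs, exact = TRUE)
    if (is.finite(kap) && kap > kappaMax)
        stop("ill-conditioned design (condition number ",
             format(kap, digits = 3), "): ",
             paste(colnames(X)[-1L], collapse = ", "))
    fit <- stats::lm.fit(X, y)
    res <- fit$residuals
    dfres <- length(y) - ncol(X)
    sigma2 <- sum(res^2) / dfres
    XtXinv <- solve(crossprod(X))
    se <- sqrt(sigma2 * XtXinv[2L, 2L])
    slope <- fit$coefficients[["dosage"]]
    tval <- slope / se
    syy <- sum((y - mean(y))^2)
    data.frame(n = length(y), slope = slope, se = se,
               p_nominal = 2 * stats::pt(-abs(tval), dfres),
               r_squared = if (syy > 0) 1 - sum(res^2) / syy else 0,
               n_dropped = nDropped, stringsAsFactors = FALSE)
}

#' One-at-a-time covariate robustness sweep
#'
#' For each association result and each covariate in turn, refits the
#' linear model with that single covariate added and compares the dosage
#' slope with the unadjusted one; also fits a SNP x covariate interaction
#' model and reports the interaction P value (an F test over the
#' interaction terms for categorical covariates).  An eQTL is flagged
#' \code{"unchanged"} when the absolute slope change is below
#' \code{tolerance} times the absolute base slope.  Covariates absent
#' from the metadata are skipped with a message.
#'
#' @param results data.frame from [scanAssociations()] (or a subset).
#' @param geno a [GenotypeExperiment-class].
#' @param expr an [ExpressionExperiment-class].
#' @param meta data.frame of sample metadata with \code{sample_id}.
#' @param covariates covariate column names (default
#'   \code{c("age", "sex", "crp", "sjc")}).
#' @param tolerance relative slope-change tolerance (default 0.1).
#' @return data.frame with one row per (eQTL, covariate):
#'   \code{rsid}, \code{probe_id}, \code{covariate}, \code{slope_base},
#'   \code{slope_adjusted}, \code{delta}, \code{interaction_p},
#'   \code{flag}.
#' @export
robustnessSweep <- function(results, geno, expr, meta,
                            covariates = c("age", "sex", "crp", "sjc"),
                            tolerance = 0.1) {
    if (!nrow(results) || !length(covariates))
        return(data.frame(rsid = character(0), probe_id = character(0),
                          covariate = character(0),
                          slope_base = numeric(0),
                          slope_adjusted = numeric(0), delta = numeric(0),
                          interaction_p = numeric(0), flag = character(0),
                          stringsAsFactors = FALSE))
    meta <- as.data.frame(meta)
    missing <- setdiff(covariates, colnames(meta))
    if (length(missing)) {
        message("covariate(s) absent from metadata, skipped: ",
                paste(missing, collapse = ", "))
        covariates <- setdiff(covariates, missing)
    }
    samples <- intersect(intersect(colnames(geno), colnames(expr)),
                         meta$sample_id)
    meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
    d <- dosages(geno)[, samples, drop = FALSE]
    e <- exprValues(expr)[, samples, drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(results))) {
        x <- d[results$rsid[i], ]
        y <- e[results$probe_id[i], ]
        base <- results$slope[i]
        for (cv in covariates) {
            cov1 <- meta[, cv, drop = FALSE]
            adj <- fitAdjusted(x, y, cov1)
            delta <- adj$slope - base
            intp <- .interactionP(x, y, cov1[[1L]])
            out[[length(out) + 1L]] <- data.frame(
                rsid = results$rsid[i], probe_id = results$probe_id[i],
                covariate = cv, slope_base = base,
                slope_adjusted = adj$slope, delta = delta,
                interaction_p = intp,
                flag = if (abs(delta) < tolerance * abs(base))
                    "unchanged" else "changed",
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

# P value of the SNP x covariate interaction: t test for a numeric
# covariate's single interaction coefficient, F test over all interaction
# terms for a categorical one.
.interactionP <- function(x, y, covariate) {
    df <- data.frame(y = y, g = x, cv = covariate)
    if (is.character(df$cv)) df$cv <- factor(df$cv)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    add <- stats::lm(y ~ g + cv, data = df)
    full <- stats::lm(y ~ g * cv, data = df)
    an <- stats::anova(add, full)
    an[["Pr(>F)"]][2L]
}

#' Diagnosis-stratified association rescan
#'
#' Restricts the cohort to one diagnostic stratum and repeats the
#' association scan with an identical output schema, supporting the check
#' that eQTL gene lists do not change materially when disease subgroups
#' are analysed independently.
#'
#' @param geno a [GenotypeExperiment-class].
#' @param expr an [ExpressionExperiment-class].
#' @param blocks an [LDBlockSet-class].
#' @param assignments output of [classifyProbes()].
#' @param meta data.frame with \code{sample_id} and \code{diagnosis}.
#' @param stratum a diagnosis class, or \code{NULL} for all samples.
#' @param minSamples refusal floor for stratum size (default 20).
#' @param mode \code{"cis"} or \code{"trans"}.
#' @return data.frame of association results as from
#'   [scanAssociations()].
#' @export
stratifiedScan <- function(geno, expr, blocks, assignments, meta,
                           stratum = NULL, minSamples = 20L,
                           mode = c("cis", "trans")) {
    mode <- match.arg(mode)
    meta <- as.data.frame(meta)
    keep <- if (is.null(stratum)) meta$sample_id
            else meta$sample_id[meta$diagnosis == stratum]
    keep <- intersect(intersect(keep, colnames(geno)), colnames(expr))
    if (length(keep) < minSamples)
        stop("stratum '", if (is.null(stratum)) "all" else stratum,
             "' has ", length(keep), " samples, below the floor of ",
             minSamples)
    scanAssociations(geno[, keep], expr[, keep], blocks, assignments,
                     mode = mode)
}
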