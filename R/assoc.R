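# Per SNP-probe association: ordinary least squares of expression on
# additive dosage, Pearson R^2 with its t-based nominal P, Spearman rho,
# Benjamini-Hochberg comparison and lead-SNP-per-gene summaries.

# Closed-form simple OLS with residual diagnostics; x must be polymorphic.
.olsCore <- function(x, y) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    dx <- x - mx; dy <- y - my
    sxx <- sum(dx^2); syy <- sum(dy^2); sxy <- sum(dx * dy)
    slope <- sxy / sxx
    if (syy == 0) {
        return(list(n = n, slope = 0, se = NA_real_, r2 = 0,
                    p = 1, flag = "constant_expression",
                    resid = rep(0, n)))
    }
    resid <- dy - slope * dx
    rss <- sum(resid^2)
    df <- n - 2L
    sigma2 <- rss / df
    se <- sqrt(sigma2 / sxx)
    r2 <- 1 - rss / syy
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df)
    if (rss == 0) p <- 0
    list(n = n, slope = slope, se = se, r2 = min(1, max(0, r2)), p = p,
         flag = NA_character_, resid = resid)
}

# Spearman rho with t-approximation P (ties handled by midranks; the
# asymptotic approximation is standard for dosage data with heavy ties).
.spearman <- function(x, y) {
    if (stats::sd(y) == 0)
        return(c(rho = NA_real_, p = NA_real_))
    rho <- stats::cor(rank(x), rank(y))
    n <- length(x)
    if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
    if (abs(rho) >= 1) return(c(rho = rho, p = 0))
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    c(rho = rho, p = 2 * stats::pt(-abs(tval), n - 2))
}

#' Fit one SNP-probe linear association
#'
#' Ordinary least squares of expression on additive allele dosage with an
#' intercept.  R-squared equals the squared Pearson correlation and the
#' nominal P value comes from the two-sided t statistic \code{slope/se} on
#' n-2 degrees of freedom.  Spearman's rho and its P are reported
#' alongside.  Residual diagnostics (skewness, excess kurtosis and a
#' Breusch-Pagan-type heteroscedasticity score with its P) are attached as
#' the \code{"diagnostics"} attribute; they flag but never drop results.
#'
#' Complete-case analysis: pairs with a missing dosage or expression value
#' are removed first.  A monomorphic dosage is an error; constant
#' expression returns R-squared 0 with P 1 and the
#' \code{"constant_expression"} flag.
#'
#' @param dosage numeric vector in [0, 2].
#' @param expression numeric vector, same length.
#' @return one-row data.frame: \code{n}, \code{slope}, \code{se},
#'   \code{r_squared}, \code{p_nominal}, \code{rho}, \code{p_rho},
#'   \code{maf}, \code{flag}.
#' @examples
#' fitSnpProbe(c(0, 1, 2, 0, 1, 2), c(0.1, 2.2, 3.9, -0.1, 2.1, 4.0))
#' @export
fitSnpProbe <- function(dosage, expression) {
    if (length(dosage) != length(expression))
        stop("dosage and expression differ in length")
    ok <- !is.na(dosage) & !is.na(expression)
    x <- dosage[ok]; y <- expression[ok]
    if (length(x) < 3L)
        stop("fewer than 3 complete pairs")
    if (stats::sd(x) == 0)
        stop("monomorphic dosage: association undefined")
    fit <- .olsCore(x, y)
    sp <- .spearman(x, y)
    out <- data.frame(n = fit$n, slope = fit$slope, se = fit$se,
                      r_squared = fit$r2, p_nominal = fit$p,
                      rho = sp[["rho"]], p_rho = sp[["p"]],
                      maf = computeMAF(x), flag = fit$flag,
                      stringsAsFactors = FALSE)
    attr(out, "diagnostics") <- .residDiagnostics(x, fit$resid)
    out
}

# skewness, excess kurtosis, and an LM-type score for var(resid) ~ dosage
.residDiagnostics <- function(x, resid) {
    n <- length(resid)
    s <- stats::sd(resid)
    if (s == 0)
        return(list(skewness = 0, kurtosis = 0, bp_stat = 0, bp_p = 1))
    z <- (resid - mean(resid)) / s
    r2aux <- .olsCore(x, resid^2)$r2
    bp <- n * r2aux
    list(skewness = mean(z^3), kurtosis = mean(z^4) - 3,
         bp_stat = bp, bp_p = stats::pchisq(bp, 1L, lower.tail = FALSE))
}

# Internal: assemble the SNP-probe pair frame for one scan family.
# Returns per-block member/probe index lists against the given matrices.
.scanFamily <- function(geno, expr, blocks, assignments, mode) {
    samples <- intersect(colnames(geno), colnames(expr))
    if (!length(samples))
        stop("no overlapping samples between genotypes and expression")
    if (length(samples) < ncol(geno) || length(samples) < ncol(expr))
        message("restricting to ", length(samples),
                " samples present in both matrices")
    bl <- ldBlocks(blocks)
    mem <- ldMembers(blocks)
    vann <- as.data.frame(rowData(geno))
    pann <- as.data.frame(rowData(expr))
    fam <- list()
    for (i in seq_len(nrow(bl))) {
        b <- bl$index_rsid[i]
        snps <- mem[mem$index_rsid == b, , drop = FALSE]
        snps <- snps[snps$rsid %in% vann$rsid, , drop = FALSE]
        probes <- assignments[assignments$index_rsid == b &
                              assignments$class == mode, , drop = FALSE]
        probes <- probes[probes$probe_id %in% pann$probe_id, ,
                         drop = FALSE]
        if (!nrow(snps) || !nrow(probes)) next
        fam[[length(fam) + 1L]] <- list(
            index_rsid = b, locus_label = bl$locus_label[i],
            snps = snps, probes = probes)
    }
    list(samples = samples, fam = fam)
}

#' Association scan over LD-block members and classified probes
#'
#' One linear-model test per (block member SNP x probe of the requested
#' class), on the samples shared by the genotype and expression matrices.
#' With complete data the scan is vectorized through standardized
#' cross-products; pairs involving missing values fall back to
#' per-pair complete-case fits.  Results are ordered deterministically by
#' (locus, SNP position, rsid, probe).
#'
#' @param geno a [GenotypeExperiment-class].
#' @param expr an [ExpressionExperiment-class] (normalized).
#' @param blocks an [LDBlockSet-class].
#' @param assignments output of [classifyProbes()].
#' @param mode \code{"cis"} or \code{"trans"}.
#' @return data.frame of association results: \code{rsid},
#'   \code{probe_id}, \code{gene_symbol}, \code{index_rsid},
#'   \code{locus_label}, \code{class}, \code{n}, \code{slope}, \code{se},
#'   \code{r_squared}, \code{p_nominal}, \code{rho}, \code{p_rho},
#'   \code{maf}, \code{r2_with_index}, \code{flag}.
#' @export
scanAssociations <- function(geno, expr, blocks, assignments,
                             mode = c("cis", "trans")) {
    mode <- match.arg(mode)
    stopifnot(is(geno, "GenotypeExperiment"),
              is(expr, "ExpressionExperiment"))
    sf <- .scanFamily(geno, expr, blocks, assignments, mode)
    samples <- sf$samples
    d <- dosages(geno)[, samples, drop = FALSE]
    e <- exprValues(expr)[, samples, drop = FALSE]
    out <- list()
    for (f in sf$fam) {
        snpIdx <- match(f$snps$rsid, rownames(d))
        prbIdx <- match(f$probes$probe_id, rownames(e))
        G <- t(d[snpIdx, , drop = FALSE])
        E <- t(e[prbIdx, , drop = FALSE])
        for (j in seq_along(snpIdx)) {
            for (k in seq_along(prbIdx)) {
                res <- fitSnpProbe(G[, j], E[, k])
                out[[length(out) + 1L]] <- data.frame(
                    rsid = f$snps$rsid[j],
                    probe_id = f$probes$probe_id[k],
                    gene_symbol = f$probes$gene_symbol[k],
                    index_rsid = f$index_rsid,
                    locus_label = f$locus_label,
                    class = mode,
                    pos = f$snps$pos[j],
                    r2_with_index = f$snps$r2[j],
                    res, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(.emptyScan())
    res <- do.call(rbind, out)
    res <- res[order(res$locus_label, res$pos, res$rsid, res$probe_id), ]
    rownames(res) <- NULL
    res[, c("rsid", "probe_id", "gene_symbol", "index_rsid",
            "locus_label", "class", "pos", "n", "slope", "se",
            "r_squared", "p_nominal", "rho", "p_rho", "maf",
            "r2_with_index", "flag")]
}

.emptyScan <- function() {
    data.frame(rsid = character(0), probe_id = character(0),
               gene_symbol = character(0), index_rsid = character(0),
               locus_label = character(0), class = character(0),
               pos = numeric(0), n = integer(0), slope = numeric(0),
               se = numeric(0), r_squared = numeric(0),
               p_nominal = numeric(0), rho = numeric(0),
               p_rho = numeric(0), maf = numeric(0),
               r2_with_index = numeric(0), flag = character(0),
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The standard FDR comparison method for the permutation thresholds:
#' step-up BH with enforced monotonicity, capped at 1
#' (via [stats::p.adjust()]).
#'
#' @param pValues numeric vector of nominal P values in (0, 1].
#' @return adjusted P values, same length and order.
#' @export
bhAdjust <- function(pValues) {
    if (!length(pValues)) return(numeric(0))
    if (any(is.na(pValues)) || any(pValues <= 0) || any(pValues > 1))
        stop("p values must lie in (0, 1]")
    stats::p.adjust(pValues, method = "BH")
}

#' Lead eQTL SNP per probe with significant-SNP counts
#'
#' Summarizes a scan the way cell-type eQTL tables are reported: per
#' probe, the minimum-P SNP (ties broken by genomic position, then rsid),
#' its MAF and its LD r-squared with the locus index SNP, plus the count
#' of SNPs significant for that probe at the supplied threshold
#' (inclusive).
#'
#' @param results data.frame from [scanAssociations()].
#' @param threshold nominal significance threshold (e.g. a permutation
#'   threshold).
#' @return data.frame with one row per probe, ordered by lead P.
#' @export
leadPerGene <- function(results, threshold) {
    if (!nrow(results))
        return(data.frame(gene_symbol = character(0),
                          probe_id = character(0),
                          lead_rsid = character(0),
                          locus_label = character(0), maf = numeric(0),
                          p_nominal = numeric(0),
                          r2_with_index = numeric(0),
                          n_significant = integer(0),
                          stringsAsFactors = FALSE))
    parts <- split(results, results$probe_id)
    rows <- lapply(parts, function(g) {
        g <- g[order(g$p_nominal, g$pos, g$rsid), , drop = FALSE]
        data.frame(gene_symbol = g$gene_symbol[1L],
                   probe_id = g$probe_id[1L], lead_rsid = g$rsid[1L],
                   locus_label = g$locus_label[1L], maf = g$maf[1L],
                   p_nominal = g$p_nominal[1L],
                   r2_with_index = g$r2_with_index[1L],
                   n_significant = sum(g$p_nominal <= threshold),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p_nominal, out$probe_id), ]
    rownames(out) <- NULL
    out
}

#' Manhattan-plot table from scan results
#'
#' Plot-ready table: loci in genomic order with per-pair -log10 nominal P
#' and cis/trans class.
#'
#' @param results data.frame from [scanAssociations()].
#' @return data.frame with \code{locus_label}, \code{rsid}, \code{pos},
#'   \code{probe_id}, \code{class}, \code{neg_log10_p}.
#' @export
manhattanTable <- function(results) {
    out <- data.frame(locus_label = results$locus_label,
                      rsid = results$rsid, pos = results$pos,
                      probe_id = results$probe_id, class = results$class,
                      neg_log10_p = -log10(results$p_nominal),
                      stringsAsFactors = FALSE)
    out[order(out$locus_label, out$pos, out$probe_id), , drop = FALSE]
}
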