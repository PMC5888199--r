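# Synthetic cohort generator: genotypes with block LD, expression with
# planted additive cis effects, clinical metadata, and a ground-truth ledger.

#' Simulate genotype dosages with block LD
#'
#' Diploid dosages are built as the sum of two haplotypes.  Within a locus,
#' haplotype alleles follow a first-order Markov copying chain: a latent
#' uniform is copied from the previous variant with probability
#' \code{ldDecay} and redrawn otherwise, and the allele is the indicator
#' that the uniform falls below the variant's target allele frequency.
#' Copying the latent uniform rather than the allele itself preserves every
#' variant's marginal MAF exactly while giving adjacent-variant haplotype
#' correlation \code{ldDecay} (when the two variants share a MAF), so
#' expected pairwise dosage r-squared decays geometrically with marker
#' distance.  Each locus sits on its own chromosome with strictly
#' increasing 1-based positions.
#'
#' With \code{imputationCertainty < 1}, hard calls are softened into
#' genotype posterior triples (per-sample certainty drawn from a Beta
#' distribution with that mean; residual mass split over the other two
#' genotypes in Hardy-Weinberg proportions) and the stored dosages become
#' the posterior-expected dosages, so downstream INFO filtering is
#' exercised.
#'
#' @param cfg a [SimConfig-class].
#' @return a [GenotypeExperiment-class] with rowData columns \code{rsid},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{locus},
#'   \code{maf_target}.
#' @examples
#' ge <- simulateGenotypes(simConfig(nSamples = 50, nLoci = 2, seed = 1))
#' ge
#' @export
simulateGenotypes <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    set.seed(cfg@seed)
    nS <- cfg@nSamples
    nh <- 2L * nS
    sampleIds <- sprintf("S%04d", seq_len(nS))
    dosList <- list()
    annList <- list()
    for (l in seq_len(cfg@nLoci)) {
        chrom <- as.character(((l - 1L) %% 22L) + 1L)
        base <- 5e7 + ((l - 1L) %/% 22L) * 2e7
        pos <- base + (seq_len(cfg@snpsPerLocus) - 1L) * 5000L
        p <- stats::runif(cfg@snpsPerLocus, cfg@mafRange[1], cfg@mafRange[2])
        u <- matrix(NA_real_, nh, cfg@snpsPerLocus)
        u[, 1L] <- stats::runif(nh)
        if (cfg@snpsPerLocus > 1L) {
            for (j in 2:cfg@snpsPerLocus) {
                copy <- stats::runif(nh) < cfg@ldDecay
                u[, j] <- ifelse(copy, u[, j - 1L], stats::runif(nh))
            }
        }
        alleles <- sweep(u, 2L, p, `<`) * 1
        dos <- alleles[seq(1L, nh, by = 2L), , drop = FALSE] +
               alleles[seq(2L, nh, by = 2L), , drop = FALSE]
        dosList[[l]] <- t(dos)
        annList[[l]] <- data.frame(
            rsid = sprintf("rs%07d", l * 1000L + seq_len(cfg@snpsPerLocus)),
            chrom = chrom, pos = pos, ref = "A", alt = "G",
            locus = l, maf_target = p, stringsAsFactors = FALSE)
    }
    dosage <- do.call(rbind, dosList)
    colnames(dosage) <- sampleIds
    variants <- do.call(rbind, annList)

    posteriors <- NULL
    if (cfg@imputationCertainty < 1) {
        cc <- cfg@imputationCertainty
        q <- matrix(stats::rbeta(length(dosage), 30 * cc, 30 * (1 - cc)),
                    nrow(dosage), ncol(dosage))
        gp <- .softenGenotypes(dosage, q, variants$maf_target)
        posteriors <- gp
        dosage <- gp$gpAB + 2 * gp$gpBB
        dimnames(dosage) <- list(variants$rsid, sampleIds)
    }
    GenotypeExperiment(dosage, variants, posteriors = posteriors)
}

# Turn hard genotype calls into posterior triples: weight q on the true
# genotype, remaining mass on the other two genotypes in HWE proportions.
.softenGenotypes <- function(hard, q, p) {
    hw <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
    gpAA <- gpAB <- gpBB <- matrix(0, nrow(hard), ncol(hard))
    for (g in 0:2) {
        idx <- hard == g
        other <- setdiff(0:2, g)
        denom <- hw[, other[1] + 1L] + hw[, other[2] + 1L]
        w1 <- hw[, other[1] + 1L] / denom
        for (i in seq_len(nrow(hard))) {
            sel <- idx[i, ]
            if (!any(sel)) next
            rest <- 1 - q[i, sel]
            tri <- matrix(0, 3L, sum(sel))
            tri[g + 1L, ] <- q[i, sel]
            tri[other[1] + 1L, ] <- rest * w1[i]
            tri[other[2] + 1L, ] <- rest * (1 - w1[i])
            gpAA[i, sel] <- gpAA[i, sel] + tri[1L, ]
            gpAB[i, sel] <- gpAB[i, sel] + tri[2L, ]
            gpBB[i, sel] <- gpBB[i, sel] + tri[3L, ]
        }
    }
    list(gpAA = gpAA, gpAB = gpAB, gpBB = gpBB)
}

#' Simulate expression with planted cis effects and clinical metadata
#'
#' Expression for probe j of sample i is the probe baseline plus any
#' planted additive allelic effect, a per-batch offset, clinical covariate
#' effects, and Gaussian noise.  Probes of one locus share an
#' equicorrelated noise component with pairwise correlation
#' \code{probeCor}.  Probes are placed on the locus chromosome within
#' 1.5 Mb of the variant span, so every planted effect is cis under the
#' 4-Mb window rule.  Values are emitted on the normalized intensity scale
#' (state \code{"normalized"}): planted slopes are defined on the scale the
#' association scan consumes.
#'
#' Sample metadata emulate an early-arthritis cohort: age, sex (1 =
#' female), CRP, ESR, swollen joint count (0-28), a three-level diagnosis
#' (RA / non-RA inflammatory / noninflammatory), processing batch, and
#' normalized transcript surrogates of T cell activation (CD25, CD69,
#' IFN-gamma).  Covariate effects on expression default to zero.
#'
#' @param geno a [GenotypeExperiment-class] from [simulateGenotypes()].
#' @param cfg the same [SimConfig-class] used to generate \code{geno}.
#' @return list with elements \code{expr} (an
#'   [ExpressionExperiment-class], metadata in \code{colData}),
#'   \code{truth} (data.frame ledger: \code{rsid}, \code{probe_id},
#'   \code{slope}, \code{class}), and \code{meta} (the sample metadata as a
#'   data.frame).
#' @examples
#' cfg <- simConfig(nSamples = 50, nLoci = 1, effectSizes = 0.5, seed = 2)
#' sim <- simulateExpression(simulateGenotypes(cfg), cfg)
#' sim$truth
#' @export
simulateExpression <- function(geno, cfg) {
    stopifnot(is(geno, "GenotypeExperiment"), is(cfg, "SimConfig"))
    if (ncol(geno) != cfg@nSamples)
        stop("genotype sample count (", ncol(geno),
             ") does not match cfg@nSamples (", cfg@nSamples, ")")
    if (length(cfg@effectSizes) > cfg@nLoci)
        stop("planted effect refers to an absent locus")
    set.seed(cfg@seed + 1L)
    nS <- cfg@nSamples
    sampleIds <- colnames(geno)
    vann <- as.data.frame(rowData(geno))

    meta <- .simulateMeta(nS, sampleIds, cfg@nBatches)

    probeList <- list()
    for (l in seq_len(cfg@nLoci)) {
        vl <- vann[vann$locus == l, ]
        span <- range(vl$pos)
        offs <- if (cfg@probesPerLocus == 1L) 0 else
            round(seq(-1.5e6, 1.5e6, length.out = cfg@probesPerLocus))
        probeList[[l]] <- data.frame(
            probe_id = sprintf("ILMN_%07d",
                               l * 100L + seq_len(cfg@probesPerLocus)),
            gene_symbol = sprintf("GENE%d.%d", l,
                                  seq_len(cfg@probesPerLocus)),
            chrom = vl$chrom[1L],
            start_pos = pmax(1, span[1L] + offs),
            locus = l, stringsAsFactors = FALSE)
    }
    probes <- do.call(rbind, probeList)
    nP <- nrow(probes)

    mu <- stats::rnorm(nP, 8, 1)
    E <- matrix(mu, nP, nS)
    colnames(E) <- sampleIds

    # equicorrelated Gaussian noise within each locus's probe set
    for (l in seq_len(cfg@nLoci)) {
        rows <- which(probes$locus == l)
        shared <- stats::rnorm(nS)
        eps <- matrix(stats::rnorm(length(rows) * nS), length(rows), nS)
        noise <- sqrt(cfg@probeCor) * matrix(shared, length(rows), nS,
                                             byrow = TRUE) +
                 sqrt(1 - cfg@probeCor) * eps
        E[rows, ] <- E[rows, ] + cfg@noiseSd * noise
    }

    # per-batch, per-probe offsets
    if (cfg@batchEffectSd > 0 && cfg@nBatches > 1L) {
        off <- matrix(stats::rnorm(cfg@nBatches * nP, 0, cfg@batchEffectSd),
                      cfg@nBatches, nP)
        E <- E + t(off[meta$batch, , drop = FALSE])
    }

    # clinical covariate effects (standardized covariates), zero by default
    gam <- cfg@covariateEffects
    if (any(gam != 0)) {
        covs <- cbind(age = as.numeric(scale(meta$age)),
                      sex = as.numeric(scale(meta$sex)),
                      crp = as.numeric(scale(meta$crp)),
                      sjc = as.numeric(scale(meta$sjc)))
        E <- E + matrix(rep(drop(covs %*% gam[colnames(covs)]), each = nP),
                        nP, nS)
    }

    # planted additive cis effects: middle SNP of the locus acts on the
    # locus's first probe
    truth <- data.frame(rsid = character(0), probe_id = character(0),
                        slope = numeric(0), class = character(0),
                        stringsAsFactors = FALSE)
    dos <- dosages(geno)
    for (l in seq_along(cfg@effectSizes)) {
        beta <- cfg@effectSizes[l]
        vl <- vann[vann$locus == l, ]
        snp <- vl$rsid[(nrow(vl) + 1L) %/% 2L]
        prb <- probes$probe_id[probes$locus == l][1L]
        E[match(prb, probes$probe_id), ] <-
            E[match(prb, probes$probe_id), ] + beta * dos[snp, ]
        span <- range(vl$pos)
        pstart <- probes$start_pos[probes$probe_id == prb]
        dist <- if (pstart >= span[1] && pstart <= span[2]) 0 else
            min(abs(pstart - span[1]), abs(pstart - span[2]))
        truth <- rbind(truth, data.frame(
            rsid = snp, probe_id = prb, slope = beta,
            class = if (dist <= 4e6) "cis" else "trans",
            stringsAsFactors = FALSE))
    }

    expr <- ExpressionExperiment(E, probes[, c("probe_id", "gene_symbol",
                                               "chrom", "start_pos")],
                                 samples = meta, state = "normalized")
    list(expr = expr, truth = truth, meta = meta)
}

# Table-1-like clinical metadata: three diagnostic strata with
# RA-predominant female fraction and inflammation markers.
.simulateMeta <- function(nS, sampleIds, nBatches) {
    diagnosis <- sample(c("RA", "non-RA inflammatory", "noninflammatory"),
                        nS, replace = TRUE,
                        prob = c(124, 113, 107) / 344)
    age <- round(pmin(90, pmax(18, stats::rnorm(nS, 55, 13))))
    sex <- stats::rbinom(nS, 1L, 0.7)
    crp <- round(stats::rlnorm(nS, log(9), 0.9), 1)
    esr <- round(stats::rlnorm(nS, log(18), 0.8), 1)
    sjc <- pmin(28L, stats::rpois(nS, 2.5))
    data.frame(sample_id = sampleIds, age = age, sex = sex, crp = crp,
               esr = esr, sjc = sjc, diagnosis = diagnosis,
               batch = rep_len(seq_len(nBatches), nS),
               cd25 = round(stats::rnorm(nS), 6),
               cd69 = round(stats::rnorm(nS), 6),
               ifng = round(stats::rnorm(nS), 6),
               stringsAsFactors = FALSE)
}

#' Write a simulated cohort as plain-text fixture files
#'
#' Emits \code{genotypes.tsv} (or \code{genotypes.vcf} with DS and, when
#' posteriors are stored, GP FORMAT fields), \code{expression.tsv},
#' \code{probe_annotation.tsv}, \code{sample_metadata.tsv} and
#' \code{truth.tsv} into \code{dir}.  Numeric matrices are printed with
#' 17 significant digits so that reading the files back through
#' [readGenotypes()] / [readExpression()] reproduces every value
#' bit-identically, and repeated writes of the same objects are
#' byte-identical.
#'
#' @param geno a [GenotypeExperiment-class].
#' @param expr an [ExpressionExperiment-class].
#' @param truth the ground-truth ledger data.frame (may have zero rows).
#' @param dir output directory (created if absent).
#' @param format \code{"tsv"} (dosage matrix) or \code{"vcf"}.
#' @return invisibly, the named vector of file paths written.
#' @export
writeFixture <- function(geno, expr, truth, dir, format = c("tsv", "vcf")) {
    format <- match.arg(format)
    if (ncol(geno) == 0L || ncol(expr) == 0L)
        stop("refusing to write an empty cohort (0 samples)")
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", dir)
    paths <- c(
        genotypes = file.path(dir, paste0("genotypes.",
                                          if (format == "vcf") "vcf" else "tsv")),
        expression = file.path(dir, "expression.tsv"),
        probes = file.path(dir, "probe_annotation.tsv"),
        meta = file.path(dir, "sample_metadata.tsv"),
        truth = file.path(dir, "truth.tsv"))

    if (format == "tsv") {
        ann <- as.data.frame(rowData(geno))[, c("rsid", "chrom", "pos",
                                                "ref", "alt")]
        .writeTsv(cbind(ann, .fmtMat(dosages(geno))), paths[["genotypes"]])
    } else {
        .writeVcf(geno, paths[["genotypes"]])
    }
    .writeTsv(cbind(probe_id = rowData(expr)$probe_id,
                    .fmtMat(exprValues(expr))), paths[["expression"]])
    .writeTsv(as.data.frame(rowData(expr))[, c("probe_id", "gene_symbol",
                                               "chrom", "start_pos")],
              paths[["probes"]])
    .writeTsv(as.data.frame(colData(expr)), paths[["meta"]])
    .writeTsv(truth, paths[["truth"]])
    invisible(paths)
}

# 17 significant digits: exact double round trip through text
.fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
}

.fmtMat <- function(m) {
    out <- matrix(.fmtNum(m), nrow(m), ncol(m))
    colnames(out) <- colnames(m)
    as.data.frame(out, stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

# Minimal VCF 4.2 writer with per-sample DS (and GP) fields.
.writeVcf <- function(geno, path) {
    ann <- as.data.frame(rowData(geno))
    hasGP <- all(c("gpAA", "gpAB", "gpBB") %in% assayNames(geno))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
        if (hasGP)
            "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior probabilities\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(geno)), collapse = "\t")), con)
    d <- dosages(geno)
    fmt <- if (hasGP) "DS:GP" else "DS"
    for (i in seq_len(nrow(geno))) {
        fields <- .fmtNum(d[i, ])
        if (hasGP) {
            gp <- paste(.fmtNum(assay(geno, "gpAA")[i, ]),
                        .fmtNum(assay(geno, "gpAB")[i, ]),
                        .fmtNum(assay(geno, "gpBB")[i, ]), sep = ",")
            fields <- paste(fields, gp, sep = ":")
        }
        writeLines(paste(c(ann$chrom[i], ann$pos[i], ann$rsid[i],
                           ann$ref[i], ann$alt[i], ".", "PASS", ".",
                           fmt, fields), collapse = "\t"), con)
    }
    invisible(path)
}
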