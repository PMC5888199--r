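# End-to-end pipeline: QC -> normalization -> LD blocks -> cis/trans scans
# -> permutation thresholds -> covariate robustness -> reports, driven by a
# validated configuration with per-stage artifacts and provenance records.

#' Read and validate a pipeline configuration
#'
#' YAML configuration with input paths (\code{genotypes},
#' \code{expression}, \code{probe_annotation}, \code{metadata},
#' \code{index_snps}), QC thresholds, the LD r-squared threshold, the cis
#' window, permutation settings (replicates, seed, alphas), the
#' normalization method, the covariate list and the output directory.
#' Unspecified fields take the documented defaults; thresholds outside
#' their ranges are refused.  A seed is mandatory because the permutation
#' stage is stochastic.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    defaults <- list(min_call_rate = 0.98, min_sample_call_rate = 0.98,
                     min_maf = 0.01, min_info = 0.8, r2_min = 0.8,
                     search_window_bp = 1e6, window_bp = 4e6,
                     permutations = 10000L, alphas = c(0.05, 0.10),
                     normalization = "log-quantile",
                     covariates = c("age", "sex", "crp", "sjc"),
                     expression_state = "raw",
                     output_dir = "riskqtl-output")
    for (nm in names(defaults))
        if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    needPaths <- c("genotypes", "expression", "probe_annotation",
                   "index_snps")
    miss <- needPaths[!vapply(needPaths, function(f)
        !is.null(cfg[[f]]), logical(1))]
    if (length(miss))
        stop("config lacks input path(s): ", paste(miss, collapse = ", "))
    if (is.null(cfg$seed))
        stop("config must set a seed: the permutation stage is stochastic")
    checkRange <- function(nm, lo, hi) {
        v <- cfg[[nm]]
        if (!is.numeric(v) || any(v < lo) || any(v > hi))
            stop("config field '", nm, "' outside [", lo, ", ", hi, "]")
    }
    checkRange("min_call_rate", 0, 1); checkRange("min_maf", 0, 0.5)
    checkRange("min_info", 0, 1); checkRange("r2_min", 0, 1)
    checkRange("alphas", 0, 1)
    cfg$permutations <- as.integer(cfg$permutations)
    cfg$seed <- as.integer(cfg$seed)
    cfg
}

.stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
        stop("pipeline stage '", name, "' failed: ",
             conditionMessage(e), call. = FALSE))
}

.provenance <- function(dir, stage, inputs, cfg) {
    rec <- list(stage = stage,
                inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
                seed = cfg$seed,
                package_version = as.character(
                    utils::packageVersion("riskQTL")),
                r_version = paste(R.version$major, R.version$minor,
                                  sep = "."))
    jsonlite::write_json(rec, file.path(dir,
                                        paste0(stage, ".provenance.json")),
                         auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full eQTL mapping pipeline
#'
#' Executes QC, normalization (plus optional batch correction when the
#' metadata carry a \code{batch} column), LD-block expansion, cis and
#' trans association scans, min-P permutation thresholds for each scan
#' family, BH comparison, covariate robustness of the experiment-wide
#' significant cis eQTLs, and the summary tables.  Every stage writes its
#' artifact and a JSON provenance record into \code{config$output_dir};
#' a failing stage halts with its name and cause, retaining earlier
#' artifacts.
#'
#' @param config a list from [readPipelineConfig()] (or of the same
#'   shape).
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config) {
    dir <- config$output_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    inputs <- unlist(config[c("genotypes", "expression",
                              "probe_annotation", "index_snps",
                              "metadata")])

    geno <- .stage("read-genotypes", function()
        readGenotypes(config$genotypes))
    expr <- .stage("read-expression", function()
        readExpression(config$expression, config$probe_annotation,
                       state = config$expression_state))
    meta <- if (!is.null(config$metadata))
        .stage("read-metadata", function()
            readSampleMetadata(config$metadata)) else NULL

    qc <- .stage("qc", function()
        applyGenotypeFilters(geno, minCallRate = config$min_call_rate,
                             minSampleCallRate = config$min_sample_call_rate,
                             minMAF = config$min_maf,
                             minINFO = config$min_info))
    geno <- qc$genotypes
    .writeTsv(data.frame(rule = c(names(qc$report@samplesRemoved),
                                  names(qc$report@variantsRemoved),
                                  "survivors"),
                         axis = c(rep("samples",
                                      length(qc$report@samplesRemoved)),
                                  rep("variants",
                                      length(qc$report@variantsRemoved)),
                                  "variants"),
                         count = c(qc$report@samplesRemoved,
                                   qc$report@variantsRemoved,
                                   qc$report@nVariantsOut)),
              file.path(dir, "qc_report.tsv"))
    .provenance(dir, "qc", inputs, config)

    expr <- .stage("normalize", function() {
        if (normState(expr) == "raw" && config$normalization != "none")
            normalizeExpression(expr, method = config$normalization)
        else expr
    })
    if (!is.null(meta) && "batch" %in% colnames(meta)) {
        expr <- .stage("batch-correct", function() {
            b <- meta$batch[match(colnames(expr), meta$sample_id)]
            if (length(unique(b[!is.na(b)])) > 1L)
                regressOutBatch(expr, b) else expr
        })
    }
    .writeTsv(cbind(probe_id = rowData(expr)$probe_id,
                    .fmtMat(exprValues(expr))),
              file.path(dir, "expression_prepared.tsv"))
    .provenance(dir, "normalize", inputs, config)

    blocks <- .stage("map-loci", function() {
        idx <- readIndexSnps(config$index_snps)
        buildLDBlocks(idx, geno, r2Min = config$r2_min,
                      searchWindowBp = config$search_window_bp)
    })
    .writeTsv(ldBlocks(blocks), file.path(dir, "ld_blocks.tsv"))
    .writeTsv(ldMembers(blocks), file.path(dir, "ld_members.tsv"))
    writeBlocksBed(blocks, file.path(dir, "ld_blocks.bed"))
    assignments <- .stage("classify", function()
        classifyProbes(blocks, expr, windowBp = config$window_bp))
    .writeTsv(assignments, file.path(dir, "assignments.tsv"))
    .provenance(dir, "map-loci", inputs, config)

    summaries <- list()
    for (mode in c("cis", "trans")) {
        res <- .stage(paste0("scan-", mode), function()
            scanAssociations(geno, expr, blocks, assignments, mode = mode))
        if (!nrow(res)) next
        null <- .stage(paste0("permute-", mode), function()
            permuteScan(geno, expr, blocks, assignments,
                        R = config$permutations, seed = config$seed,
                        mode = mode))
        thr <- deriveThresholds(null, config$alphas)
        res$p_adjusted_perm <- empiricalAdjustedP(res$p_nominal, null)
        res$p_adjusted_bh <- bhAdjust(res$p_nominal)
        res$significant <- res$p_nominal <= thr[[1L]]
        .writeTsv(res, file.path(dir, paste0(mode, "_results.tsv")))
        .writeTsv(data.frame(min_p = .fmtNum(minP(null))),
                  file.path(dir, paste0(mode, "_perm_null.tsv")))
        jsonlite::write_json(
            list(mode = mode, R = null@R, n_tests = null@nTests,
                 seed = null@seed,
                 thresholds = as.list(thr)),
            file.path(dir, paste0(mode, "_thresholds.json")),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
        .writeTsv(leadPerGene(res, thr[[1L]]),
                  file.path(dir, paste0(mode, "_lead_table.tsv")))
        .writeTsv(manhattanTable(res),
                  file.path(dir, paste0(mode, "_manhattan.tsv")))
        .provenance(dir, paste0("scan-", mode), inputs, config)
        summaries[[mode]] <- list(results = res, thresholds = thr)
    }

    if (!is.null(meta) && "cis" %in% names(summaries) &&
        length(config$covariates)) {
        cis <- summaries$cis$results
        sig <- cis[cis$significant, , drop = FALSE]
        if (nrow(sig)) {
            rob <- .stage("covars", function()
                robustnessSweep(sig, geno, expr, meta,
                                covariates = config$covariates))
            .writeTsv(rob, file.path(dir, "covariate_robustness.tsv"))
            .provenance(dir, "covars", inputs, config)
        }
    }
    invisible(dir)
}
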