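# Readers and writers for the pipeline's plain-text interchange formats:
# dosage VCF/TSV, expression TSV with probe annotation, index-SNP lists,
# sample metadata and YAML pipeline configuration.

#' Read a genotype dosage matrix
#'
#' Accepts either a VCF 4.x file with per-sample \code{DS} (dosage) and/or
#' \code{GP} (genotype posterior) FORMAT fields, or a TSV dosage matrix
#' whose leading columns are \code{rsid}, \code{chrom}, \code{pos} (and
#' optionally \code{ref}, \code{alt}) followed by one column per sample.
#' Dosages are taken from \code{DS} when present, derived from posteriors
#' as \code{P(het) + 2 P(hom-alt)} when only \code{GP} is present, and
#' counted from hard \code{GT} calls otherwise.  Values outside [0, 2] are
#' clamped with a warning reporting the count; missing calls become
#' \code{NA}.
#'
#' @param path file path; VCF is detected by extension or the
#'   \code{##fileformat} header line.
#' @return a [GenotypeExperiment-class].
#' @export
readGenotypes <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    isVcf <- grepl("\\.vcf(\\.gz)?$", path) ||
        startsWith(readLines(path, n = 1L), "##fileformat")
    if (isVcf) .readGenotypesVcf(path) else .readGenotypesTsv(path)
}

.clampDosage <- function(d) {
    bad <- sum(d < 0 | d > 2, na.rm = TRUE)
    if (bad > 0) {
        warning(bad, " dosage value(s) outside [0, 2] clamped")
        d[!is.na(d) & d < 0] <- 0
        d[!is.na(d) & d > 2] <- 2
    }
    d
}

.readGenotypesVcf <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix)))  # single-variant files collapse to a vector
        fix <- t(fix)
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    variants <- data.frame(rsid = fix$ID, chrom = fix$CHROM,
                           pos = as.numeric(fix$POS), ref = fix$REF,
                           alt = fix$ALT, stringsAsFactors = FALSE)
    fmt <- unlist(strsplit(vcf@gt[1L, "FORMAT"], ":", fixed = TRUE))
    posteriors <- NULL
    if ("GP" %in% fmt) {
        gp <- vcfR::extract.gt(vcf, element = "GP")
        split3 <- function(k) {
            m <- apply(gp, c(1L, 2L), function(s)
                if (is.na(s)) NA_real_
                else as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]][k]))
            m
        }
        posteriors <- list(gpAA = split3(1L), gpAB = split3(2L),
                           gpBB = split3(3L))
    }
    if ("DS" %in% fmt) {
        ds <- vcfR::extract.gt(vcf, element = "DS")
        dosage <- matrix(suppressWarnings(as.numeric(ds)),
                         nrow(ds), ncol(ds), dimnames = dimnames(ds))
    } else if (!is.null(posteriors)) {
        dosage <- posteriors$gpAB + 2 * posteriors$gpBB
    } else if ("GT" %in% fmt) {
        gt <- vcfR::extract.gt(vcf, element = "GT")
        dosage <- matrix(vapply(gt, function(s) {
            if (is.na(s)) return(NA_real_)
            sum(as.integer(strsplit(s, "[/|]")[[1L]]))
        }, numeric(1)), nrow(gt), ncol(gt), dimnames = dimnames(gt))
    } else {
        stop("VCF carries none of DS, GP or GT FORMAT fields")
    }
    rownames(dosage) <- variants$rsid
    GenotypeExperiment(.clampDosage(dosage), variants,
                       posteriors = posteriors)
}

.readGenotypesTsv <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    need <- c("rsid", "chrom", "pos")
    if (!all(need %in% colnames(tab)))
        stop("TSV dosage matrix must start with columns rsid, chrom, pos")
    metaCols <- intersect(c("rsid", "chrom", "pos", "ref", "alt"),
                          colnames(tab))
    sampleCols <- setdiff(colnames(tab), metaCols)
    if (!length(sampleCols))
        stop("no sample columns found in ", path)
    d <- as.matrix(tab[, sampleCols, drop = FALSE])
    if (is.character(d)) {
        num <- suppressWarnings(matrix(as.numeric(d), nrow(d), ncol(d)))
        bad <- which(is.na(num) & !is.na(d) & d != "NA", arr.ind = TRUE)
        if (nrow(bad))
            stop("malformed dosage at data line ", bad[1L, 1L],
                 ", sample column '", sampleCols[bad[1L, 2L]], "'")
        d <- num
    }
    storage.mode(d) <- "double"
    dimnames(d) <- list(tab$rsid, sampleCols)
    variants <- tab[, metaCols, drop = FALSE]
    variants$chrom <- as.character(variants$chrom)
    GenotypeExperiment(.clampDosage(d), variants)
}

#' Read an expression matrix with probe annotation
#'
#' The expression TSV may be oriented probes x samples (first column =
#' probe ids) or samples x probes; the orientation is auto-detected by
#' matching ids against the annotation's \code{probe_id} column and the
#' matrix is returned probes x samples either way.  Probes without
#' annotation are retained in the matrix but carry \code{NA} coordinates,
#' which excludes them from cis/trans classification.
#'
#' @param path expression TSV path.
#' @param annotationPath probe annotation TSV with columns
#'   \code{probe_id}, \code{gene_symbol}, \code{chrom}, \code{start_pos}.
#' @param state normalization state of the stored values (default
#'   \code{"raw"}).
#' @return an [ExpressionExperiment-class].
#' @export
readExpression <- function(path, annotationPath,
                           state = c("raw", "normalized",
                                     "batch_corrected")) {
    state <- match.arg(state)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    ann <- utils::read.delim(annotationPath, check.names = FALSE,
                             stringsAsFactors = FALSE)
    need <- c("probe_id", "gene_symbol", "chrom", "start_pos")
    if (!all(need %in% colnames(ann)))
        stop("probe annotation must carry columns: ",
             paste(need, collapse = ", "))
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    headerHits <- mean(colnames(m) %in% ann$probe_id)
    firstColHits <- mean(ids %in% ann$probe_id)
    if (headerHits > firstColHits)
        m <- t(m)  # samples x probes on disk
    dup <- rownames(m)[duplicated(rownames(m))]
    if (length(dup))
        stop("duplicate probe ids: ", paste(unique(dup), collapse = ", "))
    idx <- match(rownames(m), ann$probe_id)
    if (all(is.na(idx)))
        stop("no probe in ", path, " resolvable against the annotation")
    probes <- data.frame(probe_id = rownames(m),
                         gene_symbol = ann$gene_symbol[idx],
                         chrom = as.character(ann$chrom[idx]),
                         start_pos = ann$start_pos[idx],
                         stringsAsFactors = FALSE)
    nUnann <- sum(is.na(idx))
    if (nUnann > 0)
        message(nUnann, " probe(s) without annotation retained but ",
                "excluded from cis/trans classification")
    ExpressionExperiment(m, probes, state = state)
}

#' Read an index-SNP list
#'
#' @param path TSV with columns \code{rsid}, \code{chrom}, \code{pos} and
#'   optionally \code{locus_label}.
#' @return data.frame of index SNPs.
#' @export
readIndexSnps <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("rsid", "chrom", "pos")
    if (!all(need %in% colnames(tab)))
        stop("index SNP list must carry columns: ",
             paste(need, collapse = ", "))
    tab$chrom <- as.character(tab$chrom)
    tab
}

#' Read sample metadata
#'
#' @param path TSV with a \code{sample_id} column plus clinical columns.
#' @return data.frame of sample metadata.
#' @export
readSampleMetadata <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(tab))
        stop("metadata must carry a sample_id column")
    tab
}

#' Export LD blocks as BED
#'
#' Block spans are converted from the package's 1-based inclusive
#' coordinates to BED's 0-based half-open convention
#' (\code{start - 1}, \code{end}).
#'
#' @param blocks an [LDBlockSet-class].
#' @param path output BED path.
#' @return invisibly, the path.
#' @export
writeBlocksBed <- function(blocks, path) {
    bl <- ldBlocks(blocks)
    bed <- data.frame(chrom = bl$chrom, start = bl$span_start - 1L,
                      end = bl$span_end, name = bl$index_rsid)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
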