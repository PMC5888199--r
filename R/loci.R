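# Risk-locus machinery: r-squared proxy expansion of index SNPs into LD
# blocks and window-based cis/trans classification of expression probes.

#' Composite LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of additive dosages over complete pairs
#' (the composite-LD convention, applicable to imputed dosages where
#' haplotype phase is unavailable).  Symmetric and invariant to allele
#' relabeling at either site.
#'
#' @param dosagesA,dosagesB numeric vectors of equal length in [0, 2];
#'   \code{NA} allowed, at least 3 complete pairs required.
#' @return r-squared in [0, 1].
#' @examples
#' computeLDr2(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0))  # 1
#' @export
computeLDr2 <- function(dosagesA, dosagesB) {
    if (length(dosagesA) != length(dosagesB))
        stop("dosage vectors differ in length")
    ok <- !is.na(dosagesA) & !is.na(dosagesB)
    if (sum(ok) < 3L)
        stop("fewer than 3 complete pairs")
    a <- dosagesA[ok]; b <- dosagesB[ok]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("r2 undefined for a monomorphic variant")
    stats::cor(a, b)^2
}

#' Expand index SNPs into LD blocks of r-squared proxies
#'
#' For each index SNP present in the genotype matrix, every variant on the
#' same chromosome within \code{searchWindowBp} whose dosage r-squared
#' with the index is at least \code{r2Min} (inclusive: r-squared exactly
#' at the threshold is a proxy) becomes a block member; the index SNP is
#' always a member with r-squared 1, so a block of size one is valid.  The
#' block span is the interval covering all member positions.  Index SNPs
#' absent from the genotypes are recorded as skipped.
#'
#' @param indexSnps data.frame with columns \code{rsid}, \code{chrom},
#'   \code{pos} and optionally \code{locus_label}.
#' @param geno a [GenotypeExperiment-class].
#' @param r2Min proxy threshold (default 0.8).
#' @param searchWindowBp half-width of the proxy search window around the
#'   index SNP (default 1 Mb).
#' @return an [LDBlockSet-class].
#' @export
buildLDBlocks <- function(indexSnps, geno, r2Min = 0.8,
                          searchWindowBp = 1e6) {
    stopifnot(is(geno, "GenotypeExperiment"),
              all(c("rsid", "chrom", "pos") %in% colnames(indexSnps)))
    if (anyDuplicated(indexSnps$rsid))
        stop("index SNP rsids must be unique")
    if (!"locus_label" %in% colnames(indexSnps))
        indexSnps$locus_label <- indexSnps$rsid
    vann <- as.data.frame(rowData(geno))
    d <- dosages(geno)
    blocks <- list(); members <- list(); skipped <- character(0)
    for (i in seq_len(nrow(indexSnps))) {
        idx <- match(indexSnps$rsid[i], vann$rsid)
        if (is.na(idx)) {
            skipped <- c(skipped, indexSnps$rsid[i])
            next
        }
        cand <- which(as.character(vann$chrom) ==
                          as.character(vann$chrom[idx]) &
                      abs(vann$pos - vann$pos[idx]) <= searchWindowBp)
        di <- d[idx, ]
        r2 <- vapply(cand, function(j) {
            if (j == idx) return(1)
            ok <- !is.na(di) & !is.na(d[j, ])
            if (sum(ok) < 3L || stats::sd(d[j, ok]) == 0 ||
                stats::sd(di[ok]) == 0) return(NA_real_)
            stats::cor(di[ok], d[j, ok])^2
        }, numeric(1))
        keep <- !is.na(r2) & r2 >= r2Min
        keep[cand == idx] <- TRUE
        mem <- data.frame(index_rsid = indexSnps$rsid[i],
                          rsid = vann$rsid[cand[keep]],
                          chrom = as.character(vann$chrom[cand[keep]]),
                          pos = vann$pos[cand[keep]],
                          r2 = r2[keep], stringsAsFactors = FALSE)
        mem <- mem[order(mem$pos, mem$rsid), ]
        members[[length(members) + 1L]] <- mem
        blocks[[length(blocks) + 1L]] <- data.frame(
            index_rsid = indexSnps$rsid[i],
            chrom = as.character(vann$chrom[idx]),
            index_pos = vann$pos[idx],
            locus_label = indexSnps$locus_label[i],
            span_start = min(mem$pos), span_end = max(mem$pos),
            n_members = nrow(mem), stringsAsFactors = FALSE)
    }
    if (length(skipped))
        message("index SNP(s) absent from genotypes, skipped: ",
                paste(skipped, collapse = ", "))
    new("LDBlockSet",
        blocks = if (length(blocks)) do.call(rbind, blocks) else
            data.frame(index_rsid = character(0), chrom = character(0),
                       index_pos = numeric(0), locus_label = character(0),
                       span_start = numeric(0), span_end = numeric(0),
                       n_members = integer(0)),
        members = if (length(members)) do.call(rbind, members) else
            data.frame(index_rsid = character(0), rsid = character(0),
                       chrom = character(0), pos = numeric(0),
                       r2 = numeric(0)),
        r2Min = r2Min, skipped = skipped)
}

#' Classify probes as cis or trans relative to LD blocks
#'
#' A probe's distance to a block is 0 if its start site lies inside the
#' block span, otherwise the distance to the nearer span edge.  The probe
#' is cis to the block iff it is on the same chromosome and the distance
#' is at most \code{windowBp} ("within 4 Mb" read as inclusive);
#' everything else -- including any probe on another chromosome -- is
#' trans.  Probes without genomic coordinates are excluded with a message.
#'
#' @param blocks an [LDBlockSet-class].
#' @param probes a data.frame/DataFrame with \code{probe_id},
#'   \code{chrom}, \code{start_pos} (and optionally \code{gene_symbol}),
#'   or an [ExpressionExperiment-class] whose rowData carries them.
#' @param windowBp the cis window (default 4,000,000 bp).
#' @return data.frame with one row per (block, probe): \code{probe_id},
#'   \code{gene_symbol}, \code{index_rsid}, \code{locus_label},
#'   \code{class} ("cis"/"trans") and \code{distance_bp}.
#' @export
classifyProbes <- function(blocks, probes, windowBp = 4e6) {
    stopifnot(is(blocks, "LDBlockSet"))
    if (is(probes, "ExpressionExperiment"))
        probes <- as.data.frame(rowData(probes))
    probes <- as.data.frame(probes)
    if (!"gene_symbol" %in% colnames(probes))
        probes$gene_symbol <- NA_character_
    unplaced <- is.na(probes$chrom) | is.na(probes$start_pos)
    if (any(unplaced))
        message(sum(unplaced), " probe(s) without coordinates excluded ",
                "from cis/trans classification")
    probes <- probes[!unplaced, , drop = FALSE]
    bl <- ldBlocks(blocks)
    out <- vector("list", nrow(bl))
    for (i in seq_len(nrow(bl))) {
        sameChrom <- as.character(probes$chrom) == as.character(bl$chrom[i])
        inside <- probes$start_pos >= bl$span_start[i] &
                  probes$start_pos <= bl$span_end[i]
        dist <- pmin(abs(probes$start_pos - bl$span_start[i]),
                     abs(probes$start_pos - bl$span_end[i]))
        dist[inside] <- 0
        cis <- sameChrom & dist <= windowBp
        out[[i]] <- data.frame(
            probe_id = probes$probe_id,
            gene_symbol = probes$gene_symbol,
            index_rsid = bl$index_rsid[i],
            locus_label = bl$locus_label[i],
            class = ifelse(cis, "cis", "trans"),
            distance_bp = dist,
            stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}
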