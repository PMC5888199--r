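# riskQTL

Cell-type eQTL mapping at disease risk loci with permutation-based
family-wise error control.

## The problem

Disease-genetics cohorts often combine genome-wide genotypes with
expression profiles of purified cell populations (for example CD4+ T or
CD19+ B lymphocytes from early-arthritis patients).  A published list of
lead risk variants defines a small set of loci of interest; the question
is which of those risk loci act as *expression quantitative trait loci*
(eQTLs) in each cell type — i.e. whose alleles shift the expression of
nearby (cis) or distant (trans) genes.  riskQTL implements that analysis
end to end for analysts working with dosage-level genotype data and
probe-level expression matrices:

* post-imputation genotype QC (call rate < 0.98, MAF < 0.01, INFO < 0.8
  exclusions; HLA-region and external quality blacklists);
* expression normalization (`log2(x+1)` + quantile normalization, or
  rank-based inverse-normal scores), per-probe linear-model batch
  correction, and PCA diagnostics;
* expansion of each index SNP into its LD block — all variants with
  dosage r² ≥ 0.8 against the index — and classification of every probe
  as cis (start site within 4 Mb of the block span, same chromosome) or
  trans;
* a per SNP–probe linear-model scan, `y = β₀ + β₁·dosage + ε`, with
  Pearson R², two-sided t-based nominal P on n−2 df, and Spearman ρ
  reported alongside;
* experiment-wide significance by the **min-P permutation procedure**:
  each replicate permutes the genotype↔expression sample linkage once for
  the whole test family, rescans, and records the minimum nominal P; the
  α-level threshold is the ⌊α(R+1)⌋-th smallest replicate minimum, which
  controls the family-wise error rate exactly under the null while
  honouring the LD and co-expression dependence that Šidák/Bonferroni
  ignore.  Benjamini–Hochberg adjustment is computed for comparison;
* covariate robustness: one-at-a-time refits with clinical covariates
  (age, sex, CRP, swollen joint count, activation surrogates),
  SNP × covariate interaction tests, and diagnosis-stratified rescans.

A synthetic cohort generator (`simConfig`, `simulateGenotypes`,
`simulateExpression`) produces genotypes with Markov-copying haplotype LD,
expression with planted additive cis effects, batch/covariate structure
and Table-1-style clinical metadata, plus a ground-truth ledger — the
basis for the calibration and parameter-recovery studies in the test
suite.

## Worked example

Simulate a 250-sample cohort with two risk loci (one carrying a planted
cis effect of 0.5 expression units per allele), run QC, expand LD blocks,
scan, and derive permutation thresholds:

```r
library(riskQTL)

cfg  <- simConfig(nSamples = 250, nLoci = 2, snpsPerLocus = 20,
                  probesPerLocus = 10, ldDecay = 0.95,
                  effectSizes = c(0.5, 0), seed = 20)
geno <- simulateGenotypes(cfg)
sim  <- simulateExpression(geno, cfg)

qc     <- applyGenotypeFilters(geno)
vann   <- as.data.frame(SummarizedExperiment::rowData(qc$genotypes))
index  <- data.frame(rsid = c("rs0001010", "rs0002010"),
                     chrom = c("1", "2"),
                     pos = vann$pos[vann$rsid %in% c("rs0001010", "rs0002010")],
                     locus_label = c("1q21", "2p15"))
blocks <- buildLDBlocks(index, qc$genotypes, r2Min = 0.8)
blocks
#> LDBlockSet: 2 blocks, 3 member variants (r2 >= 0.8 )

asg  <- classifyProbes(blocks, sim$expr)
res  <- scanAssociations(qc$genotypes, sim$expr, blocks, asg, mode = "cis")
null <- permuteScan(qc$genotypes, sim$expr, blocks, asg, R = 1000, seed = 42)
(thr <- deriveThresholds(null))
#>    0.05     0.1
#> 0.00181 0.00423

head(leadPerGene(res, thr[["0.05"]]), 3)
#>   gene_symbol     probe_id lead_rsid locus_label   maf p_nominal r2_with_index n_significant
#> 1     GENE1.1 ILMN_0000101 rs0001010        1q21 0.224  7.74e-06         1.000             1
#> 2     GENE1.3 ILMN_0000103 rs0001010        1q21 0.224  2.43e-02         1.000             0
#> 3     GENE2.1 ILMN_0000201 rs0002011        2p15 0.260  1.37e-01         0.841             0
```

The planted eQTL (`rs0001010` → `ILMN_0000101`) is the only pair below
the α = 5% experiment-wide threshold of 0.00181: its nominal P of
7.7 × 10⁻⁶ survives, while the strongest null-locus pair (P = 0.137) does
not.  The threshold itself is far looser than a Bonferroni cut at
0.05/30 ≈ 0.0017 would suggest for independent tests — the permutation
null has absorbed the r² ≈ 0.84–1.0 dependence among block members.
Covariate adjustment leaves the detected slope essentially untouched:

```r
sig <- res[res$p_nominal <= thr[["0.05"]], ]
robustnessSweep(sig[1, ], qc$genotypes, sim$expr, sim$meta)[,
    c("covariate", "slope_base", "slope_adjusted", "delta", "flag")]
#>   covariate slope_base slope_adjusted     delta      flag
#> 1       age      0.489          0.486 -0.002334 unchanged
#> 2       sex      0.489          0.493  0.004147 unchanged
#> 3       crp      0.489          0.488 -0.000213 unchanged
#> 4       sjc      0.489          0.493  0.004787 unchanged
```

`runPipeline(readPipelineConfig("config.yaml"))` drives the same stages
from files (dosage VCF/TSV, expression TSV, probe annotation, index-SNP
list, metadata), writing per-stage TSV artifacts, permutation-null
summaries, lead tables, Manhattan-plot tables and JSON provenance records
into the configured output directory.

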