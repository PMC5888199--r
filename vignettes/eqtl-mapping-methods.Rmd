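---
title: "Methods: cell-type eQTL mapping at risk loci with permutation-based FWER control"
author: "riskQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type eQTL mapping at risk loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

riskQTL maps expression quantitative trait loci (eQTLs) in purified immune
cell populations at a predefined set of disease risk loci, rather than
genome-wide.  The design targets the situation of a disease-genetics cohort
(for example, early arthritis patients with genotypes and cell-sorted
microarray expression): a published list of lead risk variants defines the
loci of interest, each lead variant is expanded into the set of its
linkage-disequilibrium proxies, and every proxy is tested for association
with every expression probe near (cis) or far from (trans) the resulting LD
block.  Because the number of tests is in the hundreds to thousands and the
tests are strongly dependent -- proxies within a block are correlated by
construction, and neighbouring probes are co-expressed -- multiplicity is
controlled by the minimum-P permutation procedure, which calibrates the
family-wise error rate (FWER) against the empirical dependence structure
instead of assuming independence.

The pipeline stages, each an exported function:

1. **Genotype QC** (`applyGenotypeFilters`): samples and variants with call
   rate below 0.98 are excluded, then variants with minor allele frequency
   (MAF) below 0.01, imputation INFO score below 0.8, positions inside a
   region blacklist (by default the extended HLA interval chr6:25-35 Mb),
   or membership in an externally supplied quality blacklist.  All
   exclusions are strict inequalities -- a variant sitting exactly on a
   threshold survives -- and each variant is attributed to the *first* rule
   it fails, so the `QCReport` counts always sum to the input count.
2. **Expression preparation** (`normalizeExpression`, `regressOutBatch`,
   `pcaCheck`, `excludeProbes`): a variance-stabilizing `log2(x+1)`
   transform followed by quantile normalization across samples; per-probe
   linear-model batch correction; PCA diagnostics confirming that batch
   structure has been removed; removal of probes flagged for
   cross-hybridization.
3. **LD blocks** (`buildLDBlocks`): each index SNP is expanded to all
   variants within a search window whose dosage r^2 with it is >= 0.8
   (inclusive), and the block span is the interval covering the members.
4. **Cis/trans classification** (`classifyProbes`): a probe is *cis* to a
   block iff it is on the same chromosome and its start site lies within
   4 Mb of the block span (distance 0 inside the span, else distance to
   the nearer edge, boundary inclusive); everything else is *trans*.
5. **Association scan** (`scanAssociations`, `fitSnpProbe`): per SNP-probe
   pair, ordinary least squares of expression on additive allele dosage.
6. **Experiment-wide significance** (`permuteScan`, `deriveThresholds`,
   `empiricalAdjustedP`): the min-P permutation null, with
   Benjamini-Hochberg adjustment (`bhAdjust`) reported for comparison.
7. **Covariate robustness** (`fitAdjusted`, `robustnessSweep`,
   `stratifiedScan`): refits with clinical covariates added one at a time,
   SNP x covariate interaction tests, and diagnosis-stratified rescans.

# The association model

For a dosage vector $g \in [0,2]^n$ and expression vector $y$, the model is

$$y_i = \beta_0 + \beta_1 g_i + \varepsilon_i, \qquad
  \varepsilon_i \sim N(0, \sigma^2),$$

fitted by OLS on complete cases.  The reported $R^2$ equals the squared
Pearson correlation, and the nominal P value is the two-sided t test of
$\beta_1/\mathrm{se}(\beta_1)$ on $n-2$ degrees of freedom -- algebraically
identical to the Pearson correlation test, an identity the test suite
asserts to 1e-10.  Spearman's rho and its (t-approximation) P value are
reported alongside for presentation, but Pearson-based P values drive all
significance decisions; where both appear in the field's tables and
figures, which statistic gated significance is rarely stated, and the
package makes the Pearson choice explicit.  Residual skewness, excess
kurtosis and a Breusch-Pagan-type heteroscedasticity score are attached to
each fit as diagnostics; they flag but never drop results, because no
principled automatic exclusion rule exists for "model assumptions
verified".

Genotype coding is additive only (no dominance term), on dosages rather
than best-guess genotypes: imputed data arrive as expected allele counts,
and the additive linear model is the field's default.

# The min-P permutation procedure

Let $p_{(1)}$ be the minimum nominal P value across all $m$ SNP-probe
tests in a scan family (cis and trans families are kept separate, since
each is reported with its own test count).  For each permutation replicate
$r = 1, \dots, R$:

* draw **one** random permutation of the sample linkage between the
  genotype matrix and the entire expression matrix;
* repeat the full scan and record the minimum nominal P value $q_r$.

The single shared permutation is the load-bearing choice: permuting each
pair independently would destroy the LD among SNPs and the co-expression
among probes, which is exactly the dependence the min-P distribution must
reflect.  What is permuted is the genotype-expression linkage (covariates,
when present, travel with the expression side so the covariate-expression
relationship is preserved).  Under the global null the observed statistic
and the $R$ replicate statistics are exchangeable, so the procedure is
exactly calibrated by construction.

The threshold at level $\alpha$ is the $k$-th smallest $q_r$ with
$k = \lfloor \alpha (R+1) \rfloor$, and a nominal P is experiment-wide
significant iff it is at or below the threshold (inclusive).  The
order-statistic convention (rather than an interpolated quantile) is
conservative and integer-deterministic; it yields rejection probability
exactly $k/(R+1)$ under exchangeability.  `empiricalAdjustedP` gives the
matching single-step adjusted P, $(1 + \#\{q_r \le p\})/(R+1)$, with floor
$1/(R+1)$.  $R \ge 100$ is enforced ($R = 10{,}000$ is the design value
for a production run; the calibration studies below use $R = 199$, which
makes the 5% threshold the 10th order statistic).  Permutation thresholds
under strong dependence are *less* stringent than the Sidak value
$1-(1-\alpha)^{1/m}$, and converge to it when tests are independent; both
behaviours are asserted in the test suite.

# The synthetic cohort generator

No public dataset pairs patient-level genotypes with cell-sorted
expression for this design, so validation rests on a generator
(`simConfig`, `simulateGenotypes`, `simulateExpression`) that reproduces
the statistical structure the analysis assumes, with a ground-truth ledger
for every planted effect.

**Genotypes.** Dosages are sums of two haplotypes.  Along each locus,
haplotype alleles follow a first-order Markov copying chain implemented on
a latent uniform: $u_1 \sim U(0,1)$; $u_j = u_{j-1}$ with probability
`ldDecay`, else a fresh uniform; the allele is $\mathbf{1}(u_j < p_j)$ for
target allele frequency $p_j$.  Copying the latent uniform rather than the
allele preserves each variant's marginal MAF exactly whatever the MAF
spectrum, while the adjacent-haplotype correlation equals `ldDecay` when
neighbours share a MAF, so pairwise dosage r^2 decays geometrically with
marker distance.  This gives tunable r^2-graded proxies -- all the
analysis consumes -- without pretending to model recombination maps or
coalescent history, which is out of scope.  With
`imputationCertainty < 1`, hard calls are softened into genotype posterior
triples (Beta-distributed per-sample certainty; residual mass split in
Hardy-Weinberg proportions) so the INFO filter has something to act on.

**Expression.** Probe $j$ of sample $i$ is
$\mu_j + \sum \beta\, g + b_{batch(i),j} + \gamma^\top c_i +
\varepsilon_{ij}$: a probe baseline, planted additive allelic effects
(the middle SNP of a locus acting on the locus's first probe), optional
per-batch offsets, optional clinical covariate effects (zero by default,
so the null covariate-robustness result is recoverable), and Gaussian
noise that is equicorrelated within a locus's probe set at level
`probeCor` to mimic co-expression.  Values are emitted on the normalized
intensity scale, so planted slopes are defined on the scale the scan
consumes.  Metadata emulate an early-arthritis cohort: age, sex (~70%
female), CRP, ESR, swollen joint count, a three-level diagnosis (RA /
non-RA inflammatory / noninflammatory in roughly 124:113:107 proportions),
batch, and activation surrogate transcripts (CD25, CD69, IFN-gamma).

**What the generator does not emulate** -- and hence what passing tests do
not certify about real data: bead-level microarray artefacts, population
structure and relatedness, realistic recombination, non-Gaussian
expression noise, missingness patterns, and trans-regulatory networks.
Calibration results transfer to real data only insofar as the exchangeable
-sample assumption of the permutation argument holds there.

**Generator defaults** are a cohort of 250 samples (the size of a
realistic cell-sorted subset), five loci of 20 SNPs with copying
probability 0.7, ten probes per locus, unit noise, three batches with no
batch effect, null covariate effects, and no planted eQTLs.  Defaults are
the null configuration; effects are planted explicitly.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| variant/sample call rate | 0.98 | fraction | standard array QC exclusion, strict `<` |
| MAF floor | 0.01 | frequency | rare variants are untestable at cohort scale |
| INFO floor | 0.8 | ratio in [0,1] | standard post-imputation quality bar |
| HLA blacklist | chr6:25-35 Mb | 1-based bp | the region is excluded for cross-hybridization and copy-number confounding; no published coordinates accompany the exclusion, so a conventional extended-MHC interval is the overridable default |
| LD proxy threshold | r^2 >= 0.8 | squared correlation | the field's proxy definition, inclusive |
| proxy search window | 1 Mb | bp | proxy discovery radius; not a published value, configurable |
| cis window | 4 Mb | bp | inclusive ("within"); trans is the strict complement |
| permutation replicates | 10,000 | count | design value; >= 100 enforced |
| alpha levels | 0.05, 0.10 | probability | the two predetermined experiment-wide levels |
| robustness tolerance | 0.1 | relative slope change | operationalizes "made no difference"; qualitative in origin, so configurable |
| CRP left-censoring | "<5" -> 2.5 | g/liter | interval midpoint; the handling is not prescribed anywhere, midpoint is the neutral choice |

# Numerical and design choices

* **LD estimator**: composite r^2 from dosage correlation, not
  haplotype-phase EM -- imputed dosages carry no phase, and the estimator
  choice is not prescribed; the composite convention is documented as a
  deviation from phase-aware r^2.
* **Window anchoring**: the 4-Mb distance is measured from the LD-block
  span edges, not the index SNP, matching "within 4 Mb of these LD
  blocks"; trans classification is genome-wide (other chromosomes are
  trans at any distance).
* **Filter order and attribution**: sample call rate, variant call rate,
  MAF, INFO, region blacklist, quality blacklist; first failing rule wins.
  Variant statistics are computed on the samples surviving the sample
  filter.  Array-platform cluster-separation metrics cannot be computed
  from dosages and enter only as an external quality blacklist.
* **Normalization stand-in**: the bead-array-specific robust spline
  normalization + variance-stabilizing transform pipeline is replaced by
  `log2(x+1)` + quantile normalization (config-switchable to rank-based
  inverse-normal scores, which are robust to heavy tails).  Downstream
  eQTL arithmetic only requires a monotone variance-stabilized matrix, so
  the normalizer dialect is not load-bearing.  Merging of component
  cohorts is a column-aligned concatenation on the common probe ids with
  cohort-of-origin batch labels; the pipeline order is merge, normalize,
  batch-correct.
* **Batch correction** subtracts per-probe batch means and restores the
  grand mean, so post-correction batch means agree to machine precision
  and the per-probe grand mean is preserved to 1e-10; singleton batches
  are excluded from estimation with a warning.
* **Tie-breaks**: lead SNP per probe = smallest P, then smallest position,
  then lexicographic rsid.
* **Degenerate inputs**: monomorphic dosages error; constant expression
  returns R^2 = 0, P = 1, flagged; empty QC survivor sets warn and flag
  rather than silently returning an empty matrix.
* **Coordinates**: 1-based inclusive everywhere internally; BED exports
  convert to 0-based half-open.  Strand is ignored throughout (dosage and
  probe-start logic are strand-free).
* **Determinism**: every stochastic stage takes an explicit integer seed;
  fixture writers print doubles with 17 significant digits so files
  round-trip bit-identically.
* **Permutation unit**: what exactly is permuted is usually left unstated
  in published descriptions; the genotype-expression linkage is the only
  choice consistent with recording "the minimum nominal P across the total
  number of tests in each replicate", since the minimum is only meaningful
  if one replicate preserves the within-family dependence.

# Validation studies and problem sizes

The test suite (`tests/testthat`) validates each stage against independent
oracles: brute-force haplotype forward simulation for the LD generator,
`stats::lm` and explicit closed-form OLS for the association fit,
exhaustive all-pairs thresholding for block membership, Beta(1, m) and
Sidak limits for the independent-test permutation null, the Frisch-Waugh
identity for covariate adjustment, and hand-computed fixtures for QC
accounting, quantile normalization and BH adjustment.

The headline calibration study (`calibrateFWER`, also run by
`scripts/acceptance.R`) simulates 400 independent global-null cohorts of
100 samples, each with one locus of 20 LD-correlated SNPs (copying
probability 0.7) and 10 co-expressed probes (pairwise noise correlation
0.3), i.e. 200 dependent tests per cohort; per cohort, thresholds come
from R = 199 permutation replicates, and the fraction of cohorts with any
nominal P at or below the threshold estimates the FWER at alpha = 5% and
10%.  These sizes keep the full calibration around a minute on one CPU
while leaving the binomial standard error (about 1.1 percentage points at
alpha = 5%) small against the effect sizes of interest.  Companion studies
use one 200-test independent cohort with R = 2,000 (Sidak/Beta limit), 500
replicates of n = 250 for parameter recovery of a planted slope of 0.5 at
MAF 0.3, 100 one-signal cohorts for the BH-versus-permutation stringency
property, and 200 replicates for the covariate-robustness null.

# Known limitations

* Association is marginal OLS: no mixed models, kinship or ancestry
  adjustment, conditional secondary-signal analysis, or colocalization.
* The permutation family requires complete data on the analysed samples;
  samples with missing values in the family are dropped (per-pair
  complete cases would change the test count across replicates).
* Sample call-rate filtering is computed over the variant set present at
  entry, so re-running QC after external variant removal can shift sample
  call rates; filtering is idempotent on complete-data cohorts.
* The trans scan shares the cis machinery and its permutation family, but
  no claims are made about power for trans discovery at these cohort
  sizes.
* Comparisons with external eQTL compendia, and reproduction of any
  specific published eQTL gene list, are out of scope: the latter requires
  patient-level data that are not publicly paired.
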