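---
title: "Inferring trait-transcript-metabolite association chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring trait-transcript-metabolite association chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdbchains)
```

## The inference problem

Sleep-disordered breathing (SDB) is characterized by repeated breathing
reductions during sleep with oxyhemoglobin desaturation. Three standard
overnight measures summarize it: the apnea-hypopnea index (AHI, events per
hour, strongly right-skewed and zero-inflated), and the minimum and average
oxyhemoglobin saturation during sleep (MinO2, AvgO2, percentages bounded
near the high end of [70, 100]). A cross-sectional association between an
SDB trait and the expression of a blood transcript is causally ambiguous:
the trait may alter expression, expression may alter the trait, both, or a
confounder such as body mass index (BMI) may drive both.

`sdbchains` implements a multi-cohort design that partially resolves this
ambiguity with genetic instruments:

1. **Discovery.** In a cohort with cell-type-resolved RNA-seq and
   polysomnography, each transcript's log2 expression is regressed on each
   SDB trait with covariates; permutation-based empirical p-values guard
   against the skewed exposures, and Benjamini-Hochberg FDR < 0.1 within
   each (trait, cell type) family selects transcripts for follow-up.
2. **Instrument construction.** For each selected transcript, a genome-wide
   association study of its (two-stage rank-normalized) expression provides
   summary statistics from which transcript polygenic risk scores (tPRS)
   are built by clumping and thresholding.
3. **Instrument validation.** In an independent cohort with whole-blood
   expression, the three candidate tPRS per transcript are tested against
   measured expression with a kinship-aware mixed model; the best candidate
   is retained only if its p-value beats the Bonferroni bound 0.05/3
   (0.017 after display rounding).
4. **Reverse association.** In a third cohort with genotypes, sleep traits,
   and serum metabolomics - but no RNA-seq - the standardized tPRS is
   tested against the SDB trait in a mixed model with kinship, household,
   and sampling-block random effects. Because the tPRS is a genetic proxy
   for expression, a significant association evidences the transcript
   *upstream* of the trait (the instrumental-variable logic: only the
   instrument-outcome association is needed, not a full Mendelian
   randomization effect estimate).
5. **Metabolite chains.** The tPRS is scanned against named serum
   metabolites (survey-weighted regression, per-transcript FDR < 0.05), and
   a trait-metabolite association (p < 0.05) is required to call a complete
   trait-transcript-metabolite chain. BMI-adjusted and unadjusted analyses
   run as parallel tracks; a trait-metabolite link that is significant
   unadjusted but not after BMI adjustment is flagged (and classified) as
   BMI-driven.

Every decision threshold lives in `chain_thresholds()` and is compared
strictly (`<`).

## The synthetic study and what it emulates

No individual-level cohort data ship with the package. `simulate_study()`
draws three linked cohorts (discovery n = 800 with three cell types:
PBMC, monocytes, T cells; validation n = 1200 with whole blood; target
n = 3000 with metabolites and survey structure) from a single generative
model with one shared variant panel, so that every pipeline stage has
planted ground truth:

* **Genotypes.** A Gaussian copula with AR(1) correlation `rho` (default
  0.6) inside each LD block, independence across blocks, thresholded to
  haplotype alleles at each variant's allele frequency (MAF uniform on
  [0.1, 0.5] by default); a person is the sum of two haplotypes. This was
  chosen over coalescent simulation because it is cheap, seed-stable, and
  its marginal frequencies and implied dosage correlations can be checked
  analytically or by trivial Monte Carlo. Blocks are spaced about 1 Mb
  apart across chromosomes so the +/-250 kb clump window and +/-1 Mb cis
  window act realistically.
* **Relatedness and survey structure.** A configurable fraction of samples
  (default 20%) form full-sibling pairs that share parental transmissions
  block-wise, giving expected kinship 0.25. Siblings share a household,
  some unrelated pairs do too, households nest in sampling block units,
  block units in four strata, and strata determine inverse-probability
  sampling weights - enough structure to exercise the survey estimator and
  the three-component mixed model non-trivially.
* **Traits.** Latent trait scores combine planted transcript paths, a BMI
  path, and noise shared across traits (`trait_cor`, default 0.3, exposed
  as configuration because the real-data trait correlation is only loosely
  characterized). AHI is a floored, shifted lognormal of its latent (sample
  skewness > 1, a point mass at zero); MinO2 and AvgO2 are bounded
  Gaussians on [70, 100]. Higher latent always means worse SDB.
* **Transcripts.** Each transcript has two cis causal variants in a home
  block with alternating-sign weights; the genetic burden is scaled so it
  explains exactly `eqtl_h2` (default 0.3) of the physiological expression
  variance. Scenario paths (trait-to-transcript, transcript-to-trait, BMI
  confounding, complete chain, null) add standardized effects; the
  generator rejects any configuration whose planted variance fractions
  exceed 1. Measured counts are negative binomial (dispersion size 60)
  around the exponentiated latent; two decoy transcripts are generated at
  very low counts so the expression filter has real work to do.
* **Metabolites.** Lognormal, with planted transcript paths for chain
  scenarios and a BMI path for the confounded scenario, then left-censored
  at the limit-of-detection quantile (default 0.2) to create realistic
  missingness. About 10% of metabolites are flagged unidentified and are
  excluded from association scans.
* **Variant metadata.** Imputation quality is uniform on [0.78, 1] and
  missingness uniform on [0, 0.011], so roughly 9% of common variants fail
  each of the target-cohort QC rules (quality >= 0.8,
  missingness <= 0.01). Real imputed panels concentrate quality near 1 for
  common variants; these ranges keep the QC stage active without making
  instrument loss the dominant source of pipeline failure.

What the generator does **not** emulate: real allele-frequency spectra or
LD beyond AR(1) blocks, gene-level count distributions from RNA-seq
pipelines, batch structure, population stratification (genetic PCs are
computed and adjusted for, but no confounding is planted on them),
platform-specific metabolite chemistry, or informative missingness other
than left-censoring. Passing tests therefore demonstrate the statistical
machinery under a faithful but idealized data-generating process, not
performance on real cohort data.

## Numerical and methodological choices

* **Empirical p-values.** The exposure is residualized on the covariates
  and the residuals permuted (Freedman-Lane style), all transcripts are
  re-tested per permutation, and null p-values are pooled across
  transcripts and permutations: with B = 100 permutations and m
  transcripts the null pool has 100m entries, giving resolution far finer
  than 1/B. The estimator `(1 + #{null <= observed}) / (1 + N)` is valid
  and never returns zero. Pooling across transcripts assumes approximate
  exchangeability of the per-transcript null distributions, which holds
  here because all transcripts are tested under the same design; the
  permutation scheme and pool are recorded in the result's attributes.
* **Joint trait test.** The three SDB traits can be tested jointly by a
  multivariate Wald test (chi-square, df = 3) on the exposure coefficient
  vector; no empirical p-values are attached to the joint test because the
  single-exposure permutation scheme does not apply.
* **Two-stage rank normalization.** Outcomes are residualized on
  covariates, inverse-normal transformed (Blom offset 3/8, average ranks
  for ties), and the covariates are included again in the association
  model. This controls type-I error under heavy skew at a small cost in
  power under normality.
* **Clumping.** Greedy, sorted by ascending p with ties broken by
  (chromosome, position) so the output is independent of input row order;
  r-squared is computed from dosage correlations in the designated LD
  reference (the pruned discovery cohort by default). The three
  p-thresholds (5e-8, 1e-7, 1e-6) share one clump solution, so candidates
  nest. Empty candidates propagate as "tPRS not available" rather than
  errors.
* **Scoring.** The effect allele is ALT by convention; at scoring time each
  model variant is reconciled against the panel's REF/ALT and flipped
  (dosage to 2 - dosage) when stored in the opposite orientation; variants
  matching neither orientation are dropped with a warning. Missing dosages
  are mean-imputed per variant and the final score is standardized in the
  scoring cohort, so downstream effects are per SD of tPRS.
* **Mixed models.** `fit_lmm()` is an average-information REML iteration
  with step-halving, so the restricted log-likelihood is nondecreasing
  along accepted steps; variance components are kept nonnegative by
  projection, with the residual floored just above zero. Covariance
  structures are sparse throughout (kinship entries below 0.022 are
  zeroed, matching a sparse-kinship representation; household and block
  random effects are indicator products), so the Cholesky factorizations
  stay near block-diagonal and a three-component model at n = 3000 fits in
  about a second. Wald t-tests use n - p degrees of freedom, which makes
  the no-structure boundary case agree exactly with OLS. Relatedness
  pruning for the GWAS uses greedy removal above kinship 0.0884
  (third-degree), deterministic with ties broken by sample order.
* **Repeated visits.** When the same individual contributes several
  expression measurements, a per-individual random intercept is estimated
  once from the covariate-only model and all observations are whitened with
  the analytic inverse square root of the compound-symmetric block, making
  the per-variant GWAS a GLS at negligible extra cost.
* **Survey regression.** Weighted least squares with a stratified
  between-cluster linearization variance: cluster-summed weighted scores
  are centered within strata and their covariance forms the sandwich meat.
  The default applies no small-sample cluster factor, which makes the
  estimator collapse *exactly* to HC0 robust OLS standard errors in the
  degenerate design (unit weights, singleton clusters, one stratum) - a
  useful identity for verification; the conventional n_h/(n_h - 1) factor
  is available via `small_sample = "clusters"`. Metabolites are prepared by
  minimum-value imputation (missingness assumed to be below-detection) and
  inverse-normal transformation, with the imputed block tied at the lowest
  ranks; only named metabolites with < 25% missingness are scanned.
* **Filter semantics.** "Expression range" is read as max - min - the only
  reading under which a constant transcript fails - and all four filter
  thresholds retain at equality, because removal is stated for strictly
  exceeding the bounds. Zero replacement before the log2 transform uses
  half the minimum positive value per transcript across the analysis
  sample.
* **Median normalization.** The per-sample scale factor is the sample
  median divided by the geometric mean of all sample medians; the
  geometric-mean reference makes the operation symmetric in samples and
  idempotent.

## Problem sizes used in the shipped checks

The package's own simulations use the documented configuration: discovery
800, validation 1200, target 3000 samples, 200 variants in 20 LD blocks,
eQTL h2 = 0.3, B = 100 permutations; the scenario battery runs 25
replicates per scenario and 20 all-null replicates, and smaller unit
fixtures (tens to hundreds of samples) cover the individual operations.
These sizes were chosen so that every planted effect is comfortably
detectable while a full battery remains a desk-scale computation.

## Known limitations

* The association-chain logic tests instrument-outcome associations only;
  it does not estimate causal effect sizes (no IVW or MR-Egger estimators),
  and cannot distinguish bidirectional from transcript-to-trait patterns
  when both paths are present.
* Validation in whole blood while discovery is cell-type-specific means a
  failed validation may reflect cell-type composition rather than a weak
  instrument; the pipeline reports, but cannot correct, this.
* When the same gene validates in several cell types the chains are kept
  separate; no cross-cell-type reconciliation is attempted.
* Direction concordance between the discovery estimate and the tPRS-trait
  effect is reported and flagged, never enforced - discordant chains remain
  in the output for the analyst to judge.

## A worked run

```{r, eval = FALSE}
spec <- cohort_spec(seed = 42)
run <- run_pipeline(spec, seed = 42, B = 100, bmi_track = TRUE)
rep <- report_run(run)
rep$summary
head(rep$top_table)
cat(rep$dot)
```

`run_pipeline()` writes all stage tables as TSV plus a JSON manifest when
`out_dir` is given; reruns with the same master seed are bit-identical.
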