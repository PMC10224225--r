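---
title: "Methods: multi-omics integration of gut microbiota, inflammation and metabolites with carotid plaque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics integration of gut microbiota, inflammation and metabolites with carotid plaque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutplaque)
```

## The analysis problem

`gutplaque` implements a desk-scale, fully reproducible version of a
multi-omics association analysis common in cardiometabolic microbiome
epidemiology: shotgun-metagenomic species and functional-enzyme
abundances, a serum inflammatory-protein panel (log2 NPX units), and
plasma metabolite intensities are related to a binary carotid-plaque
outcome under covariate adjustment, and then integrated — which species
track a microbially produced metabolite such as imidazole propionate
(ImP), which enzyme categories are enriched among outcome-associated
enzymes, how much of a species–outcome association is attenuated by
inflammation profiles or by the metabolite, and how a weighted
gut-microbiota (GMB) score built from metabolite-associated species
relates to the outcome.

Cohort-scale omics data are access-restricted, so the package ships a
synthetic cohort generator that emulates the statistical structure these
analyses assume, together with a planted ground-truth record. All
statistical machinery is exercised and validated against that generator
and against closed-form oracles; nothing in the package depends on the
original data.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws, from a single seed:

* **Species counts.** Latent per-species log-normal abundances
  (per-species mean ~ N(0, 1.5), log-SD ~ U(0.5, 1.5)) with per-species
  structural-zero fractions drawn U(0, 0.95); per-sample compositions
  are multinomially sampled at a sequencing depth of 50,000. The wide
  sparsity range is deliberate: it produces a realistic rare-species
  tail so that the default prevalence/abundance filter (below) actually
  removes features.
* **Outcome.** A logistic model on the standardized CLR abundances of a
  configurable species set plus covariates: age (N(50, 10) years, effect
  0.5 per SD), a binary serostatus (65% prevalence, effect 0.3), and a
  3-level study site (no effect by default). This is the smallest
  covariate set that exercises continuous, binary and categorical
  adjustment paths. The default planted structure is one harmful species
  at log(1.5) per SD and five protective species at log(0.7), echoing a
  one-pathogen/several-commensals pattern. The intercept is calibrated
  by root search so the expected outcome prevalence is 26.25% (84 cases
  per 320), unless an explicit intercept is supplied. The real outcome
  process in any given cohort is unknown; the logistic generator is a
  testing assumption, not a claim about nature.
* **Target metabolite.** `ImP` = a weighted sum of producer-species
  standardized CLR abundances (default 17 species: 8 positive at +0.30,
  9 negative at −0.25, overlapping the protective outcome species) plus
  Gaussian noise, on a positive baseline of 10 intensity units so the
  CV-based QC rule is meaningful. All other metabolites are
  baseline-plus-noise with **left-censored** missingness: the lowest
  values of each column are set missing, mimicking below-detection-limit
  dropout rather than missingness at random.
* **Functional gene.** A `hutH`-like enzyme abundance driven by three
  carrier species' relative abundances plus noise, among log-normal
  background enzymes.
* **Proteins.** NPX columns as a sparse loading matrix applied to
  (species CLR z-scores, standardized target metabolite) plus unit
  log2-scale noise; by default the first ten markers load on the
  outcome species and the first five on the metabolite, planting the
  mediation structure the attenuation analysis looks for.
* **Care variables.** ART use and viral load distributions chosen so
  suppression summaries resemble a treated cohort (~76% suppressed at
  the stringent cutoff, ~92% at the lenient one).

Not emulated: read-level sequencing, batch/plate effects, LC–MS peak
artifacts, covariate–microbiome confounding beyond the planted terms,
and phylogenetic signal in abundances (trees from `generate_tree()` are
random topologies). Passing recovery tests therefore demonstrates that
the estimators do what they claim under their assumptions — not that
those assumptions hold in any real cohort.

## Transform chain

* **Filtering** (`filter_features()`): keep species with prevalence
  ≥ 20% and mean relative abundance ≥ 1e-5 (0.001%). Exclusion is
  strict (`< 20%` is dropped, exactly 20% is kept). Prevalence counts
  samples with a nonzero value. Filtering happens **before** the CLR
  transform; the alternative order is defensible but this one keeps the
  CLR geometric mean on the analyzed feature set.
* **CLR** (`clr_transform()`): per-sample log-ratios about the
  geometric mean. Zeros are replaced by half the smallest nonzero
  relative abundance in the table — the same half-minimum convention
  used for below-detection metabolites — before taking logs. Rows sum
  to zero within 1e-9 and the transform is scale-invariant per sample.
* **INT** (`int_transform()`): rank-based inverse-normal per column
  with the Blom offset c = 3/8 (the common epidemiology convention),
  average ranks on ties; applied to CLR output it yields the INT-CLR
  abundances the GMB score is built on.
* **QC and imputation** (`qc_filter()`, `impute_half_min()`): proteins
  kept when detected in strictly more than 75% of samples; metabolites
  kept when CV < 30% and missing rate < 20% (boundary values dropped);
  remaining missing values imputed with half the per-feature minimum.

## Differential abundance

Three screens are run and, on strongly planted features, should agree:

* **Per-species covariate-adjusted logistic models**
  (`logistic_screen()`): effect per SD of CLR abundance, Wald 95% CI,
  BH q-values with the false-discovery cutoff at 10%.
* **Two-class LDA effect size** (`lefse_lda_scores()`). The reference
  tool's internals are under-documented, so the package fixes a
  documented variant: Kruskal–Wallis prefilter at 0.05; abundances
  rescaled so the table maximum maps to 1e6; 30 class-stratified
  2/3-subsamples; ridge-regularized two-class LDA (λ = 1e-3 · trace/m)
  per subsample; per-feature effect |(w + Δμ)/2|; score =
  log10(1 + mean effect), signed by the enriched class; a feature
  passes when |score| > 3 strictly. Exact numeric replication of the
  reference tool's scores is not attainable or claimed; order-of-
  magnitude behavior is tested instead.
* **Pairwise log-ratio W statistic** (`ancom_w()`): for every feature
  pair, `ln(x_i/x_j) ~ outcome + covariates`; per-feature BH over its
  m−1 pairwise p-values; W counts adjusted p < 0.05; detection when
  W/(m−1) ≥ 0.6 (also reported at 0.7/0.8/0.9). All pairs share one
  design matrix, so the screen is a single multi-response least-squares
  solve; W is invariant to per-sample rescaling.

## Inflammation profiling and community-level tests

`plsda_fit()` is a deterministic NIPALS PLS1 on the standardized marker
panel against the centered 0/1 outcome — for two classes this is
equivalent to a two-column PLS-DA and simpler. Eight components are
extracted by default and the five most outcome-associated carried
forward, both plain configuration values. Contributor ranking uses
loadings (not weights), with lexicographic tie-breaks. Component scores
feed covariate-adjusted logistic models via `pc_outcome_association()`.
Alpha diversity (Shannon, Simpson, Chao-1 with the bias-corrected form
when no doubletons exist) and distances (Bray–Curtis via vegan;
normalized weighted UniFrac implemented branch-by-branch per its
definition) summarize community structure; `permanova()` wraps
`vegan::adonis2` with a seeded permutation stream and add-one p-values.

## Integration arm

* `correlation_screen()`: all species × metabolite (partial) Spearman
  correlations with one BH adjustment per screen. The metabolite screen
  is unadjusted by default (plain Spearman), with covariates available —
  both modes exist because field practice varies between plain and
  partial correlations here.
* `conditional_selection()`: one joint linear model of the metabolite
  on all screen-significant species plus covariates ("mutual
  adjustment"); species with joint-model p < 0.05 count as
  independently associated — the conventional reading of independence
  in such models — and their betas become score weights.
* `build_gmb_score()`: per-sample weighted sum of INT-CLR abundances,
  standardized to unit SD so outcome models read per SD of the score.
* `ec_enrichment()`: hypergeometric over-representation of enzyme-level
  hits (p < 0.05) within EC level-III categories, BH across categories
  at FDR 10%. The hypergeometric test is the standard enrichment
  default and exactly testable by enumeration; depletion is not tested.
* `attenuation_analysis()`: percent attenuation
  `100(|β_base| − |β_adj|)/|β_base|` on the log-odds scale — symmetric
  for protective and harmful exposures — comparing the base
  covariate-adjusted model with models further adjusted for the top
  PLS-DA components, the metabolite, or both. This is a covariate-
  adjustment comparison, not a formal mediation decomposition.

## Numerical and design choices

* Wald (not profile-likelihood) CIs throughout; symmetric, cheap, and
  standard for forest-plot presentation. Exposures are standardized
  with the analysis sample's SD after transformation.
* Categorical covariates are reference-coded with the most frequent
  level as reference, so designs are deterministic.
* Quasi-separation and non-convergence in logistic fits produce a
  flagged record (`converged = FALSE`), never a crash; penalized fits
  are deliberately avoided to keep the estimator auditable.
* Quartile groups: low = quartile 1, medium = quartiles 2–3, high =
  quartile 4, with boundary ties assigned to the lower group.
* Viral-suppression percentages are rounded half-up to one decimal.
* BH q-values are monotone in p but (contrary to a common intuition)
  the step-up map is not idempotent; only monotonicity is asserted.

## Test problem sizes

The test suite validates calibration and recovery at sizes chosen to be
informative yet desk-scale: null calibration uses 200 replicates of
n = 400 with 300 species under the zero-effect generator (pooled
p-values tested for uniformity, observed FDR at q < 0.10 checked
against 0.15 to allow Monte-Carlo error); W-statistic null behavior
uses 40 replicates of 30 features at n = 200; recovery uses 100 seeds
of n = 400 with 100 species at a fixed moderate structural-zero
fraction of 0.3 so every planted feature is observable, with metabolite
noise set to half the signal SD for the score-recovery scenario. These
sizes are the package's own calibration choices and are fixed in the
acceptance script as well.

## Known limitations

* The LDA effect-size variant and the W-statistic variant are
  documented reimplementations, not bit-compatible clones of the
  reference tools.
* No rarefaction, batch correction, ILR/ALR alternatives, sparse PLS,
  cross-validated component selection, or formal causal mediation.
* The generator's layers are conditionally Gaussian given the species;
  heavy-tailed metabolite distributions and plate effects are out of
  scope.
* Weighted UniFrac requires a user-supplied or simulated rooted tree;
  simulated trees carry no biological signal.
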