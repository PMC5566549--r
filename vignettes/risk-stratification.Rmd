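---
title: "Methods: combined genetic and environmental risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined genetic and environmental risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pcarisk` builds case-control risk stratification models of the form

$$\operatorname{logit} P(\text{case}) = \alpha + \beta_{score} \cdot S + \gamma \cdot PS$$

where $S$ is a risk score and $PS$ the selection propensity.  A score is
always a sum of sample-estimated log odds ratios times predictor values:

* **GRS** $= \sum_j \hat\beta_j g_j$ over risk-allele dosages
  $g_j \in \{0,1,2\}$ (0/1 for the X-linked SNP in an all-male cohort),
  each $\hat\beta_j$ from a propensity-adjusted logistic fit;
* **ERS** $= \sum_k \hat\beta_k x_k$ over category indicators of
  modifiable covariates that pass a lenient screen
  ($p \le 0.20$, propensity-adjusted), each factor releveled so its
  lowest-risk category is the reference;
* **FH**, family history, kept out of the ERS because it is not
  modifiable, and fitted as a separate binary factor.

Sample weights, not published ones, are used deliberately: external
weights may be mis-calibrated for the target population.  The price is
in-sample optimism, which is confronted directly by bootstrap internal
validation rather than by shrinking the coefficients.

The three per-unit effects combine into the multiplicative
relative-risk equation

$$RS = OR_{ERS}^{\,ERS-\overline{ERS}} \times OR_{FH}^{\,FH} \times
       OR_{GRS}^{\,GRS-\overline{GRS}},$$

anchored so that the population-average subject has $RS = 1$ exactly.
Multiplying age-specific population incidence rates by $RS$ (the
standard OR-for-rate-ratio approximation for a rare-ish outcome) turns
relative into absolute risk; `risk_advancement()` reads off how much
earlier an elevated-risk subject reaches the incidence level the
average-risk population only sees at its peak age.

### Assumptions

* Additivity on the log-odds scale within each score (no gene-gene or
  gene-environment interaction terms).
* Selection effects (age structure, centre response, ancestry) are
  adequately summarised by one continuous propensity covariate.
* ORs approximate rate ratios when projecting onto incidence curves.
* NRI and IDI are computed only for nested model pairs; the functions
  refuse non-nested comparisons.

## The synthetic cohort generator

Subject-level data of this kind are confidential, so the package treats
its simulator as a first-class, tested component.  `sim_config()`
defaults encode the study conditions the analysis targets:

| parameter | default | meaning |
|---|---|---|
| `n_cases`, `n_controls` | 818 / 1,006 | retained sample sizes |
| `n_snps` | 56 | susceptibility panel, one SNP on X coded 0/1 |
| `or_range`, `or_skew` | 1.06–1.79, 6 | per-allele OR envelope and skew |
| `fh_prevalence`, `fh_log_or` | 0.0728, log 3.3 | family history |
| `env_effects` | see `default_env_effects()` | diabetes 0.58, weight tertiles 0.94/0.70, BMI 1.03/1.26, alcohol tertiles 1.46/1.19, red meat ≥65 g/day 1.28, plus two near-null diet covariates |
| `baseline_prevalence` | 0.10 | disease probability at the population-average linear predictor |
| `n_ancestry_markers` | 200 | disease-neutral markers for ancestry PCA |
| `ld_pairs` | none | engineered redundant SNP pairs for QC tests |

Generation proceeds by oversampling a source population under the
logistic disease model (the intercept is solved by `uniroot()` so the
population prevalence matches `baseline_prevalence`), then sampling
exactly `n_cases` cases and `n_controls` controls, the latter
frequency-matched to the realised case distribution over 5-year age
bands — mirroring a matched population-based design without modelling
recruitment rosters.  Identical seeds give bit-identical cohorts.

Three generator choices deserve justification:

* **Per-allele effect sizes.**  Only the envelope 1.06–1.79 is given by
  the study conditions.  A uniform draw over that range makes the
  aggregate score far stronger than the regime the analysis targets
  (population mean near 7 points, genetic AUROC in the mid-0.60s),
  because genome-wide significant susceptibility loci cluster near the
  lower end of their OR range.  The default therefore draws
  $\log OR = \log 1.06 + (\log 1.79 - \log 1.06)\,B$ with
  $B \sim \mathrm{Beta}(1, 6)$, which lands the simulated cohorts in
  that regime; `or_skew = 1` restores the uniform draw.
* **Ancestry markers.**  Ancestry principal components belong in the
  propensity model, but in a case-control sample the leading component
  of the susceptibility panel itself aligns with the risk-allele burden
  and would leak genetic signal into the "adjustment".  Real analyses
  compute PCs from genome-wide genotyping; the simulator emulates this
  with 200 additional null markers, and `genotype_pca()` uses them by
  default.
* **LD pairs.**  A flagged pair is drawn from a correlated-allele-copy
  model: two gametes per subject, each a Bernoulli pair with
  correlation $\sqrt{r^2}$, so the dosage correlation squared targets
  the requested $r^2$.  Engineered partners share the first SNP's
  allele frequency (a high-$r^2$ proxy necessarily has a close
  frequency, and equal frequencies keep any target feasible); an
  infeasible user-specified combination is a hard error, not a silent
  approximation.

Environmental covariates are generated independently of one another —
their joint distribution is not part of the stated study conditions —
with marginals (log-normal for intakes, normal for anthropometry)
chosen to give control category frequencies close to the published
ones.  Per-centre covariate shifts and per-centre control sampling
weights are available to induce the selection bias that the propensity
adjustment exists to remove; the parameter-recovery tests use exactly
that hook.

### What the simulator does not emulate

Questionnaire measurement error and recall bias, missing-data patterns
(an optional uniform missingness rate exists for robustness checks
only), realistic genome-wide LD structure beyond the engineered pairs,
age-dependent disease risk (age enters matching and the propensity, not
the generative model), and tumour aggressiveness.  Passing tests
therefore certify the statistical machinery, not robustness to
real-world data pathology.

## Numerical and procedural choices

* **Logistic fits** go through `stats::glm` (IRLS) with convergence
  tightened to `epsilon = 1e-10`.  Aliased columns are reported by
  warning; complete or quasi-complete separation (|coefficient| > 15 or
  SE > 200) is a hard error naming the predictor, because a silently
  divergent coefficient must never be summed into a score.  Wald 95%
  intervals are reported throughout.
* **HWE test**: 1-df $\chi^2$ against expected counts
  $(n\hat p^2, 2n\hat p\hat q, n\hat q^2)$, no continuity correction,
  computed in controls only (cases may deviate through genuine
  association); exclusion threshold $p < 10^{-4}$.  Monomorphic SNPs fit
  their expectation exactly ($p = 1$); the hemizygous X SNP is skipped.
* **LD pruning**: squared Pearson correlation of dosages (composite LD —
  phase is not available in this data model), greedy first-listed-wins,
  so the survivor set is deterministic, all surviving pairs are at or
  below threshold, and every removed SNP names a retained partner above
  it.
* **Dosage coding**: re-orientation to the sample risk allele by the
  allele-count cross-product OR; monomorphic SNPs keep the panel
  orientation with a warning.
* **Deciles**: boundaries from the pooled case+control distribution
  (the stratification displays both groups on one axis); boundary ties
  fall to the lower decile; if heavy ties empty a decile the boundaries
  are recomputed on distinct values with a warning.  The reference
  decile has OR 1 with a degenerate interval by construction.
* **AUROC**: rank-based Mann-Whitney with ties counted one half,
  unweighted by default.  A per-case weighted variant (weights
  proportional to the number of cases in the case's decile) is provided
  because that weighting has been used in this literature, but it does
  not correspond to a uniquely defined standard estimator, so it is
  opt-in.
* **Bootstrap optimism**: refit-on-resample — for each resample, refit,
  take in-resample AUROC minus the refit's AUROC on the original data;
  the mean difference is subtracted from the apparent AUROC.
  Resampling is over subjects jointly (cases and controls together) by
  default, with a stratified option; one-class resamples are redrawn
  with a cap.
* **Missing dosages** are mean-imputed per SNP before PCA and scoring;
  regressions use complete cases.
* **GRS coefficient mode**: single-SNP propensity-adjusted fits by
  default (matching how per-SNP associations are reported for additive
  scores); a joint 56-SNP fit is available via `snp_mode = "joint"`.
  A jointly-fitted score is exactly self-calibrated — refitting the
  outcome on the score reproduces a per-unit coefficient of 1 — which
  the test suite exploits as an invariant.

## Problem sizes used by the checks

The simulation-based checks run at sizes chosen to balance statistical
resolution against a default test run of about a minute: the
qualitative stratification findings are replicated on 50 full-scale
cohorts (818/1,006, 56 SNPs); coefficient coverage uses 200 replicates
at 300/300 with 6 SNPs and two environmental factors; the overfitting
check uses 56 null SNPs at 150/150 with 200 bootstrap resamples.
Reporting-grade bootstrap inference should use `n_boot = 1000`.

## Known limitations

* The optimism bootstrap under-corrects when overfitting is severe
  (tens of free parameters at a few hundred observations): the
  resample-refitted model is tested on the original sample, which
  shares most of its subjects with the resample, so the test
  performance is itself optimistic.  At the deliberately extreme
  56-predictors/300-subjects setting exercised in the test suite the
  corrected AUROC remains visibly above one half; at moderate
  overfitting the correction behaves as expected.  Users validating
  saturated models at small n should prefer cross-validation.
* Per-SNP single fits ignore SNP-SNP non-collapsibility; with many weak
  independent effects the distortion is small, and the joint mode is
  available.
* The propensity is a one-dimensional summary; residual confounding by
  design variables is possible if their effect on selection is not
  captured by the logistic propensity model.
* Scores are developed and evaluated in the same sample.  Internal
  validation corrects optimism in discrimination but is no substitute
  for external validation in an independent cohort.
* The packaged incidence table is synthetic (registry-shaped, not
  registry data); users should supply their own
  `age_low, age_high, rate_per_100k` CSV for substantive projection.
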