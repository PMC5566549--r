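# pcarisk

Risk stratification for prostate cancer from genetic and environmental
scores.

## What this package is for

Prostate cancer risk is driven by age, family history and a polygenic
background of dozens of common susceptibility variants, with a smaller
contribution from modifiable lifestyle factors.  `pcarisk` implements, as
a tested and reusable pipeline, the case-control analysis that combines
these components into one stratification model:

* a **genetic risk score (GRS)** — the per-subject sum of log odds
  ratios times risk-allele dosage over a panel of susceptibility SNPs,
  with the coefficients estimated in the analysis sample itself rather
  than taken from published weights;
* an **environmental risk score (ERS)** — the analogous sum over
  screened modifiable covariates (diabetes, weight, BMI, alcohol, red
  meat, ...), categorised with control-anchored cutoffs;
* **family history (FH)** as a separate non-modifiable factor;
* a selection **propensity score** (age band, education, recruiting
  centre, 3 genotype ancestry components, entered as one continuous
  logit-scale covariate) adjusting every model for differential
  case/control selection.

Around the scores the package provides the supporting machinery a
genetic-epidemiology analysis needs: variant QC (Hardy-Weinberg
filtering at p < 10⁻⁴ in controls, LD pruning at dosage r² > 0.8,
genotype PCA), decile stratification with per-decile odds ratios,
discrimination metrics (Mann-Whitney AUROC, bootstrap optimism
correction, continuous NRI, IDI, an individual/cumulative AUROC
ladder), and projection of the combined relative risk onto age-specific
population incidence rates via the multiplicative equation

```
RS = OR_ERS^(ERS - mean_ERS) * OR_FH^FH * OR_GRS^(GRS - mean_GRS)
```

so that a subject at the population average of both scores with no
family history has RS = 1 exactly.

Because subject-level cohort data of this kind are confidential, the
package ships a first-class **synthetic cohort simulator**
(`sim_config()`, `simulate_panel()`, `simulate_cohort()`) whose defaults
generate the study conditions the analysis was designed for: 818 cases
and 1,006 age-frequency-matched controls, 56 susceptibility SNPs in
Hardy-Weinberg proportions with per-allele odds ratios between 1.06 and
1.79 (one X-linked SNP coded 0/1), family history at ~7% control
prevalence with OR 3.3, and Table-2-style environmental effects.  Every
stage of the pipeline is therefore testable end to end without any data
download.

## Worked example

```r
library(pcarisk)

res <- run_pipeline(sim_config(seed = 7))

res$grs
#> GRS risk score: 56 terms; population mean 8.669
#>   per-unit OR 2.756 (95% CI 2.38 - 3.191 )

res$ladder[, c("variable", "auroc_individual", "auroc_cumulative")]
#>         variable auroc_individual auroc_cumulative
#> 1 family_history            0.586            0.586
#> 2            ers            0.604            0.644
#> 3            grs            0.698            0.741

res$grs_deciles[c(1, 5, 10), c("decile", "or", "or_lower", "or_upper")]
#>    decile    or or_lower or_upper
#> 1       1  1.00    1.000     1.00
#> 5       5  3.29    2.048     5.29
#> 10     10 11.35    6.929    18.60

res$add_grs_to_ers
#> base AUROC 0.604 -> full AUROC 0.719 (improvement 0.116)
#> continuous NRI 0.596 (cases 0.308, controls 0.288); IDI 0.1101
res$add_ers_to_grs
#> base AUROC 0.698 -> full AUROC 0.719 (improvement 0.021)
#> continuous NRI 0.287 (cases 0.161, controls 0.125); IDI 0.0265
```

Reading the output: the genetic score alone discriminates cases from
controls with AUROC 0.70 while the environmental score reaches 0.60;
risk rises nearly monotonically across GRS deciles (decile 10 carries
11-fold the odds of decile 1); and adding the GRS to an
environmental-only model reclassifies far more subjects correctly
(NRI 0.60) than the reverse addition (NRI 0.29) — genetic susceptibility
dominates the modifiable factors, which is the scientific point of the
combined model.

Absolute-risk projection uses the fitted (or published) equation against
an incidence table:

```r
eq <- res$equation
#> RS = 2.72^(ERS-1.13) * 3.77^FH * 2.76^(GRS-8.67)
relative_risk(eq, ers = 1, fh = 1, grs = 9)
#> [1] 4.64109

tab <- read_incidence(system.file("extdata",
        "incidence_spain_synthetic.csv", package = "pcarisk"))
risk_advancement(tab, rs = 3)   # reaches the population peak at...
#>   age_low age_high
#> 5      60       64
```

A subject with three times the average risk reaches, between ages 60 and
64, the incidence level the average-risk population only experiences at
its 70-74 peak.

The methods vignette (`vignettes/risk-stratification.Rmd`) documents the
generative model, every tunable parameter, the numerical choices and the
known limitations.

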