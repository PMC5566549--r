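#' Run the full risk-stratification pipeline on a simulated cohort
#'
#' Chains every stage on data from [simulate_cohort()]: covariate
#' categorisation, risk-allele dosage coding, Hardy-Weinberg and LD QC,
#' genotype PCA, propensity fitting, ERS variable screening, GRS and ERS
#' construction, family-history fit, decile stratification of the GRS,
#' the individual/cumulative AUROC ladder, and the two nested-model
#' comparisons (adding GRS to ERS, and ERS to GRS).  This is the
#' analysis a practitioner would run; it is also the engine of the
#' package's simulation-based checks.
#'
#' @param config a [sim_config()].
#' @param n_boot bootstrap resamples for the model comparisons (0 keeps
#'   the run fast; use 1000 for reporting-grade inference).
#' @param snp_mode per-SNP coefficient mode for the GRS, see
#'   [build_score()].
#' @return list: `panel` (post-QC), `cohort`, `qc` (HWE + LD reports),
#'   `propensity`, `ers_vars`, `grs`, `ers` (score models), `fh_fit`,
#'   `grs_deciles`, `ladder`, `add_grs_to_ers`, `add_ers_to_grs`
#'   (score comparisons), `equation` (fitted [risk_equation()]).
#' @export
run_pipeline <- function(config = sim_config(), n_boot = 0L,
                         snp_mode = c("single", "joint")) {
  snp_mode <- match.arg(snp_mode)
  panel <- simulate_panel(config)
  cohort <- simulate_cohort(panel, config)
  cohort <- categorize_covariates(cohort)
  cohort <- code_dosages(cohort, panel)
  panel <- attr(cohort, "panel")

  hwe <- hwe_filter(cohort, panel)
  if (length(hwe$dropped_hwe)) {
    panel <- panel[!panel$snp_id %in% hwe$dropped_hwe, , drop = FALSE]
    class(panel) <- c("variant_panel", "data.frame")
  }
  pruned <- ld_prune(cohort, panel)
  panel <- pruned$panel
  cohort$genotypes <- cohort$genotypes[, panel$snp_id, drop = FALSE]

  pcs <- genotype_pca(cohort, n_components = 3L)
  prop <- fit_propensity(cohort, pcs)

  candidates <- intersect(
    c("diabetes", "weight_cat", "bmi_cat", "alcohol_cat", "red_meat_cat",
      "vegetables_cat", "fruits_cat"),
    names(cohort$covariates))
  ers_vars <- screen_ers_variables(cohort, candidates, prop$logit)
  if (length(ers_vars) == 0) ers_vars <- candidates  # degenerate fallback

  grs <- build_score(cohort, "grs", prop$logit, snp_mode = snp_mode)
  ers <- build_score(cohort, "ers", prop$logit, ers_vars = ers_vars)
  fh_fit <- adjusted_fit(cohort$status, cohort$covariates$family_history,
                         prop$logit, name = "family_history")

  grs_deciles <- decile_stratify(grs, cohort$status, prop$logit)

  df <- data.frame(status = cohort$status, propensity = prop$logit,
                   grs = grs$scores, ers = ers$scores,
                   family_history = cohort$covariates$family_history)
  ladder <- auroc_ladder(df, c("ers", "family_history", "grs"))
  add_grs_to_ers <- compare_scores(status ~ ers + propensity,
                                   status ~ ers + grs + propensity,
                                   df, n_boot = n_boot)
  add_ers_to_grs <- compare_scores(status ~ grs + propensity,
                                   status ~ grs + ers + propensity,
                                   df, n_boot = n_boot)

  list(panel = panel, cohort = cohort,
       qc = list(hwe = hwe, ld = pruned$report),
       propensity = prop, ers_vars = ers_vars,
       grs = grs, ers = ers, fh_fit = fh_fit,
       grs_deciles = grs_deciles, ladder = ladder,
       add_grs_to_ers = add_grs_to_ers,
       add_ers_to_grs = add_ers_to_grs,
       equation = risk_equation_from_models(ers, grs, fh_fit))
}
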