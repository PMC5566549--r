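expand_2x2 <- function(a, b, c, d) {
  # a: exposed cases, b: unexposed cases, c: exposed controls, d: unexposed
  data.frame(y = rep(c(1, 1, 0, 0), c(a, b, c, d)),
             x = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}

test_that("logistic estimate on a 2x2 table equals the log cross-product", {
  cases <- list(c(30, 10, 20, 40), c(165, 649, 73, 930), c(12, 55, 9, 101))
  for (cc in cases) {
    df <- expand_2x2(cc[1], cc[2], cc[3], cc[4])
    fit <- fit_logistic(df$y, df["x"])
    expect_equal(unname(fit$coefficients["x"]),
                 log(cc[1] * cc[4] / (cc[2] * cc[3])), tolerance = 1e-6)
  }
  # the family-history table: cross-product OR 3.24
  df <- expand_2x2(165, 649, 73, 930)
  fit <- fit_logistic(df$y, df["x"])
  expect_equal(unname(exp(fit$coefficients["x"])), 3.2389, tolerance = 1e-4)
})

test_that("balanced outcome with no predictors gives intercept zero", {
  # the constant column aliases the intercept and must be reported
  expect_warning(
    fit <- fit_logistic(rep(c(1, 0), 25), data.frame(z = rep(1, 50))),
    "aliased")
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-8)
})

test_that("fit_logistic agrees with an independent Newton maximiser", {
  set.seed(11)
  for (i in 1:5) {
    n <- 150
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
    y <- rbinom(n, 1, plogis(-0.3 + X %*% c(0.8, -0.5, 0.3)))
    fit <- fit_logistic(y, as.data.frame(X))
    oracle <- logistic_newton(y, X)
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
  }
})

test_that("separation is a hard error naming the predictor", {
  y <- rep(c(1, 0), each = 20)
  x <- y                                  # perfect separation
  expect_error(fit_logistic(y, data.frame(sep_var = x, ok = rnorm(40))),
               "sep_var")
})

test_that("aliased columns are reported, not silently dropped", {
  set.seed(12)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(x))
  expect_warning(fit <- fit_logistic(y, data.frame(x = x, x2 = 2 * x)),
                 "aliased")
  expect_equal(fit$aliased, "x2")
})

test_that("null-adjustment propensity leaves SNP estimates unchanged", {
  # design variables independent of status: propensity ~ constant
  cfg <- sim_config(n_cases = 400, n_controls = 400, n_snps = 3,
                    per_allele_log_or = c(0.5, 0.2, 0),
                    x_linked_index = NA, env_effects = list(),
                    fh_log_or = 0, n_ancestry_markers = 30, seed = 19)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  pcs <- genotype_pca(cohort, 3)
  prop <- fit_propensity(cohort, pcs)
  d <- cohort$genotypes[, 1]
  unadj <- fit_logistic(cohort$status, data.frame(d = d))$coefficients["d"]
  adj <- fit_logistic(cohort$status,
                      data.frame(d = d, propensity = prop$logit)
                      )$coefficients["d"]
  expect_equal(unname(adj), unname(unadj), tolerance = 0.08)
})

test_that("propensity adjustment removes centre-driven selection bias", {
  truth <- log(2)
  for (s in c(11, 12, 13)) {
    cfg <- sim_config(n_cases = 500, n_controls = 500, n_snps = 2,
                      per_allele_log_or = c(0, 0),
                      env_effects = list(
                        red_meat = env_cutoff(truth, 65,
                                              dist_lognormal(log(62), 0.55))),
                      fh_log_or = 0, n_centres = 3,
                      centre_control_weights = c(5, 1, 0.2),
                      centre_covariate_shift = list(red_meat = c(-30, 0, 60)),
                      n_ancestry_markers = 20, seed = s)
    cohort <- categorize_covariates(simulate_cohort(simulate_panel(cfg), cfg))
    x <- as.integer(cohort$covariates$red_meat_cat == "high")
    unadj <- fit_logistic(cohort$status,
                          data.frame(rm = x))$coefficients["rm"]
    prop <- fit_propensity(cohort, genotype_pca(cohort, 3))
    adj <- fit_logistic(cohort$status,
                        data.frame(rm = x, propensity = prop$logit)
                        )$coefficients["rm"]
    expect_lt(abs(adj - truth), abs(unadj - truth))
    expect_lt(abs(adj - truth), 0.35)
  }
})

test_that("perfect centre-status confounding propagates as an error", {
  g <- matrix(rbinom(80, 2, 0.5), 40, 2,
              dimnames = list(NULL, c("rs1", "rs2")))
  status <- rep(c(1, 0), each = 20)
  cov <- data.frame(
    age_band = rep(c("60-64", "65-69"), 20),
    centre = rep(c("c1", "c2"), each = 20),   # cases all c1, controls all c2
    education = rep(c("primary", "secondary"), 20))
  cohort <- make_cohort(status, g, cov)
  expect_error(suppressWarnings(fit_propensity(cohort)), "confounded")
})

test_that("variable screening keeps strong effects and respects the threshold", {
  cfg <- sim_config(n_cases = 500, n_controls = 500, n_snps = 2,
                    per_allele_log_or = c(0, 0),
                    env_effects = list(
                      strong = env_binary(log(2.5), 0.3),
                      nullv  = env_binary(0, 0.5)),
                    fh_log_or = 0, n_ancestry_markers = 10, seed = 29)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  prop <- fit_propensity(cohort, genotype_pca(cohort, 3))
  sel <- screen_ers_variables(cohort, c("strong", "nullv"), prop$logit)
  expect_true("strong" %in% sel)
  pv <- attr(sel, "p_values")
  expect_lt(pv["strong"], 1e-6)
  expect_identical(as.character(sel),
                   c("strong", "nullv")[pv <= 0.20])

  expect_length(screen_ers_variables(cohort, character(0), prop$logit), 0)
  expect_error(screen_ers_variables(cohort, "family_history", prop$logit),
               "not modifiable")
})

test_that("ERS gives all-reference subjects a score of exactly zero", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, n_snps = 2,
                    n_ancestry_markers = 10, seed = 37)
  cohort <- categorize_covariates(simulate_cohort(simulate_panel(cfg), cfg))
  prop <- fit_propensity(cohort, genotype_pca(cohort, 3))
  ers <- build_score(cohort, "ers", prop$logit, ers_vars = "red_meat_cat")
  # reference = category with the lowest observed risk; its subjects score 0
  risk <- tapply(cohort$status, cohort$covariates$red_meat_cat, mean)
  ref_cat <- names(which.min(risk))
  in_ref <- cohort$covariates$red_meat_cat == ref_cat
  expect_true(any(in_ref) && !all(in_ref))
  expect_true(all(ers$scores[in_ref] == 0))
  expect_equal(unique(ers$scores[!in_ref]), ers$terms$beta)
})

test_that("score construction is linear and order-invariant in its terms", {
  cfg <- sim_config(n_cases = 200, n_controls = 200, n_snps = 4,
                    x_linked_index = NA, n_ancestry_markers = 10, seed = 41)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  prop <- fit_propensity(cohort, genotype_pca(cohort, 3))
  grs <- build_score(cohort, "grs", prop$logit)
  # score equals the explicit sum of beta * dosage
  manual <- as.vector(cohort$genotypes[, grs$terms$term] %*% grs$terms$beta)
  expect_equal(grs$scores, manual, tolerance = 1e-12)
  # permuting SNP columns leaves per-subject scores unchanged
  cohort2 <- cohort
  perm <- c(3, 1, 4, 2)
  cohort2$genotypes <- cohort$genotypes[, perm]
  grs2 <- build_score(cohort2, "grs", prop$logit)
  expect_equal(grs2$scores, grs$scores, tolerance = 1e-10)
})

test_that("a jointly-fitted score is self-calibrated (per-unit beta = 1)", {
  cfg <- sim_config(n_cases = 250, n_controls = 250, n_snps = 5,
                    x_linked_index = NA, n_ancestry_markers = 10, seed = 43)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  prop <- fit_propensity(cohort, genotype_pca(cohort, 3))
  grs <- build_score(cohort, "grs", prop$logit, snp_mode = "joint")
  expect_equal(log(grs$per_unit_or), 1, tolerance = 1e-6)
})

test_that("single-SNP fit recovers a generating per-allele OR of 2", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_snps = 1,
                    allele_freqs = 0.3, per_allele_log_or = log(2),
                    x_linked_index = NA, env_effects = list(),
                    fh_log_or = 0, n_ancestry_markers = 0, seed = 47)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  fit <- fit_logistic(cohort$status,
                      data.frame(d = cohort$genotypes[, 1]))
  expect_gt(log(2), fit$ci["d", "lower"])
  expect_lt(log(2), fit$ci["d", "upper"])
})

test_that("decile stratification partitions subjects with reference OR 1", {
  cfg <- sim_config(n_cases = 400, n_controls = 500, n_snps = 10,
                    x_linked_index = NA, n_ancestry_markers = 10, seed = 53)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  prop <- fit_propensity(cohort, genotype_pca(cohort, 3))
  grs <- build_score(cohort, "grs", prop$logit)
  dec <- decile_stratify(grs, cohort$status, prop$logit)
  expect_equal(sum(dec$n_cases) + sum(dec$n_controls), 900)
  expect_equal(dec$or[1], 1)
  expect_equal(dec$or_lower[1], 1)
  expect_true(all(diff(dec$score_low) > 0))
  # every subject assigned to exactly one decile
  expect_length(attr(dec, "decile"), 900)

  expect_error(decile_stratify(rep(1:5, 20), rep(c(0, 1), 50), rep(0, 100)),
               "distinct")
})
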