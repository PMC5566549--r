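test_that("simulate_panel respects the configuration", {
  cfg <- sim_config(n_snps = 56, seed = 3)
  panel <- simulate_panel(cfg)
  expect_s3_class(panel, "variant_panel")
  expect_equal(nrow(panel), 56)
  expect_false(anyDuplicated(panel$snp_id) > 0)
  expect_true(all(panel$risk_allele_freq > 0 & panel$risk_allele_freq < 1))
  expect_equal(panel$chrom[56], "X")

  single <- simulate_panel(sim_config(n_snps = 1, allele_freqs = 0.5,
                                      x_linked_index = NA, seed = 1))
  expect_equal(nrow(single), 1)
  expect_equal(single$risk_allele_freq, 0.5)
})

test_that("panel orientation puts the positive log-OR on the risk allele", {
  cfg <- sim_config(n_snps = 3, allele_freqs = c(0.2, 0.5, 0.7),
                    per_allele_log_or = c(0.4, -0.3, 0.1),
                    x_linked_index = NA, seed = 2)
  panel <- simulate_panel(cfg)
  expect_true(all(panel$true_log_or >= 0))
  # flipped SNP 2: frequency complemented
  expect_equal(panel$risk_allele_freq, c(0.2, 0.5, 0.7))
})

test_that("LD pairs are flagged and invalid frequencies rejected by index", {
  cfg <- sim_config(n_snps = 4, ld_pairs = list(c(1, 2, 1.0)),
                    x_linked_index = NA, seed = 1)
  panel <- simulate_panel(cfg)
  expect_equal(panel$ld_partner[1], panel$snp_id[2])
  expect_equal(panel$ld_partner[2], panel$snp_id[1])
  expect_true(all(is.na(panel$ld_partner[3:4])))

  expect_error(sim_config(n_snps = 2, allele_freqs = c(0.5, 1.0)),
               "SNP index 2")
  expect_error(sim_config(n_snps = 2, ld_pairs = list(c(1, 2, 1.4))),
               "r2")
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- tiny_config(seed = 42)
  c1 <- simulate_cohort(simulate_panel(cfg), cfg)
  c2 <- simulate_cohort(simulate_panel(cfg), cfg)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$status, c2$status)
  expect_identical(c1$ancestry_markers, c2$ancestry_markers)
})

test_that("cohort invariants hold: dosage ranges, both classes, sizes", {
  cfg <- sim_config(n_cases = 120, n_controls = 150, n_snps = 6,
                    n_ancestry_markers = 0, seed = 9)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  expect_equal(sum(cohort$status == 1), 120)
  expect_equal(sum(cohort$status == 0), 150)
  expect_true(all(cohort$genotypes[, 1:5] %in% 0:2))
  expect_true(all(cohort$genotypes[, 6] %in% 0:1))  # X-linked hemizygous
  expect_false(anyNA(cohort$covariates))
})

test_that("null generative model gives no case-control dosage difference", {
  cfg <- sim_config(n_cases = 400, n_controls = 400, n_snps = 4,
                    per_allele_log_or = rep(0, 4), env_effects = list(),
                    fh_log_or = 0, x_linked_index = NA,
                    n_ancestry_markers = 0, seed = 17)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  d <- colMeans(cohort$genotypes[cohort$status == 1, ]) -
    colMeans(cohort$genotypes[cohort$status == 0, ])
  expect_true(all(abs(d) < 0.15))
})

test_that("simulated genotypes sit in Hardy-Weinberg proportions", {
  cfg <- sim_config(n_cases = 300, n_controls = 500, n_snps = 30,
                    per_allele_log_or = rep(0, 30), env_effects = list(),
                    fh_log_or = 0, x_linked_index = NA,
                    n_ancestry_markers = 0, seed = 23)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  qc <- hwe_filter(cohort, simulate_panel(cfg))
  # expected failure rate at alpha = 1e-4 is ~0.01%; none of 30 should fail
  expect_length(qc$dropped_hwe, 0)
  expect_true(mean(qc$hwe_pvalues >= 1e-4, na.rm = TRUE) >= 0.99)
})

test_that("family-history prevalence calibrates to the target regime", {
  cfg <- sim_config(n_cases = 600, n_controls = 700, n_snps = 8,
                    n_ancestry_markers = 0, seed = 5)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  fh <- cohort$covariates$family_history
  expect_gt(mean(fh[cohort$status == 0]), 0.03)
  expect_lt(mean(fh[cohort$status == 0]), 0.11)
  expect_gt(mean(fh[cohort$status == 1]), 0.12)
  expect_lt(mean(fh[cohort$status == 1]), 0.28)
})

test_that("LD-paired SNPs hit the target dosage correlation", {
  cfg <- sim_config(n_cases = 500, n_controls = 500, n_snps = 4,
                    per_allele_log_or = rep(0, 4),
                    allele_freqs = c(0.4, 0.4, 0.3, 0.6),
                    ld_pairs = list(c(1, 2, 0.9)), env_effects = list(),
                    fh_log_or = 0, x_linked_index = NA,
                    n_ancestry_markers = 0, seed = 31)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  r2 <- cor(cohort$genotypes[, 1], cohort$genotypes[, 2])^2
  expect_gt(r2, 0.82)
  expect_lt(r2, 0.97)
  r2_indep <- cor(cohort$genotypes[, 3], cohort$genotypes[, 4])^2
  expect_lt(r2_indep, 0.05)
})

test_that("controls are frequency-matched to the case age distribution", {
  cfg <- sim_config(n_cases = 500, n_controls = 600, n_snps = 2,
                    n_ancestry_markers = 0, seed = 13)
  cohort <- simulate_cohort(simulate_panel(cfg), cfg)
  ab <- cohort$covariates$age_band
  case_p <- prop.table(table(ab[cohort$status == 1]))
  ctrl_p <- prop.table(table(ab[cohort$status == 0]))
  expect_true(all(abs(case_p - ctrl_p) < 0.02))
})

test_that("categorization applies the stated cutoffs at the boundary", {
  cov <- data.frame(red_meat = c(64.99, 65, 80, 10),
                    bmi = c(29.9, 30, 18.4, 22),
                    vegetables = c(200, 200.1, 150, 400),
                    physical_activity = c(2.9, 3, 6, 7))
  cohort <- make_cohort(c(0, 1, 0, 1), matrix(0:1, 4, 1,
                        dimnames = list(NULL, "rs1")), cov)
  out <- categorize_covariates(cohort)$covariates
  expect_equal(as.character(out$red_meat_cat),
               c("low", "high", "high", "low"))
  expect_equal(as.character(out$bmi_cat),
               c("overweight", "obese", "underweight", "normal"))
  expect_equal(as.character(out$vegetables_cat),
               c("low", "high", "low", "high"))
  expect_equal(as.character(out$physical_activity_cat),
               c("light", "moderate", "vigorous", "vigorous"))
})

test_that("tertile boundaries come from controls and split them evenly", {
  set.seed(4)
  n <- 450
  cov <- data.frame(alcohol = runif(n, 0, 50))
  status <- rep(c(0, 1), c(300, 150))
  cohort <- make_cohort(status, matrix(0L, n, 1,
                        dimnames = list(NULL, "rs1")), cov)
  out <- categorize_covariates(cohort)
  tab <- table(out$covariates$alcohol_cat[status == 0])
  expect_true(all(abs(tab - 100) <= 1))
  b <- attr(out, "categorization")$alcohol
  expect_equal(b, quantile(cov$alcohol[status == 0], c(1, 2) / 3,
                           names = FALSE))
})

test_that("requesting an absent covariate warns and skips it", {
  cohort <- make_cohort(c(0, 1), matrix(0L, 2, 1,
                        dimnames = list(NULL, "rs1")),
                        data.frame(red_meat = c(10, 90)))
  expect_warning(out <- categorize_covariates(cohort, c("red_meat", "fish")),
                 "fish")
  expect_true("red_meat_cat" %in% names(out$covariates))
  expect_false("fish_cat" %in% names(out$covariates))
})

test_that("cohort and panel round-trip through TSV with seed provenance", {
  cfg <- tiny_config(seed = 8)
  panel <- simulate_panel(cfg)
  cohort <- simulate_cohort(panel, cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, tsv)
  back <- read_cohort(tsv)
  expect_equal(back$status, cohort$status)
  expect_equal(back$genotypes, cohort$genotypes)
  expect_equal(back$seed, 8L)
  expect_equal(as.character(back$covariates$age_band),
               as.character(cohort$covariates$age_band))

  ptsv <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, ptsv)
  pback <- read_panel(ptsv)
  expect_equal(pback$snp_id, panel$snp_id)
  expect_equal(pback$risk_allele_freq, panel$risk_allele_freq)
})

test_that("sim_config round-trips through YAML", {
  cfg <- sim_config(n_cases = 50, n_controls = 60, n_snps = 3,
                    allele_freqs = c(0.2, 0.4, 0.6),
                    per_allele_log_or = c(0.1, 0.2, 0.3),
                    ld_pairs = list(c(1, 2, 0.5)), seed = 99)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, yml)
  back <- read_sim_config(yml)
  expect_equal(back$allele_freqs, cfg$allele_freqs)
  expect_equal(back$ld_pairs, cfg$ld_pairs)
  expect_equal(back$seed, cfg$seed)
  expect_equal(names(back$env_effects), names(cfg$env_effects))
})
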