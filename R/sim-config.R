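#' Distribution helpers for simulated continuous covariates
#'
#' Small constructors describing the marginal distribution a continuous
#' covariate is drawn from in [simulate_cohort()].  Log-normal is the
#' usual choice for intake variables (non-negative, right-skewed);
#' normal for anthropometry.
#'
#' @param meanlog,sdlog log-scale mean and sd (log-normal).
#' @param mean,sd mean and sd (normal).
#' @return a list with `family` and its parameters.
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  stopifnot(is.finite(meanlog), sdlog > 0)
  list(family = "lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' @rdname dist_lognormal
#' @export
dist_normal <- function(mean, sd) {
  stopifnot(is.finite(mean), sd > 0)
  list(family = "normal", mean = mean, sd = sd)
}

r_dist <- function(n, dist) {
  switch(dist$family,
    lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
    normal    = rnorm(n, dist$mean, dist$sd),
    stop("unknown distribution family: ", dist$family)
  )
}

q_dist <- function(p, dist) {
  switch(dist$family,
    lognormal = qlnorm(p, dist$meanlog, dist$sdlog),
    normal    = qnorm(p, dist$mean, dist$sd),
    stop("unknown distribution family: ", dist$family)
  )
}

#' Environmental covariate effect specifications
#'
#' Describe how one environmental covariate is generated and how it acts
#' on disease odds in the simulated logistic model.  Four kinds are
#' supported, mirroring the covariate handling of the analysis:
#'
#' * `env_binary()` — a yes/no covariate (e.g. diabetes) with a given
#'   prevalence; `log_or` is the log odds ratio of the "yes" category.
#' * `env_cutoff()` — a continuous covariate dichotomised at a fixed
#'   cutoff (e.g. red meat at 65 g/day); the risk category is above the
#'   cutoff when `risk_high = TRUE`, below otherwise.
#' * `env_tertile()` — a continuous covariate acting through tertiles;
#'   `log_or` has length 2 (tertile 2 and tertile 3 vs tertile 1).
#' * `env_bmi()` — body-mass index acting through WHO classes; `log_or`
#'   has length 2 (overweight 25-29.9 and obese >= 30 vs under/normal).
#'
#' @param log_or log odds ratio(s) of the non-reference categor(ies).
#' @param prevalence probability of the "yes" category (binary kind).
#' @param cutoff dichotomisation threshold, same units as `dist`.
#' @param dist a [dist_lognormal()] / [dist_normal()] marginal.
#' @param risk_high logical; is the risk (coded) category above the cutoff?
#' @param unit free-text unit label, for reporting only.
#' @return a list of class `env_effect`.
#' @export
env_binary <- function(log_or, prevalence) {
  stopifnot(length(log_or) == 1, prevalence > 0, prevalence < 1)
  structure(list(kind = "binary", log_or = log_or, prevalence = prevalence),
            class = "env_effect")
}

#' @rdname env_binary
#' @export
env_cutoff <- function(log_or, cutoff, dist, risk_high = TRUE, unit = "") {
  stopifnot(length(log_or) == 1, is.finite(cutoff))
  structure(list(kind = "cutoff", log_or = log_or, cutoff = cutoff,
                 dist = dist, risk_high = isTRUE(risk_high), unit = unit),
            class = "env_effect")
}

#' @rdname env_binary
#' @export
env_tertile <- function(log_or, dist) {
  stopifnot(length(log_or) == 2)
  structure(list(kind = "tertile", log_or = log_or, dist = dist),
            class = "env_effect")
}

#' @rdname env_binary
#' @export
env_bmi <- function(log_or, dist) {
  stopifnot(length(log_or) == 2)
  structure(list(kind = "bmi", log_or = log_or, dist = dist),
            class = "env_effect")
}

#' Default environmental effect set
#'
#' The covariate set and effect sizes emulate the multivariate-adjusted
#' odds ratios of a Spanish prostate-cancer case-control study: diabetes
#' protective (OR 0.58), weight tertiles (0.94, 0.70), BMI classes
#' (1.03, 1.26), past alcohol tertiles (1.46, 1.19), red meat >= 65 g/day
#' (OR 1.28), plus two near-null diet covariates (vegetables and fruit
#' dichotomised at 200 g/day) so that variable screening has something to
#' reject.  Marginal distributions are chosen to give control category
#' frequencies close to the ones observed in that study population.
#'
#' @return named list of [env_binary()]-family specifications.
#' @export
default_env_effects <- function() {
  list(
    diabetes   = env_binary(log(0.58), prevalence = 0.22),
    weight     = env_tertile(c(log(0.94), log(0.70)), dist_normal(78, 11)),
    bmi        = env_bmi(c(log(1.03), log(1.26)), dist_normal(27.3, 3.9)),
    alcohol    = env_tertile(c(log(1.46), log(1.19)),
                             dist_lognormal(log(12), 1.0)),
    red_meat   = env_cutoff(log(1.28), cutoff = 65,
                            dist_lognormal(log(62), 0.55), unit = "g/day"),
    vegetables = env_cutoff(log(0.91), cutoff = 200,
                            dist_lognormal(log(150), 0.6),
                            risk_high = FALSE, unit = "g/day"),
    fruits     = env_cutoff(log(0.84), cutoff = 200,
                            dist_lognormal(log(280), 0.7),
                            risk_high = FALSE, unit = "g/day")
  )
}

#' Configuration for the synthetic case-control cohort
#'
#' Collects every knob of the generative model: the case-control sample
#' sizes, the variant panel (allele frequencies and per-allele log odds
#' ratios), the environmental effects, family history, optional LD pairs
#' and population structure, and the seed.  Defaults reproduce the study
#' conditions the analysis was designed for: 818 cases and 1,006
#' age-frequency-matched controls, 56 susceptibility SNPs with per-allele
#' odds ratios between 1.06 and 1.79, one X-linked SNP coded 0/1, family
#' history with ~7% control prevalence and OR 3.3, and the environmental
#' effects of [default_env_effects()].
#'
#' @param n_cases,n_controls number of cases and controls retained.
#' @param n_snps number of biallelic SNPs on the panel.
#' @param allele_freqs optional vector of risk-allele frequencies, one
#'   per SNP, strictly inside (0,1); drawn Uniform(0.1, 0.9) if `NULL`.
#' @param per_allele_log_or optional vector of true per-allele log odds
#'   ratios; drawn uniformly on `log(or_range)` if `NULL`.
#' @param or_range range of per-allele odds ratios used when
#'   `per_allele_log_or` is `NULL`.
#' @param or_skew shape2 of the Beta(1, `or_skew`) draw that places the
#'   log odds ratios inside `log(or_range)`.  The default (6) makes most
#'   effects cluster near the lower end of the range, as genome-wide
#'   significant susceptibility loci do; with 56 SNPs this yields an
#'   aggregate score with a population mean near 7 and a discrimination
#'   in the mid-0.60s, the regime the analysis was designed for.  Set
#'   to 1 for a uniform draw.
#' @param env_effects named list of environmental effect specifications
#'   ([env_binary()] and friends).
#' @param fh_prevalence population prevalence of a positive family
#'   history of prostate cancer.
#' @param fh_log_or log odds ratio of family history.
#' @param x_linked_index index of the SNP placed on chromosome X and
#'   coded 0/1 (males are hemizygous); `NA` for none.
#' @param ld_pairs list of `c(i, j, r2)` triples: SNPs `i` and `j` are
#'   drawn jointly so their dosage correlation squared targets `r2`.
#' @param baseline_prevalence disease probability at the reference
#'   covariate pattern's population average (sets the model intercept).
#' @param n_centres number of recruiting centres.
#' @param centre_control_weights optional per-centre relative sampling
#'   weights applied when drawing controls (models differential control
#'   response by centre); equal weights if `NULL`.
#' @param centre_covariate_shift optional named list,
#'   covariate -> numeric vector of per-centre shifts added to the raw
#'   continuous covariate value (induces centre-covariate confounding).
#' @param ancestry_groups number of latent ancestry subpopulations.
#' @param ancestry_divergence total allele-frequency spread between the
#'   extreme subpopulations (0 = panmictic).
#' @param n_ancestry_markers number of additional null markers carrying
#'   ancestry structure but no disease effect, emulating the
#'   genome-wide genotyping that ancestry principal components are
#'   estimated from (a susceptibility panel alone cannot provide
#'   disease-neutral components: in a case-control sample its leading
#'   component aligns with the risk-allele burden).
#' @param missing_rate proportion of genotype calls set missing.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list of class `sim_config`.
#' @seealso [simulate_panel()], [simulate_cohort()]
#' @export
sim_config <- function(n_cases = 818L, n_controls = 1006L, n_snps = 56L,
                       allele_freqs = NULL, per_allele_log_or = NULL,
                       or_range = c(1.06, 1.79), or_skew = 6,
                       env_effects = default_env_effects(),
                       fh_prevalence = 0.0728, fh_log_or = log(3.3),
                       x_linked_index = n_snps,
                       ld_pairs = list(),
                       baseline_prevalence = 0.10,
                       n_centres = 5L,
                       centre_control_weights = NULL,
                       centre_covariate_shift = NULL,
                       ancestry_groups = 1L,
                       ancestry_divergence = 0,
                       n_ancestry_markers = 200L,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_snps >= 1)
  if (!is.null(allele_freqs)) {
    if (length(allele_freqs) != n_snps)
      stop("allele_freqs must have length n_snps (", n_snps, ")")
    bad <- which(!(allele_freqs > 0 & allele_freqs < 1))
    if (length(bad))
      stop("allele frequency for SNP index ", bad[1],
           " must lie strictly inside (0, 1), got ", allele_freqs[bad[1]])
  }
  if (!is.null(per_allele_log_or) && length(per_allele_log_or) != n_snps)
    stop("per_allele_log_or must have length n_snps (", n_snps, ")")
  stopifnot(baseline_prevalence > 0, baseline_prevalence < 1,
            fh_prevalence > 0, fh_prevalence < 1,
            or_range[1] > 0, or_range[2] >= or_range[1], or_skew > 0,
            missing_rate >= 0, missing_rate < 1)
  for (pr in ld_pairs) {
    if (length(pr) != 3)
      stop("each ld_pairs entry must be c(i, j, r2)")
    if (pr[1] < 1 || pr[2] > n_snps || pr[1] >= pr[2])
      stop("ld pair indices must satisfy 1 <= i < j <= n_snps")
    if (pr[3] < 0 || pr[3] > 1)
      stop("ld pair target r2 must lie in [0, 1]")
  }
  idx <- unlist(lapply(ld_pairs, function(p) p[1:2]))
  if (anyDuplicated(idx))
    stop("a SNP may appear in at most one LD pair")
  if (!is.null(centre_control_weights) &&
      length(centre_control_weights) != n_centres)
    stop("centre_control_weights must have length n_centres")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps),
    allele_freqs = allele_freqs, per_allele_log_or = per_allele_log_or,
    or_range = or_range, or_skew = or_skew,
    env_effects = env_effects,
    fh_prevalence = fh_prevalence, fh_log_or = fh_log_or,
    x_linked_index = if (is.na(x_linked_index)) NA_integer_
                     else as.integer(x_linked_index),
    ld_pairs = ld_pairs,
    baseline_prevalence = baseline_prevalence,
    n_centres = as.integer(n_centres),
    centre_control_weights = centre_control_weights,
    centre_covariate_shift = centre_covariate_shift,
    ancestry_groups = as.integer(ancestry_groups),
    ancestry_divergence = ancestry_divergence,
    n_ancestry_markers = as.integer(n_ancestry_markers),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read / write a simulation configuration as YAML
#'
#' Only scalar and vector fields are serialised; environmental effect
#' specifications round-trip through their list representation.
#'
#' @param config a [sim_config()] object.
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$env_effects <- lapply(x$env_effects, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  env <- lapply(x$env_effects, function(e) structure(e, class = "env_effect"))
  x$env_effects <- env
  x$ld_pairs <- lapply(x$ld_pairs, unlist)
  do.call(sim_config, x)
}
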