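#' Simulate a susceptibility variant panel
#'
#' Draws per-SNP metadata: risk-allele frequency, true per-allele log
#' odds ratio, chromosome and allele labels.  The risk allele is the
#' allele whose dosage carries the positive log odds ratio; if a
#' user-supplied `per_allele_log_or` is negative the alleles are swapped
#' (frequency complemented, sign flipped) so this orientation invariant
#' holds for every SNP.
#'
#' @param config a [sim_config()].
#' @return a data frame of class `variant_panel` with columns `snp_id`,
#'   `chrom`, `risk_allele`, `other_allele`, `risk_allele_freq`,
#'   `source`, `proxy_r2`, `true_log_or`, `ld_partner`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_snps
  freqs <- config$allele_freqs %||% runif(k, 0.1, 0.9)
  lor <- config$per_allele_log_or %||%
    (log(config$or_range[1]) +
       (log(config$or_range[2]) - log(config$or_range[1])) *
         rbeta(k, 1, config$or_skew))
  flip <- lor < 0
  freqs[flip] <- 1 - freqs[flip]
  lor[flip] <- -lor[flip]
  # engineered LD partners share the allele frequency of the first-listed
  # SNP: a high-r2 proxy of a variant necessarily has a close frequency,
  # and equal frequencies keep any target correlation feasible
  if (is.null(config$allele_freqs))
    for (pr in config$ld_pairs) freqs[pr[2]] <- freqs[pr[1]]
  alleles <- t(vapply(seq_len(k),
                      function(i) sample(c("A", "C", "G", "T"), 2),
                      character(2)))
  chrom <- as.character(sample(1:22, k, replace = TRUE))
  if (!is.na(config$x_linked_index)) chrom[config$x_linked_index] <- "X"
  ld_partner <- rep(NA_character_, k)
  ids <- sprintf("rs9%06d", sample(1e5:999999, k))
  for (pr in config$ld_pairs) {
    ld_partner[pr[1]] <- ids[pr[2]]
    ld_partner[pr[2]] <- ids[pr[1]]
  }
  panel <- data.frame(
    snp_id = ids, chrom = chrom,
    risk_allele = alleles[, 1], other_allele = alleles[, 2],
    risk_allele_freq = freqs,
    source = "array", proxy_r2 = NA_real_,
    true_log_or = lor, ld_partner = ld_partner,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

## joint Bernoulli pair with correlation r at the allele (gamete) level;
## summing two independent gametes preserves the correlation for dosages.
draw_ld_gametes <- function(n, p1, p2, r) {
  p11 <- p1 * p2 + r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  if (p11 > min(p1, p2) + 1e-12 || p11 < max(0, p1 + p2 - 1) - 1e-12)
    stop("target LD r2 is infeasible for allele frequencies ",
         signif(p1, 3), " and ", signif(p2, 3))
  a <- rbinom(n, 1, p1)
  pb <- ifelse(a == 1, p11 / p1, (p2 - p11) / (1 - p1))
  b <- rbinom(n, 1, pmin(pmax(pb, 0), 1))
  cbind(a, b)
}

draw_genotypes <- function(n, panel, config, group) {
  k <- nrow(panel)
  g <- matrix(0L, n, k, dimnames = list(NULL, panel$snp_id))
  offsets <- if (config$ancestry_groups > 1)
    seq(-config$ancestry_divergence / 2, config$ancestry_divergence / 2,
        length.out = config$ancestry_groups)
  else 0
  ld_idx <- unlist(lapply(config$ld_pairs, function(p) p[1:2]))
  for (j in seq_len(k)) {
    if (j %in% ld_idx) next
    p <- pmin(pmax(panel$risk_allele_freq[j] + offsets[group], 0.01), 0.99)
    ploidy <- if (!is.na(config$x_linked_index) &&
                  j == config$x_linked_index) 1L else 2L
    g[, j] <- rbinom(n, ploidy, p)
  }
  for (pr in config$ld_pairs) {
    i <- pr[1]; j <- pr[2]; r <- sqrt(pr[3])
    p1 <- panel$risk_allele_freq[i]; p2 <- panel$risk_allele_freq[j]
    g1 <- draw_ld_gametes(n, p1, p2, r)
    g2 <- draw_ld_gametes(n, p1, p2, r)
    g[, i] <- g1[, 1] + g2[, 1]
    g[, j] <- g1[, 2] + g2[, 2]
  }
  g
}

env_category <- function(raw, spec) {
  switch(spec$kind,
    binary = raw,                      # already 0/1
    cutoff = if (spec$risk_high) as.integer(raw >= spec$cutoff)
             else as.integer(raw <= spec$cutoff),
    tertile = {
      q <- q_dist(c(1, 2) / 3, spec$dist)
      1L + as.integer(raw > q[1]) + as.integer(raw > q[2])
    },
    bmi = cut(raw, c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
              labels = FALSE)          # 1 under, 2 normal, 3 over, 4 obese
  )
}

env_contribution <- function(cat, spec) {
  switch(spec$kind,
    binary = spec$log_or * cat,
    cutoff = spec$log_or * cat,
    tertile = c(0, spec$log_or)[cat],
    bmi = c(0, 0, spec$log_or)[cat]
  )
}

age_band_levels <- function() {
  sprintf("%d-%d", seq(40, 80, 5), seq(44, 84, 5))
}

## largest-remainder apportionment of n over shares
apportion <- function(n, shares) {
  raw <- n * shares / sum(shares)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    o <- order(raw - out, decreasing = TRUE)
    out[o[seq_len(rem)]] <- out[o[seq_len(rem)]] + 1L
  }
  as.integer(out)
}

draw_ancestry_markers <- function(n, freqs, config, group) {
  m <- length(freqs)
  if (m == 0) return(NULL)
  out <- matrix(0L, n, m,
                dimnames = list(NULL, sprintf("am_%04d", seq_len(m))))
  offsets <- if (config$ancestry_groups > 1)
    seq(-config$ancestry_divergence / 2, config$ancestry_divergence / 2,
        length.out = config$ancestry_groups)
  else 0
  for (j in seq_len(m)) {
    p <- pmin(pmax(freqs[j] + offsets[group], 0.01), 0.99)
    out[, j] <- rbinom(n, 2, p)
  }
  out
}

draw_source_block <- function(n, panel, config, alpha = NULL,
                              marker_freqs = NULL) {
  group <- sample.int(config$ancestry_groups, n, replace = TRUE)
  centre <- factor(sample.int(config$n_centres, n, replace = TRUE),
                   levels = seq_len(config$n_centres),
                   labels = paste0("centre_", seq_len(config$n_centres)))
  geno <- draw_genotypes(n, panel, config, group)
  lp <- as.vector(geno %*% panel$true_log_or)

  cov <- data.frame(row.names = seq_len(n))
  for (nm in names(config$env_effects)) {
    spec <- config$env_effects[[nm]]
    if (spec$kind == "binary") {
      raw <- rbinom(n, 1, spec$prevalence)
    } else {
      raw <- r_dist(n, spec$dist)
      sh <- config$centre_covariate_shift[[nm]]
      if (!is.null(sh)) raw <- raw + sh[as.integer(centre)]
    }
    cat <- env_category(raw, spec)
    lp <- lp + env_contribution(cat, spec)
    cov[[nm]] <- raw
  }
  fh <- rbinom(n, 1, config$fh_prevalence)
  lp <- lp + config$fh_log_or * fh

  if (is.null(alpha)) {
    prev <- config$baseline_prevalence
    alpha <- uniroot(function(a) mean(plogis(a + lp)) - prev,
                     c(-40, 40), tol = 1e-10)$root
  }
  status <- rbinom(n, 1, plogis(alpha + lp))

  band_w <- c(2, 4, 7, 10, 12, 12, 9, 6, 3)
  age_band <- factor(sample(age_band_levels(), n, replace = TRUE,
                            prob = band_w / sum(band_w)),
                     levels = age_band_levels())
  education <- factor(sample(c("primary", "secondary", "university"), n,
                             replace = TRUE, prob = c(0.35, 0.40, 0.25)),
                      levels = c("primary", "secondary", "university"))
  list(status = status, genotypes = geno, alpha = alpha,
       ancestry_markers = draw_ancestry_markers(n, marker_freqs, config,
                                                group),
       covariates = cbind(
         data.frame(age_band = age_band, centre = centre,
                    education = education, family_history = fh),
         cov))
}

#' Simulate a case-control cohort
#'
#' Oversamples a source population under a logistic disease model (SNP
#' dosages, environmental categories and family history enter additively
#' on the log-odds scale; the intercept is solved numerically so the
#' population disease probability equals `baseline_prevalence`), then
#' retains exactly `n_cases` cases and `n_controls` controls.  Controls
#' are frequency-matched to the realised case age distribution by 5-year
#' age band, mirroring the matched-control design of population
#' case-control studies; optional per-centre control sampling weights
#' emulate differential response by recruiting centre.
#'
#' Genotypes are drawn in Hardy-Weinberg proportions (two independent
#' allele copies per autosomal SNP; one for the X-linked SNP, which is
#' therefore coded 0/1 in this all-male cohort).  SNPs named in
#' `ld_pairs` are drawn jointly from a correlated-allele-copy model so
#' the squared dosage correlation targets the requested r².
#'
#' @param panel a [simulate_panel()] result consistent with `config`.
#' @param config the same [sim_config()].
#' @param max_blocks maximum number of source-population blocks drawn
#'   before giving up on reaching the requested case count.
#' @return a list of class `cohort` with elements `status` (0/1 vector),
#'   `genotypes` (subjects x SNPs dosage matrix), `covariates` (data
#'   frame: age band, centre, education, family history, raw
#'   environmental values), `ancestry_markers` (disease-neutral marker
#'   matrix for ancestry PCA, or `NULL`) and `seed`.  The generating truth (intercept,
#'   per-SNP and environmental log odds ratios) is kept in
#'   `attr(cohort, "truth")` for parameter-recovery checks.
#' @export
simulate_cohort <- function(panel, config, max_blocks = 6L) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "variant_panel"))
  if (nrow(panel) != config$n_snps)
    stop("panel has ", nrow(panel), " SNPs but config expects ",
         config$n_snps)
  set.seed((config$seed + 1L) %% .Machine$integer.max)

  prev <- config$baseline_prevalence
  n0 <- ceiling(1.6 * max(config$n_cases / prev,
                          config$n_controls / (1 - prev)))
  marker_freqs <- if (config$n_ancestry_markers > 0)
    runif(config$n_ancestry_markers, 0.1, 0.9) else numeric(0)
  acc <- NULL
  alpha <- NULL
  for (b in seq_len(max_blocks)) {
    blk <- draw_source_block(n0, panel, config, alpha, marker_freqs)
    alpha <- blk$alpha
    acc <- if (is.null(acc)) blk else list(
      status = c(acc$status, blk$status),
      genotypes = rbind(acc$genotypes, blk$genotypes),
      alpha = alpha,
      ancestry_markers = rbind(acc$ancestry_markers, blk$ancestry_markers),
      covariates = rbind(acc$covariates, blk$covariates))
    if (sum(acc$status == 1) >= config$n_cases &&
        sum(acc$status == 0) >= 2L * config$n_controls) break
  }
  if (sum(acc$status == 1) < config$n_cases)
    stop("could not reach the requested case count (",
         config$n_cases, ") after ", max_blocks,
         " source blocks; raise baseline_prevalence or max_blocks")

  case_idx <- sample(which(acc$status == 1), config$n_cases)
  ctrl_pool <- which(acc$status == 0)

  ## frequency-match controls to the realised case age-band distribution
  bands <- age_band_levels()
  case_counts <- table(factor(acc$covariates$age_band[case_idx],
                              levels = bands))
  target <- apportion(config$n_controls, as.numeric(case_counts))
  w <- config$centre_control_weights
  ctrl_idx <- integer(0)
  deficit <- 0L
  for (i in seq_along(bands)) {
    pool <- ctrl_pool[acc$covariates$age_band[ctrl_pool] == bands[i]]
    take <- min(target[i], length(pool))
    deficit <- deficit + target[i] - take
    if (take > 0) {
      pw <- if (is.null(w)) NULL else w[as.integer(acc$covariates$centre[pool])]
      ctrl_idx <- c(ctrl_idx,
                    if (length(pool) == 1) pool
                    else sample(pool, take, prob = pw))
    }
  }
  if (deficit > 0) {
    warning("control pool short in ", deficit,
            " matched slots; filling from remaining controls")
    rest <- setdiff(ctrl_pool, ctrl_idx)
    ctrl_idx <- c(ctrl_idx, sample(rest, deficit))
  }

  keep <- c(case_idx, ctrl_idx)
  geno <- acc$genotypes[keep, , drop = FALSE]
  if (config$missing_rate > 0) {
    miss <- runif(length(geno)) < config$missing_rate
    geno[miss] <- NA_integer_
  }
  cov <- acc$covariates[keep, , drop = FALSE]
  rownames(cov) <- NULL
  cov <- cbind(id = sprintf("subj_%05d", seq_along(keep)), cov)
  truth <- list(alpha = alpha,
                per_allele_log_or = setNames(panel$true_log_or,
                                             panel$snp_id),
                env_effects = config$env_effects,
                fh_log_or = config$fh_log_or)
  structure(list(status = as.integer(acc$status[keep]),
                 genotypes = geno, covariates = cov,
                 ancestry_markers =
                   if (is.null(acc$ancestry_markers)) NULL
                   else acc$ancestry_markers[keep, , drop = FALSE],
                 seed = config$seed),
            class = "cohort", truth = truth)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Case-control cohort:", sum(x$status == 1), "cases /",
      sum(x$status == 0), "controls;",
      ncol(x$genotypes), "SNPs;",
      ncol(x$covariates) - 1L, "covariate columns\n")
  invisible(x)
}

tertile_rules <- c("alcohol", "spirits", "weight", "waist", "fish",
                   "milk", "dairy", "calcium", "vitamin_d")

#' Categorise raw lifestyle covariates
#'
#' Applies the categorisation rules used throughout the analysis:
#' red meat dichotomised at 65 g/day (>= 65 is the high-intake
#' category), vegetables and fruit each at 200 g/day (low intake is
#' <= 200), BMI into WHO classes with obese >= 30 kg/m², leisure-time
#' physical activity into light/moderate/vigorous at 3 and 6 METs, and
#' alcohol, spirits, weight, waist, fish, milk, dairy, calcium and
#' vitamin D into tertiles.  Tertile boundaries are computed from the
#' control distribution, so the cutoffs are anchored to the comparison
#' population rather than the pooled sample.
#'
#' New factor columns named `<covariate>_cat` are appended; the applied
#' boundaries are recorded in `attr(cohort, "categorization")`.
#'
#' @param cohort a [simulate_cohort()]-style cohort with raw values.
#' @param covariates which covariates to categorise; defaults to every
#'   known rule whose raw column is present.  Explicitly requested but
#'   absent covariates are skipped with a warning.
#' @return the cohort with categorical columns appended.
#' @export
categorize_covariates <- function(cohort, covariates = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  cv <- cohort$covariates
  known <- c("red_meat", "vegetables", "fruits", "bmi",
             "physical_activity", tertile_rules)
  req <- covariates %||% intersect(known, names(cv))
  absent <- setdiff(req, names(cv))
  if (length(absent)) {
    warning("covariate(s) absent, categorization skipped: ",
            paste(absent, collapse = ", "))
    req <- setdiff(req, absent)
  }
  ctrl <- cohort$status == 0
  bounds <- list()
  for (nm in req) {
    x <- cv[[nm]]
    cat_col <- paste0(nm, "_cat")
    if (nm == "red_meat") {
      cv[[cat_col]] <- factor(ifelse(x >= 65, "high", "low"),
                              levels = c("low", "high"))
      bounds[[nm]] <- 65
    } else if (nm %in% c("vegetables", "fruits")) {
      cv[[cat_col]] <- factor(ifelse(x <= 200, "low", "high"),
                              levels = c("high", "low"))
      bounds[[nm]] <- 200
    } else if (nm == "bmi") {
      cv[[cat_col]] <- cut(x, c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
                           labels = c("underweight", "normal",
                                      "overweight", "obese"))
      bounds[[nm]] <- c(18.5, 25, 30)
    } else if (nm == "physical_activity") {
      cv[[cat_col]] <- cut(x, c(-Inf, 3, 6, Inf), right = FALSE,
                           labels = c("light", "moderate", "vigorous"))
      bounds[[nm]] <- c(3, 6)
    } else {                              # control-anchored tertiles
      q <- quantile(x[ctrl], c(1, 2) / 3, na.rm = TRUE, names = FALSE)
      cv[[cat_col]] <- cut(x, c(-Inf, q, Inf),
                           labels = c("T1", "T2", "T3"))
      bounds[[nm]] <- q
    }
  }
  cohort$covariates <- cv
  attr(cohort, "categorization") <- bounds
  cohort
}
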