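#' Fit the selection propensity model
#'
#' Case/control status is regressed on age band, education, recruiting
#' centre and the leading genotype principal components; the per-subject
#' prediction on the logit scale is the propensity score.  Entered as a
#' single continuous covariate, it absorbs differential case and control
#' selection frequencies (age structure, centre response rates,
#' ancestry) without spending a parameter per design variable in every
#' downstream model.  Factor levels with an empty case or control cell
#' are merged into the largest level with a warning.
#'
#' @param cohort a cohort (after [categorize_covariates()] or not; only
#'   design variables are used).
#' @param pca_scores matrix from [genotype_pca()], or `NULL` to omit
#'   ancestry components.
#' @return list of class `propensity_model`: `logit` (per-subject
#'   propensity on the logit scale), `fit` (the `risk_logit`).
#' @export
fit_propensity <- function(cohort, pca_scores = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  cv <- cohort$covariates
  df <- data.frame(
    age_band = merge_sparse_levels(cv$age_band, cohort$status, "age band"),
    education = merge_sparse_levels(cv$education, cohort$status, "education"),
    centre = merge_sparse_levels(cv$centre, cohort$status, "centre"))
  if (!is.null(pca_scores)) {
    pca_scores <- as.matrix(pca_scores)
    colnames(pca_scores) <- paste0("PC", seq_len(ncol(pca_scores)))
    df <- cbind(df, pca_scores)
  }
  fit <- fit_logistic(cohort$status, df)
  logit <- as.vector(predict(fit$model, type = "link"))
  structure(list(logit = logit, fit = fit), class = "propensity_model")
}

## adjusted single-predictor fit: status ~ x + propensity
adjusted_fit <- function(status, x, propensity, name = "x") {
  df <- data.frame(x = x, propensity = propensity)
  names(df)[1] <- name
  fit_logistic(status, df)
}

#' Screen modifiable covariates for the environmental score
#'
#' Each candidate (a categorical column, typically produced by
#' [categorize_covariates()]) is tested one at a time in a
#' propensity-adjusted logistic model; candidates whose likelihood-ratio
#' p-value is at or below the threshold are retained, in their input
#' order.  Family history is deliberately not a candidate: the
#' environmental score contains modifiable factors only.
#'
#' @param cohort the cohort.
#' @param candidates character vector of covariate column names.
#' @param propensity per-subject propensity (logit scale).
#' @param p_threshold retention threshold (default 0.20 — deliberately
#'   lenient, as is usual for score-building pre-selection).
#' @return retained column names, with the per-candidate p-values in
#'   `attr(, "p_values")`.
#' @export
screen_ers_variables <- function(cohort, candidates, propensity,
                                 p_threshold = 0.20) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(candidates) == 0)
    return(structure(character(0), p_values = numeric(0)))
  if ("family_history" %in% candidates)
    stop("family history is not modifiable and cannot enter the ERS")
  pv <- setNames(numeric(length(candidates)), candidates)
  for (nm in candidates) {
    x <- cohort$covariates[[nm]]
    if (is.null(x)) stop("candidate covariate not found: ", nm)
    df <- data.frame(x = x, propensity = propensity, .y = cohort$status)
    full <- quiet_glm(.y ~ x + propensity, df)
    null <- quiet_glm(.y ~ propensity, df)
    pv[nm] <- anova(null, full, test = "LRT")[2, "Pr(>Chi)"]
  }
  keep <- candidates[pv <= p_threshold]
  structure(keep, p_values = pv)
}

## relevel a factor so the reference is the category with the lowest
## observed case proportion ("lowest-risk category as reference")
relevel_lowest_risk <- function(f, status) {
  f <- droplevels(factor(f))
  risk <- tapply(status, f, mean)
  relevel(f, ref = names(which.min(risk)))
}

#' Build a genetic or environmental risk score
#'
#' A risk score is the per-subject sum of estimated log odds ratios
#' times predictor values, using coefficients estimated in this sample
#' (published external weights are deliberately not used — they may be
#' over-estimated for the target population; the bootstrap optimism
#' correction is the guard against the resulting in-sample optimism).
#'
#' * **GRS** — per-SNP coefficients from propensity-adjusted logistic
#'   fits of status on risk-allele dosage, either one SNP at a time
#'   (`snp_mode = "single"`, the default, matching the per-SNP
#'   associations an additive score is built from) or one joint fit
#'   (`snp_mode = "joint"`).  Score = sum of beta times dosage.
#' * **ERS** — one joint propensity-adjusted fit of status on the
#'   selected categorical covariates, each releveled so its
#'   lowest-risk category is the reference.  Score = sum of beta times
#'   category indicator.
#'
#' The per-unit odds ratio is obtained by refitting status on the score
#' plus propensity, so it answers "how much does one point of the score
#' multiply the odds?" on the same adjustment scale as every other model.
#'
#' @param cohort the cohort (dosage-coded for GRS; categorised for ERS).
#' @param kind `"grs"` or `"ers"`.
#' @param propensity per-subject propensity (logit scale).
#' @param ers_vars for ERS: names of the selected categorical columns.
#' @param snp_mode for GRS: `"single"` or `"joint"`.
#' @return list of class `score_model`: `kind`, `terms` (data frame of
#'   term, beta, se, CI), `scores` (per subject), `reference_mean`
#'   (population average score), `per_unit_or`, `per_unit_ci`, `fit`
#'   (the per-unit refit).
#' @export
build_score <- function(cohort, kind = c("grs", "ers"), propensity,
                        ers_vars = NULL, snp_mode = c("single", "joint")) {
  kind <- match.arg(kind)
  snp_mode <- match.arg(snp_mode)
  stopifnot(inherits(cohort, "cohort"))
  status <- cohort$status
  if (kind == "grs") {
    g <- cohort$genotypes
    for (j in seq_len(ncol(g))) {          # mean-impute for scoring
      m <- is.na(g[, j])
      if (any(m)) g[m, j] <- mean(g[, j], na.rm = TRUE)
    }
    if (snp_mode == "single") {
      terms <- do.call(rbind, lapply(colnames(g), function(s) {
        fit <- adjusted_fit(status, g[, s], propensity, name = "dose")
        data.frame(term = s, beta = unname(fit$coefficients["dose"]),
                   se = unname(fit$se["dose"]),
                   lower = unname(fit$ci["dose", "lower"]),
                   upper = unname(fit$ci["dose", "upper"]),
                   stringsAsFactors = FALSE)
      }))
    } else {
      df <- as.data.frame(g)
      df$propensity <- propensity
      fit <- fit_logistic(status, df)
      nm <- intersect(colnames(g), names(fit$coefficients))
      terms <- data.frame(term = nm, beta = unname(fit$coefficients[nm]),
                          se = unname(fit$se[nm]),
                          lower = unname(fit$ci[nm, "lower"]),
                          upper = unname(fit$ci[nm, "upper"]),
                          stringsAsFactors = FALSE)
    }
    scores <- as.vector(g[, terms$term, drop = FALSE] %*% terms$beta)
  } else {
    if (is.null(ers_vars) || length(ers_vars) == 0)
      stop("ers_vars must name at least one selected covariate")
    miss <- setdiff(ers_vars, names(cohort$covariates))
    if (length(miss))
      stop("ERS covariates missing from cohort: ",
           paste(miss, collapse = ", "))
    df <- cohort$covariates[ers_vars]
    for (nm in ers_vars) {
      x <- df[[nm]]
      if (is.numeric(x) && length(unique(x)) <= 2) x <- factor(x)
      if (is.factor(x) || is.character(x))
        df[[nm]] <- relevel_lowest_risk(x, status)
    }
    mm <- model.matrix(~ ., df)[, -1, drop = FALSE]
    dd <- as.data.frame(mm)
    dd$propensity <- propensity
    fit <- fit_logistic(status, dd)
    nm <- intersect(colnames(mm), names(fit$coefficients))
    ## model.matrix mangles names with spaces; match positionally if needed
    if (length(nm) < ncol(mm))
      nm <- setdiff(names(fit$coefficients), c("(Intercept)", "propensity"))
    terms <- data.frame(term = nm, beta = unname(fit$coefficients[nm]),
                        se = unname(fit$se[nm]),
                        lower = unname(fit$ci[nm, "lower"]),
                        upper = unname(fit$ci[nm, "upper"]),
                        stringsAsFactors = FALSE)
    scores <- as.vector(mm[, nm, drop = FALSE] %*% terms$beta)
  }
  refit <- adjusted_fit(status, scores, propensity, name = "score")
  structure(list(kind = toupper(kind), terms = terms, scores = scores,
                 reference_mean = mean(scores),
                 per_unit_or = unname(exp(refit$coefficients["score"])),
                 per_unit_ci = unname(exp(refit$ci["score", ])),
                 fit = refit),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(x$kind, "risk score:", nrow(x$terms), "terms;",
      "population mean", round(x$reference_mean, 3), "\n")
  cat("  per-unit OR", round(x$per_unit_or, 3), "(95% CI",
      round(x$per_unit_ci[1], 3), "-", round(x$per_unit_ci[2], 3), ")\n")
  invisible(x)
}

#' Stratify subjects by score decile
#'
#' Decile boundaries come from the pooled case+control score
#' distribution; subjects whose score ties a boundary fall in the lower
#' decile.  Per-decile odds ratios against decile 1 are estimated from a
#' propensity-adjusted logistic model with decile indicators; the
#' reference decile has OR 1 with a degenerate interval by construction.
#' If heavy ties empty a decile, boundaries are recomputed on the
#' distinct score values with a warning.
#'
#' @param scores numeric per-subject scores, or a `score_model`.
#' @param status binary case status.
#' @param propensity per-subject propensity (logit scale).
#' @return data frame of class `decile_stratification`: decile, score
#'   range, case/control counts, OR, CI; the per-subject decile
#'   assignment is in `attr(, "decile")`.
#' @export
decile_stratify <- function(scores, status, propensity) {
  if (inherits(scores, "score_model")) scores <- scores$scores
  if (length(unique(scores)) < 10)
    stop("decile stratification needs at least 10 distinct score values")
  br <- quantile(scores, probs = seq(0.1, 0.9, 0.1), names = FALSE)
  dec <- cut(scores, c(-Inf, br, Inf), labels = FALSE, right = TRUE)
  if (length(unique(dec)) < 10) {
    warning("tied boundaries emptied a decile; recomputing on distinct values")
    br <- quantile(unique(scores), probs = seq(0.1, 0.9, 0.1), names = FALSE)
    dec <- cut(scores, c(-Inf, br, Inf), labels = FALSE, right = TRUE)
  }
  decf <- merge_sparse_levels(factor(dec, levels = sort(unique(dec))),
                              status, "decile")
  fit <- fit_logistic(status, data.frame(decile = decf,
                                         propensity = propensity))
  lev <- levels(decf)
  or <- c(1, rep(NA_real_, length(lev) - 1))
  lo <- c(1, rep(NA_real_, length(lev) - 1))
  hi <- c(1, rep(NA_real_, length(lev) - 1))
  for (i in seq_along(lev)[-1]) {
    cf <- paste0("decile", lev[i])
    or[i] <- exp(fit$coefficients[cf])
    lo[i] <- exp(fit$ci[cf, "lower"])
    hi[i] <- exp(fit$ci[cf, "upper"])
  }
  rng <- tapply(scores, decf, range)
  out <- data.frame(
    decile = as.integer(lev),
    score_low = vapply(rng[lev], `[`, numeric(1), 1),
    score_high = vapply(rng[lev], `[`, numeric(1), 2),
    n_cases = as.vector(table(decf[status == 1])),
    n_controls = as.vector(table(decf[status == 0])),
    or = or, or_lower = lo, or_upper = hi)
  class(out) <- c("decile_stratification", "data.frame")
  attr(out, "decile") <- dec
  out
}
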