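#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a randomly chosen case
#' receives a higher predicted risk than a randomly chosen control, with
#' tied pairs counted one half.  Computed from ranks, so it is exact and
#' O(n log n).  An optional per-case weight vector gives the
#' case-weighted variant in which each case-control pair contributes the
#' case's weight (used with weights proportional to the number of cases
#' in the case's score decile).
#'
#' @param predicted numeric risk values (any monotone scale).
#' @param status binary 0/1; both classes must be present.
#' @param case_weights optional non-negative weight per *case*
#'   (length = number of cases, in case order), or per subject
#'   (length = n; control entries ignored).
#' @return the AUROC in \[0, 1\].
#' @export
auroc <- function(predicted, status, case_weights = NULL) {
  if (length(predicted) != length(status))
    stop("predicted and status lengths differ")
  ok <- !is.na(predicted) & !is.na(status)
  predicted <- predicted[ok]; status <- status[ok]
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: both classes must be present")
  if (is.null(case_weights)) {
    r <- rank(predicted)
    return((sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  if (length(case_weights) == length(status))
    case_weights <- case_weights[status == 1]
  if (length(case_weights) != n1)
    stop("case_weights must have one entry per case")
  ctrl <- sort(predicted[status == 0])
  cs <- predicted[status == 1]
  below <- findInterval(cs, ctrl, left.open = TRUE)       # strictly less
  upto <- findInterval(cs, ctrl)                          # less or equal
  u <- (below + (upto - below) / 2) / n0
  sum(case_weights * u) / sum(case_weights)
}

## Hanley-McNeil standard error of an AUROC
auroc_se <- function(a, n1, n0) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
         (n1 * n0))
}

#' Continuous net reclassification improvement
#'
#' For nested risk models evaluated on the same subjects, the case
#' component is the net proportion of cases whose predicted risk moves
#' up under the new model, and the control component the net proportion
#' of controls whose risk moves down; the NRI is their sum.  Ties
#' (no movement) contribute zero.  Range \[-2, 2\].
#'
#' @param p_old,p_new predicted risks from the nested (old) and
#'   extended (new) model, same subjects, same order.
#' @param status binary 0/1.
#' @return list: `nri`, `case_component`, `control_component`.
#' @export
nri_continuous <- function(p_old, p_new, status) {
  if (length(p_old) != length(p_new) || length(p_old) != length(status))
    stop("p_old, p_new and status must have equal length")
  d <- p_new - p_old
  case <- status == 1
  if (!any(case) || all(case)) stop("both classes must be present")
  case_component <- mean(d[case] > 0) - mean(d[case] < 0)
  control_component <- mean(d[!case] < 0) - mean(d[!case] > 0)
  list(nri = case_component + control_component,
       case_component = case_component,
       control_component = control_component)
}

#' Integrated discrimination improvement
#'
#' The change, from old model to new, in the mean predicted risk of
#' cases minus the change in the mean predicted risk of controls.  A
#' better model pushes case probabilities up and control probabilities
#' down, so a positive IDI means improved discrimination slope.
#'
#' @inheritParams nri_continuous
#' @return the IDI (scalar).
#' @export
idi <- function(p_old, p_new, status) {
  if (length(p_old) != length(p_new) || length(p_old) != length(status))
    stop("p_old, p_new and status must have equal length")
  case <- status == 1
  if (!any(case) || all(case)) stop("both classes must be present")
  (mean(p_new[case]) - mean(p_old[case])) -
    (mean(p_new[!case]) - mean(p_old[!case]))
}

draw_resample <- function(n, status, stratified, max_redraw = 100L) {
  for (i in seq_len(max_redraw)) {
    idx <- if (stratified) {
      w1 <- which(status == 1); w0 <- which(status == 0)
      c(w1[sample.int(length(w1), length(w1), replace = TRUE)],
        w0[sample.int(length(w0), length(w0), replace = TRUE)])
    } else sample.int(n, n, replace = TRUE)
    if (length(unique(status[idx])) == 2) return(list(idx = idx, redraws = i - 1L))
  }
  stop("could not draw a bootstrap resample containing both classes")
}

#' Bootstrap optimism correction of the AUROC
#'
#' Internal validation by the refit-on-resample scheme: for each
#' bootstrap resample the model is refitted, its AUROC on the resample
#' (in-sample, optimistic) is compared with the AUROC of the same
#' refitted model applied back to the original data, and the mean of
#' these differences estimates the optimism of the apparent AUROC.  The
#' corrected AUROC is apparent minus optimism; the percentile interval
#' of the resample AUROCs is reported alongside.
#'
#' @param formula model formula, e.g. `status ~ grs + propensity`.
#' @param data data frame holding the response and predictors.
#' @param n_boot number of bootstrap resamples (1000 for final
#'   reporting; fewer for exploration).
#' @param seed optional integer seed for reproducibility.
#' @param stratified resample cases and controls separately?
#' @return list of class `evaluation_report`: `auroc_apparent`,
#'   `optimism`, `auroc_corrected`, `auroc_ci` (percentile 95%),
#'   `boot_aurocs`, `n_boot`, `n_redraws`, `seed`.
#' @export
bootstrap_optimism <- function(formula, data, n_boot = 1000L, seed = NULL,
                               stratified = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  fit0 <- quiet_glm(formula, data)
  y <- fit0$y
  p0 <- fitted(fit0)
  apparent <- auroc(p0, y)
  n <- nrow(data)
  opt <- numeric(n_boot)
  auc_in <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    rs <- draw_resample(n, y, stratified)
    redraws <- redraws + rs$redraws
    fitb <- quiet_glm(formula, data[rs$idx, , drop = FALSE])
    auc_in[b] <- auroc(fitted(fitb), y[rs$idx])
    pb <- predict(fitb, newdata = data, type = "response")
    opt[b] <- auc_in[b] - auroc(pb, y)
  }
  structure(list(auroc_apparent = apparent,
                 optimism = mean(opt),
                 auroc_corrected = apparent - mean(opt),
                 auroc_ci = unname(quantile(auc_in, c(0.025, 0.975))),
                 boot_aurocs = auc_in,
                 n_boot = n_boot, n_redraws = redraws, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("AUROC apparent ", round(x$auroc_apparent, 3),
      ", optimism ", round(x$optimism, 4),
      " -> corrected ", round(x$auroc_corrected, 3), "\n",
      "bootstrap 95% CI (", x$n_boot, " resamples): ",
      round(x$auroc_ci[1], 3), " - ", round(x$auroc_ci[2], 3), "\n",
      sep = "")
  invisible(x)
}

#' Incremental value of one score over another
#'
#' Fits the base and the extended (nested) propensity-adjusted models,
#' and reports the continuous NRI, the IDI and the improvement in
#' apparent AUROC.  With `n_boot > 0`, resampling both model fits gives
#' a bootstrap normal-approximation p-value for the AUROC improvement
#' and percentile intervals for all three quantities.
#'
#' @param base_formula,full_formula nested model formulas (the full
#'   model must contain every base predictor).
#' @param data data frame with response and predictors.
#' @param n_boot bootstrap resamples for inference (0 = point estimates
#'   only).
#' @param seed optional seed.
#' @return list of class `score_comparison`: `auroc_base`,
#'   `auroc_full`, `delta_auroc`, `nri`, `nri_components`, `idi`, and
#'   (if bootstrapped) `delta_auroc_p`, `ci` (rows delta/nri/idi).
#' @export
compare_scores <- function(base_formula, full_formula, data,
                           n_boot = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base_vars <- all.vars(base_formula[[3]])
  full_vars <- all.vars(full_formula[[3]])
  if (!all(base_vars %in% full_vars))
    stop("models are not nested: the full model must contain every ",
         "base predictor (NRI and IDI are defined for nested models only)")
  fit_b <- quiet_glm(base_formula, data)
  fit_f <- quiet_glm(full_formula, data)
  y <- fit_b$y
  pb <- fitted(fit_b); pf <- fitted(fit_f)
  a_b <- auroc(pb, y); a_f <- auroc(pf, y)
  nri <- nri_continuous(pb, pf, y)
  out <- list(auroc_base = a_b, auroc_full = a_f,
              delta_auroc = a_f - a_b,
              nri = nri$nri,
              nri_components = c(case = nri$case_component,
                                 control = nri$control_component),
              idi = idi(pb, pf, y))
  if (n_boot > 0) {
    n <- nrow(data)
    dd <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("delta", "nri", "idi")))
    for (b in seq_len(n_boot)) {
      idx <- draw_resample(n, y, stratified = FALSE)$idx
      db <- data[idx, , drop = FALSE]
      fb <- quiet_glm(base_formula, db)
      ff <- quiet_glm(full_formula, db)
      yb <- fb$y
      dd[b, "delta"] <- auroc(fitted(ff), yb) - auroc(fitted(fb), yb)
      dd[b, "nri"] <- nri_continuous(fitted(fb), fitted(ff), yb)$nri
      dd[b, "idi"] <- idi(fitted(fb), fitted(ff), yb)
    }
    se <- sd(dd[, "delta"])
    out$delta_auroc_p <- if (se > 0)
      2 * pnorm(-abs(out$delta_auroc) / se) else NA_real_
    out$ci <- t(apply(dd, 2, quantile, c(0.025, 0.975)))
    out$n_boot <- n_boot
  }
  class(out) <- "score_comparison"
  out
}

#' @export
print.score_comparison <- function(x, ...) {
  cat("base AUROC ", round(x$auroc_base, 3),
      " -> full AUROC ", round(x$auroc_full, 3),
      " (improvement ", round(x$delta_auroc, 3),
      if (!is.null(x$delta_auroc_p))
        paste0(", bootstrap p ", signif(x$delta_auroc_p, 2)) else "",
      ")\n", "continuous NRI ", round(x$nri, 3),
      " (cases ", round(x$nri_components["case"], 3),
      ", controls ", round(x$nri_components["control"], 3),
      "); IDI ", round(x$idi, 4), "\n", sep = "")
  invisible(x)
}

#' Individual and cumulative AUROC ladder
#'
#' For a set of predictors, computes each variable's individual
#' propensity-adjusted AUROC, orders the variables by increasing
#' individual AUROC, and reports the cumulative AUROC as the variables
#' are added in that order — the standard display of how much each
#' factor contributes to the predictive accuracy of the combined model.
#' Wald-style confidence intervals use the Hanley-McNeil standard error.
#'
#' @param data data frame holding `status`, `propensity` and the
#'   predictor columns.
#' @param vars character vector of predictor column names.
#' @param status_col,propensity_col column names of the response and
#'   propensity.
#' @return data frame: variable, individual AUROC and CI, cumulative
#'   AUROC and CI, in increasing-individual-AUROC order.
#' @export
auroc_ladder <- function(data, vars, status_col = "status",
                         propensity_col = "propensity") {
  stopifnot(length(vars) >= 1, all(vars %in% names(data)))
  y <- data[[status_col]]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  ind <- vapply(vars, function(v) {
    f <- as.formula(paste(status_col, "~", v, "+", propensity_col))
    auroc(fitted(quiet_glm(f, data)), y)
  }, numeric(1))
  ord <- order(ind)
  cum <- numeric(length(vars))
  for (i in seq_along(ord)) {
    f <- as.formula(paste(status_col, "~",
                          paste(vars[ord[seq_len(i)]], collapse = " + "),
                          "+", propensity_col))
    cum[i] <- auroc(fitted(quiet_glm(f, data)), y)
  }
  z <- qnorm(0.975)
  se_i <- vapply(ind[ord], auroc_se, numeric(1), n1, n0)
  se_c <- vapply(cum, auroc_se, numeric(1), n1, n0)
  data.frame(variable = vars[ord],
             auroc_individual = unname(ind[ord]),
             ind_lower = unname(pmax(0.0, ind[ord] - z * se_i)),
             ind_upper = unname(pmin(1.0, ind[ord] + z * se_i)),
             auroc_cumulative = cum,
             cum_lower = pmax(0.0, cum - z * se_c),
             cum_upper = pmin(1.0, cum + z * se_c),
             stringsAsFactors = FALSE)
}
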