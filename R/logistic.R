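## internal: binomial glm with tight convergence control, warnings muted
## (saturated fits on bootstrap resamples legitimately push fitted
## probabilities to 0/1)
quiet_glm <- function(formula, data, maxit = 100) {
  suppressWarnings(glm(formula, data = data, family = binomial(),
                       control = glm.control(epsilon = 1e-10,
                                             maxit = maxit)))
}

#' Fit a logistic regression with diagnostics
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, as implemented in [stats::glm()], run to a tight convergence
#' tolerance) with Wald 95% confidence intervals, explicit reporting of
#' aliased (rank-deficient) columns, and a hard error on complete or
#' quasi-complete separation naming the offending predictor — a
#' silently divergent fit must never propagate into a risk score.
#'
#' @param outcome binary 0/1 vector with both classes present.
#' @param design data frame or matrix of predictors.
#' @return list of class `risk_logit`: `coefficients`, `se`, `ci`
#'   (Wald 95%), `p`, `vcov`, `fitted` (probabilities), `deviance`,
#'   `aliased` (dropped column names), `model` (the glm object).
#' @examples
#' ## on a 2x2 table the estimate equals the log cross-product ratio
#' y <- rep(c(1, 1, 0, 0), c(30, 10, 20, 40))
#' x <- rep(c(1, 0, 1, 0), c(30, 10, 20, 40))
#' fit <- fit_logistic(y, data.frame(exposed = x))
#' all.equal(unname(fit$coefficients["exposed"]),
#'           log(30 * 40 / (10 * 20)), tolerance = 1e-6)
#' @export
fit_logistic <- function(outcome, design) {
  outcome <- as.numeric(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop("outcome must contain both classes")
  df <- as.data.frame(design)
  df$.y <- outcome
  fit <- quiet_glm(.y ~ ., df)
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased))
    warning("aliased (rank-deficient) columns dropped: ",
            paste(aliased, collapse = ", "))
  est <- cf[!is.na(cf)]
  se <- sqrt(diag(vcov(fit)))
  sep <- names(est)[abs(est) > 15 | se[names(est)] > 200]
  sep <- setdiff(sep, "(Intercept)")
  if (length(sep))
    stop("complete or quasi-complete separation detected for predictor(s): ",
         paste(sep, collapse = ", "))
  z <- qnorm(0.975)
  ci <- cbind(lower = est - z * se[names(est)],
              upper = est + z * se[names(est)])
  pv <- 2 * pnorm(-abs(est / se[names(est)]))
  structure(list(coefficients = est, se = se[names(est)], ci = ci, p = pv,
                 vcov = vcov(fit), fitted = fitted(fit),
                 deviance = fit$deviance, aliased = aliased, model = fit),
            class = "risk_logit")
}

#' @export
print.risk_logit <- function(x, ...) {
  z <- data.frame(beta = x$coefficients, se = x$se,
                  OR = exp(x$coefficients),
                  lower = exp(x$ci[, "lower"]), upper = exp(x$ci[, "upper"]),
                  p = x$p)
  print(round(z, 4), ...)
  invisible(x)
}

## merge factor levels that have zero cases or zero controls into the
## largest level, so the propensity / decile models stay estimable
merge_sparse_levels <- function(f, status, what = "factor") {
  f <- droplevels(factor(f))
  tab <- table(f, status)
  bad <- rownames(tab)[tab[, 1] == 0 | tab[, 2] == 0]
  if (length(bad) == 0) return(f)
  if (length(bad) == nlevels(f))
    stop(what, " is perfectly confounded with case status")
  target <- names(which.max(table(f[!(f %in% bad)])))
  warning(what, " level(s) with an empty case or control cell merged into '",
          target, "': ", paste(bad, collapse = ", "))
  levels(f)[levels(f) %in% bad] <- target
  droplevels(f)
}
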