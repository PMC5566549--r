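# Independent oracles and small fixture builders used across the suite.

# exhaustive pair-count AUROC: every case-control pair, ties count 1/2
auroc_bruteforce <- function(pred, status) {
  cs <- pred[status == 1]
  ct <- pred[status == 0]
  s <- 0
  for (a in cs) for (b in ct) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cs) * length(ct))
}

# HWE chi-square recomputed from first principles
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stats::pchisq(sum((c(n_AA, n_Aa, n_aa) - e)^2 / e), 1, lower.tail = FALSE)
}

# Newton-Raphson logistic ML, independent of glm's IRLS path
logistic_newton <- function(y, X, iter = 60) {
  X <- cbind(1, X)
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    p <- plogis(as.vector(X %*% b))
    W <- p * (1 - p)
    H <- crossprod(X * W, X)
    b <- b + solve(H, crossprod(X, y - p))
  }
  as.vector(b)
}

# minimal hand-built cohort for unit tests of the genotype operations
make_cohort <- function(status, genotypes, covariates = NULL) {
  n <- length(status)
  cov <- data.frame(id = sprintf("s%03d", seq_len(n)))
  if (!is.null(covariates)) cov <- cbind(cov, covariates)
  structure(list(status = as.integer(status),
                 genotypes = genotypes, covariates = cov, seed = NA_integer_),
            class = "cohort")
}

make_panel <- function(snp_ids, chrom = rep("1", length(snp_ids)),
                       freq = rep(0.5, length(snp_ids))) {
  k <- length(snp_ids)
  p <- data.frame(snp_id = snp_ids, chrom = chrom,
                  risk_allele = rep("A", k), other_allele = rep("G", k),
                  risk_allele_freq = freq, source = rep("array", k),
                  proxy_r2 = rep(NA_real_, k), stringsAsFactors = FALSE)
  class(p) <- c("variant_panel", "data.frame")
  p
}

# small, fast simulation setup used when the exact study scale is not
# the point of the test
tiny_config <- function(seed = 1, ...) {
  sim_config(n_cases = 80, n_controls = 100, n_snps = 4,
             n_ancestry_markers = 10, seed = seed, ...)
}
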