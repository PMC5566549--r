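#' Code genotypes as risk-allele dosages
#'
#' Re-orients every SNP so the coded allele is the *sample* risk allele:
#' the allele whose dosage is associated with higher disease odds in the
#' analysis sample.  Autosomal dosages are counts in \{0, 1, 2\}; the
#' X-linked SNP is hemizygous in an all-male cohort and must be coded
#' 0/1.  A monomorphic SNP has no within-sample orientation, so the
#' panel's declared risk allele is kept and a warning is emitted.
#'
#' @param cohort a cohort whose `genotypes` count copies of the panel's
#'   `risk_allele`.
#' @param panel the matching `variant_panel`.
#' @return the cohort, with genotypes re-oriented where necessary and
#'   the panel (updated `risk_allele`, `other_allele`,
#'   `risk_allele_freq` and a logical `flipped` column) stored in
#'   `attr(cohort, "panel")`.
#' @export
code_dosages <- function(cohort, panel) {
  stopifnot(inherits(cohort, "cohort"), inherits(panel, "variant_panel"))
  g <- cohort$genotypes
  if (!all(panel$snp_id %in% colnames(g)))
    stop("panel SNPs missing from cohort genotypes: ",
         paste(setdiff(panel$snp_id, colnames(g)), collapse = ", "))
  g <- g[, panel$snp_id, drop = FALSE]
  x_linked <- panel$chrom == "X"
  for (j in seq_len(ncol(g))) {
    ploidy <- if (x_linked[j]) 1L else 2L
    bad <- which(!(g[, j] %in% c(0:ploidy, NA)))
    if (length(bad))
      stop("dosage ", g[bad[1], j], " outside {0..", ploidy,
           "} for subject ", cohort$covariates$id[bad[1]],
           ", SNP ", panel$snp_id[j])
  }
  status <- cohort$status
  flipped <- logical(nrow(panel))
  for (j in seq_len(ncol(g))) {
    d <- g[, j]
    ok <- !is.na(d)
    if (length(unique(d[ok])) < 2) {
      warning("SNP ", panel$snp_id[j],
              " is monomorphic; keeping panel risk-allele orientation")
      next
    }
    ploidy <- if (x_linked[j]) 1L else 2L
    ## allele-count 2x2 cross-product: orientation by observed allele OR
    a1_case <- sum(d[ok & status == 1]); a0_case <- sum(ploidy - d[ok & status == 1])
    a1_ctrl <- sum(d[ok & status == 0]); a0_ctrl <- sum(ploidy - d[ok & status == 0])
    or <- (a1_case * a0_ctrl) / (a0_case * a1_ctrl)
    if (is.finite(or) && or < 1) flipped[j] <- TRUE
  }
  for (j in which(flipped)) {
    ploidy <- if (x_linked[j]) 1L else 2L
    g[, j] <- ploidy - g[, j]
  }
  panel$flipped <- flipped
  tmp <- panel$risk_allele[flipped]
  panel$risk_allele[flipped] <- panel$other_allele[flipped]
  panel$other_allele[flipped] <- tmp
  panel$risk_allele_freq[flipped] <- 1 - panel$risk_allele_freq[flipped]
  if ("true_log_or" %in% names(panel))
    panel$true_log_or[flipped] <- -panel$true_log_or[flipped]
  cohort$genotypes <- g
  attr(cohort, "panel") <- panel
  cohort
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-squared test of observed genotype counts
#' against the Hardy-Weinberg expectations (n p², 2 n p q, n q²) at the
#' sample allele frequency, without continuity correction.  A
#' monomorphic SNP fits its expectation exactly and returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (AA = two risk alleles).
#' @return the chi-squared p-value.
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions: p = 1
#' hwe_test(50, 0, 50)    # no heterozygotes: chi-squared = 100
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("HWE test undefined for zero total count")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Hardy-Weinberg QC filter over a panel
#'
#' Tests each autosomal SNP in controls only (the comparison group is
#' expected to be population-representative; cases can deviate from HWE
#' through genuine association) and flags SNPs with p below the
#' threshold.  The X-linked SNP is hemizygous (0/1) and carries no
#' genotype-level HWE information, so it is skipped with `NA`.
#'
#' @param cohort a dosage-coded cohort.
#' @param panel the matching panel.
#' @param threshold exclusion threshold on the HWE p-value.
#' @param controls_only test in controls (default) or all subjects.
#' @return list with `hwe_pvalues` (named vector) and `dropped_hwe`
#'   (character vector of flagged SNP ids).
#' @export
hwe_filter <- function(cohort, panel, threshold = 1e-4,
                       controls_only = TRUE) {
  stopifnot(inherits(cohort, "cohort"), inherits(panel, "variant_panel"))
  keep <- if (controls_only) cohort$status == 0 else rep(TRUE, length(cohort$status))
  pvals <- setNames(rep(NA_real_, nrow(panel)), panel$snp_id)
  for (j in seq_len(nrow(panel))) {
    if (panel$chrom[j] == "X") next
    d <- cohort$genotypes[keep, panel$snp_id[j]]
    d <- d[!is.na(d)]
    pvals[j] <- hwe_test(sum(d == 2), sum(d == 1), sum(d == 0))
  }
  list(hwe_pvalues = pvals,
       dropped_hwe = panel$snp_id[!is.na(pvals) & pvals < threshold])
}

#' Prune variants in linkage disequilibrium
#'
#' Computes the squared Pearson correlation of dosages (composite LD)
#' for every SNP pair and removes, from each pair exceeding the
#' threshold, the SNP listed later in the panel.  The greedy
#' first-listed-wins rule makes the result deterministic and maximal:
#' no surviving pair exceeds the threshold and re-adding any removed SNP
#' would violate it against its retained partner.
#'
#' @param cohort a dosage-coded cohort.
#' @param panel the matching panel.
#' @param r2_threshold pairs with dosage r² strictly above this are
#'   redundant (default 0.8).
#' @return list with `panel` (survivors, class `variant_panel`) and
#'   `report`: `ld_r2` (data frame of flagged pairs), `dropped_ld`
#'   (data frame: dropped SNP, retained partner, r²).
#' @export
ld_prune <- function(cohort, panel, r2_threshold = 0.8) {
  stopifnot(inherits(cohort, "cohort"), inherits(panel, "variant_panel"))
  k <- nrow(panel)
  if (k == 0)
    return(list(panel = panel,
                report = list(ld_r2 = data.frame(), dropped_ld = data.frame())))
  g <- cohort$genotypes[, panel$snp_id, drop = FALSE]
  r2 <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  keep <- rep(TRUE, k)
  dropped <- data.frame(snp_id = character(), kept_partner = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    prior <- which(keep[seq_len(j - 1)])
    over <- prior[r2[j, prior] > r2_threshold]
    if (length(over)) {
      keep[j] <- FALSE
      best <- over[which.max(r2[j, over])]
      dropped <- rbind(dropped, data.frame(
        snp_id = panel$snp_id[j], kept_partner = panel$snp_id[best],
        r2 = r2[j, best], stringsAsFactors = FALSE))
    }
  }
  flagged <- which(upper.tri(r2) & r2 > r2_threshold, arr.ind = TRUE)
  ld_r2 <- data.frame(snp_a = panel$snp_id[flagged[, 1]],
                      snp_b = panel$snp_id[flagged[, 2]],
                      r2 = r2[flagged], stringsAsFactors = FALSE)
  surv <- panel[keep, , drop = FALSE]
  class(surv) <- c("variant_panel", "data.frame")
  list(panel = surv, report = list(ld_r2 = ld_r2, dropped_ld = dropped))
}

#' Principal components of the genotype matrix
#'
#' Ancestry components from the column-standardised dosage matrix: each
#' SNP is centred and scaled to unit variance (monomorphic SNPs are
#' dropped; missing dosages are mean-imputed per SNP), and the leading
#' principal components are returned per subject, ordered by decreasing
#' explained variance.
#'
#' For ancestry adjustment the components should come from
#' disease-neutral genome-wide markers (`markers = "ancestry"`, the
#' default when the cohort carries an `ancestry_markers` matrix): in a
#' case-control sample the leading component of a susceptibility panel
#' itself aligns with the risk-allele burden and would leak disease
#' signal into the propensity model.
#'
#' @param cohort a dosage-coded cohort.
#' @param n_components number of components (must not exceed the rank
#'   of the standardised matrix).
#' @param markers `"ancestry"` (the cohort's `ancestry_markers`
#'   matrix) or `"panel"` (the susceptibility SNP dosages).
#' @return subjects x `n_components` score matrix with columns
#'   `PC1..PCk`; proportion of variance explained in
#'   `attr(, "var_explained")`.
#' @export
genotype_pca <- function(cohort, n_components = 3L,
                         markers = c("ancestry", "panel")) {
  stopifnot(inherits(cohort, "cohort"), n_components >= 1)
  markers <- match.arg(markers)
  g <- if (markers == "ancestry" && !is.null(cohort$ancestry_markers))
    cohort$ancestry_markers else cohort$genotypes
  for (j in seq_len(ncol(g))) {
    m <- is.na(g[, j])
    if (any(m)) g[m, j] <- mean(g[, j], na.rm = TRUE)
  }
  sds <- apply(g, 2, sd)
  g <- g[, sds > 0, drop = FALSE]
  if (ncol(g) < n_components)
    stop("fewer informative SNPs (", ncol(g),
         ") than requested components (", n_components, ")")
  pc <- prcomp(g, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-8)
  if (n_components > rank)
    stop("requested ", n_components,
         " components but the standardised genotype matrix has rank ",
         rank)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  attr(scores, "var_explained") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  scores
}
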