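#' Write / read a cohort as TSV
#'
#' One row per subject: `status`, the covariate columns, then one
#' dosage column per SNP.  A `# seed:` header line records the
#' generating seed, so a written cohort documents its own provenance.
#'
#' @param cohort a cohort.
#' @param path output file.
#' @return (read) a `cohort`; (write) the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- cbind(status = cohort$status, cohort$covariates,
              as.data.frame(cohort$genotypes))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", cohort$seed %||% NA), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param snp_cols columns holding dosages; default: every column whose
#'   name looks like an rs identifier.
#' @export
read_cohort <- function(path, snp_cols = NULL) {
  first <- readLines(path, n = 1)
  seed <- if (startsWith(first, "# seed:"))
    suppressWarnings(as.integer(trimws(sub("# seed:", "", first))))
  else NA_integer_
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = TRUE)
  if (is.null(snp_cols)) snp_cols <- grep("^rs", names(df), value = TRUE)
  geno <- as.matrix(df[snp_cols])
  rownames(geno) <- NULL
  cov <- df[setdiff(names(df), c("status", snp_cols))]
  if ("id" %in% names(cov)) cov$id <- as.character(cov$id)
  structure(list(status = as.integer(df$status), genotypes = geno,
                 covariates = cov, seed = seed),
            class = "cohort")
}

#' Write / read a variant panel as TSV
#'
#' @param panel a `variant_panel`.
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "variant_panel"))
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "risk_allele", "risk_allele_freq")
  if (!all(need %in% names(x)))
    stop("panel TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x$snp_id)) stop("snp_id values must be unique")
  if ("source" %in% names(x) && "proxy_r2" %in% names(x)) {
    prox <- x$source == "proxy"
    if (any(prox & is.na(x$proxy_r2)))
      stop("proxy SNPs must declare proxy_r2")
    if (any(!is.na(x$proxy_r2) & x$proxy_r2 <= 0.8))
      stop("proxy_r2 must exceed 0.8")
  }
  class(x) <- c("variant_panel", "data.frame")
  x
}

#' Serialise a score model to JSON
#'
#' Stores the fitted terms, the population reference mean and the
#' per-unit odds ratio — everything needed to apply the score to new
#' subjects or to reconstruct the relative-risk equation.
#'
#' @param model a `score_model`.
#' @param path output JSON path.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  jsonlite::write_json(
    list(kind = model$kind, terms = model$terms,
         reference_mean = model$reference_mean,
         per_unit_or = model$per_unit_or,
         per_unit_ci = model$per_unit_ci),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import dosages from a VCF
#'
#' Reads GT fields with \pkg{vcfR} and converts them to risk-allele
#' dosage counts against a panel: the dosage is the number of risk
#' alleles, where the panel's `risk_allele` is matched to the VCF REF or
#' ALT allele.  Diploid autosomes yield 0/1/2; haploid X calls are
#' accepted and yield 0/1.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param panel a `variant_panel`; only its SNPs are imported, in panel
#'   order.
#' @return subjects x SNPs dosage matrix.
#' @export
read_vcf_dosages <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages() needs the 'vcfR' package")
  stopifnot(inherits(panel, "variant_panel"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  found <- match(panel$snp_id, ids)
  if (anyNA(found))
    stop("panel SNPs missing from VCF: ",
         paste(panel$snp_id[is.na(found)], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- matrix(NA_integer_, ncol(gt), nrow(panel),
                dimnames = list(colnames(gt), panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    row <- found[j]
    ref <- fix[row, "REF"]; alt <- fix[row, "ALT"]
    risk_is_alt <- panel$risk_allele[j] == alt
    if (!risk_is_alt && panel$risk_allele[j] != ref)
      stop("risk allele ", panel$risk_allele[j], " of ", panel$snp_id[j],
           " matches neither REF nor ALT in the VCF")
    calls <- gt[row, ]
    alleles <- strsplit(gsub("\\|", "/", calls), "/")
    out[, j] <- vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
      n_alt <- sum(a == "1")
      if (risk_is_alt) n_alt else length(a) - n_alt
    }, integer(1))
  }
  out
}
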