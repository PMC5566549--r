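#' Multiplicative relative-risk equation
#'
#' Combines the three per-unit effects — environmental score,
#' family history and genetic score — into one multiplicative relative
#' risk against the population-average individual:
#'
#' \deqn{RS = OR_{ERS}^{\,ERS - \bar{ERS}} \times OR_{FH}^{\,FH}
#'       \times OR_{GRS}^{\,GRS - \bar{GRS}}}
#'
#' so a subject at the population mean of both scores with no family
#' history has RS = 1 exactly.
#'
#' `risk_equation()` builds the equation from explicit constants;
#' `published_risk_equation()` returns the constants reported by the
#' Spanish prostate-cancer case-control study this model family comes
#' from (per-unit ORs 2.47 for the ERS, 3.32 for family history, 2.05
#' for the GRS; population means 0.94 and 6.98), useful to reproduce its
#' published arithmetic; `risk_equation_from_models()` takes them from
#' score models and a family-history fit of the current analysis.
#'
#' @param or_ers,or_fh,or_grs per-unit odds ratios (> 0).
#' @param mean_ers,mean_grs population mean scores.
#' @return list of class `risk_equation`.
#' @export
risk_equation <- function(or_ers, or_fh, or_grs, mean_ers, mean_grs) {
  stopifnot(or_ers > 0, or_fh > 0, or_grs > 0,
            is.finite(mean_ers), is.finite(mean_grs))
  structure(list(or_ers = or_ers, or_fh = or_fh, or_grs = or_grs,
                 mean_ers = mean_ers, mean_grs = mean_grs),
            class = "risk_equation")
}

#' @rdname risk_equation
#' @export
published_risk_equation <- function() {
  risk_equation(or_ers = 2.47, or_fh = 3.32, or_grs = 2.05,
                mean_ers = 0.94, mean_grs = 6.98)
}

#' @rdname risk_equation
#' @param ers_model,grs_model `score_model` objects ([build_score()]).
#' @param fh_fit a `risk_logit` whose coefficient `family_history` is
#'   the adjusted family-history log odds ratio.
#' @export
risk_equation_from_models <- function(ers_model, grs_model, fh_fit) {
  stopifnot(inherits(ers_model, "score_model"),
            inherits(grs_model, "score_model"),
            inherits(fh_fit, "risk_logit"))
  risk_equation(or_ers = ers_model$per_unit_or,
                or_fh = unname(exp(fh_fit$coefficients["family_history"])),
                or_grs = grs_model$per_unit_or,
                mean_ers = ers_model$reference_mean,
                mean_grs = grs_model$reference_mean)
}

#' @export
print.risk_equation <- function(x, ...) {
  cat(sprintf("RS = %.3g^(ERS-%.3g) * %.3g^FH * %.3g^(GRS-%.3g)\n",
              x$or_ers, x$mean_ers, x$or_fh, x$or_grs, x$mean_grs))
  invisible(x)
}

#' Relative risk of a subject versus the population average
#'
#' Evaluates the [risk_equation()] at given score values.  Vectorised
#' over `ers`, `fh` and `grs`.
#'
#' @param eq a `risk_equation`.
#' @param ers environmental score value(s).
#' @param fh family history, 0 or 1.
#' @param grs genetic score value(s).
#' @return relative risk(s) versus the population-average individual.
#' @examples
#' eq <- published_risk_equation()
#' relative_risk(eq, 0.94, 0, 6.98)  # population average: exactly 1
#' relative_risk(eq, 1, 1, 7)        # approximately 3.56
#' @export
relative_risk <- function(eq, ers, fh, grs) {
  stopifnot(inherits(eq, "risk_equation"))
  if (!all(fh %in% c(0, 1)))
    stop("family history must be coded 0 (absent) or 1 (present)")
  eq$or_ers^(ers - eq$mean_ers) * eq$or_fh^fh * eq$or_grs^(grs - eq$mean_grs)
}

#' Age-band incidence table
#'
#' Validated container for age-specific incidence rates (per 100,000
#' person-years) in ordered, non-overlapping age bands, as published by
#' population cancer registries.
#'
#' @param age_low,age_high inclusive band bounds in years, ascending.
#' @param rate_per_100k non-negative rate per 100,000 person-years.
#' @param population,year optional labels.
#' @return data frame of class `incidence_table`.
#' @export
incidence_table <- function(age_low, age_high, rate_per_100k,
                            population = "", year = NA) {
  stopifnot(length(age_low) == length(age_high),
            length(age_low) == length(rate_per_100k))
  if (any(rate_per_100k < 0)) stop("incidence rates must be non-negative")
  if (any(age_high < age_low)) stop("age_high must be >= age_low")
  if (is.unsorted(age_low, strictly = TRUE))
    stop("age bands must be in ascending order")
  if (any(age_low[-1] <= age_high[-length(age_high)]))
    stop("age bands must not overlap")
  structure(data.frame(age_low = age_low, age_high = age_high,
                       rate_per_100k = rate_per_100k),
            population = population, year = year,
            class = c("incidence_table", "data.frame"))
}

#' Read an incidence CSV
#'
#' Expects columns `age_low, age_high, rate_per_100k`.  A small
#' synthetic table with the shape of Spanish prostate-cancer rates ships
#' with the package:
#' `system.file("extdata", "incidence_spain_synthetic.csv", package = "pcarisk")`.
#'
#' @param path CSV file path.
#' @return an [incidence_table()].
#' @export
read_incidence <- function(path) {
  x <- read.csv(path, comment.char = "#")
  need <- c("age_low", "age_high", "rate_per_100k")
  if (!all(need %in% names(x)))
    stop("incidence CSV must have columns: ", paste(need, collapse = ", "))
  incidence_table(x$age_low, x$age_high, x$rate_per_100k)
}

#' Project incidence rates for a relative risk
#'
#' Multiplies every band's rate by the relative risk — the standard
#' rare-disease approximation in which the odds ratio stands in for the
#' rate ratio.  Band structure is preserved.
#'
#' @param table an [incidence_table()].
#' @param rs relative risk (> 0).
#' @return the projected `incidence_table`.
#' @export
project_incidence <- function(table, rs) {
  stopifnot(inherits(table, "incidence_table"))
  if (!is.numeric(rs) || length(rs) != 1 || rs <= 0)
    stop("relative risk must be a single positive number")
  if (any(table$rate_per_100k < 0)) stop("incidence rates must be non-negative")
  out <- table
  out$rate_per_100k <- table$rate_per_100k * rs
  out
}

#' Risk advancement: when does an elevated-risk subject reach the
#' population peak?
#'
#' Finds the youngest age band at which the projected rate
#' (`rate * rs`) reaches or exceeds the *peak* band rate of the
#' unprojected table — i.e. how much earlier in life a subject with
#' relative risk `rs` experiences the incidence the average person only
#' reaches at the peak age.
#'
#' @param table an [incidence_table()].
#' @param rs relative risk (> 0).
#' @return one-row data frame (`age_low`, `age_high`) of the youngest
#'   qualifying band, or `NULL` if the projected curve never reaches
#'   the population peak.
#' @export
risk_advancement <- function(table, rs) {
  stopifnot(inherits(table, "incidence_table"))
  if (nrow(table) == 0) stop("empty incidence table")
  if (!is.numeric(rs) || length(rs) != 1 || rs <= 0)
    stop("relative risk must be a single positive number")
  peak <- max(table$rate_per_100k)
  hit <- which(table$rate_per_100k * rs >= peak)
  if (length(hit) == 0) return(NULL)
  table[min(hit), c("age_low", "age_high")]
}
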