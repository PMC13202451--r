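## Stratified-exposure population attributable fractions (PAF) over APOE
## genotypes with the e2/e2 reference, allele-level e3/e4 decomposition
## and bound-propagated confidence intervals.
##
## The stratum PAF follows the case-load (Miettinen/Hanley) form
##   PAF_g = case_fraction_g * (OR_g - 1) / OR_g,
## treating odds ratios as risk-ratio approximations (standard for a rare
## outcome; no odds-to-risk conversion is applied). A literal variant
## (OR-1)/(OR * case_fraction) is available behind `formula = "literal"`
## for auditability; it is not a fraction (it exceeds 1 for small case
## fractions) and is not used by any pipeline stage.

EXPOSED_STRATA <- c("e3/e3", "e3/e4", "e2/e3", "e2/e4", "e4/e4")

#' Genotype-stratum population attributable fraction
#'
#' @param odds_ratio Odds ratio vs the reference stratum (> 0).
#' @param case_fraction Proportion of all cases carrying this genotype.
#' @param formula `"case-load"` (default) or `"literal"` (the printed
#'   arrangement (OR-1)/(OR*CF); audit only).
#' @return Stratum PAF (vectorised).
#' @export
stratum_paf <- function(odds_ratio, case_fraction,
                        formula = c("case-load", "literal")) {
  formula <- match.arg(formula)
  if (any(odds_ratio <= 0)) stop("odds_ratio must be > 0")
  if (any(case_fraction < 0 | case_fraction > 1)) {
    stop("case_fraction must lie in [0, 1]")
  }
  if (formula == "case-load") {
    case_fraction * (odds_ratio - 1) / odds_ratio
  } else {
    (odds_ratio - 1) / (odds_ratio * case_fraction)
  }
}

check_strata <- function(strata, require_all = TRUE) {
  stopifnot(is.data.frame(strata),
            all(c("genotype", "or", "case_fraction") %in% names(strata)))
  if (require_all) {
    missing <- setdiff(EXPOSED_STRATA, strata$genotype)
    if (length(missing) > 0) {
      stop("missing exposed stratum/strata: ", paste(missing, collapse = ", "))
    }
  }
  strata[strata$genotype %in% EXPOSED_STRATA, , drop = FALSE]
}

#' Joint PAF over all e3- or e4-containing genotypes
#'
#' Sum of the five exposed-stratum PAFs (e3/e3, e3/e4, e2/e3, e2/e4,
#' e4/e4), each computed against the e2/e2 reference. The reference
#' stratum contributes 0 by construction.
#'
#' @param strata Data frame with columns `genotype`, `or`,
#'   `case_fraction` (and optionally `se_log_or` for bounds).
#' @param formula See [stratum_paf()].
#' @return Joint PAF (scalar).
#' @export
joint_paf <- function(strata, formula = "case-load") {
  s <- check_strata(strata)
  sum(stratum_paf(s$or, s$case_fraction, formula))
}

#' Allele-decomposition weight for the e3/e4 stratum
#'
#' With R = OR(e4/e2) / OR(e3/e2), the share of the e3/e4 stratum's PAF
#' attributed to e4 is R / (R + 1); e3 receives the complement.
#'
#' @param or_e4e2,or_e3e2 Odds ratios vs e2/e2 for e2/e4 and e2/e3 (> 0).
#' @return The e4 weight in (0, 1).
#' @export
allele_weight <- function(or_e4e2, or_e3e2) {
  if (any(c(or_e4e2, or_e3e2) <= 0)) stop("odds ratios must be > 0")
  r <- or_e4e2 / or_e3e2
  r / (r + 1)
}

#' Allele-level PAF decomposition
#'
#' `paf_e4 = PAF(e4/e4) + PAF(e2/e4) + w * PAF(e3/e4)` and
#' `paf_e3 = PAF(e3/e3) + PAF(e2/e3) + (1 - w) * PAF(e3/e4)`, with `w`
#' the [allele_weight()]. The e2/e4 stratum is attributed wholly to e4
#' and e2/e3 wholly to e3 (only the e3/e4 stratum is weight-split), so
#' `paf_e4 + paf_e3` equals the joint PAF exactly.
#'
#' @param strata As in [joint_paf()].
#' @param weight_e4 The e4 share of the e3/e4 stratum, in (0, 1).
#' @param formula See [stratum_paf()].
#' @return List with `paf_e4`, `paf_e3`, `paf_joint`, `weight_e4`.
#' @export
allele_paf <- function(strata, weight_e4, formula = "case-load") {
  stopifnot(weight_e4 > 0, weight_e4 < 1)
  s <- check_strata(strata)
  p <- stats::setNames(stratum_paf(s$or, s$case_fraction, formula), s$genotype)
  list(paf_e4 = unname(p["e4/e4"] + p["e2/e4"] + weight_e4 * p["e3/e4"]),
       paf_e3 = unname(p["e3/e3"] + p["e2/e3"] + (1 - weight_e4) * p["e3/e4"]),
       paf_joint = sum(p), weight_e4 = weight_e4)
}

#' Bound-propagated PAF confidence limits
#'
#' Per-stratum bounds replace each OR by `exp(log OR -/+ 1.96 * se)` and
#' re-evaluate the stratum PAF; the joint bounds sum the per-stratum
#' bounds (strata treated as independent -- a bound propagation matching
#' the replicated description, not a delta-method CI). Decomposition
#' bounds use the lower/upper bounds of the OR ratio R for the weight,
#' with `se(log R) = sqrt(se4^2 + se3^2)`.
#'
#' @param strata Data frame with `genotype`, `or`, `case_fraction`,
#'   `se_log_or`.
#' @param formula See [stratum_paf()].
#' @return List of data frame `strata` (with `paf`, `paf_lower`,
#'   `paf_upper`) and lists `joint`, `e4`, `e3` each holding `paf`,
#'   `lower`, `upper` (plus the weight bounds under `weight`).
#' @export
paf_bounds <- function(strata, formula = "case-load") {
  s <- check_strata(strata)
  stopifnot("se_log_or" %in% names(s))
  or_lo <- exp(log(s$or) - 1.96 * s$se_log_or)
  or_hi <- exp(log(s$or) + 1.96 * s$se_log_or)
  s$paf <- stratum_paf(s$or, s$case_fraction, formula)
  s$paf_lower <- stratum_paf(or_lo, s$case_fraction, formula)
  s$paf_upper <- stratum_paf(or_hi, s$case_fraction, formula)
  idx <- function(g) match(g, s$genotype)
  w_point <- allele_weight(s$or[idx("e2/e4")], s$or[idx("e2/e3")])
  se_logr <- sqrt(s$se_log_or[idx("e2/e4")]^2 + s$se_log_or[idx("e2/e3")]^2)
  r <- s$or[idx("e2/e4")] / s$or[idx("e2/e3")]
  r_lo <- exp(log(r) - 1.96 * se_logr)
  r_hi <- exp(log(r) + 1.96 * se_logr)
  w_lo <- r_lo / (r_lo + 1)
  w_hi <- r_hi / (r_hi + 1)
  dec <- function(p, w) {
    c(e4 = unname(p[idx("e4/e4")] + p[idx("e2/e4")] + w * p[idx("e3/e4")]),
      e3 = unname(p[idx("e3/e3")] + p[idx("e2/e3")] + (1 - w) * p[idx("e3/e4")]))
  }
  point <- dec(s$paf, w_point)
  lower <- dec(s$paf_lower, w_lo)
  upper <- dec(s$paf_upper, w_hi)
  list(strata = s,
       joint = list(paf = sum(s$paf), lower = sum(s$paf_lower),
                    upper = sum(s$paf_upper)),
       e4 = list(paf = point[["e4"]], lower = lower[["e4"]], upper = upper[["e4"]]),
       e3 = list(paf = point[["e3"]], lower = lower[["e3"]], upper = upper[["e3"]]),
       weight = list(point = w_point, lower = w_lo, upper = w_hi, ratio = r,
                     ratio_lower = r_lo, ratio_upper = r_hi))
}

#' End-to-end PAF from logistic fit results and case counts
#'
#' Assembles the stratum table from a genotypic logistic fit with e2/e2
#' reference (one OR and SE per non-reference genotype) and per-genotype
#' case counts, then computes stratum, joint and allele-decomposed PAFs
#' with bound-propagated confidence limits.
#'
#' @param fits Data frame from [fit_logistic()] with
#'   `reference = "e2/e2"` (columns `term`, `estimate`, `se`).
#' @param case_counts Named vector of case counts per diplotype
#'   (including the reference; used only for case fractions).
#' @param formula See [stratum_paf()].
#' @return An object of class `apoe_paf`: the [paf_bounds()] structure
#'   plus `case_total` and the formula used.
#' @export
paf_from_fits <- function(fits, case_counts, formula = "case-load") {
  missing <- setdiff(EXPOSED_STRATA, fits$term)
  if (length(missing) > 0) {
    stop("fit results missing genotype term(s): ", paste(missing, collapse = ", "))
  }
  total <- sum(case_counts)
  cf <- function(g) {
    cnt <- case_counts[g]
    if (is.na(cnt)) stop("no case count supplied for genotype ", g)
    unname(cnt) / total
  }
  i <- match(EXPOSED_STRATA, fits$term)
  bad <- !is.finite(fits$estimate[i]) | exp(fits$estimate[i]) <= 0
  if (any(bad)) {
    stop("non-estimable odds ratio(s) for genotype(s) ",
         paste(fits$term[i][bad], collapse = ", "),
         ": the fit did not yield a finite positive OR (no cases in the ",
         "stratum or in the reference?)")
  }
  if (any(fits$se[i] > 10)) {
    warning("odds-ratio standard error(s) > 10 (near-empty reference ",
            "stratum?); PAF estimates and bounds will be unstable")
  }
  strata <- data.frame(genotype = EXPOSED_STRATA,
                       or = exp(fits$estimate[i]),
                       se_log_or = fits$se[i],
                       case_fraction = vapply(EXPOSED_STRATA, cf, numeric(1)),
                       stringsAsFactors = FALSE)
  out <- paf_bounds(strata, formula)
  out$case_total <- total
  out$formula <- formula
  class(out) <- "apoe_paf"
  out
}

#' @export
print.apoe_paf <- function(x, ...) {
  cat("APOE population attributable fractions (", x$formula, " formula)\n", sep = "")
  s <- x$strata
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-6s OR %6.2f  CF %6.3f  PAF %s%% (%s%%, %s%%)\n",
                s$genotype[i], s$or[i], s$case_fraction[i], pct1(s$paf[i]),
                pct1(s$paf_lower[i]), pct1(s$paf_upper[i])))
  }
  cat(sprintf("  e4 weight for e3/e4 stratum: %.3f\n", x$weight$point))
  for (nm in c("e4", "e3", "joint")) {
    b <- x[[nm]]
    cat(sprintf("  PAF %-5s %s%% (%s%%, %s%%)\n", nm, pct1(b$paf),
                pct1(b$lower), pct1(b$upper)))
  }
  invisible(x)
}

#' Write a PAF report (TSV + JSON twin)
#' @param paf An `apoe_paf` object.
#' @param tsv_path,json_path Output paths (`NULL` to skip).
#' @return Invisibly, the stratum data frame.
#' @export
write_paf_report <- function(paf, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(paf$strata, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(paf), json_path, dataframe = "rows",
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(paf$strata)
}
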