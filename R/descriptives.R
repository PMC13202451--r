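## Genotype count tables, carrier statistics and the carrier-enrichment
## exact binomial test.
##
## Count tables can be built from per-sample calls (summarize_genotypes)
## or directly from printed counts (genotype_count_table), including
## tables where rare case cells are masked (NA): the e4-dose rows then
## stand in for the masked diplotype cells wherever possible and any
## quantity that still needs a masked cell propagates NA.

derive_dose_counts <- function(dip) {
  c(`0` = unname(dip["e2/e2"] + dip["e2/e3"] + dip["e3/e3"]),
    `1` = unname(dip["e2/e4"] + dip["e3/e4"]),
    `2` = unname(dip["e4/e4"]))
}

group_summary <- function(dip_counts, dose_counts = NULL) {
  dip <- stats::setNames(rep(NA_real_, 6), apoe_diplotypes())
  dip[names(dip_counts)] <- as.numeric(dip_counts)
  dose <- if (is.null(dose_counts)) derive_dose_counts(dip) else {
    stats::setNames(as.numeric(dose_counts[c("0", "1", "2")]), c("0", "1", "2"))
  }
  n <- if (!anyNA(dip)) sum(dip) else if (!anyNA(dose)) sum(dose) else NA_real_
  freq <- vapply(c("e2", "e3", "e4"), function(a) {
    hom <- dip[paste(a, a, sep = "/")]
    het <- sum(dip[allele_dose(apoe_diplotypes(), a) == 1L])
    f <- (2 * hom + het) / (2 * n)
    if (is.na(f) && a == "e4" && !anyNA(dose)) f <- (dose[["1"]] + 2 * dose[["2"]]) / (2 * n)
    f
  }, numeric(1))
  list(n = n, diplotype_counts = dip, diplotype_props = dip / n,
       dose_counts = dose, dose_props = dose / n, allele_freqs = freq)
}

#' Build a genotype count table from printed counts
#'
#' @param control_counts,case_counts Named numeric vectors of diplotype
#'   counts (names among [apoe_diplotypes()]); `NA` marks masked cells.
#' @param control_dose,case_dose Optional named vectors (`"0"`, `"1"`,
#'   `"2"`) of e4-allele-dose counts; derived from the diplotype counts
#'   when omitted. Supplying them allows e4 statistics even when rare
#'   diplotype cells are masked.
#' @return An object of class `apoe_genotype_table`: per-group (`cases`,
#'   `controls`, `overall`) counts, proportions and allele frequencies.
#' @export
genotype_count_table <- function(control_counts, case_counts,
                                 control_dose = NULL, case_dose = NULL) {
  controls <- group_summary(control_counts, control_dose)
  cases <- group_summary(case_counts, case_dose)
  overall <- group_summary(controls$diplotype_counts + cases$diplotype_counts,
                           controls$dose_counts + cases$dose_counts)
  out <- list(cases = cases, controls = controls, overall = overall)
  class(out) <- "apoe_genotype_table"
  for (g in names(out)) {
    if (is.na(out[[g]]$n) || out[[g]]$n == 0) {
      warning("group '", g, "' is empty or of unknown size; its proportions are undefined")
    }
  }
  out
}

#' Summarise per-sample diplotypes into a genotype count table
#'
#' @param diplotypes Character vector of diplotype labels.
#' @param status Logical (or 0/1) vector: `TRUE` for cases.
#' @return An `apoe_genotype_table`; see [genotype_count_table()].
#' @export
summarize_genotypes <- function(diplotypes, status) {
  stopifnot(length(diplotypes) == length(status))
  status <- as.logical(status)
  tab <- function(d) {
    cnt <- stats::setNames(rep(0, 6), apoe_diplotypes())
    t <- table(d)
    cnt[names(t)[names(t) %in% names(cnt)]] <- t[names(t) %in% names(cnt)]
    cnt
  }
  genotype_count_table(control_counts = tab(diplotypes[!status]),
                       case_counts = tab(diplotypes[status]))
}

#' Carrier counts and proportions for one allele
#'
#' Carriers are all diplotypes containing the allele; heterozygous means
#' exactly one copy, homozygous two. For e4, masked diplotype cells are
#' recovered from the dose rows when available.
#'
#' @param table An `apoe_genotype_table`.
#' @param allele Allele label (`"e2"`, `"e3"` or `"e4"`).
#' @param group `"overall"`, `"cases"` or `"controls"`.
#' @return Named list: counts and proportions for any / het / hom carriage.
#' @export
carrier_stats <- function(table, allele, group = "overall") {
  stopifnot(inherits(table, "apoe_genotype_table"))
  g <- table[[match.arg(group, c("overall", "cases", "controls"))]]
  dip <- g$diplotype_counts
  het <- sum(dip[allele_dose(names(dip), allele) == 1L])
  hom <- unname(dip[paste(allele, allele, sep = "/")])
  if (allele == "e4" && (is.na(het) || is.na(hom)) && !anyNA(g$dose_counts)) {
    het <- g$dose_counts[["1"]]
    hom <- g$dose_counts[["2"]]
  }
  carriers <- het + hom
  list(n = g$n,
       carriers = carriers, het = het, hom = hom,
       prop_carrier = carriers / g$n, prop_het = het / g$n, prop_hom = hom / g$n)
}

#' Exact two-sided binomial carrier-enrichment test
#'
#' Tests whether the observed carrier proportion differs from an external
#' reference proportion, using the exact binomial test with the
#' minimum-likelihood two-sided convention (sum the probabilities of all
#' outcomes no more likely than the observed count).
#'
#' @param carriers Observed carrier count.
#' @param n Sample size.
#' @param reference_proportion Reference carrier proportion in (0, 1).
#' @return Two-sided p-value.
#' @export
carrier_enrichment_test <- function(carriers, n, reference_proportion) {
  stopifnot(carriers >= 0, carriers <= n, n >= 1)
  if (reference_proportion <= 0 || reference_proportion >= 1) {
    stop("reference_proportion must be strictly inside (0, 1)")
  }
  stats::binom.test(round(carriers), round(n), p = reference_proportion,
                    alternative = "two.sided")$p.value
}

#' Render a proportion as a one-decimal percentage
#'
#' Values of extreme magnitude (|x| > 10, i.e. beyond 1000%), which arise
#' in bound propagation from nearly-empty strata, fall back to scientific
#' notation rather than printing hundreds of digits.
#'
#' @param x Proportion(s), typically in [0, 1].
#' @return Character vector like `"17.5"`.
#' @export
pct1 <- function(x) {
  ifelse(is.finite(x) & abs(x) <= 10,
         formatC(100 * x, format = "f", digits = 1),
         formatC(100 * x, format = "g", digits = 3))
}

#' Write a genotype count report (TSV + JSON twin)
#'
#' @param table An `apoe_genotype_table`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report data frame.
#' @export
write_genotype_report <- function(table, tsv_path = NULL, json_path = NULL) {
  rows <- list()
  for (g in c("cases", "controls", "overall")) {
    s <- table[[g]]
    rows[[g]] <- rbind(
      data.frame(group = g, block = "diplotype", item = names(s$diplotype_counts),
                 count = unname(s$diplotype_counts),
                 proportion = unname(s$diplotype_props)),
      data.frame(group = g, block = "e4_dose", item = names(s$dose_counts),
                 count = unname(s$dose_counts), proportion = unname(s$dose_props)),
      data.frame(group = g, block = "allele_freq", item = names(s$allele_freqs),
                 count = NA_real_, proportion = unname(s$allele_freqs)))
  }
  report <- do.call(rbind, rows)
  report$pct <- pct1(report$proportion)
  if (!is.null(tsv_path)) {
    utils::write.table(report, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(report)
}
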