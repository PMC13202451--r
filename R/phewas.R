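## Phenome-wide association screen: every eligible trait regressed on
## APOE genotype (vs e3/e3) with the primary covariate set; Bonferroni
## and Benjamini-Hochberg multiplicity control.
##
## Multiplicity unit: by default m = number of eligible traits (the
## 0.05/m convention), with the genotype terms of one trait sharing that
## trait's test slot -- a term passes Bonferroni when its p-value beats
## alpha/m, and FDR flags are computed by Benjamini-Hochberg over the
## per-trait minimum p-values and inherited by the trait's terms, which
## keeps Bonferroni-flagged always a subset of FDR-flagged. Note the
## family-wise error guarantee of Bonferroni attaches to the number of
## comparisons actually made: with five genotype terms per trait the
## per-trait unit does not bound FWER at alpha under a global null;
## `multiplicity_unit = "term"` counts trait x genotype tests and does.

#' Determine trait eligibility for the screen
#'
#' Binary traits need at least 500 cases among non-missing values;
#' quantitative traits need more than 1000 non-missing observations
#' (strict inequality).
#'
#' @param cohort Cohort data frame.
#' @param traits Data frame manifest with columns `name` (column in
#'   `cohort`) and `kind` (`"binary"` or `"quantitative"`).
#' @return The manifest with `n` (cases or observed) and `eligible`
#'   flags; `attr(, "m")` records the eligible-trait count.
#' @export
eligible_traits <- function(cohort, traits) {
  stopifnot(all(c("name", "kind") %in% names(traits)))
  traits$n <- vapply(seq_len(nrow(traits)), function(i) {
    x <- cohort[[traits$name[i]]]
    if (is.null(x)) return(0L)
    x <- x[!is.na(x)]
    if (traits$kind[i] == "binary") sum(as.logical(x)) else length(x)
  }, integer(1))
  traits$eligible <- ifelse(traits$kind == "binary",
                            traits$n >= 500L, traits$n > 1000L)
  attr(traits, "m") <- sum(traits$eligible)
  traits
}

#' Bonferroni significance threshold
#' @param alpha Family-wise error target in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Benjamini-Hochberg step-up rejection flags
#' @param p P-values in [0, 1].
#' @param q FDR target.
#' @return Logical rejection flags (same order as `p`).
#' @export
bh_fdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH") <= q
}

#' Run the phenome-wide association screen
#'
#' Each eligible trait is regressed on genotype (genotypic coding vs the
#' e3/e3 reference by default) plus the primary covariate set: linear
#' models for quantitative traits, logistic for binary. The test count m
#' is fixed at eligibility time; a non-converging fit keeps its slot in m
#' and is reported with flag `"failed"`.
#'
#' @param cohort Cohort data frame with diplotypes and trait columns.
#' @param traits Trait manifest (see [eligible_traits()]); eligibility is
#'   (re)computed here.
#' @param covariates Adjustment covariates.
#' @param reference Reference diplotype.
#' @param alpha Family-wise error / FDR target (default 0.05).
#' @param multiplicity_unit `"trait"` (default; m = eligible traits, slot
#'   shared by a trait's genotype terms) or `"term"` (m = trait x
#'   genotype tests).
#' @return Data frame: one row per eligible trait x non-reference
#'   genotype term with `estimate`, `se`, `p`, `effect_direction`,
#'   `passes_bonferroni`, `passes_fdr`, `flag`; `attr(, "m")` and
#'   `attr(, "bonferroni_threshold")` record the multiplicity bookkeeping.
#' @export
run_phewas <- function(cohort, traits,
                       covariates = c("age_at_recruitment", "gender",
                                      paste0("pc", 1:10), "ancestry"),
                       reference = "e3/e3", alpha = 0.05,
                       multiplicity_unit = c("trait", "term")) {
  multiplicity_unit <- match.arg(multiplicity_unit)
  traits <- eligible_traits(cohort, traits)
  elig <- traits[traits$eligible, , drop = FALSE]
  m_traits <- nrow(elig)
  if (m_traits == 0) {
    message("no eligible traits; screen skipped")
    out <- data.frame()
    attr(out, "m") <- 0L
    return(out)
  }
  dat <- cohort[!grepl("e1", cohort$diplotype, fixed = TRUE), , drop = FALSE]
  dat$geno <- stats::relevel(factor(dat$diplotype), ref = reference)
  covs <- intersect(covariates, names(dat))
  covs <- covs[vapply(covs, function(v) length(unique(dat[[v]])) > 1L, logical(1))]
  rhs <- paste(c("geno", covs), collapse = " + ")

  rows <- lapply(seq_len(m_traits), function(i) {
    nm <- elig$name[i]
    kind <- elig$kind[i]
    fml <- stats::as.formula(paste(nm, "~", rhs))
    res <- tryCatch({
      fit <- if (kind == "binary") {
        stats::glm(fml, data = dat, family = stats::binomial())
      } else {
        stats::lm(fml, data = dat)
      }
      co <- summary(fit)$coefficients
      keep <- grepl("^geno", rownames(co))
      co <- co[keep, , drop = FALSE]
      data.frame(trait = nm, kind = kind, term = sub("^geno", "", rownames(co)),
                 estimate = co[, 1], se = co[, 2], p = co[, 4],
                 flag = "ok", row.names = NULL, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(trait = nm, kind = kind, term = NA_character_,
                 estimate = NA_real_, se = NA_real_, p = NA_real_,
                 flag = "failed", stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out$effect_direction <- sign(out$estimate)

  if (multiplicity_unit == "trait") {
    m <- m_traits
    thr <- bonferroni_threshold(alpha, m)
    out$passes_bonferroni <- !is.na(out$p) & out$p < thr
    trait_p <- tapply(out$p, out$trait, function(p) {
      if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE)
    })
    trait_p_vec <- ifelse(is.na(trait_p), 1, trait_p)
    trait_fdr <- stats::setNames(bh_fdr(trait_p_vec, alpha), names(trait_p))
    out$passes_fdr <- unname(trait_fdr[out$trait]) & !is.na(out$p)
  } else {
    m <- sum(!is.na(out$p)) + sum(is.na(out$p)) # failed fits keep their slot
    thr <- bonferroni_threshold(alpha, m)
    out$passes_bonferroni <- !is.na(out$p) & out$p < thr
    p_all <- ifelse(is.na(out$p), 1, out$p)
    out$passes_fdr <- bh_fdr(p_all, alpha) & !is.na(out$p)
  }
  attr(out, "m") <- m
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "traits") <- traits
  out
}

#' Write PheWAS results (TSV + JSON + plot-ready table)
#'
#' The plot-ready table mirrors a phenome-wide summary figure: one row
#' per genotype-trait association passing the FDR flag, with `-log10(p)`,
#' effect direction and genotype.
#'
#' @param results Data frame from [run_phewas()].
#' @param tsv_path,json_path,plot_path Output paths (`NULL` to skip).
#' @return Invisibly, the plot-ready data frame.
#' @export
write_phewas_report <- function(results, tsv_path = NULL, json_path = NULL,
                                plot_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(results, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(results, json_path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  plot_tab <- results[!is.na(results$p) & results$passes_fdr,
                      c("trait", "term", "p", "effect_direction")]
  plot_tab$neg_log10_p <- -log10(plot_tab$p)
  if (!is.null(plot_path)) {
    utils::write.table(plot_tab, plot_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(plot_tab)
}
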