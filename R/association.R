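## Genotype-dementia association models.
##
## The survival clock is age from a fixed origin (16 years primary; 60 in
## the over-60 sensitivity mode). Cases contribute time from the origin to
## diagnosis; controls are administratively censored at
## censor_date - birth_year. By default there is no left truncation at
## recruitment, mirroring the replicated construction; an opt-in
## left-truncation mode enters samples at their recruitment age instead
## (the default induces immortal person-time for a recruited cohort --
## documented, not silently changed).

#' Survival/logistic model configuration
#'
#' @param origin_age Time origin in years (16 primary; 60 for the over-60
#'   sensitivity analysis, which also drops samples recruited at or before
#'   the origin and cases diagnosed before it).
#' @param censor_date Administrative censoring date (decimal years).
#' @param covariates Adjustment covariates (column names). The default is
#'   the replicated set: age at recruitment, gender, PCs 1-10, ancestry.
#'   Note age at recruitment is adjusted for even though the time axis is
#'   age-based; drop it from this vector to remove it.
#' @param coding `"genotypic"` (each diplotype its own term),
#'   `"additive"` (e4 allele count 0/1/2) or `"dominant"` (any-e4
#'   indicator).
#' @param reference Reference diplotype for the genotypic coding
#'   (`"e3/e3"` primary; `"e2/e2"` for PAF inputs).
#' @param strata Optional: `"gender"` fits separate per-stratum models.
#' @param left_truncation Enter samples at recruitment age (default
#'   `FALSE`).
#' @return A list of class `apoe_surv_config`.
#' @export
survival_config <- function(origin_age = 16, censor_date = 2024.92,
                            covariates = c("age_at_recruitment", "gender",
                                           paste0("pc", 1:10), "ancestry"),
                            coding = c("genotypic", "additive", "dominant"),
                            reference = "e3/e3", strata = NULL,
                            left_truncation = FALSE) {
  coding <- match.arg(coding)
  cfg <- list(origin_age = origin_age, censor_date = censor_date,
              covariates = covariates, coding = coding, reference = reference,
              strata = strata, left_truncation = left_truncation)
  class(cfg) <- "apoe_surv_config"
  cfg
}

#' Build event/censoring times on the age-from-origin clock
#'
#' Cases: `time = age_at_diagnosis - origin_age`. Controls:
#' `time = (censor_date - birth_year) - origin_age`. Samples with
#' non-positive time are excluded with a logged reason; when
#' `origin_age > 16` (sensitivity mode) cases diagnosed before the origin
#' and samples recruited at or before the origin are excluded first.
#'
#' @param cohort Cohort data frame (needs `dementia_status`,
#'   `age_at_diagnosis`, `birth_year`; `age_at_recruitment` for the
#'   sensitivity restriction and left truncation).
#' @param config A [survival_config()].
#' @return The cohort with `time`, `status` (and `entry` when left
#'   truncation is on); excluded-row counts in `attr(, "n_excluded")`.
#' @export
build_survival_times <- function(cohort, config = survival_config()) {
  excl <- c()
  if (config$origin_age > 16) {
    drop_rec <- cohort$age_at_recruitment <= config$origin_age
    drop_case <- cohort$dementia_status &
      !is.na(cohort$age_at_diagnosis) & cohort$age_at_diagnosis < config$origin_age
    excl["recruited_at_or_before_origin"] <- sum(drop_rec)
    excl["diagnosed_before_origin"] <- sum(drop_case & !drop_rec)
    cohort <- cohort[!(drop_rec | drop_case), , drop = FALSE]
  }
  censor_age <- config$censor_date - cohort$birth_year
  time <- ifelse(cohort$dementia_status,
                 cohort$age_at_diagnosis - config$origin_age,
                 censor_age - config$origin_age)
  keep <- !is.na(time) & time > 0
  excl["non_positive_time"] <- sum(!keep)
  if (any(!keep)) {
    message(sum(!keep), " sample(s) excluded: non-positive follow-up time")
  }
  cohort <- cohort[keep, , drop = FALSE]
  cohort$time <- time[keep]
  cohort$status <- as.integer(cohort$dementia_status)
  if (config$left_truncation) {
    entry <- pmax(0, cohort$age_at_recruitment - config$origin_age)
    ok <- entry < cohort$time
    excl["entry_at_or_after_exit"] <- sum(!ok)
    cohort <- cohort[ok, , drop = FALSE]
    cohort$entry <- entry[ok]
  }
  attr(cohort, "n_excluded") <- excl
  cohort
}

## Shared model-frame preparation: drop e1 carriers, attach the genotype
## exposure column per coding, drop constant covariates.
prepare_model_data <- function(cohort, config) {
  e1 <- grepl("e1", cohort$diplotype, fixed = TRUE)
  if (any(e1)) {
    warning(sum(e1), " e1 carrier(s) excluded from association modelling")
    cohort <- cohort[!e1, , drop = FALSE]
  }
  cohort$geno <- switch(config$coding,
    genotypic = stats::relevel(factor(cohort$diplotype), ref = config$reference),
    additive = allele_dose(cohort$diplotype, "e4"),
    dominant = as.integer(carries_allele(cohort$diplotype, "e4")))
  covs <- intersect(config$covariates, names(cohort))
  if (length(covs) < length(config$covariates)) {
    warning("covariate(s) absent from cohort: ",
            paste(setdiff(config$covariates, covs), collapse = ", "))
  }
  const <- vapply(covs, function(v) length(unique(cohort[[v]])) < 2L, logical(1))
  if (any(const)) {
    message("dropping constant covariate(s): ", paste(covs[const], collapse = ", "))
    covs <- covs[!const]
  }
  list(data = cohort, covs = covs)
}

term_labels <- function(coding) {
  switch(coding, genotypic = "^geno", additive = "^geno$", dominant = "^geno$")
}

extract_results <- function(fit, data, coding, model_label) {
  s <- summary(fit)
  co <- s$coefficients
  keep <- grepl(term_labels(coding), rownames(co))
  co <- co[keep, , drop = FALSE]
  term <- sub("^geno", "", rownames(co))
  term[term == ""] <- if (coding == "additive") "e4_dose" else "e4_carrier"
  est <- co[, 1]
  se <- co[, grep("^se|^Std", colnames(co))[1]]
  n_events <- if (!is.null(fit$nevent)) fit$nevent else sum(data$status)
  if (coding == "genotypic") {
    ev <- tapply(data$status, data$geno, sum)
    term_events <- as.numeric(ev[term])
  } else {
    term_events <- rep(n_events, length(term))
  }
  flag <- ifelse(is.na(est), "non-estimable",
          ifelse(!is.na(term_events) & term_events == 0, "no-events",
          ifelse(se > 10, "separation-or-wide-ci", "ok")))
  data.frame(term = term, estimate = est, se = se,
             ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
             hr = exp(est), hr_lo = exp(est - 1.96 * se),
             hr_hi = exp(est + 1.96 * se),
             z = est / se, p = co[, ncol(co)],
             n_events = n_events, n_samples = nrow(data),
             model = model_label, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the Cox proportional-hazards genotype model
#'
#' Partial-likelihood fit with Efron tie handling on the age-from-origin
#' clock, adjusted for the configured covariates. Returns one row per
#' genotype term (non-reference diplotypes under the genotypic coding; a
#' single dose or carrier term otherwise). With `strata = "gender"`,
#' separate models are fitted per gender without the gender covariate.
#'
#' @param cohort Cohort data frame with a `diplotype` column.
#' @param config A [survival_config()].
#' @param return_fit Also return the `coxph` object(s) in
#'   `attr(, "fit")` (needed for [schoenfeld_diagnostics()]).
#' @return Data frame of association results (log-hazard scale estimates
#'   with Wald CIs and p-values, plus exponentiated columns).
#' @export
fit_cox <- function(cohort, config = survival_config(), return_fit = FALSE) {
  dat <- build_survival_times(cohort, config)
  pm <- prepare_model_data(dat, config)
  fit_one <- function(d, covs, label) {
    surv <- if (config$left_truncation) "survival::Surv(entry, time, status)" else
      "survival::Surv(time, status)"
    fml <- stats::as.formula(paste(surv, "~",
      paste(c("geno", covs), collapse = " + ")))
    fit <- survival::coxph(fml, data = d, ties = "efron",
                           control = survival::coxph.control(eps = 1e-8,
                                                             iter.max = 200))
    res <- extract_results(fit, d, config$coding, label)
    if (return_fit) attr(res, "fit") <- fit
    res
  }
  if (is.null(config$strata)) {
    fit_one(pm$data, pm$covs, paste0("cox_", config$coding))
  } else {
    strata_var <- config$strata
    levels <- unique(pm$data[[strata_var]])
    out <- lapply(sort(levels), function(l) {
      d <- pm$data[pm$data[[strata_var]] == l, , drop = FALSE]
      fit_one(d, setdiff(pm$covs, strata_var),
              paste0("cox_", config$coding, "[", strata_var, "=", l, "]"))
    })
    res <- do.call(rbind, lapply(out, function(x) { attr(x, "fit") <- NULL; x }))
    if (return_fit) attr(res, "fit") <- lapply(out, attr, "fit")
    res
  }
}

#' Fit the logistic genotype model
#'
#' Maximum-likelihood logistic regression of dementia status on genotype
#' plus the same covariates as the Cox model. The reference diplotype is
#' configurable (e3/e3 primary; e2/e2 when producing odds ratios for the
#' attributable-fraction stage, where the rare reference widens CIs --
#' such terms are flagged rather than suppressed).
#'
#' @inheritParams fit_cox
#' @return Data frame of association results on the log-odds scale (the
#'   `hr*` columns hold exponentiated odds ratios).
#' @export
fit_logistic <- function(cohort, config = survival_config(), return_fit = FALSE) {
  pm <- prepare_model_data(cohort, config)
  d <- pm$data
  d$status <- as.integer(d$dementia_status)
  fml <- stats::as.formula(paste("status ~",
    paste(c("geno", pm$covs), collapse = " + ")))
  fit <- stats::glm(fml, data = d, family = stats::binomial())
  res <- extract_results(fit, d, config$coding, paste0("logistic_", config$coding))
  if (return_fit) attr(res, "fit") <- fit
  res
}

#' Kaplan-Meier dementia-free survival by e4 allele dose
#'
#' Product-limit estimates (Greenwood variance) of dementia-free survival
#' for carriers of 0, 1 or 2 e4 alleles on the age-from-origin clock.
#' Curves start at 1 and are non-increasing. Empty dose groups are
#' omitted with a warning.
#'
#' @inheritParams fit_cox
#' @return Data frame of curve coordinates: `dose`, `time`, `n_risk`,
#'   `n_event`, `surv`, `se`, `lower`, `upper`.
#' @export
km_by_dose <- function(cohort, config = survival_config()) {
  dat <- build_survival_times(cohort, config)
  dat <- dat[!grepl("e1", dat$diplotype, fixed = TRUE), , drop = FALSE]
  dat$dose <- allele_dose(dat$diplotype, "e4")
  present <- sort(unique(dat$dose))
  if (!all(0:2 %in% present)) {
    warning("empty e4 dose group(s) omitted: ",
            paste(setdiff(0:2, present), collapse = ", "))
  }
  sf <- survival::survfit(survival::Surv(time, status) ~ dose, data = dat,
                          conf.type = "log")
  strata_names <- if (is.null(sf$strata)) paste0("dose=", present) else names(sf$strata)
  reps <- if (is.null(sf$strata)) length(sf$time) else sf$strata
  data.frame(dose = as.integer(sub(".*=", "", rep(strata_names, reps))),
             time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv, se = sf$std.err * sf$surv,
             lower = sf$lower, upper = sf$upper,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scaled Schoenfeld residual tests of proportional hazards
#'
#' Per-covariate and global score tests for a time trend in the scaled
#' Schoenfeld residuals of a fitted Cox model. Skipped (with a warning,
#' returning `NULL`) when the fit has fewer than 10 events.
#'
#' @param fit A converged `coxph` fit (e.g. from
#'   `attr(fit_cox(..., return_fit = TRUE), "fit")`).
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return Data frame with `term`, `chisq`, `df`, `p` (last row `GLOBAL`).
#' @export
schoenfeld_diagnostics <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "coxph"))
  if (fit$nevent < 10) {
    warning("fewer than 10 events; Schoenfeld diagnostics skipped")
    return(NULL)
  }
  z <- survival::cox.zph(fit, transform = transform)
  data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p = z$table[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}
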