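# Survival-time construction, Cox and logistic genotype models,
# Kaplan-Meier curves and proportional-hazards diagnostics.

test_that("survival times follow the age-from-origin construction", {
  coh <- data.frame(sample_id = c("A", "B", "C"),
                    diplotype = c("e3/e4", "e3/e3", "e3/e3"),
                    dementia_status = c(TRUE, FALSE, TRUE),
                    age_at_diagnosis = c(73.3, NA, 55),
                    birth_year = c(1950, 1980, 1962),
                    age_at_recruitment = c(70, 40, 58),
                    stringsAsFactors = FALSE)
  out <- build_survival_times(coh, survival_config(origin_age = 16,
                                                   censor_date = 2024.92))
  expect_equal(out$time[out$sample_id == "A"], 73.3 - 16)
  expect_equal(out$time[out$sample_id == "B"], 2024.92 - 1980 - 16)

  # over-60 sensitivity: early-diagnosed cases and young recruits drop
  s60 <- build_survival_times(coh, survival_config(origin_age = 60))
  expect_false("C" %in% s60$sample_id) # diagnosed at 55
  expect_false("B" %in% s60$sample_id) # recruited at 40
  expect_equal(s60$time[s60$sample_id == "A"], 73.3 - 60)

  # non-positive times are excluded with a message
  late <- coh
  late$birth_year[2] <- 2010
  expect_message(out2 <- build_survival_times(late), "non-positive")
  expect_false("B" %in% out2$sample_id)
})

test_that("genotypic results are order-invariant and omit the reference", {
  coh <- quick_cohort(n = 6000, seed = 61, baseline_hazard = 3e-3)
  r1 <- suppressWarnings(fit_cox(coh, survival_config()))
  set.seed(1)
  r2 <- suppressWarnings(fit_cox(coh[sample(nrow(coh)), ], survival_config()))
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
  expect_false("e3/e3" %in% r1$term)
  expect_setequal(r1$term, setdiff(apoe_diplotypes(), "e3/e3"))
  expect_equal(r1$ci_lo, r1$estimate - 1.96 * r1$se, tolerance = 1e-12)
  expect_true(all(r1$hr_lo <= r1$hr & r1$hr <= r1$hr_hi))
})

test_that("additive coding recovers a multiplicative per-allele hazard", {
  coh <- quick_cohort(n = 20000, seed = 62, baseline_hazard = 1e-3,
                      true_log_hr = additive_log_hr(1.55))
  r <- fit_cox(coh, survival_config(coding = "additive"))
  expect_identical(r$term, "e4_dose")
  expect_gt(log(1.55), r$ci_lo)
  expect_lt(log(1.55), r$ci_hi)

  # additive estimate lies between het and hom genotypic estimates on the
  # log scale when the truth is multiplicative
  g <- suppressWarnings(fit_cox(coh, survival_config()))
  b_add <- r$estimate
  b_het <- g$estimate[g$term == "e3/e4"]
  b_hom <- g$estimate[g$term == "e4/e4"]
  expect_gt(b_add, min(b_het, b_hom / 2) - 0.1)
  expect_lt(b_add, max(b_het, b_hom / 2) + 0.1)

  d <- fit_cox(coh, survival_config(coding = "dominant"))
  expect_identical(d$term, "e4_carrier")
})

test_that("logistic fits obey the reference-change identity and approximate Cox", {
  coh <- quick_cohort(n = 20000, seed = 63, baseline_hazard = 1.5e-3)
  a <- fit_logistic(coh, survival_config(reference = "e3/e3"))
  b <- suppressWarnings(fit_logistic(coh, survival_config(reference = "e2/e2")))
  # OR(e4/e4 vs e2/e2) = OR(e3/e3 vs e2/e2) * OR(e4/e4 vs e3/e3): exact
  # reparameterisation of the same maximum-likelihood fit
  lhs <- b$estimate[b$term == "e4/e4"]
  rhs <- b$estimate[b$term == "e3/e3"] + a$estimate[a$term == "e4/e4"]
  expect_equal(lhs, rhs, tolerance = 1e-6)

  # rare outcome: odds ratios approximate hazard ratios
  cx <- suppressWarnings(fit_cox(coh, survival_config()))
  i <- match("e3/e4", a$term)
  j <- match("e3/e4", cx$term)
  expect_lt(abs(a$estimate[i] - cx$estimate[j]) / abs(cx$estimate[j]), 0.25)
})

test_that("gender-stratified fits return one model per stratum", {
  coh <- quick_cohort(n = 8000, seed = 64, baseline_hazard = 3e-3)
  r <- suppressWarnings(fit_cox(coh, survival_config(strata = "gender")))
  expect_true(any(grepl("gender=Female", r$model)))
  expect_true(any(grepl("gender=Male", r$model)))
  expect_equal(sum(r$term == "e3/e4"), 2)
})

test_that("Kaplan-Meier curves honour product-limit arithmetic", {
  base <- data.frame(sample_id = paste0("S", 1:5),
                     diplotype = rep("e3/e3", 5),
                     dementia_status = FALSE, age_at_diagnosis = NA_real_,
                     birth_year = 1960, age_at_recruitment = 40,
                     stringsAsFactors = FALSE)
  # no events: curve constant at 1
  km0 <- suppressWarnings(km_by_dose(base))
  expect_true(all(km0$surv == 1))

  # single event at time t: step of size 1/n_at_risk
  one <- base
  one$dementia_status[1] <- TRUE
  one$age_at_diagnosis[1] <- 46
  km1 <- suppressWarnings(km_by_dose(one))
  step <- km1[km1$n_event == 1, ]
  expect_equal(step$surv, 1 - 1 / step$n_risk)
  expect_equal(step$time, 30)

  # stochastic ordering: dose-2 curve sits below dose-0 under higher hazard
  coh <- quick_cohort(n = 30000, seed = 65, baseline_hazard = 2e-3)
  km <- km_by_dose(coh)
  s_at <- function(d, t) {
    k <- km[km$dose == d & km$time <= t, ]
    if (nrow(k) == 0) 1 else k$surv[which.max(k$time)]
  }
  for (t in c(30, 45, 60)) expect_lte(s_at(2, t), s_at(0, t))
  expect_true(all(tapply(km$surv, km$dose, function(s) all(diff(s) <= 1e-12))))
})

test_that("Schoenfeld diagnostics calibrate under PH and detect violations", {
  # under exact proportional hazards the global test rejects at ~5%
  rej <- vapply(1:60, function(s) {
    coh <- quick_cohort(n = 3000, seed = 100 + s, baseline_hazard = 4e-3)
    f <- suppressWarnings(fit_cox(coh, survival_config(
      covariates = c("age_at_recruitment", "gender"), coding = "dominant"),
      return_fit = TRUE))
    z <- schoenfeld_diagnostics(attr(f, "fit"))
    z$p[z$term == "GLOBAL"] < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))

  # a strongly time-varying effect is detected with power > 50%
  sim_tv <- function(seed) {
    set.seed(seed)
    n <- 20000
    z <- rbinom(n, 1, 0.5)
    base <- 2e-3
    # piecewise hazard for z=1: HR 3 before t=25, HR 1/3 after
    t1 <- rexp(n, base * ifelse(z == 1, 3, 1))
    t2 <- 25 + rexp(n, base * ifelse(z == 1, 1 / 3, 1))
    t <- ifelse(t1 <= 25, t1, t2)
    cens <- runif(n, 30, 60)
    data.frame(time = pmin(t, cens), status = as.integer(t <= cens), z = z)
  }
  power <- vapply(1:10, function(s) {
    d <- sim_tv(200 + s)
    fit <- survival::coxph(survival::Surv(time, status) ~ z, data = d)
    z <- schoenfeld_diagnostics(fit)
    z$p[z$term == "GLOBAL"] < 0.05
  }, logical(1))
  expect_gt(mean(power), 0.5)

  # too few events: skipped with a warning
  tiny <- quick_cohort(n = 400, seed = 66, baseline_hazard = 2e-4)
  f <- suppressWarnings(fit_cox(tiny, survival_config(
    covariates = "age_at_recruitment", coding = "dominant"), return_fit = TRUE))
  expect_warning(out <- schoenfeld_diagnostics(attr(f, "fit")), "fewer than 10")
  expect_null(out)
})

test_that("Wald confidence intervals cover the true log-HR at ~95%", {
  cover <- vapply(1:200, function(s) {
    coh <- quick_cohort(n = 4000, seed = 300 + s, baseline_hazard = 4e-3)
    r <- suppressWarnings(fit_cox(coh, survival_config()))
    i <- match("e3/e4", r$term)
    r$ci_lo[i] <= log(1.5) && log(1.5) <= r$ci_hi[i]
  }, logical(1))
  se <- sqrt(0.95 * 0.05 / 200)
  expect_gt(mean(cover), 0.95 - 3 * se)
  expect_lt(mean(cover), 0.95 + 3 * se + 1e-9)
})
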