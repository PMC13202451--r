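# The stratified-exposure PAF engine and its allele decomposition,
# checked against independent arithmetic oracles and fuzzed invariants.

toy_strata <- function() {
  data.frame(genotype = c("e3/e3", "e3/e4", "e4/e4", "e2/e3", "e2/e4"),
             or = c(2, 3, 5, 1.5, 4),
             case_fraction = c(0.671, 0.2166, 0.0326, 0.0635, 0.0147),
             se_log_or = c(0.1, 0.12, 0.3, 0.2, 0.35),
             stringsAsFactors = FALSE)
}

test_that("stratum PAF follows the case-load form", {
  expect_equal(stratum_paf(1, 0.4), 0)
  expect_equal(stratum_paf(1e12, 0.25), 0.25, tolerance = 1e-11) # OR -> Inf limit
  expect_equal(stratum_paf(5.45, 20 / 614), (20 / 614) * (4.45 / 5.45),
               tolerance = 1e-12)
  expect_equal(stratum_paf(5.45, 20 / 614), 0.0266, tolerance = 1e-3)
  # negative for protective strata, always below the case fraction
  expect_lt(stratum_paf(0.5, 0.3), 0)
  expect_error(stratum_paf(0, 0.3), "> 0")
  expect_error(stratum_paf(-1, 0.3), "> 0")
  # literal printed arrangement kept for audit: not a fraction
  expect_equal(stratum_paf(2, 0.1, formula = "literal"), 1 / 0.2)
})

test_that("joint PAF sums the five exposed strata", {
  s <- toy_strata()
  expect_equal(joint_paf(s), sum(stratum_paf(s$or, s$case_fraction)),
               tolerance = 1e-15)
  # independent arithmetic oracle on a two-stratum table
  two <- data.frame(genotype = c("e3/e3", "e3/e4", "e4/e4", "e2/e3", "e2/e4"),
                    or = c(2, 4, 1, 1, 1),
                    case_fraction = c(0.3, 0.2, 0, 0, 0))
  expect_equal(joint_paf(two), 0.3 * 0.5 + 0.2 * 0.75, tolerance = 1e-15)
  # all ORs 1 -> 0
  null <- transform(toy_strata(), or = 1)
  expect_equal(joint_paf(null), 0)
  expect_error(joint_paf(toy_strata()[-2, ]), "e3/e4")
})

test_that("allele weight is the OR ratio share", {
  expect_equal(allele_weight(2, 2), 0.5)
  expect_equal(allele_weight(4, 2), 2 / 3, tolerance = 1e-15)
  expect_lt(allele_weight(1, 1e9), 1e-8) # or_e3e2 -> Inf limit
  expect_error(allele_weight(-1, 2), "> 0")
})

test_that("allele decomposition matches the spreadsheet oracle and conserves", {
  s <- toy_strata()
  w <- allele_weight(or_e4e2 = 4, or_e3e2 = 1.5)
  expect_equal(w, (4 / 1.5) / (4 / 1.5 + 1), tolerance = 1e-15)
  dec <- allele_paf(s, w)
  # independent arithmetic: e4 gets e4/e4 + e2/e4 + w * e3/e4
  oracle_e4 <- 0.0326 * (4 / 5) + 0.0147 * (3 / 4) + w * (0.2166 * (2 / 3))
  expect_equal(dec$paf_e4, oracle_e4, tolerance = 1e-12)
  expect_equal(dec$paf_e4 + dec$paf_e3, dec$paf_joint, tolerance = 1e-12)
  expect_equal(dec$paf_joint, joint_paf(s), tolerance = 1e-15)

  # symmetric split when only the e3/e4 stratum is non-null
  only <- data.frame(genotype = c("e3/e3", "e3/e4", "e4/e4", "e2/e3", "e2/e4"),
                     or = c(1, 3, 1, 1, 1),
                     case_fraction = c(0.2, 0.4, 0.1, 0.2, 0.1))
  half <- allele_paf(only, 0.5)
  expect_equal(half$paf_e4, half$paf_e3, tolerance = 1e-15)
  expect_equal(half$paf_e4, stratum_paf(3, 0.4) / 2, tolerance = 1e-15)
})

test_that("bounds re-evaluate the formula at the OR confidence limits", {
  one <- data.frame(genotype = c("e3/e3", "e3/e4", "e4/e4", "e2/e3", "e2/e4"),
                    or = c(2, 1, 1, 1, 1),
                    case_fraction = c(0.5, 0, 0, 0, 0),
                    se_log_or = c(0.1, 0, 0, 0, 0))
  b <- paf_bounds(one)
  expect_equal(b$joint$lower, 0.5 * (1 - 1 / exp(log(2) - 1.96 * 0.1)),
               tolerance = 1e-12)
  expect_equal(b$joint$upper, 0.5 * (1 - 1 / exp(log(2) + 1.96 * 0.1)),
               tolerance = 1e-12)
  expect_equal(b$joint$lower, 0.195868, tolerance = 1e-5)
  expect_equal(b$joint$upper, 0.294497, tolerance = 1e-5)

  # zero SEs collapse the bounds onto the point estimate
  s0 <- transform(toy_strata(), se_log_or = 0)
  b0 <- paf_bounds(s0)
  expect_equal(b0$joint$lower, b0$joint$paf, tolerance = 1e-12)
  expect_equal(b0$joint$upper, b0$joint$paf, tolerance = 1e-12)

  # monotone: lower <= point <= upper for OR > 1 strata
  b1 <- paf_bounds(toy_strata())
  above <- b1$strata$or > 1
  expect_true(all(b1$strata$paf_lower[above] <= b1$strata$paf[above]))
  expect_true(all(b1$strata$paf[above] <= b1$strata$paf_upper[above]))
})

test_that("conservation and monotonicity hold over fuzzed stratum tables", {
  set.seed(99)
  for (i in 1:1000) {
    or <- exp(rnorm(5, 0, 1))
    cf <- as.numeric(rmultinom(1, 1000, runif(6) + 0.05)) / 1000
    s <- data.frame(genotype = c("e3/e3", "e3/e4", "e4/e4", "e2/e3", "e2/e4"),
                    or = or, case_fraction = cf[1:5],
                    se_log_or = runif(5, 0, 0.5))
    w <- runif(1, 0.01, 0.99)
    dec <- allele_paf(s, w)
    stopifnot(abs(dec$paf_e4 + dec$paf_e3 - dec$paf_joint) < 1e-12)
    # monotonicity: raising one OR never lowers the joint PAF
    j <- joint_paf(s)
    s2 <- s
    k <- sample(5, 1)
    s2$or[k] <- s2$or[k] * (1 + runif(1))
    stopifnot(joint_paf(s2) >= j - 1e-14)
    # stratum PAF bounded by the case fraction
    stopifnot(all(stratum_paf(s$or, s$case_fraction) < s$case_fraction + 1e-14))
  }
  succeed()
})

test_that("formula PAF equals the counterfactual case deficit with risk ratios", {
  # explicit-population oracle: with risk ratios (not odds ratios) and
  # exact case fractions the summed PAF equals
  # (observed - expected-under-reference-risk) / observed, identically
  n_g <- c("e2/e2" = 500, "e2/e3" = 4000, "e2/e4" = 600,
           "e3/e3" = 30000, "e3/e4" = 9000, "e4/e4" = 700)
  r0 <- 0.004
  rr <- c("e2/e2" = 1, "e2/e3" = 1.1, "e2/e4" = 2.0,
          "e3/e3" = 1.3, "e3/e4" = 2.2, "e4/e4" = 3.5)
  cases_g <- n_g * r0 * rr
  observed <- sum(cases_g)
  expected_ref <- sum(n_g) * r0
  s <- data.frame(genotype = names(n_g)[-1], or = unname(rr[-1]),
                  case_fraction = unname(cases_g[-1]) / observed)
  expect_equal(joint_paf(s), (observed - expected_ref) / observed,
               tolerance = 1e-12)

  # with odds ratios from the 2x2 tables the identity holds to the
  # rare-disease approximation
  odds <- (cases_g / (n_g - cases_g))
  or_vec <- unname(odds / odds[["e2/e2"]])[-1]
  s_or <- s
  s_or$or <- or_vec
  expect_equal(joint_paf(s_or), (observed - expected_ref) / observed,
               tolerance = 0.02)
})

test_that("the end-to-end wrapper composes the primitive operations", {
  fits <- data.frame(term = c("e3/e3", "e3/e4", "e4/e4", "e2/e3", "e2/e4"),
                     estimate = log(c(2, 3, 5, 1.5, 4)),
                     se = c(0.1, 0.12, 0.3, 0.2, 0.35),
                     stringsAsFactors = FALSE)
  counts <- c("e2/e2" = 10, "e3/e3" = 671, "e3/e4" = 216.6, "e4/e4" = 32.6,
              "e2/e3" = 63.5, "e2/e4" = 14.7)
  paf <- paf_from_fits(fits, counts)
  s <- paf$strata
  expect_equal(paf$joint$paf, joint_paf(s), tolerance = 1e-15)
  w <- allele_weight(s$or[s$genotype == "e2/e4"], s$or[s$genotype == "e2/e3"])
  manual <- allele_paf(s, w)
  expect_equal(paf$e4$paf, manual$paf_e4, tolerance = 1e-15)
  expect_equal(paf$e3$paf, manual$paf_e3, tolerance = 1e-15)
  expect_equal(paf$weight$point, w, tolerance = 1e-15)
  # reference stratum contributes nothing: case fractions include it but
  # only the five exposed strata enter the sum
  expect_equal(sum(s$case_fraction) + 10 / sum(counts), 1, tolerance = 1e-12)

  expect_error(paf_from_fits(fits[-2, ], counts), "e3/e4")
})
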