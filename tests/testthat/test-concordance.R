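test_that("Cohen's kappa matches hand-computed and library values", {
  v <- vectorsFromTable(10, 5, 3, 82)
  k <- cohensKappa(v$x, v$y, method = "asymptotic")
  # p_o = 0.92, p_e = 0.759 -> kappa = 0.161/0.241
  expect_equal(k$estimate, (0.92 - 0.759) / (1 - 0.759), tolerance = 1e-12)
  expect_equal(unname(k$table), c(10, 5, 3, 82))
  expect_lt(k$p_value, 0.001)

  x <- rep(c(1, 0), 10)
  expect_equal(cohensKappa(x, x, method = "asymptotic")$estimate, 1)
  expect_equal(cohensKappa(x, 1 - x, method = "asymptotic")$estimate, -1)
  # degenerate chance agreement: undefined, not a number
  expect_true(is.na(cohensKappa(rep(1, 10), rep(1, 10))$estimate))

  skip_if_not_installed("e1071")
  set.seed(11)
  for (i in 1:20) {
    x <- rbinom(60, 1, 0.4)
    y <- as.integer((x + rbinom(60, 1, 0.3)) %% 2 == 0)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    ours <- cohensKappa(x, y, method = "asymptotic")$estimate
    ref <- e1071::classAgreement(table(x, y))$kappa
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("tau-b on binary data equals the phi coefficient", {
  v <- vectorsFromTable(3, 1, 2, 14)
  expect_equal(kendallTauB(v$x, v$y, method = "asymptotic")$estimate,
               40 / sqrt(4800), tolerance = 1e-12)
  x <- rep(c(1, 0), 8)
  expect_equal(kendallTauB(x, x, method = "asymptotic")$estimate, 1)
  expect_true(is.na(kendallTauB(rep(0, 9), rbinom(9, 1, .5))$estimate))

  # random spot-check of the closed form against the generic rank oracle
  set.seed(21)
  for (i in 1:20) {
    x <- rbinom(40, 1, 0.3); y <- rbinom(40, 1, 0.5)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendallTauB(x, y, method = "asymptotic")$estimate,
                 unname(cor(x, y, method = "kendall")), tolerance = 1e-10)
  }
})

test_that("tau-b handles tied count data like the standard rank routine", {
  set.seed(31)
  for (i in 1:15) {
    x <- rpois(50, 1.2); y <- pmin(x + rpois(50, 1), 6)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendallTauB(x, y, method = "asymptotic")$estimate,
                 unname(cor(x, y, method = "kendall")), tolerance = 1e-10)
  }
})

test_that("kappa and tau are symmetric in their arguments", {
  set.seed(41)
  x <- rbinom(50, 1, 0.4); y <- rbinom(50, 1, 0.3)
  expect_equal(cohensKappa(x, y, method = "asymptotic")$estimate,
               cohensKappa(y, x, method = "asymptotic")$estimate)
  expect_equal(kendallTauB(x, y, method = "asymptotic")$estimate,
               kendallTauB(y, x, method = "asymptotic")$estimate)
})

test_that("permutation p-values behave under the null and match asymptotics", {
  # null calibration: with heavily tied binary data the two-sided
  # permutation test is discrete and conservative, never anti-conservative
  set.seed(51)
  ps <- replicate(200, {
    x <- rbinom(40, 1, 0.4); y <- rbinom(40, 1, 0.4)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
    kendallTauB(x, y, nPerm = 199, seed = sample.int(1e6, 1))$p_value
  })
  ps <- ps[!is.na(ps)]
  expect_gte(mean(ps), 0.5)
  expect_lte(mean(ps <= 0.05), 0.08)
  expect_lte(mean(ps <= 0.25), 0.28)

  # agreement of the two p-value methods at pooled-cohort scale (n = 330)
  set.seed(61)
  x <- rbinom(330, 1, 0.12)
  y <- as.integer(runif(330) < ifelse(x == 1, 0.35, 0.12))
  tp <- kendallTauB(x, y, method = "permutation", nPerm = 20000, seed = 3)
  ta <- kendallTauB(x, y, method = "asymptotic")
  expect_lt(abs(tp$p_value - ta$p_value), 0.02)
  kp <- cohensKappa(x, y, method = "permutation", nPerm = 20000, seed = 3)
  ka <- cohensKappa(x, y, method = "asymptotic")
  expect_lt(abs(kp$p_value - ka$p_value), 0.02)
})

test_that("featureAgreement reports per-feature kappa and tau", {
  # duplicating one rater gives perfect agreement wherever defined
  a <- randomCohortLong(4, seed = 71, rater = "R1")
  b <- a; b$rater_id <- "R2"
  co <- cohortFromTable(rbind(a, b))
  fa <- featureAgreement(co, "R1", "R2", method = "asymptotic")
  defined <- !is.na(fa$kappa)
  expect_true(any(defined))
  expect_equal(fa$kappa[defined], rep(1, sum(defined)))
  expect_equal(fa$tau[!is.na(fa$tau)], rep(1, sum(!is.na(fa$tau))))
  expect_equal(nrow(fa), 10L)  # 7 features + 3 count variants
  expect_true(all(fa$n == 88L))

  # raters scoring different patients cannot be aligned
  c2 <- cohortFromTable(rbind(a, {
    d <- randomCohortLong(3, seed = 72, rater = "R2")
    d$ez <- a$ez[seq_len(nrow(d))]  # irrelevant; alignment fails first
    d
  }))
  expect_error(featureAgreement(c2, "R1", "R2", method = "asymptotic"),
               "identical \\(patient, ROI\\) keys")
})

test_that("ezAssociation pools seizure-free ROIs and recovers enrichment", {
  sim <- simulateCohort(simConfig(nPatients = 60, seed = 81))
  assoc <- ezAssociation(sim$truth, "latent", method = "asymptotic")
  expect_equal(nrow(assoc), 10L)
  expect_equal(unique(assoc$n), 60L * 22L)
  # enriched features associate positively with the EZ; cysts do not
  enriched <- c("calcification", "increased_thickness", "transmantle_sign")
  expect_true(all(assoc$tau[assoc$measure %in% enriched] > 0))
  expect_true(all(assoc$p_value[assoc$measure %in% enriched] < 0.001))
  expect_lt(abs(assoc$tau[assoc$measure == "cyst"]), 0.1)
  expect_gt(assoc$tau[assoc$measure == "n_abnormalities"], 0)
})
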