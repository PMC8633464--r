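test_that("rules validate and apply the at-least-t-of-S predicate", {
  expect_error(rule(c("tuber", "cyst"), 3), "threshold")
  expect_error(rule(character(), 1), "non-empty")
  expect_error(rule(c("tuber", "nonsense"), 1), "subset")

  obs <- setNames(as.list(rep(0, 7)), allFeatures())
  obs$tuber <- 1; obs$calcification <- 1
  expect_true(applyRule(rule(c("tuber", "calcification"), 2),
                        as.data.frame(obs)))
  empty <- as.data.frame(setNames(as.list(rep(0, 7)), allFeatures()))
  expect_false(applyRule(rule(c("calcification", "largest_fcd_area"), 1),
                         empty))

  # threshold monotonicity: what fires at t also fires at t - 1
  set.seed(101)
  m <- as.data.frame(matrix(rbinom(700, 1, 0.3), ncol = 7,
                            dimnames = list(NULL, allFeatures())))
  for (i in 1:10) {
    S <- sample(allFeatures(), sample(2:7, 1))
    t <- if (length(S) == 2) 2L else sample(2:length(S), 1)
    hi <- applyRule(rule(S, t), m)
    lo <- applyRule(rule(S, t - 1), m)
    expect_true(all(lo[hi]))
  }
})

test_that("evaluateRule scores 100%-PPV patients from hand-built fixtures", {
  # patient A: features only in the EZ ROI; patient B: in one EZ and one
  # non-EZ ROI -> exactly one perfect patient among the 44 ROIs
  a <- minimalLong("PA", ez_roi = "left.frontal_mesial")
  a <- setFeature(a, "tuber", "left.frontal_mesial")
  a <- setFeature(a, "calcification", "left.frontal_mesial")
  b <- minimalLong("PB", ez_roi = "left.temporal_mesial")
  for (roi in c("left.temporal_mesial", "right.occipital_mesial")) {
    b <- setFeature(b, "tuber", roi)
    b <- setFeature(b, "calcification", roi)
  }
  co <- cohortFromTable(rbind(a, b))
  r <- rule(c("tuber", "calcification"), 2)
  ev <- evaluateRule(r, co, "R1")
  expect_equal(ev$n_perfect, 1L)
  expect_equal(ev$per_patient$perfect, c(TRUE, FALSE))
  expect_equal(ev$per_patient$n_flagged, c(1L, 2L))
  expect_equal(ev$per_patient$fp, c(0L, 1L))

  # a rule that never fires is perfect nowhere
  ev0 <- evaluateRule(rule("cyst", 1), co, "R1")
  expect_equal(ev0$n_perfect, 0L)
  expect_true(all(ev0$per_patient$n_flagged == 0L))

  # strict reading: requires a unique flagged ROI
  multi <- minimalLong("PC", ez_roi = "left.frontal_mesial")
  multi$ez[2] <- 1L   # two-ROI EZ
  multi <- setFeature(multi, "tuber",
                      c("left.frontal_mesial", "left.frontal_lateral"))
  cm <- cohortFromTable(multi)
  expect_equal(evaluateRule(rule("tuber", 1), cm, "R1")$n_perfect, 1L)
  expect_equal(evaluateRule(rule("tuber", 1), cm, "R1",
                            perfect = "unique")$n_perfect, 0L)
})

test_that("searchRules enumerates exactly sum C(m,k)*k rules", {
  sim <- simulateCohort(simConfig(nPatients = 5, seed = 111))
  for (pool in list(allFeatures(), lesionFeatures(),
                    c("tuber", "calcification", "largest_fcd_area"))) {
    m <- length(pool)
    expected <- sum(choose(m, seq_len(m)) * seq_len(m))
    sr <- searchRules(sim$cohort, "rater_A", featurePool = pool)
    expect_equal(sr$n_rules, expected)
  }
  expect_equal(sum(choose(7, 1:7) * 1:7), 448L)
  expect_error(searchRules(sim$cohort, "rater_A", featurePool = character()),
               "non-empty")
})

test_that("searchRules agrees with an independent naive enumerator", {
  for (seed in c(121, 122)) {
    long <- randomCohortLong(6, seed = seed)
    co <- cohortFromTable(long)
    pool <- c("tuber", "calcification", "gwm_blurring", "largest_fcd_area")
    sr <- searchRules(co, "R1", featurePool = pool)
    naive <- naiveSearch(cohortTable(co), pool)
    key <- function(d) paste(d$features, d$threshold)
    naive_n <- setNames(naive$n_perfect, key(naive))
    expect_equal(sr$rules$n_perfect, unname(naive_n[key(sr$rules)]))
  }
})

test_that("rankings are stable under patient order and recover planted rules", {
  long <- randomCohortLong(8, seed = 131)
  co <- cohortFromTable(long)
  set.seed(132)
  shuffled <- cohortFromTable(long[sample(nrow(long)), ])
  a <- searchRules(co, "R1")
  b <- searchRules(shuffled, "R1")
  expect_equal(a$rules, b$rules)

  sim <- simulateCohort(noiselessConfig(12, 141))
  planted_rule <- rule(c("tuber", "transmantle_sign", "calcification"), 2)
  planted <- plantRule(sim, planted_rule)
  sr <- searchRules(planted$cohort, "rater_A")
  best <- max(sr$rules$n_perfect)
  expect_equal(best, 12L)
  hit <- sr$rules$features == "calcification+transmantle_sign+tuber" &
    sr$rules$threshold == 2L
  expect_equal(sum(hit), 1L)
  expect_equal(sr$rules$n_perfect[hit], 12L)
  expect_true(sr$rules$frontier[hit])
})

test_that("the frontier drops feature-superset rules with identical flags", {
  # only calcification is informative; adding a never-present feature to
  # the set cannot change any flag, so the larger rule is dominated
  long <- minimalLong(ez_roi = "left.frontal_mesial")
  long <- setFeature(long, "calcification", "left.frontal_mesial")
  co <- cohortFromTable(long)
  sr <- searchRules(co, "R1", featurePool = c("calcification", "cyst"))
  rules <- sr$rules
  small <- rules$features == "calcification" & rules$threshold == 1
  big <- rules$features == "calcification+cyst" & rules$threshold == 1
  expect_equal(rules$n_perfect[small], 1L)
  expect_equal(rules$n_perfect[big], 1L)
  expect_true(rules$frontier[small])
  expect_false(rules$frontier[big])
})
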