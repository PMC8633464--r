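# Independent oracles, kept free of the code paths they check.

# phi coefficient of a 2x2 table (a = both pos, b = x only, c = y only, d)
phiOracle <- function(a, b, c, d) {
  den <- sqrt(a + b) * sqrt(c + d) * sqrt(a + c) * sqrt(b + d)
  if (den == 0) return(NA_real_)
  (a * d - b * c) / den
}

# paired binary vectors realizing a 2x2 table
vectorsFromTable <- function(a, b, c, d) {
  list(x = rep(c(1, 1, 0, 0), c(a, b, c, d)),
       y = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}

# expected 2x2 joint cell probabilities for two raters scoring a latent
# Bernoulli(p) feature with independent per-rater fp/fn flip rates
flipJoint <- function(p, flA, flB) {
  q1A <- 1 - flA[["fn"]]; q0A <- flA[["fp"]]
  q1B <- 1 - flB[["fn"]]; q0B <- flB[["fp"]]
  c(p11 = p * q1A * q1B + (1 - p) * q0A * q0B,
    p10 = p * q1A * (1 - q1B) + (1 - p) * q0A * (1 - q0B),
    p01 = p * (1 - q1A) * q1B + (1 - p) * (1 - q0A) * q0B,
    p00 = p * (1 - q1A) * (1 - q1B) + (1 - p) * (1 - q0A) * (1 - q0B))
}

# closed-form Cohen kappa and its large-sample variance (Fleiss, Cohen &
# Everitt) from 2x2 cell probabilities
kappaFromJoint <- function(pr, n) {
  pA <- pr[["p11"]] + pr[["p10"]]
  pB <- pr[["p11"]] + pr[["p01"]]
  po <- pr[["p11"]] + pr[["p00"]]
  pe <- pA * pB + (1 - pA) * (1 - pB)
  k <- (po - pe) / (1 - pe)
  A <- pr[["p11"]] * (1 - (pA + pB) * (1 - k))^2 +
    pr[["p00"]] * (1 - ((1 - pA) + (1 - pB)) * (1 - k))^2
  B <- (1 - k)^2 * (pr[["p10"]] * (pB + (1 - pA))^2 +
                      pr[["p01"]] * (pA + (1 - pB))^2)
  C <- (k - pe * (1 - k))^2
  list(kappa = k, se = sqrt((A + B - C) / (n * (1 - pe)^2)))
}

# latent mixture prevalence of a feature under a SimulationConfig
mixturePrev <- function(config, feature) {
  w <- sum(config@ezSizeDist * 1:4) / 22
  p0 <- config@baselinePrev[[feature]]
  p1 <- plogis(qlogis(p0) + log(config@ezOddsRatio[[feature]]))
  if (p0 == 0) p1 <- 0
  w * p1 + (1 - w) * p0
}

# observed (post-flip) prevalence for one rater
observedPrev <- function(config, feature, rater) {
  p <- mixturePrev(config, feature)
  fl <- config@raterFlip[[rater]]
  p * (1 - fl[["fn"]]) + (1 - p) * fl[["fp"]]
}

# Naive "at least t of S" enumerator over a long observation table, written
# as per-ROI loops over named feature vectors, independent of searchRules'
# matrix-plus-rowsum arithmetic.
naiveSearch <- function(long, pool, perfect = "any") {
  patients <- unique(long$patient_id)
  rois_of <- lapply(patients, function(p) {
    sub <- long[long$patient_id == p, ]
    lapply(seq_len(nrow(sub)), function(r)
      list(feat = unlist(sub[r, allFeatures()]), ez = sub$ez[r] == 1))
  })
  out <- list()
  k <- 0L
  for (sz in seq_along(pool)) {
    for (S in combn(sort(pool), sz, simplify = FALSE)) {
      for (t in seq_len(sz)) {
        nPerfect <- 0L
        for (pr in rois_of) {
          nFlag <- 0L; fp <- 0L
          for (ro in pr) {
            if (sum(ro$feat[S]) >= t) {
              nFlag <- nFlag + 1L
              if (!ro$ez) fp <- fp + 1L
            }
          }
          ok <- if (perfect == "unique") nFlag == 1L && fp == 0L
          else nFlag >= 1L && fp == 0L
          if (ok) nPerfect <- nPerfect + 1L
        }
        k <- k + 1L
        out[[k]] <- data.frame(features = paste(S, collapse = "+"),
                               threshold = t, n_perfect = nPerfect,
                               stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# noise-free two-rater simulation settings used by recovery tests
noiselessConfig <- function(nPatients, seed) {
  simConfig(nPatients = nPatients, seed = seed,
            raterFlip = list(rater_A = c(fp = 0, fn = 0),
                             rater_B = c(fp = 0, fn = 0)))
}
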