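# run expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed)
    old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration with study-like defaults
#'
#' Builds a validated [SimulationConfig-class]. The defaults emulate the
#' structure of a surgical TSC cohort: 28 patients, per-ROI baseline
#' prevalences matching whole-cohort ROI positivity of the six lesion
#' features (tubers 30.3%, cysts 1.8%, calcifications 2.1%, increased
#' thickness 5.5%, gray-white matter blurring 17.9%, transmantle sign
#' 10.6%), an epileptogenic-zone size distribution over 1-4 ROIs derived
#' from the mix of focal, lobar, multilobar and hemispheric resections
#' (18:5:4:1), EZ enrichment of every feature except cysts (odds ratios >
#' 1; cysts 1, i.e. no association), and two raters whose false-positive /
#' false-negative scoring rates yield fair-to-substantial agreement. All
#' simulated patients are seizure-free: only the resected-and-seizure-free
#' patients define the EZ, and incomplete resections are not modelled.
#'
#' @param nPatients number of patients.
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @param baselinePrev named per-feature Bernoulli probability of a non-EZ
#'   ROI carrying the feature.
#' @param ezOddsRatio named per-feature multiplicative odds change inside
#'   the EZ, so within-EZ probabilities never leave \[0, 1\].
#' @param ezSizeDist probabilities of EZ sizes 1-4 ROIs.
#' @param raterFlip named list; per rater, `c(fp = , fn = )` scoring error
#'   rates applied independently per feature per ROI.
#' @return a validated [SimulationConfig-class].
#' @export
simConfig <- function(nPatients = 28L,
                      seed = 1L,
                      baselinePrev = c(
                        tuber = 0.303, cyst = 0.018, calcification = 0.021,
                        increased_thickness = 34 / 616,
                        gwm_blurring = 0.179, transmantle_sign = 0.106),
                      ezOddsRatio = c(
                        tuber = 4, cyst = 1, calcification = 12,
                        increased_thickness = 10, gwm_blurring = 4,
                        transmantle_sign = 6),
                      ezSizeDist = c(18, 5, 4, 1) / 28,
                      raterFlip = list(
                        rater_A = c(fp = 0.02, fn = 0.12),
                        rater_B = c(fp = 0.03, fn = 0.18))) {
  new("SimulationConfig",
      nPatients = as.integer(nPatients), seed = as.integer(seed),
      baselinePrev = baselinePrev[.LESION_FEATURES],
      ezOddsRatio = ezOddsRatio[.LESION_FEATURES],
      ezSizeDist = ezSizeDist, raterFlip = raterFlip)
}

# largest-FCD-area designation: argmax of FCD-like feature count per scan,
# no designation when all counts are zero, ties broken by a seeded draw
.assignLargestArea <- function(feat) {
  cnt <- feat$increased_thickness + feat$gwm_blurring + feat$transmantle_sign
  la <- matrix(FALSE, nrow = nrow(cnt), ncol = ncol(cnt))
  for (j in seq_len(ncol(cnt))) {
    m <- max(cnt[, j])
    if (m >= 1L) {
      cands <- which(cnt[, j] == m)
      pick <- if (length(cands) == 1L) cands else
        cands[sample.int(length(cands), 1L)]
      la[pick, j] <- TRUE
    }
  }
  la
}

.longFromMatrices <- function(feat, largest, ez, patients, rater) {
  n <- length(patients)
  rt <- roiTable()
  out <- data.frame(
    patient_id = rep(patients, each = 22L),
    rater_id = rater,
    hemisphere = rep(rt$hemisphere, times = n),
    region = rep(rt$region, times = n),
    stringsAsFactors = FALSE
  )
  for (f in .LESION_FEATURES)
    out[[f]] <- as.integer(as.vector(feat[[f]]))
  out$largest_fcd_area <- as.integer(as.vector(largest))
  out$ez <- as.integer(as.vector(ez))
  out$seizure_free <- 1L
  out
}

# observed scores + truth cohort from latent features (RNG already seeded)
.assembleSim <- function(latent, ez, config) {
  n <- config@nPatients
  patients <- sprintf("P%03d", seq_len(n))
  truth_long <- .longFromMatrices(latent, .assignLargestArea(latent), ez,
                                  patients, "latent")
  obs_long <- lapply(names(config@raterFlip), function(r) {
    fl <- config@raterFlip[[r]]
    observed <- lapply(latent, function(m) {
      u <- matrix(runif(length(m)), nrow = nrow(m))
      (m & u >= fl[["fn"]]) | (!m & u < fl[["fp"]])
    })
    .longFromMatrices(observed, .assignLargestArea(observed), ez, patients, r)
  })
  list(cohort = cohortFromTable(do.call(rbind, obs_long)),
       truth = cohortFromTable(truth_long))
}

#' Generate a synthetic rater-scored cohort
#'
#' Draws a cohort under the generative model of [simConfig()]: (1) an EZ
#' ROI set per patient, sized by `ezSizeDist` and placed uniformly among
#' the 22 ROIs (spatial contiguity is not modelled — no downstream
#' statistic depends on it); (2) latent per-ROI features, Bernoulli with
#' baseline probability outside the EZ and odds multiplied by
#' `ezOddsRatio` inside it, independent across features; (3) per rater,
#' each latent feature flipped with the rater's false-positive /
#' false-negative rates; (4) the largest-FCD-area ROI designated per scan
#' as the argmax of the FCD-like feature count, ties broken by a seeded
#' draw.
#'
#' @param config a [SimulationConfig-class], see [simConfig()].
#' @return list with `cohort` (observed [TscCohort-class], one column per
#'   patient x rater), `truth` (noise-free [TscCohort-class] with the
#'   single pseudo-rater `"latent"`), `latent` (list of six 22 x n logical
#'   matrices), `ez` (22 x n logical matrix) and `config`.
#' @examples
#' sim <- simulateCohort(simConfig(nPatients = 5, seed = 42))
#' sim$cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, {
    n <- config@nPatients
    ez <- matrix(FALSE, nrow = 22L, ncol = n)
    sizes <- sample.int(4L, n, replace = TRUE, prob = config@ezSizeDist)
    for (j in seq_len(n))
      ez[sample.int(22L, sizes[j]), j] <- TRUE
    latent <- lapply(setNames(nm = .LESION_FEATURES), function(f) {
      p0 <- config@baselinePrev[[f]]
      p1 <- plogis(qlogis(p0) + log(config@ezOddsRatio[[f]]))
      if (p0 == 0) p1 <- 0       # qlogis(0) = -Inf; zero stays zero
      if (p0 == 1) p1 <- 1
      p <- ifelse(ez, p1, p0)
      matrix(runif(22L * n) < p, nrow = 22L)
    })
    c(.assembleSim(latent, ez, config),
      list(latent = latent, ez = ez, config = config))
  })
}

#' Plant a decision rule into a simulated cohort
#'
#' Edits the latent features of a simulated cohort so that the rule holds
#' exactly on the epileptogenic zone: every EZ ROI satisfies "at least t of
#' S" and no non-EZ ROI does. Edits are minimal and touch only features in
#' the rule's set: absent features are switched on (in name order) in EZ
#' ROIs until the threshold is met, and present ones switched off in
#' non-EZ ROIs until the count drops below it. Rater noise and the
#' largest-area designation are then re-applied under a seed derived from
#' the config seed.
#'
#' Only the six lesion features can be planted: `largest_fcd_area` is a
#' derived per-scan designation, so a per-ROI guarantee cannot be enforced
#' by editing features, and rules naming it are rejected as infeasible.
#'
#' @param sim result of [simulateCohort()].
#' @param rule a [Rule-class], see [rule()].
#' @return a list of the same shape as [simulateCohort()]'s, with edited
#'   latent features and re-scored cohorts.
#' @examples
#' sim <- simulateCohort(simConfig(nPatients = 5, seed = 7))
#' planted <- plantRule(sim, rule(c("tuber", "calcification"), 2))
#' evaluateRule(rule(c("tuber", "calcification"), 2),
#'              planted$truth, "latent")
#' @export
plantRule <- function(sim, rule) {
  stopifnot(is(rule, "Rule"))
  validObject(rule)
  if (!all(rule@features %in% .LESION_FEATURES))
    stop("infeasible rule: only the six lesion features can be planted",
         call. = FALSE)
  latent <- sim$latent
  ez <- sim$ez
  s <- sort(rule@features)
  t <- rule@threshold
  cnt <- Reduce(`+`, latent[s])
  for (f in s) {               # raise EZ ROIs to the threshold
    need <- ez & cnt < t & !latent[[f]]
    latent[[f]][need] <- TRUE
    cnt[need] <- cnt[need] + 1L
  }
  for (f in s) {               # push non-EZ ROIs below the threshold
    drop <- !ez & cnt >= t & latent[[f]]
    latent[[f]][drop] <- FALSE
    cnt[drop] <- cnt[drop] - 1L
  }
  config <- sim$config
  .withSeed(config@seed + 1L,
            c(.assembleSim(latent, ez, config),
              list(latent = latent, ez = ez, config = config)))
}
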