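# Builders for small hand-made cohorts, kept independent of the package's
# simulator so fixture structure is fully explicit.

# one patient x one rater, all features absent, one EZ ROI
minimalLong <- function(patient = "P1", rater = "R1",
                        ez_roi = "left.frontal_mesial",
                        seizure_free = 1L) {
  rt <- roiTable()
  df <- data.frame(
    patient_id = patient, rater_id = rater,
    hemisphere = rt$hemisphere, region = rt$region,
    tuber = 0L, cyst = 0L, calcification = 0L, increased_thickness = 0L,
    gwm_blurring = 0L, transmantle_sign = 0L, largest_fcd_area = 0L,
    ez = as.integer(rownames(rt) == ez_roi),
    seizure_free = seizure_free,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

# set a feature in given ROIs (by canonical key) of a long table
setFeature <- function(long, feature, rois,
                       patient = long$patient_id[1L],
                       rater = long$rater_id[1L]) {
  key <- paste(long$hemisphere, long$region, sep = ".")
  hit <- long$patient_id == patient & long$rater_id == rater & key %in% rois
  long[[feature]][hit] <- 1L
  long
}

# single-rater cohort realizing exact patient-level and ROI-level positive
# counts per feature (ROI positives distributed round-robin over the
# positive patients); used for printed-arithmetic checks
countsCohortLong <- function(nPatients, spec, rater = "R1") {
  longs <- lapply(seq_len(nPatients), function(i)
    minimalLong(sprintf("P%02d", i), rater))
  for (f in names(spec)) {
    np <- spec[[f]]["patients"]
    nr <- spec[[f]]["rois"]
    stopifnot(nr >= np, nr <= np * 22)
    slot <- integer(nPatients)          # next free ROI index per patient
    for (k in seq_len(nr)) {
      p <- (k - 1L) %% np + 1L
      slot[p] <- slot[p] + 1L
      longs[[p]] <- setFeature(longs[[p]], f, roiKeys()[slot[p]])
    }
  }
  # keep the largest-area contract: one designation wherever FCD-like
  # features were placed
  longs <- lapply(longs, function(lg) {
    if (any(lg$increased_thickness | lg$gwm_blurring | lg$transmantle_sign))
      lg$largest_fcd_area[1L] <- 1L
    lg
  })
  do.call(rbind, longs)
}

# random small cohort as a plain long table (independent of simulateCohort)
randomCohortLong <- function(nPatients, seed, rater = "R1",
                             pFeature = 0.25, pEz = 2 / 22) {
  set.seed(seed)
  longs <- lapply(seq_len(nPatients), function(i) {
    lg <- minimalLong(sprintf("P%02d", i), rater,
                      ez_roi = sample(roiKeys(), 1L))
    for (f in lesionFeatures())
      lg[[f]] <- rbinom(22L, 1L, pFeature)
    extra_ez <- runif(22L) < pEz
    lg$ez <- as.integer(lg$ez | extra_ez)
    if (any(lg$increased_thickness | lg$gwm_blurring | lg$transmantle_sign)) {
      cnt <- lg$increased_thickness + lg$gwm_blurring + lg$transmantle_sign
      lg$largest_fcd_area[which.max(cnt)] <- 1L
    }
    lg
  })
  do.call(rbind, longs)
}
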