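# Feature and ROI vocabularies ------------------------------------------

.REGIONS <- c(
  "frontal_mesial", "frontal_lateral", "frontal_polar", "frontal_basal",
  "frontal_central", "temporal_mesial", "temporal_lateral",
  "parietal_mesial", "parietal_lateral", "occipital_mesial",
  "occipital_lateral"
)

.HEMISPHERES <- c("left", "right")

.LESION_FEATURES <- c(
  "tuber", "cyst", "calcification", "increased_thickness",
  "gwm_blurring", "transmantle_sign"
)

# FCD-like features drive the largest-affected-area designation
.FCD_FEATURES <- c("increased_thickness", "gwm_blurring", "transmantle_sign")

.ALL_FEATURES <- c(.LESION_FEATURES, "largest_fcd_area")

.ASSAY_NAMES <- c(.ALL_FEATURES, "ez")

.COHORT_COLUMNS <- c(
  "patient_id", "rater_id", "hemisphere", "region", .ALL_FEATURES,
  "ez", "seizure_free"
)

#' Feature and region vocabularies
#'
#' The scoring scheme uses a fixed vocabulary: 22 cortical regions of
#' interest (11 per hemisphere) and seven binary features per ROI. The six
#' lesion features are scored freely per ROI; `largest_fcd_area` marks, per
#' patient and rater, the single ROI judged to contain the most extensive
#' FCD-like change.
#'
#' @return `lesionFeatures()`, `fcdFeatures()` and `allFeatures()` return
#'   character vectors of feature names; `roiKeys()` returns the 22
#'   canonical ROI identifiers (`"<hemisphere>.<region>"`); `roiTable()`
#'   returns a 22-row data frame with `hemisphere` and `region` columns.
#' @examples
#' allFeatures()
#' head(roiTable())
#' @export
lesionFeatures <- function() .LESION_FEATURES

#' @rdname lesionFeatures
#' @export
fcdFeatures <- function() .FCD_FEATURES

#' @rdname lesionFeatures
#' @export
allFeatures <- function() .ALL_FEATURES

#' @rdname lesionFeatures
#' @export
roiTable <- function() {
  data.frame(
    hemisphere = rep(.HEMISPHERES, each = length(.REGIONS)),
    region = rep(.REGIONS, times = 2),
    row.names = paste(rep(.HEMISPHERES, each = length(.REGIONS)),
                      rep(.REGIONS, times = 2), sep = "."),
    stringsAsFactors = FALSE
  )
}

#' @rdname lesionFeatures
#' @export
roiKeys <- function() rownames(roiTable())

# TscCohort --------------------------------------------------------------

#' Rater-scored ROI cohort container
#'
#' `TscCohort` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' a cohort of rater-scored MRI grids. Rows are the 22 canonical cortical
#' ROIs; each column is one scored scan, i.e. one (patient, rater) pair;
#' assays are logical 22 x n matrices, one per feature plus `ez` (the
#' epileptogenic-zone label, identical across raters of the same patient
#' because it records the resected area, not a rater judgment). Column
#' metadata carries `patient_id`, `rater_id` and `seizure_free`.
#'
#' Validity enforces the scoring contract: complete 22-ROI grids, no
#' missing feature values, at most one largest-FCD-area ROI per scan and
#' exactly one whenever any FCD-like feature (increased thickness,
#' gray-white matter blurring, transmantle sign) is scored for that scan,
#' EZ labels consistent across raters, and at least one EZ ROI for every
#' seizure-free patient.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [readCohort()], [cohortFromTable()], [simulateCohort()]
#' @aliases TscCohort
#' @export
setClass("TscCohort", contains = "SummarizedExperiment")

.validTscCohort <- function(object) {
  msgs <- character()
  if (!identical(rownames(object), roiKeys()))
    msgs <- c(msgs, "rows must be the 22 canonical ROIs in canonical order")
  if (!setequal(assayNames(object), .ASSAY_NAMES))
    msgs <- c(msgs, sprintf("assays must be exactly: %s",
                            paste(.ASSAY_NAMES, collapse = ", ")))
  cd <- colData(object)
  needed <- c("patient_id", "rater_id", "seizure_free")
  if (!all(needed %in% colnames(cd)))
    return(c(msgs, "colData must contain patient_id, rater_id, seizure_free"))
  if (length(msgs))
    return(msgs)
  for (a in .ASSAY_NAMES) {
    m <- assay(object, a)
    if (!is.logical(m) || anyNA(m))
      msgs <- c(msgs, sprintf("assay '%s' must be logical without NAs", a))
  }
  if (length(msgs))
    return(msgs)
  key <- paste(cd$patient_id, cd$rater_id)
  if (anyDuplicated(key))
    msgs <- c(msgs, "duplicate (patient, rater) scan columns")
  # largest_fcd_area: <= 1 per scan, exactly 1 when FCD-like features present
  la <- colSums(assay(object, "largest_fcd_area"))
  fcd <- colSums(assay(object, "increased_thickness") |
                   assay(object, "gwm_blurring") |
                   assay(object, "transmantle_sign"))
  if (any(la > 1L))
    msgs <- c(msgs, "more than one largest_fcd_area ROI in a (patient, rater) scan")
  if (any(fcd > 0L & la != 1L))
    msgs <- c(msgs,
              "scans with FCD-like features must designate exactly one largest_fcd_area ROI")
  # ez and seizure_free are patient-level
  ez <- assay(object, "ez")
  for (p in unique(cd$patient_id)) {
    idx <- which(cd$patient_id == p)
    if (length(unique(cd$seizure_free[idx])) > 1L)
      msgs <- c(msgs, sprintf("seizure_free differs across raters for patient '%s'", p))
    if (length(idx) > 1L &&
        !all(ez[, idx] == ez[, idx[1L]]))
      msgs <- c(msgs, sprintf("ez labels differ across raters for patient '%s'", p))
    if (isTRUE(cd$seizure_free[idx[1L]]) && !any(ez[, idx[1L]]))
      msgs <- c(msgs, sprintf("seizure-free patient '%s' has no EZ ROI", p))
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("TscCohort", .validTscCohort)

# SimulationConfig -------------------------------------------------------

#' Synthetic-cohort simulation parameters
#'
#' Parameters of the generative model behind [simulateCohort()]: per-ROI
#' baseline Bernoulli prevalences for the six lesion features, a per-feature
#' odds ratio applied inside the epileptogenic zone, a distribution of EZ
#' sizes (in ROIs), and per-rater false-positive / false-negative scoring
#' rates. See [simConfig()] for defaults and their rationale.
#'
#' @slot nPatients integer, number of simulated patients.
#' @slot seed integer seed; identical config and seed give a bit-identical
#'   cohort.
#' @slot baselinePrev named numeric, per-feature Bernoulli probability for a
#'   non-EZ ROI.
#' @slot ezOddsRatio named numeric, multiplicative odds change inside the EZ.
#' @slot ezSizeDist numeric of length 4, probabilities of EZ sizes 1-4 ROIs.
#' @slot raterFlip named list, per rater a numeric `c(fp, fn)` of
#'   false-positive and false-negative scoring rates.
#' @export
setClass("SimulationConfig", representation(
  nPatients = "integer",
  seed = "integer",
  baselinePrev = "numeric",
  ezOddsRatio = "numeric",
  ezSizeDist = "numeric",
  raterFlip = "list"
))

.validSimulationConfig <- function(object) {
  msgs <- character()
  if (length(object@nPatients) != 1L || is.na(object@nPatients) ||
      object@nPatients < 1L)
    msgs <- c(msgs, "nPatients must be a single integer >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (!setequal(names(object@baselinePrev), .LESION_FEATURES))
    msgs <- c(msgs, "baselinePrev must name the six lesion features")
  else if (any(object@baselinePrev < 0 | object@baselinePrev > 1))
    msgs <- c(msgs, "baselinePrev values must lie in [0, 1]")
  if (!setequal(names(object@ezOddsRatio), .LESION_FEATURES))
    msgs <- c(msgs, "ezOddsRatio must name the six lesion features")
  else if (any(object@ezOddsRatio <= 0))
    msgs <- c(msgs, "ezOddsRatio values must be positive")
  if (length(object@ezSizeDist) != 4L || any(object@ezSizeDist < 0) ||
      abs(sum(object@ezSizeDist) - 1) > 1e-8)
    msgs <- c(msgs, "ezSizeDist must be 4 probabilities summing to 1")
  if (length(object@raterFlip) < 1L || is.null(names(object@raterFlip)))
    msgs <- c(msgs, "raterFlip must be a named list with at least one rater")
  else {
    ok <- vapply(object@raterFlip, function(fl) {
      is.numeric(fl) && all(c("fp", "fn") %in% names(fl)) &&
        all(fl[c("fp", "fn")] >= 0 & fl[c("fp", "fn")] <= 1)
    }, logical(1))
    if (!all(ok))
      msgs <- c(msgs, "each raterFlip entry needs fp and fn rates in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("SimulationConfig", .validSimulationConfig)

# Rule -------------------------------------------------------------------

#' An "at least t of feature set S" decision rule
#'
#' A rule flags an ROI when at least `threshold` of its `features` are
#' present. This is the hypothesis family searched exhaustively by
#' [searchRules()]: e.g. "at least 2 of {calcification, largest_fcd_area,
#' tuber}".
#'
#' @slot features character, a non-empty subset of [allFeatures()].
#' @slot threshold integer, 1 <= threshold <= number of features.
#' @seealso [rule()], [applyRule()], [evaluateRule()]
#' @export
setClass("Rule", representation(features = "character",
                                threshold = "integer"))

.validRule <- function(object) {
  msgs <- character()
  if (length(object@features) < 1L ||
      !all(object@features %in% .ALL_FEATURES))
    msgs <- c(msgs, sprintf("features must be a non-empty subset of {%s}",
                            paste(.ALL_FEATURES, collapse = ", ")))
  if (anyDuplicated(object@features))
    msgs <- c(msgs, "features must be distinct")
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 1L || object@threshold > length(object@features))
    msgs <- c(msgs, "threshold must satisfy 1 <= threshold <= |features|")
  if (length(msgs)) msgs else TRUE
}

setValidity("Rule", .validRule)
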