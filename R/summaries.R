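# round half away from zero, the convention used for all reported
# percentages (base round() rounds half to even)
.roundHalfAway <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Count abnormalities in an ROI observation
#'
#' Number of positive features per ROI, the basis of the abnormality-
#' multiplicity summaries and of the derived "number of abnormalities"
#' agreement rows. By default counts the six lesion features; the
#' largest-FCD-area designation can be added and calcifications dropped,
#' giving the three reported count variants.
#'
#' @param features a named logical (or 0/1) vector, matrix or data frame
#'   whose names/columns include the seven feature names.
#' @param includeLargestArea add `largest_fcd_area` to the count.
#' @param excludeCalcifications drop `calcification` from the count.
#' @return integer vector of counts, one per observation (range 0-7).
#' @examples
#' countAbnormalities(c(tuber = TRUE, cyst = FALSE, calcification = TRUE,
#'   increased_thickness = FALSE, gwm_blurring = TRUE,
#'   transmantle_sign = FALSE, largest_fcd_area = TRUE))
#' @export
countAbnormalities <- function(features, includeLargestArea = FALSE,
                               excludeCalcifications = FALSE) {
  if (is.null(dim(features)))
    features <- as.data.frame(as.list(features))
  features <- as.data.frame(features)
  counted <- .LESION_FEATURES
  if (excludeCalcifications)
    counted <- setdiff(counted, "calcification")
  if (includeLargestArea)
    counted <- c(counted, "largest_fcd_area")
  missing_cols <- setdiff(counted, names(features))
  if (length(missing_cols))
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  m <- sapply(features[counted], as.logical)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  as.integer(rowSums(m))
}

#' Descriptive feature prevalence for one rater
#'
#' Patient-level and ROI-level prevalence of each of the six lesion
#' features, as a whole-cohort descriptive summary: a patient counts as
#' positive when any of their 22 ROIs carries the feature. Percentages are
#' rounded half-away-from-zero to one decimal. An abnormality-multiplicity
#' histogram (ROIs with 0, 1, ..., 6 of the lesion features) accompanies
#' the table.
#'
#' @param cohort a [TscCohort-class].
#' @param rater a rater identifier present in the cohort.
#' @return An object of class `PrevalenceSummary`: a list with `features`
#'   (data frame: feature, patients_positive, patients_total, patient_pct,
#'   rois_positive, rois_total, roi_pct), `multiplicity` (named integer
#'   vector over counts 0-6), `n_patients` and `n_rois`.
#' @examples
#' sim <- simulateCohort(simConfig(nPatients = 10, seed = 1))
#' prevalenceSummary(sim$cohort, "rater_A")
#' @export
prevalenceSummary <- function(cohort, rater) {
  long <- .raterLong(cohort, rater)
  n_rois <- nrow(long)
  pts <- unique(long$patient_id)
  n_patients <- length(pts)
  rows <- lapply(.LESION_FEATURES, function(f) {
    pos <- long[[f]]
    p_pos <- length(unique(long$patient_id[pos]))
    data.frame(
      feature = f,
      patients_positive = p_pos,
      patients_total = n_patients,
      patient_pct = .roundHalfAway(100 * p_pos / n_patients),
      rois_positive = sum(pos),
      rois_total = n_rois,
      roi_pct = .roundHalfAway(100 * sum(pos) / n_rois),
      stringsAsFactors = FALSE
    )
  })
  counts <- countAbnormalities(long[.ALL_FEATURES])
  mult <- setNames(tabulate(counts + 1L, nbins = 7L), as.character(0:6))
  structure(
    list(features = do.call(rbind, rows), multiplicity = mult,
         n_patients = n_patients, n_rois = n_rois, rater = rater),
    class = "PrevalenceSummary"
  )
}

#' @export
print.PrevalenceSummary <- function(x, ...) {
  cat(sprintf("Feature prevalence, rater '%s': %d patients, %d ROIs\n",
              x$rater, x$n_patients, x$n_rois))
  print(x$features, row.names = FALSE)
  cat("ROIs by number of abnormalities (0-6):\n")
  print(x$multiplicity)
  invisible(x)
}
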