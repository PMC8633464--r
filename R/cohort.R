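# Construction from the long tabular interchange format -----------------

.checkBinaryColumn <- function(x, name) {
  if (is.logical(x)) {
    if (anyNA(x)) stop(sprintf("column '%s' has a missing value at row %d",
                               name, which(is.na(x))[1L]), call. = FALSE)
    return(x)
  }
  bad <- is.na(x) | !(x %in% c(0, 1))
  if (any(bad))
    stop(sprintf("column '%s' has a non-binary value at row %d",
                 name, which(bad)[1L]), call. = FALSE)
  as.logical(x)
}

#' Build a cohort from a long observation table
#'
#' Converts a long table with one row per (patient, rater, ROI) observation
#' into a validated [TscCohort-class]. Row order is irrelevant: columns are
#' keyed by (patient, rater) and rows by the canonical ROI order, so any
#' permutation of the input rows yields an identical object.
#'
#' @param df data frame with columns `patient_id`, `rater_id`,
#'   `hemisphere` (left/right), `region` (one of the 11 region tokens, see
#'   [roiTable()]), the seven feature columns, `ez` and `seizure_free`.
#'   Binary columns accept 0/1 (or logical).
#' @return A [TscCohort-class] object.
#' @export
cohortFromTable <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad_hemi <- !(df$hemisphere %in% .HEMISPHERES)
  if (any(bad_hemi))
    stop(sprintf("unknown hemisphere '%s' at row %d",
                 df$hemisphere[which(bad_hemi)[1L]], which(bad_hemi)[1L]),
         call. = FALSE)
  bad_region <- !(df$region %in% .REGIONS)
  if (any(bad_region))
    stop(sprintf("unknown region '%s' at row %d",
                 df$region[which(bad_region)[1L]], which(bad_region)[1L]),
         call. = FALSE)
  for (cn in c(.ALL_FEATURES, "ez", "seizure_free"))
    df[[cn]] <- .checkBinaryColumn(df[[cn]], cn)

  df$patient_id <- as.character(df$patient_id)
  df$rater_id <- as.character(df$rater_id)
  roi <- paste(df$hemisphere, df$region, sep = ".")
  scan <- paste(df$patient_id, df$rater_id, sep = "\r")
  dup <- duplicated(paste(scan, roi))
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicate observation for patient '%s', rater '%s', ROI '%s'",
                 df$patient_id[i], df$rater_id[i], roi[i]), call. = FALSE)
  }

  scans <- sort(unique(scan))
  n_roi <- table(scan)[scans]
  if (any(n_roi != 22L)) {
    i <- which(n_roi != 22L)[1L]
    parts <- strsplit(scans[i], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("%d of 22 ROIs present for patient '%s', rater '%s'",
                 n_roi[i], parts[1L], parts[2L]), call. = FALSE)
  }

  col_of <- match(scan, scans)
  row_of <- match(roi, roiKeys())
  scan_names <- sub("\r", ".", scans, fixed = TRUE)
  assay_list <- lapply(c(.ALL_FEATURES, "ez"), function(cn) {
    m <- matrix(NA, nrow = 22L, ncol = length(scans),
                dimnames = list(roiKeys(), scan_names))
    m[cbind(row_of, col_of)] <- df[[cn]]
    m
  })
  names(assay_list) <- c(.ALL_FEATURES, "ez")

  first_row <- match(scans, scan)
  cd <- S4Vectors::DataFrame(
    patient_id = df$patient_id[first_row],
    rater_id = df$rater_id[first_row],
    seizure_free = df$seizure_free[first_row],
    row.names = scan_names
  )
  # seizure_free must be a patient property, not a row property
  for (cn in c("seizure_free")) {
    agg <- tapply(df[[cn]], scan, function(v) length(unique(v)))
    if (any(agg > 1L))
      stop(sprintf("column '%s' is not constant within a (patient, rater) scan",
                   cn), call. = FALSE)
  }

  se <- SummarizedExperiment(
    assays = assay_list,
    rowData = S4Vectors::DataFrame(roiTable()),
    colData = cd
  )
  colnames(se) <- rownames(cd)
  new("TscCohort", se)
}

#' Read or write a cohort CSV
#'
#' The interchange format is a UTF-8 CSV with a header row and one row per
#' (patient, rater, ROI) observation; binary columns are coded 0/1. Writing
#' then reading a cohort reproduces it field-for-field, and row order never
#' affects the parsed object.
#'
#' @param path path to a cohort CSV file.
#' @return `readCohort()` returns a [TscCohort-class]; `writeCohort()`
#'   invisibly returns `path`.
#' @examples
#' sim <- simulateCohort(simConfig(nPatients = 3, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' writeCohort(sim$cohort, f)
#' identicalCohorts(readCohort(f), sim$cohort)
#' @export
readCohort <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  cohortFromTable(read.csv(path, stringsAsFactors = FALSE))
}

#' @param cohort a [TscCohort-class].
#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "TscCohort"))
  write.csv(cohortTable(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Long observation table of a cohort
#'
#' @param cohort a [TscCohort-class].
#' @return data frame, one row per (patient, rater, ROI), in the
#'   interchange-column order; binary columns coded 0/1.
#' @export
cohortTable <- function(cohort) {
  cd <- colData(cohort)
  n <- ncol(cohort)
  rt <- roiTable()
  out <- data.frame(
    patient_id = rep(cd$patient_id, each = 22L),
    rater_id = rep(cd$rater_id, each = 22L),
    hemisphere = rep(rt$hemisphere, times = n),
    region = rep(rt$region, times = n),
    stringsAsFactors = FALSE
  )
  for (a in c(.ALL_FEATURES, "ez"))
    out[[a]] <- as.integer(as.vector(assay(cohort, a)))
  out$seizure_free <- rep(as.integer(cd$seizure_free), each = 22L)
  out[, .COHORT_COLUMNS]
}

# Accessors --------------------------------------------------------------

#' Cohort accessors
#'
#' @param cohort a [TscCohort-class].
#' @return `patientIds()` and `raterIds()` return sorted character vectors;
#'   `seizureFree()` a named logical vector per patient; `filterRater()`
#'   and `seizureFreeOnly()` return sub-cohorts; `identicalCohorts()` a
#'   logical scalar comparing two cohorts field-for-field.
#' @export
patientIds <- function(cohort) sort(unique(colData(cohort)$patient_id))

#' @rdname patientIds
#' @export
raterIds <- function(cohort) sort(unique(colData(cohort)$rater_id))

#' @rdname patientIds
#' @export
seizureFree <- function(cohort) {
  cd <- colData(cohort)
  i <- match(patientIds(cohort), cd$patient_id)
  setNames(cd$seizure_free[i], cd$patient_id[i])
}

#' @param rater a rater identifier present in the cohort.
#' @rdname patientIds
#' @export
filterRater <- function(cohort, rater) {
  keep <- colData(cohort)$rater_id == rater
  if (!any(keep))
    stop(sprintf("unknown rater '%s'", rater), call. = FALSE)
  cohort[, keep]
}

#' @rdname patientIds
#' @export
seizureFreeOnly <- function(cohort) {
  cohort[, colData(cohort)$seizure_free]
}

#' @param x,y two [TscCohort-class] objects.
#' @rdname patientIds
#' @export
identicalCohorts <- function(x, y) {
  isTRUE(all.equal(cohortTable(x), cohortTable(y), check.attributes = FALSE))
}

# One rater's observations in pooled long form; the workhorse layout for
# all downstream statistics. Rows ordered patient-major, canonical ROIs.
.raterLong <- function(cohort, rater, seizureFreeOnly = FALSE) {
  cd <- colData(cohort)
  idx <- which(cd$rater_id == rater)
  if (!length(idx))
    stop(sprintf("unknown rater '%s'", rater), call. = FALSE)
  idx <- idx[order(cd$patient_id[idx])]
  if (seizureFreeOnly) {
    idx <- idx[cd$seizure_free[idx]]
    if (!length(idx))
      stop("no seizure-free patients in cohort", call. = FALSE)
  }
  out <- data.frame(
    patient_id = rep(cd$patient_id[idx], each = 22L),
    roi = rep(roiKeys(), times = length(idx)),
    stringsAsFactors = FALSE
  )
  for (a in c(.ALL_FEATURES, "ez"))
    out[[a]] <- as.vector(assay(cohort, a)[, idx, drop = FALSE])
  out
}

setMethod("show", "TscCohort", function(object) {
  cd <- colData(object)
  cat(sprintf("TscCohort: %d patients x %d raters, %d scored scans (%d ROIs)\n",
              length(unique(cd$patient_id)), length(unique(cd$rater_id)),
              ncol(object), 22L * ncol(object)))
  cat(sprintf("  seizure-free patients: %d of %d\n",
              sum(seizureFree(object)), length(unique(cd$patient_id))))
  pos <- vapply(.ALL_FEATURES, function(a) sum(assay(object, a)), integer(1))
  cat("  positive ROI scores:",
      paste(sprintf("%s=%d", names(pos), pos), collapse = ", "), "\n")
  invisible(object)
})
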