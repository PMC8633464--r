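#' Confusion counts of a flag vector against the EZ label
#'
#' @param flagged,ez equal-length binary (logical or 0/1) vectors.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusionCounts <- function(flagged, ez) {
  flagged <- as.logical(flagged); ez <- as.logical(ez)
  if (length(flagged) != length(ez))
    stop("flagged and ez must have equal length", call. = FALSE)
  c(tp = sum(flagged & ez), fp = sum(flagged & !ez),
    tn = sum(!flagged & !ez), fn = sum(!flagged & ez))
}

.diagRow <- function(cc) {
  n <- sum(cc)
  pospred <- cc[["tp"]] + cc[["fp"]]
  data.frame(
    tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]], fn = cc[["fn"]],
    accuracy = 100 * (cc[["tp"]] + cc[["tn"]]) / n,
    # undefined (nothing flagged) is reported as NA, never as 0 or 100
    ppv = if (pospred > 0) 100 * cc[["tp"]] / pospred else NA_real_,
    fdr = if (pospred > 0) 100 * cc[["fp"]] / pospred else NA_real_
  )
}

#' Diagnostic metrics of each feature against the EZ
#'
#' Accuracy, positive predictive value and false discovery rate of each of
#' the seven binary features as an EZ flag, computed over the ROIs of
#' seizure-free patients only (in other patients the resected area need
#' not contain the EZ, so no reference label exists). `scope = "pooled"`
#' pools all ROIs into one confusion matrix per feature; `scope =
#' "per_patient"` computes the metrics per patient over that patient's 22
#' ROIs.
#'
#' PPV and FDR are complements (they sum to 100 whenever defined) and are
#' reported as `NA` when the feature flags no ROI at all, which for the
#' per-patient scope is common. Percentages are returned at full
#' precision; reports round them to integers.
#'
#' @param cohort a [TscCohort-class].
#' @param rater a rater identifier.
#' @param scope `"pooled"` or `"per_patient"`.
#' @return data frame with columns `feature`, (`patient_id` for the
#'   per-patient scope), `tp`, `fp`, `tn`, `fn`, `accuracy`, `ppv`, `fdr`;
#'   metric columns are percentages.
#' @export
featureDiagnostics <- function(cohort, rater,
                               scope = c("pooled", "per_patient")) {
  scope <- match.arg(scope)
  long <- .raterLong(cohort, rater, seizureFreeOnly = TRUE)
  if (scope == "pooled") {
    rows <- lapply(.ALL_FEATURES, function(f)
      cbind(data.frame(feature = f, stringsAsFactors = FALSE),
            .diagRow(confusionCounts(long[[f]], long$ez))))
  } else {
    rows <- list()
    for (p in unique(long$patient_id)) {
      sub <- long[long$patient_id == p, ]
      for (f in .ALL_FEATURES)
        rows[[paste(p, f)]] <- cbind(
          data.frame(patient_id = p, feature = f, stringsAsFactors = FALSE),
          .diagRow(confusionCounts(sub[[f]], sub$ez)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
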