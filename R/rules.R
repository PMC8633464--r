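#' Construct an "at least t of S" rule
#'
#' @param features character vector of feature names (subset of
#'   [allFeatures()]).
#' @param threshold integer, how many of `features` must be present for an
#'   ROI to be flagged.
#' @return a validated [Rule-class].
#' @examples
#' rule(c("calcification", "largest_fcd_area"), 1)
#' @export
rule <- function(features, threshold) {
  new("Rule", features = as.character(features),
      threshold = as.integer(threshold))
}

#' @describeIn rule human-readable form, e.g.
#'   `"at least 2 of {calcification, largest_fcd_area, tuber}"`.
#' @param x a [Rule-class].
#' @export
describeRule <- function(x) {
  sprintf("at least %d of {%s}", x@threshold,
          paste(sort(x@features), collapse = ", "))
}

setMethod("show", "Rule", function(object) {
  cat(describeRule(object), "\n")
  invisible(object)
})

#' Apply a rule to ROI observations
#'
#' An ROI is flagged when at least `threshold` of the rule's features are
#' present. Raising the threshold never adds flagged ROIs.
#'
#' @param rule a [Rule-class].
#' @param features a named logical/0-1 vector for one ROI, or a matrix /
#'   data frame with feature columns for many.
#' @return logical vector of flags.
#' @examples
#' applyRule(rule(c("tuber", "calcification"), 2),
#'           c(tuber = 1, calcification = 1))
#' @export
applyRule <- function(rule, features) {
  stopifnot(is(rule, "Rule"))
  validObject(rule)
  if (is.null(dim(features)))
    features <- as.data.frame(as.list(features))
  features <- as.data.frame(features)
  missing_cols <- setdiff(rule@features, names(features))
  if (length(missing_cols))
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  m <- sapply(features[rule@features], as.logical)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  rowSums(m) >= rule@threshold
}

.perPatientEval <- function(flagged, ez, patient, perfect = c("any", "unique")) {
  perfect <- match.arg(perfect)
  patient <- factor(patient, levels = unique(patient))
  agg <- rowsum(cbind(n_flagged = as.integer(flagged),
                      tp = as.integer(flagged & ez),
                      fp = as.integer(flagged & !ez)),
                patient, reorder = FALSE)
  out <- data.frame(patient_id = rownames(agg), agg,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$perfect <- if (perfect == "unique")
    out$n_flagged == 1L & out$fp == 0L
  else
    out$n_flagged >= 1L & out$fp == 0L
  out
}

#' Evaluate a rule against the EZ, patient by patient
#'
#' For each seizure-free patient, the rule is applied to their 22 ROIs and
#' judged "perfect" when it achieves 100% within-patient positive
#' predictive value: at least one ROI flagged and every flagged ROI inside
#' the EZ (`perfect = "any"`, the default). The stricter reading — exactly
#' one flagged ROI, which is an EZ ROI — is available as `perfect =
#' "unique"`.
#'
#' @param rule a [Rule-class].
#' @param cohort a [TscCohort-class].
#' @param rater a rater identifier.
#' @param perfect `"any"` (>= 1 flagged, no false positive) or `"unique"`
#'   (exactly 1 flagged, no false positive).
#' @return a `RuleEvaluation`: list with `rule`, `per_patient` (data frame:
#'   patient_id, n_flagged, tp, fp, perfect), `n_perfect` and `n_patients`.
#' @examples
#' sim <- simulateCohort(simConfig(nPatients = 6, seed = 3))
#' planted <- plantRule(sim, rule(c("tuber", "transmantle_sign"), 2))
#' evaluateRule(rule(c("tuber", "transmantle_sign"), 2),
#'              planted$truth, "latent")$n_perfect
#' @export
evaluateRule <- function(rule, cohort, rater, perfect = c("any", "unique")) {
  perfect <- match.arg(perfect)
  stopifnot(is(rule, "Rule"))
  validObject(rule)
  long <- .raterLong(cohort, rater, seizureFreeOnly = TRUE)
  flagged <- applyRule(rule, long[.ALL_FEATURES])
  pp <- .perPatientEval(flagged, long$ez, long$patient_id, perfect)
  structure(list(rule = rule, per_patient = pp,
                 n_perfect = sum(pp$perfect), n_patients = nrow(pp)),
            class = "RuleEvaluation")
}

#' @export
print.RuleEvaluation <- function(x, ...) {
  cat(sprintf("%s: perfect (100%% PPV) in %d of %d patients\n",
              describeRule(x$rule), x$n_perfect, x$n_patients))
  invisible(x)
}

#' Exhaustive search for EZ-flagging rules
#'
#' Brute-force enumeration of every "at least t of S" rule over a feature
#' pool: all non-empty subsets S and all thresholds 1 <= t <= |S| (448
#' rules for the full seven-feature pool). Each rule is scored by the
#' number of seizure-free patients in whom it attains 100% within-patient
#' positive predictive value (see [evaluateRule()]); this count is the
#' sole objective, as total EZ coverage is reported but not optimized.
#'
#' Rules are ranked by `n_perfect` (descending), then smaller feature sets,
#' then larger thresholds (more parsimonious and more specific first),
#' then lexicographically for a stable order. Among the rules attaining
#' the maximum `n_perfect`, the reduced frontier drops any rule whose flag
#' sets are identical, patient for patient, to those of a rule using a
#' strict subset of its features.
#'
#' @param cohort a [TscCohort-class].
#' @param rater a rater identifier.
#' @param featurePool features to search over (default all seven; cysts
#'   are deliberately not excluded by default).
#' @param perfect see [evaluateRule()].
#' @return a `RuleSearch`: list with `rules` (ranked data frame: features,
#'   threshold, n_features, n_perfect, n_patients, total_tp, frontier),
#'   `n_rules`, `featurePool`, `rater`, `perfect`.
#' @examples
#' sim <- simulateCohort(simConfig(nPatients = 8, seed = 11))
#' sr <- searchRules(sim$cohort, "rater_A")
#' head(sr$rules)
#' @export
searchRules <- function(cohort, rater, featurePool = allFeatures(),
                        perfect = c("any", "unique")) {
  perfect <- match.arg(perfect)
  featurePool <- unique(as.character(featurePool))
  if (length(featurePool) < 1L || length(featurePool) > 7L ||
      !all(featurePool %in% .ALL_FEATURES))
    stop("featurePool must be a non-empty subset of the seven features",
         call. = FALSE)
  long <- .raterLong(cohort, rater, seizureFreeOnly = TRUE)
  fm <- sapply(long[.ALL_FEATURES], as.integer)
  ez <- as.logical(long$ez)
  patient <- long$patient_id

  rows <- list()
  sigs <- character()
  featsets <- list()
  k <- 0L
  for (sz in seq_along(featurePool)) {
    sets <- combn(sort(featurePool), sz, simplify = FALSE)
    for (S in sets) {
      cnt <- if (length(S) == 1L) fm[, S] else rowSums(fm[, S])
      for (t in seq_len(sz)) {
        flagged <- cnt >= t
        pp <- .perPatientEval(flagged, ez, patient, perfect)
        k <- k + 1L
        rows[[k]] <- data.frame(
          features = paste(S, collapse = "+"), threshold = t,
          n_features = sz, n_perfect = sum(pp$perfect),
          n_patients = nrow(pp), total_tp = sum(pp$tp),
          stringsAsFactors = FALSE)
        sigs[k] <- paste(which(flagged), collapse = ",")
        featsets[[k]] <- S
      }
    }
  }
  res <- do.call(rbind, rows)
  ord <- order(-res$n_perfect, res$n_features, -res$threshold, res$features)
  res <- res[ord, ]
  sigs <- sigs[ord]
  featsets <- featsets[ord]
  rownames(res) <- NULL

  best <- max(res$n_perfect)
  cand <- which(res$n_perfect == best)
  frontier <- logical(nrow(res))
  for (i in cand) {
    dominated <- FALSE
    for (j in cand) {
      if (j == i) next
      if (sigs[j] == sigs[i] &&
          length(featsets[[j]]) < length(featsets[[i]]) &&
          all(featsets[[j]] %in% featsets[[i]])) {
        dominated <- TRUE
        break
      }
    }
    frontier[i] <- !dominated
  }
  res$frontier <- frontier
  structure(list(rules = res, n_rules = nrow(res),
                 featurePool = sort(featurePool), rater = rater,
                 perfect = perfect),
            class = "RuleSearch")
}

#' @export
print.RuleSearch <- function(x, ...) {
  cat(sprintf("Rule search over {%s}: %d rules, rater '%s'\n",
              paste(x$featurePool, collapse = ", "), x$n_rules, x$rater))
  fr <- x$rules[x$rules$frontier, ]
  cat(sprintf("Frontier (n_perfect = %d of %d patients):\n",
              max(x$rules$n_perfect), x$rules$n_patients[1L]))
  for (i in seq_len(nrow(fr)))
    cat("  ", sprintf("at least %d of {%s}", fr$threshold[i],
                      gsub("+", ", ", fr$features[i], fixed = TRUE)), "\n")
  invisible(x)
}
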