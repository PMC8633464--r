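# 2x2 table of two binary vectors: a = both positive, b = x only,
# c = y only, d = neither
.twoByTwo <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("need at least 2 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  c(a = sum(x & y), b = sum(x & !y), c = sum(!x & y), d = sum(!x & !y))
}

.isBinary <- function(x) {
  is.logical(x) || all(x %in% c(0, 1))
}

.metricResult <- function(estimate, p_value, method, n, table = NULL,
                          metric = "metric") {
  structure(list(estimate = estimate, p_value = p_value, method = method,
                 n = n, table = table, metric = metric),
            class = "MetricResult")
}

#' @export
print.MetricResult <- function(x, ...) {
  cat(sprintf("%s = %s (n = %d, p = %s, %s)\n", x$metric,
              format(x$estimate, digits = 4), x$n,
              format(x$p_value, digits = 3), x$method))
  if (!is.null(x$table)) {
    cat("2x2 table (a, b, c, d): ")
    cat(paste(x$table, collapse = ", "), "\n")
  }
  invisible(x)
}

# Kendall S, tau-b and tie-corrected null variance from a contingency
# table (rows = x levels ascending, cols = y levels ascending)
.kendallFromTable <- function(ct) {
  ct <- unclass(ct)
  n <- sum(ct)
  R <- nrow(ct); C <- ncol(ct)
  conc <- disc <- 0
  for (i in seq_len(R)) for (j in seq_len(C)) {
    if (ct[i, j] == 0) next
    if (i < R && j < C)
      conc <- conc + ct[i, j] * sum(ct[(i + 1):R, (j + 1):C])
    if (i < R && j > 1)
      disc <- disc + ct[i, j] * sum(ct[(i + 1):R, 1:(j - 1)])
  }
  S <- conc - disc
  ti <- rowSums(ct); uj <- colSums(ct)
  n0 <- n * (n - 1) / 2
  n1 <- sum(ti * (ti - 1) / 2)
  n2 <- sum(uj * (uj - 1) / 2)
  denom <- sqrt(n0 - n1) * sqrt(n0 - n2)
  tau <- if (denom > 0) S / denom else NA_real_
  # tie-corrected variance of S under the permutation null
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(ti * (ti - 1) * (2 * ti + 5))
  vu <- sum(uj * (uj - 1) * (2 * uj + 5))
  v1 <- sum(ti * (ti - 1)) * sum(uj * (uj - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2)
    sum(ti * (ti - 1) * (ti - 2)) * sum(uj * (uj - 1) * (uj - 2)) /
      (9 * n * (n - 1) * (n - 2))
  else 0
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  list(S = S, tau = tau, varS = varS, n = n)
}

.permPvalue <- function(x, y, statFun, observed, nPerm, seed) {
  if (is.na(observed))
    return(NA_real_)
  .withSeed(seed, {
    hits <- 0L
    for (i in seq_len(nPerm)) {
      s <- statFun(sample(y))
      if (!is.na(s) && abs(s) >= abs(observed) - 1e-12)
        hits <- hits + 1L
    }
    (1 + hits) / (nPerm + 1)
  })
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, where `p_o` is the
#' observed agreement proportion and `p_e` the agreement expected from the
#' marginal rates. When the chance agreement is exactly 1 (both vectors
#' constant with equal margins) kappa is undefined and the estimate is
#' `NA`.
#'
#' The p-value tests kappa = 0 either by label permutation (seeded shuffles
#' of `y`; default, 10000 shuffles) or by the large-sample normal
#' approximation with the null standard error of kappa.
#'
#' @param x,y equal-length binary (logical or 0/1) vectors.
#' @param method `"permutation"` or `"asymptotic"`.
#' @param nPerm number of permutations.
#' @param seed seed for the permutation draws.
#' @return a `MetricResult`: list with `estimate`, `p_value`, `method`,
#'   `n` and the 2x2 `table` (a, b, c, d).
#' @examples
#' x <- rep(c(1, 0), c(15, 85))
#' y <- rep(c(1, 0, 1, 0), c(10, 5, 3, 82))
#' cohensKappa(x, y, method = "asymptotic")$estimate
#' @export
cohensKappa <- function(x, y, method = c("permutation", "asymptotic"),
                        nPerm = 10000L, seed = 1L) {
  method <- match.arg(method)
  tb <- .twoByTwo(x, y)
  n <- sum(tb)
  kappaFromA <- function(a) {
    b <- tb[["a"]] + tb[["b"]] - a     # x margin fixed
    c_ <- tb[["a"]] + tb[["c"]] - a    # y margin fixed
    d <- n - a - b - c_
    po <- (a + d) / n
    pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
    if (1 - pe < 1e-12) NA_real_ else (po - pe) / (1 - pe)
  }
  po <- (tb[["a"]] + tb[["d"]]) / n
  p1x <- (tb[["a"]] + tb[["b"]]) / n
  p1y <- (tb[["a"]] + tb[["c"]]) / n
  pe <- p1x * p1y + (1 - p1x) * (1 - p1y)
  if (1 - pe < 1e-12)
    return(.metricResult(NA_real_, NA_real_, method, n, tb, "kappa"))
  kappa <- (po - pe) / (1 - pe)
  p <- if (method == "asymptotic") {
    # Fleiss null variance of kappa
    s <- p1x * p1y * (p1x + p1y) + (1 - p1x) * (1 - p1y) * (2 - p1x - p1y)
    var0 <- (pe + pe^2 - s) / (n * (1 - pe)^2)
    if (var0 <= 0) NA_real_ else 2 * pnorm(-abs(kappa) / sqrt(var0))
  } else {
    xl <- as.logical(x)
    .permPvalue(xl, as.logical(y), function(yp) kappaFromA(sum(xl & yp)),
                kappa, nPerm, seed)
  }
  .metricResult(kappa, p, method, n, tb, "kappa")
}

#' Kendall's tau-b for tied (binary or count) data
#'
#' Tie-corrected rank correlation. For paired binary vectors tau-b reduces
#' to the phi coefficient of the 2x2 table,
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`; for count data it is computed
#' by concordant/discordant pair counting over the joint contingency
#' table. A constant vector makes the estimate undefined (`NA`).
#'
#' The p-value tests tau = 0 by seeded label permutation (default) or by
#' the normal approximation with the tie-corrected null variance of the
#' Kendall S statistic.
#'
#' @inheritParams cohensKappa
#' @param x,y equal-length numeric vectors (binary or small counts).
#' @return a `MetricResult`; the 2x2 `table` slot is filled for binary
#'   input.
#' @examples
#' x <- rep(c(1, 0), c(4, 16))
#' y <- rep(c(1, 0, 1, 0), c(3, 1, 2, 14))
#' kendallTauB(x, y, method = "asymptotic")$estimate  # 0.5774
#' @export
kendallTauB <- function(x, y, method = c("permutation", "asymptotic"),
                        nPerm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("need at least 2 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  binary <- .isBinary(x) && .isBinary(y)
  tb <- if (binary) .twoByTwo(x, y) else NULL
  if (binary) {
    a <- tb[["a"]]; b <- tb[["b"]]; c_ <- tb[["c"]]; d <- tb[["d"]]
    denom <- sqrt(a + b) * sqrt(c_ + d) * sqrt(a + c_) * sqrt(b + d)
    tau <- if (denom > 0) (a * d - b * c_) / denom else NA_real_
  } else {
    tau <- .kendallFromTable(table(x, y))$tau
  }
  if (is.na(tau))
    return(.metricResult(NA_real_, NA_real_, method, length(x), tb, "tau_b"))
  p <- if (method == "asymptotic") {
    ks <- .kendallFromTable(table(x, y))
    if (!is.finite(ks$varS) || ks$varS <= 0) NA_real_
    else 2 * pnorm(-abs(ks$S) / sqrt(ks$varS))
  } else {
    tauStat <- function(yp) .kendallFromTable(table(x, yp))$tau
    .permPvalue(x, y, tauStat, tau, nPerm, seed)
  }
  .metricResult(tau, p, method, length(x), tb, "tau_b")
}

# the three reported abnormality-count variants
.countVariants <- function(long) {
  list(
    n_abnormalities = countAbnormalities(long[.ALL_FEATURES]),
    n_abnormalities_incl_largest =
      countAbnormalities(long[.ALL_FEATURES], includeLargestArea = TRUE),
    n_abnormalities_excl_calcifications =
      countAbnormalities(long[.ALL_FEATURES], excludeCalcifications = TRUE)
  )
}

#' Per-feature inter-rater agreement
#'
#' Cohen's kappa and Kendall's tau-b between two raters for each of the
#' seven binary features, plus tau-b for the three derived
#' abnormality-count variants (all features; including the largest-area
#' designation; excluding calcifications). Both raters must have scored
#' exactly the same (patient, ROI) grid.
#'
#' @param cohort a [TscCohort-class].
#' @param raterA,raterB rater identifiers present in the cohort.
#' @inheritParams cohensKappa
#' @return data frame with one row per measure: `measure`, `kappa`,
#'   `kappa_p` (NA for the count variants), `tau`, `tau_p`, `n`.
#' @export
featureAgreement <- function(cohort, raterA, raterB,
                             method = c("permutation", "asymptotic"),
                             nPerm = 10000L, seed = 1L) {
  method <- match.arg(method)
  longA <- .raterLong(cohort, raterA)
  longB <- .raterLong(cohort, raterB)
  if (!identical(longA$patient_id, longB$patient_id))
    stop("raters do not cover identical (patient, ROI) keys", call. = FALSE)
  rows <- list()
  for (i in seq_along(.ALL_FEATURES)) {
    f <- .ALL_FEATURES[i]
    k <- cohensKappa(longA[[f]], longB[[f]], method, nPerm, seed + i)
    tv <- kendallTauB(longA[[f]], longB[[f]], method, nPerm, seed + i)
    rows[[f]] <- data.frame(measure = f, kappa = k$estimate,
                            kappa_p = k$p_value, tau = tv$estimate,
                            tau_p = tv$p_value, n = k$n,
                            stringsAsFactors = FALSE)
  }
  cvA <- .countVariants(longA)
  cvB <- .countVariants(longB)
  for (i in seq_along(cvA)) {
    nm <- names(cvA)[i]
    tv <- kendallTauB(cvA[[i]], cvB[[i]], method, nPerm,
                      seed + length(.ALL_FEATURES) + i)
    rows[[nm]] <- data.frame(measure = nm, kappa = NA_real_,
                             kappa_p = NA_real_, tau = tv$estimate,
                             tau_p = tv$p_value, n = tv$n,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature-EZ association for one rater
#'
#' Kendall's tau-b between each feature (and each abnormality-count
#' variant) and the epileptogenic-zone label, pooling the 22 ROIs of every
#' seizure-free patient into one vector. Within-patient clustering is
#' deliberately ignored in this pooled analysis (a caveat, not an option).
#'
#' @param cohort a [TscCohort-class].
#' @param rater a rater identifier.
#' @inheritParams cohensKappa
#' @return data frame: `measure`, `tau`, `p_value`, `n`.
#' @export
ezAssociation <- function(cohort, rater,
                          method = c("permutation", "asymptotic"),
                          nPerm = 10000L, seed = 1L) {
  method <- match.arg(method)
  long <- .raterLong(cohort, rater, seizureFreeOnly = TRUE)
  meas <- c(setNames(as.list(long[.ALL_FEATURES]), .ALL_FEATURES),
            .countVariants(long))
  rows <- lapply(seq_along(meas), function(i) {
    tv <- kendallTauB(as.numeric(meas[[i]]), as.numeric(long$ez),
                      method, nPerm, seed + i)
    data.frame(measure = names(meas)[i], tau = tv$estimate,
               p_value = tv$p_value, n = tv$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
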