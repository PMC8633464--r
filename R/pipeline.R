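# deterministic per-stage seed from a single top-level seed, so stages
# can be re-run in isolation; kept inside 32-bit integer range
.stageSeed <- function(seed, stage) {
  (as.integer(seed) + 9973L * as.integer(stage)) %% .Machine$integer.max
}

.stage <- function(name, quiet, expr) {
  if (!quiet) message(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

.roundPct <- function(x) ifelse(is.na(x), NA, as.integer(.roundHalfAway(x, 0)))

#' Run the full analysis pipeline
#'
#' Executes the stages end to end — optional simulation, cohort
#' validation, prevalence summary, inter-rater agreement, feature-EZ
#' association, pooled and per-patient diagnostics, and the exhaustive
#' rule search — and writes a report bundle to `outDir`: the cohort (and
#' latent truth, when simulated), prevalence / association / diagnostic
#' CSV tables, a per-patient metrics CSV, the ranked rules CSV with
#' frontier flags, a markdown summary, and a `manifest.json` recording the
#' seed, a digest of the effective configuration and all file paths, which
#' together suffice to reproduce every output bit-for-bit.
#'
#' @param config a list (or path to a JSON file) with optional entries:
#'   `seed` (integer, default 1; fans out to per-stage seeds), `simulate`
#'   (list of [simConfig()] overrides; used when no `cohort` is given),
#'   `cohort` (path to a cohort CSV to analyse instead of simulating),
#'   `pvalue` (`"permutation"` or `"asymptotic"`, default permutation),
#'   `n_perm` (default 10000), `feature_pool`, `perfect` (see
#'   [searchRules()]).
#' @param outDir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `prevalence`, `agreement`, `association`, `diagnostics`,
#'   `perPatient`, `search`, `manifest`).
#' @export
runPipeline <- function(config = list(), outDir, quiet = FALSE) {
  input_paths <- character()
  if (is.character(config)) {
    input_paths <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  pvalue <- if (is.null(config$pvalue)) "permutation" else config$pvalue
  nPerm <- if (is.null(config$n_perm)) 10000L else as.integer(config$n_perm)
  pool <- if (is.null(config$feature_pool)) allFeatures() else
    config$feature_pool
  perfect <- if (is.null(config$perfect)) "any" else config$perfect
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outDir, f)
  output_paths <- character()
  emit <- function(df, f) {
    write.csv(df, out(f), row.names = FALSE, quote = FALSE)
    output_paths <<- c(output_paths, out(f))
  }

  truth <- NULL
  if (!is.null(config$cohort)) {
    input_paths <- c(input_paths, config$cohort)
    cohort <- .stage("validate", quiet, readCohort(config$cohort))
  } else {
    sim_args <- config$simulate
    if (is.null(sim_args)) sim_args <- list()
    sim_args$seed <- .stageSeed(seed, 0L)
    sim <- .stage("simulate", quiet,
                  simulateCohort(do.call(simConfig, sim_args)))
    cohort <- sim$cohort
    truth <- sim$truth
    emit(cohortTable(cohort), "cohort.csv")
    emit(cohortTable(truth), "truth.csv")
  }
  if (!quiet)
    message(sprintf("[validate] %d patients, %d raters, %d ROIs scored",
                    length(patientIds(cohort)), length(raterIds(cohort)),
                    22L * ncol(cohort)))
  raters <- raterIds(cohort)

  prev <- .stage("prevalence", quiet, {
    tabs <- lapply(raters, function(r) {
      ps <- prevalenceSummary(cohort, r)
      cbind(rater = r, ps$features)
    })
    do.call(rbind, tabs)
  })
  emit(prev, "table1_prevalence.csv")

  agreement <- NULL
  if (length(raters) >= 2L) {
    agreement <- .stage("concordance", quiet,
      featureAgreement(cohort, raters[1L], raters[2L], method = pvalue,
                       nPerm = nPerm, seed = .stageSeed(seed, 1L)))
    emit(agreement, "agreement.csv")
  }
  association <- .stage("association", quiet, {
    do.call(rbind, lapply(seq_along(raters), function(i)
      cbind(rater = raters[i],
            ezAssociation(cohort, raters[i], method = pvalue, nPerm = nPerm,
                          seed = .stageSeed(seed, 1L + i)))))
  })
  emit(association, "table2_association.csv")

  diagnostics <- .stage("diagnostics", quiet, {
    do.call(rbind, lapply(raters, function(r) {
      d <- featureDiagnostics(cohort, r, scope = "pooled")
      d$accuracy <- .roundPct(d$accuracy)
      d$ppv <- .roundPct(d$ppv)
      d$fdr <- .roundPct(d$fdr)
      cbind(rater = r, d)
    }))
  })
  emit(diagnostics, "table3_diagnostics.csv")

  perPatient <- .stage("per_patient_diagnostics", quiet, {
    do.call(rbind, lapply(raters, function(r)
      cbind(rater = r, featureDiagnostics(cohort, r, scope = "per_patient"))))
  })
  emit(perPatient[, c("rater", "patient_id", "feature",
                      "accuracy", "ppv", "fdr")], "per_patient_metrics.csv")

  search <- .stage("rule_search", quiet, {
    res <- lapply(raters, function(r)
      searchRules(cohort, r, featurePool = pool, perfect = perfect))
    names(res) <- raters
    res
  })
  emit(do.call(rbind, lapply(raters, function(r)
    cbind(rater = r, search[[r]]$rules))), "rules.csv")
  emit(do.call(rbind, lapply(raters, function(r) {
    fr <- search[[r]]$rules[search[[r]]$rules$frontier, ]
    do.call(rbind, lapply(seq_len(nrow(fr)), function(i) {
      rl <- rule(strsplit(fr$features[i], "+", fixed = TRUE)[[1L]],
                 fr$threshold[i])
      cbind(rater = r, features = fr$features[i],
            threshold = fr$threshold[i],
            evaluateRule(rl, cohort, r, perfect)$per_patient)
    }))
  })), "rules_per_patient.csv")

  md <- .stage("report", quiet, {
    lines <- c(
      "# EZ feature-rule analysis report", "",
      sprintf("- patients: %d (%d seizure-free)", length(patientIds(cohort)),
              sum(seizureFree(cohort))),
      sprintf("- raters: %s", paste(raters, collapse = ", ")),
      sprintf("- ROIs scored: %d", 22L * ncol(cohort)),
      "", "## Frontier rules (maximum patients with 100% PPV)", "")
    for (r in raters) {
      rl <- search[[r]]$rules
      fr <- rl[rl$frontier, ]
      lines <- c(lines, sprintf("### rater %s — perfect in %d of %d patients",
                                r, max(rl$n_perfect), rl$n_patients[1L]))
      lines <- c(lines, sprintf("- at least %d of {%s}", fr$threshold,
                                gsub("+", ", ", fr$features, fixed = TRUE)),
                 "")
    }
    writeLines(lines, out("summary.md"))
    output_paths <- c(output_paths, out("summary.md"))
    lines
  })
  output_paths <- c(output_paths, out("summary.md"))

  cfg_path <- out("config.json")
  effective <- list(seed = seed, pvalue = pvalue, n_perm = nPerm,
                    feature_pool = pool, perfect = perfect,
                    simulate = config$simulate, cohort = config$cohort)
  jsonlite::write_json(effective, cfg_path, auto_unbox = TRUE, null = "null")
  manifest <- list(
    command = "runPipeline",
    tool_version = as.character(packageVersion("tscez")),
    seed = seed,
    config_digest = unname(tools::md5sum(cfg_path)),
    input_paths = input_paths,
    output_paths = sort(unique(output_paths)),
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  invisible(list(cohort = cohort, truth = truth, prevalence = prev,
                 agreement = agreement, association = association,
                 diagnostics = diagnostics, perPatient = perPatient,
                 search = search, manifest = manifest))
}
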