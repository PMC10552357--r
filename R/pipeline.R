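## End-to-end orchestration: simulate -> featurize -> nested CV -> final
## tree -> simplify -> validate, with CSV/plain-text reports and a
## reproducibility manifest.

#' Pipeline configuration
#'
#' One layered document tying the stages together. Defaults follow the
#' study design the package implements: prevalence 0.19, minimum feature
#' support 10 patients, 300-feature prescreen, 10x10 nested CV, top-9
#' feature simplification.
#'
#' @param cohort a `cohort_config`.
#' @param learner a `learner_config` (its seed is overridden by the run
#'   seed so one seed drives every stage).
#' @param s number of top features for simplification (default 9).
#' @param seed run seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, learner = learner_config(), s = 9L,
                            seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(learner, "learner_config"))
  learner$seed <- as.integer(seed)
  structure(list(cohort = cohort, learner = learner, s = as.integer(s),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(verbose, ...) {
  if (verbose)
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
}

#' Run the whole phenotyping pipeline
#'
#' Generates (or accepts) a cohort, excludes unclassifiable charts, splits
#' labelled patients into train/test and validation halves, engineers the
#' feature matrix on the train/test half only, runs the nested CV over all
#' combinations, trains the final tree with the best combination,
#' simplifies it into a one- or two-clause case definition, and validates
#' both on the held-out half. Writes the combination table, importance
#' table, candidate table, validation report, chosen definition and a run
#' manifest to `outdir` (when given).
#'
#' @param config a `pipeline_config`.
#' @param outdir optional artefact directory.
#' @param cohort optional pre-built cohort (skips generation).
#' @param verbose emit stage log lines (default TRUE).
#' @return Object of class `pipeline_result` with every stage artefact.
#' @export
run_all <- function(config, outdir = NULL, cohort = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    t0 <<- Sys.time()
  }

  log_stage(verbose, "simulate: n=", config$cohort$n_patients,
            " seed=", config$seed)
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  tick("simulate")

  lab_ids <- labelled_ids(cohort)
  split <- split_train_validation(lab_ids, config$seed)
  audit_no_leakage(split$validation, split$train_test)

  log_stage(verbose, "featurize: ", length(split$train_test),
            " train/test charts")
  train_cohort <- subset_cohort(cohort, split$train_test)
  audit_no_leakage(split$validation, train_cohort$patients$patient_id)
  fm <- build_feature_matrix(train_cohort)
  labels <- setNames(train_cohort$patients$label,
                     train_cohort$patients$patient_id)
  tick("featurize")

  log_stage(verbose, "nested CV: ", ncol(fm$values), " features, ",
            length(config$learner$grid), " hyperparameter sets")
  results <- nested_cv(fm, labels, config$learner)
  best <- select_best_combination(results)
  tick("nested_cv")

  log_stage(verbose, "final tree: combination ", best$label)
  tree <- train_final_tree(fm, labels, best, config$learner)
  simp <- simplify_definition(tree, fm, cohort, labels, s = config$s)
  tick("train_simplify")

  log_stage(verbose, "validate: ", length(split$validation), " charts")
  report <- validate_final(simp$chosen, cohort, split$validation)
  tick("validate")

  out <- structure(list(cohort = cohort, split = split,
                        feature_matrix = fm, cv_results = results,
                        best_combination = best, tree = tree,
                        simplification = simp,
                        definition = simp$chosen,
                        validation = report,
                        timings = timings,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_reports(out, outdir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("best combination:", x$best_combination$label,
      sprintf("(mean F1 = %.3f)\n", x$best_combination$mean_f1))
  cat("chosen definition:\n")
  print(x$definition)
  cat("validation on held-out half:\n")
  print(x$validation)
  invisible(x)
}

report_line <- function(r) {
  sprintf("%-45s %5.1f (%5.1f-%5.1f)", r$metric, 100 * r$est,
          100 * r$lower, 100 * r$upper)
}

#' Write the report tables of a pipeline run
#'
#' Emits `combinations.csv` (the per-combination CV metric table),
#' `importances.csv`, `candidates.csv`, `validation.csv`,
#' `case_definition.yaml`, a human-readable `report.txt` and
#' `run_manifest.yaml` (seed, stage timings, config fingerprint, package
#' version).
#'
#' @param result a `pipeline_result`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_reports <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  comb <- as.data.frame(result$cv_results)
  write.csv(comb, file.path(outdir, "combinations.csv"), row.names = FALSE)
  imp <- data.frame(feature = names(result$tree$importances),
                    importance = unname(result$tree$importances))
  write.csv(imp, file.path(outdir, "importances.csv"), row.names = FALSE)
  write.csv(result$simplification$candidates,
            file.path(outdir, "candidates.csv"), row.names = FALSE)
  write.csv(result$validation$estimates,
            file.path(outdir, "validation.csv"), row.names = FALSE)
  write_case_definition(result$definition,
                        file.path(outdir, "case_definition.yaml"))

  txt <- c(
    "phenotyping pipeline report",
    "===========================",
    "",
    sprintf("seed: %d  patients: %d  train/test: %d  validation: %d",
            result$config$seed, nrow(result$cohort$patients),
            length(result$split$train_test),
            length(result$split$validation)),
    "",
    "combination table (10-fold means):",
    sprintf("  %-45s F1=%.3f Sn=%.1f%% Sp=%.1f%% PPV=%.1f%% NPV=%.1f%%",
            comb$combination, comb$mean_f1, 100 * comb$mean_sn,
            100 * comb$mean_sp, 100 * comb$mean_ppv, 100 * comb$mean_npv),
    "",
    sprintf("best combination: %s", result$best_combination$label),
    "",
    "top feature importances:",
    sprintf("  %-45s %.5f", names(result$tree$importances),
            unname(result$tree$importances)),
    "",
    sprintf("chosen case definition: %s", result$simplification$chosen_name),
    "",
    "validation metrics (held-out half):",
    vapply(seq_len(nrow(result$validation$estimates)), function(i)
      paste0("  ", report_line(result$validation$estimates[i, ])),
      character(1)),
    sprintf("  f1: %.3f", result$validation$f1))
  writeLines(txt, file.path(outdir, "report.txt"))

  manifest <- list(
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("phenoforge")),
    config_fingerprint = config_fingerprint(result$config$cohort),
    stage_timings_seconds = result$timings,
    n_features = ncol(result$feature_matrix$values),
    n_features_prefilter = result$feature_matrix$n_features_prefilter,
    best_combination = result$best_combination$label,
    chosen_definition = result$simplification$chosen_name)
  yaml::write_yaml(manifest, file.path(outdir, "run_manifest.yaml"))
  invisible(outdir)
}
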