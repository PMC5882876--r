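# Full study orchestration: one pooled 65/35 split, per-drug derivation
# (stability selection + tuned elastic net) strictly inside the training
# partition, external same-drug validation, and cross-drug specificity.

#' Study configuration
#'
#' Bundles every tunable of the full pipeline. The defaults reproduce the
#' canonical design: a single pooled 65/35 outcome-by-drug stratified
#' split; variable selection in 20 repetitions of 5-fold cross-validation
#' (100 rounds) with a local-FDR vote threshold of 0.8; elastic-net tuning
#' by 5-fold cross-validation with 100 repetitions; genotype QC at
#' MAF > 0.01, completeness >= 0.99, LD r-squared <= 0.8.
#'
#' @param drugs the two drug-arm labels.
#' @param train_fraction training proportion of the pooled split.
#' @param selection_repetitions,selection_folds,lfdr_threshold stability
#'   selection parameters.
#' @param tune_alphas,tune_nlambda,tune_folds,tune_repetitions elastic-net
#'   tuning grid and resampling.
#' @param qc a [qc_thresholds()].
#' @param impute_trees bagged-tree ensemble size for clinical imputation.
#' @param seed master seed; every stage derives its stream from it.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(drugs = c("A", "B"),
                         train_fraction = 0.65,
                         selection_repetitions = 20L,
                         selection_folds = 5L,
                         lfdr_threshold = 0.8,
                         tune_alphas = c(0.1, 0.55, 1),
                         tune_nlambda = 12L,
                         tune_folds = 5L,
                         tune_repetitions = 100L,
                         qc = qc_thresholds(),
                         impute_trees = 25L,
                         seed = 1L) {
  structure(list(drugs = drugs, train_fraction = train_fraction,
                 selection_repetitions = as.integer(selection_repetitions),
                 selection_folds = as.integer(selection_folds),
                 lfdr_threshold = lfdr_threshold,
                 tune_alphas = tune_alphas,
                 tune_nlambda = as.integer(tune_nlambda),
                 tune_folds = as.integer(tune_folds),
                 tune_repetitions = as.integer(tune_repetitions),
                 qc = qc, impute_trees = as.integer(impute_trees),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Derive and validate one drug's model
#'
#' Restricts to one drug arm, runs stability selection and elastic-net
#' tuning/fitting strictly inside the training partition, freezes the
#' Youden threshold on training predictions, and evaluates on the training
#' (resubstitution) and same-drug validation participants. When selection
#' retains no features an intercept-only model is fitted with a warning and
#' chance-level metrics are reported rather than failing.
#'
#' @param cohort a preprocessed `"remit_cohort"` with binary outcome.
#' @param drug the arm to derive on.
#' @param split list with `train`/`validation` index vectors from
#'   [split_train_validation()] on the pooled cohort.
#' @param config a [study_config()].
#' @return List with `votes`, `tuning`, `model`, `train_report`,
#'   `validation_report`, and the arm index vectors.
#' @export
run_same_drug <- function(cohort, drug, split, config = study_config()) {
  stopifnot(inherits(cohort, "remit_cohort"))
  arm <- which(cohort$drug == drug)
  tr <- intersect(split$train, arm)
  va <- intersect(split$validation, arm)
  if (!length(tr) || !length(va)) {
    stop(sprintf("drug arm `%s` has an empty training or validation partition",
                 drug), call. = FALSE)
  }
  d_off <- match(drug, config$drugs)
  xtr <- cohort$features[tr, , drop = FALSE]
  ytr <- as_binary01(cohort$outcome[tr])
  votes <- stability_select(xtr, ytr,
                            repetitions = config$selection_repetitions,
                            folds = config$selection_folds,
                            lfdr_threshold = config$lfdr_threshold,
                            seed = derive_seed(config$seed, 50L + d_off))
  sel <- votes$retained
  tuning <- NULL
  if (length(sel) == 0L) {
    warning(sprintf("no features retained for drug `%s`; fitting an intercept-only model",
                    drug))
    model <- fit_intercept_only(ytr)
  } else {
    tuning <- tune_enet(xtr[, sel, drop = FALSE], ytr,
                        alphas = config$tune_alphas,
                        nlambda = config$tune_nlambda,
                        folds = config$tune_folds,
                        repetitions = config$tune_repetitions,
                        seed = derive_seed(config$seed, 60L + d_off))
    kinds <- cohort$feature_meta$kind[match(sel, cohort$feature_meta$name)]
    model <- fit_enet_logistic(xtr[, sel, drop = FALSE], ytr,
                               alpha = tuning$alpha, lambda = tuning$lambda,
                               kinds = kinds)
  }
  model$drug <- drug
  ptr <- predict(model, xtr)
  model$threshold <- choose_threshold(ptr, ytr)
  train_report <- evaluate_predictions(ptr, ytr, model$threshold,
                                       context = paste0("train_", drug))
  yva <- as_binary01(cohort$outcome[va])
  pva <- predict(model, cohort$features[va, , drop = FALSE])
  validation_report <- evaluate_predictions(pva, yva, model$threshold,
                                            context = paste0("validation_", drug))
  list(votes = votes, tuning = tuning, model = model,
       train_report = train_report, validation_report = validation_report,
       train_idx = tr, validation_idx = va)
}

#' Cross-drug specificity analysis
#'
#' Applies a frozen model (including its frozen threshold) to the
#' validation participants treated with the *other* drug, with no
#' refitting of any kind. Drug-specific prediction shows as a same-drug
#' validation AUC materially above the cross-drug one.
#'
#' @param model a fitted `"remit_model"` (its `drug` field names the
#'   derivation arm).
#' @param cohort the preprocessed cohort.
#' @param drug the arm to evaluate on.
#' @param split the pooled split used for derivation.
#' @return A `"remit_report"` with context `cross_<train drug>_on_<drug>`.
#' @export
run_cross_drug <- function(model, cohort, drug, split) {
  stopifnot(inherits(model, "remit_model"))
  va <- intersect(split$validation, which(cohort$drug == drug))
  if (!length(va)) {
    stop(sprintf("validation partition for drug `%s` is empty", drug),
         call. = FALSE)
  }
  y <- as_binary01(cohort$outcome[va])
  p <- predict(model, cohort$features[va, , drop = FALSE])
  evaluate_predictions(p, y, model$threshold %||% 0.5,
                       context = paste0("cross_", model$drug %||% "model",
                                        "_on_", drug))
}

#' Run the full two-drug study
#'
#' Executes the whole design: preprocessing (when the cohort still carries
#' missing values or HRSD totals), one pooled stratified train/validation
#' split, per-drug derivation and same-drug external validation, and both
#' cross-drug analyses. Validation participants are never touched by any
#' derivation step. Optionally writes all artifacts (per-drug vote tables
#' and model JSONs, per-context report JSONs and ROC point tables, and a
#' reproducibility manifest) to a directory; two runs from the same
#' configuration produce byte-identical files.
#'
#' @param cohort a `"remit_cohort"` (raw or already preprocessed).
#' @param config a [study_config()].
#' @param out_dir optional artifact directory.
#' @return An object of class `"remit_study"`: per-drug results, cross-drug
#'   reports, the split, the manifest, and the preprocessed cohort.
#' @export
run_full_study <- function(cohort, config = study_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "remit_cohort"))
  if (cohort$outcome_type != "binary" || anyNA(cohort$features)) {
    cohort <- preprocess_cohort(cohort, qc = config$qc,
                                n_trees = config$impute_trees,
                                seed = derive_seed(config$seed, 80L))
  }
  split <- split_train_validation(cohort$outcome, cohort$drug,
                                  train_fraction = config$train_fraction,
                                  seed = derive_seed(config$seed, 70L))
  per_drug <- lapply(setNames(config$drugs, config$drugs), function(d) {
    run_same_drug(cohort, d, split, config)
  })
  cross <- list()
  for (d in config$drugs) {
    other <- setdiff(config$drugs, d)[1]
    cross[[paste0(d, "_on_", other)]] <-
      run_cross_drug(per_drug[[d]]$model, cohort, other, split)
  }
  manifest <- list(
    generator = "rxremit",
    package_version = as.character(utils::packageVersion("rxremit")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "qc")],
    qc = unclass(config$qc),
    n = nrow(cohort$features),
    n_features = ncol(cohort$features),
    n_train = length(split$train),
    n_validation = length(split$validation),
    cohort_hash = hash_object(list(cohort$features, cohort$drug,
                                   cohort$outcome)),
    retained = lapply(per_drug, function(r) r$votes$retained))
  study <- structure(
    list(per_drug = per_drug, cross_drug = cross, split = split,
         config = config, manifest = manifest, cohort = cohort),
    class = "remit_study")
  if (!is.null(out_dir)) write_study_artifacts(study, out_dir)
  study
}

report_to_list <- function(r) unclass(r)

write_study_artifacts <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- study$cohort
  for (d in names(study$per_drug)) {
    res <- study$per_drug[[d]]
    write.csv(res$votes$votes, file.path(out_dir, sprintf("votes_%s.csv", d)),
              row.names = FALSE, quote = FALSE)
    export_model(res$model, file.path(out_dir, sprintf("model_%s.json", d)))
    for (ctx in c("train_report", "validation_report")) {
      rep <- res[[ctx]]
      jsonlite::write_json(report_to_list(rep),
                           file.path(out_dir, sprintf("report_%s.json", rep$context)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    va <- res$validation_idx
    rocd <- roc_points(predict(res$model, cohort$features[va, , drop = FALSE]),
                       as_binary01(cohort$outcome[va]))
    write.csv(rocd, file.path(out_dir, sprintf("roc_validation_%s.csv", d)),
              row.names = FALSE, quote = FALSE)
  }
  for (nm in names(study$cross_drug)) {
    rep <- study$cross_drug[[nm]]
    jsonlite::write_json(report_to_list(rep),
                         file.path(out_dir, sprintf("report_%s.json", rep$context)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.remit_study <- function(x, ...) {
  cat("Two-arm remission prediction study\n")
  for (d in names(x$per_drug)) {
    res <- x$per_drug[[d]]
    cat(sprintf("  drug %s: %d feature(s) retained; ", d,
                length(res$votes$retained)))
    cat(sprintf("train AUC %.2f, validation AUC %.2f\n",
                res$train_report$auc, res$validation_report$auc))
  }
  for (nm in names(x$cross_drug)) {
    cat(sprintf("  cross-drug %s: AUC %.2f\n", nm, x$cross_drug[[nm]]$auc))
  }
  invisible(x)
}
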