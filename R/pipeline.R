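#' Run the full pipeline: simulate, filter, featurize, train, evaluate,
#' attribute, recommend
#'
#' End-to-end driver over the package's stages: generate (or read) a cohort,
#' apply the eligibility rules, split at the encounter level, build feature
#' tensors, train the sequence model, compute regression and category
#' metrics, Bland-Altman agreement, paired comparisons against the
#' pharmacist benchmark column, gradient-times-input relevance, per-instance
#' dose recommendations, and the distance-reward curve. Every stage's output
#' is written under `out_dir`, and `manifest.json` records the seed, the
#' configuration, and per-stage row counts.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; stage seeds are derived from it.
#' @param cohort Optional pre-built `icu_cohort`; when NULL one is simulated
#'   from `config`.
#' @param config A [cohort_config()] used when simulating.
#' @param rules An [eligibility_rules()] object.
#' @param model_cfg A [model_config()]; its seed is overridden by `seed`.
#' @param train_fraction Encounter-level training fraction.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(out_dir, seed = 1, cohort = NULL,
                         config = cohort_config(),
                         rules = eligibility_rules(),
                         model_cfg = model_config(),
                         train_fraction = 0.8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(cohort)) cohort <- generate_cohort(config, seed = seed)
    write_cohort(cohort, file.path(out_dir, "cohort"))

    stage <- "filter"
    instances <- select_eligible(cohort, rules)
    if (nrow(instances) == 0) stop("no eligible prediction instances")
    utils::write.csv(instances, file.path(out_dir, "instances.csv"),
                     row.names = FALSE)

    stage <- "split"
    split <- split_train_test(instances, train_fraction,
                              seed = derive_seed(seed, "split"))

    stage <- "featurize"
    train_feat <- build_features(cohort, split$train)
    test_feat <- build_features(cohort, split$test, stats = train_feat$stats)
    jsonlite::write_json(train_feat$schema,
                         file.path(out_dir, "features_schema.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    stage <- "train"
    model_cfg$seed <- derive_seed(seed, "train")
    model <- train_model(train_feat, model_cfg)
    save_model(model, file.path(out_dir, "model.rds"))
    utils::write.csv(model$history, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)

    stage <- "evaluate"
    pred <- predict_troughs(model, test_feat)
    metrics <- regression_metrics(pred, test_feat$y)
    conf <- confusion_accuracy(pred, test_feat$y,
                               test_feat$range[, "lower"],
                               test_feat$range[, "upper"])
    ba <- bland_altman(pred, test_feat$y)
    pharm <- test_feat$meta$pharmacist_prediction
    comparison <- NULL
    if (all(!is.na(pharm))) {
      cats <- function(v) classify_trough(v, test_feat$range[, "lower"],
                                          test_feat$range[, "upper"])
      obs_cat <- cats(test_feat$y)
      comparison <- paired_tests(abs(pred - test_feat$y),
                                 abs(pharm - test_feat$y),
                                 cats(pred) == obs_cat,
                                 cats(pharm) == obs_cat)
    }
    jsonlite::write_json(
      list(metrics = unclass(metrics),
           confusion = list(matrix = conf$matrix, accuracy = conf$accuracy),
           bland_altman = unclass(ba)[c("mean_diff", "sd_diff",
                                        "loa_lower", "loa_upper")],
           comparison = if (!is.null(comparison)) unclass(comparison)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)

    stage <- "importance"
    rel <- relevance_scores(model, test_feat)
    utils::write.csv(rel$table, file.path(out_dir, "relevance.csv"),
                     row.names = FALSE)

    stage <- "recommend"
    recs <- recommend_all(model, test_feat)
    utils::write.csv(recs, file.path(out_dir, "recommendations.csv"),
                     row.names = FALSE)

    stage <- "reward_curve"
    curve <- reward_curve(recs, test_feat)
    utils::write.csv(curve, file.path(out_dir, "reward_curve.csv"),
                     row.names = FALSE)

    list(cohort = cohort, instances = instances, split = split,
         train_features = train_feat, test_features = test_feat,
         model = model, predictions = pred, metrics = metrics,
         confusion = conf, bland_altman = ba, comparison = comparison,
         relevance = rel, recommendations = recs, reward_curve = curve)
  }, error = function(e) {
    manifest <- list(seed = seed, failed_stage = stage,
                     error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    seed = seed,
    counts = list(
      encounters = nrow(result$cohort$encounters),
      observations = nrow(result$cohort$observations),
      doses = nrow(result$cohort$doses),
      troughs = nrow(result$cohort$troughs),
      instances = nrow(result$instances),
      train_instances = nrow(result$split$train),
      test_instances = nrow(result$split$test),
      model_parameters = n_params(result$model),
      recommendations = nrow(result$recommendations),
      reward_curve_bins = nrow(result$reward_curve)
    ),
    test_metrics = unclass(result$metrics)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
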