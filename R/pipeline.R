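#' Default pipeline configuration
#'
#' Assembles the full workflow configuration with the platform defaults:
#' 146-case synthetic cohort (49/45/52), 512-px desk-scale tiles (5120 px
#' for real slides), 5 ROIs per slide, watershed segmentation defaults,
#' selection targets 11 visual / 15 sub-visual (two-stage 171 -> 50 -> 15),
#' 75%/25% split repeated 30 times with a 30-case external hold-out, the
#' four model families, and the explainer defaults.
#'
#' @param master_seed Master seed for every stochastic stage.
#' @param mode `"synthetic"` (default) or `"real"` (5120-px tiles; images
#'   must already exist and be listed in a manifest).
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(master_seed = 1L,
                                    mode = c("synthetic", "real")) {
  mode <- match.arg(mode)
  list(mode = mode,
       cohort = list(n_per_grade = c(II = 49, III = 45, IV = 52),
                     slide_tiles = c(2, 2)),
       tile_size_px = if (mode == "real") real_slide_tile_px() else 512L,
       roi = list(k = 5L),
       segmentation = list(threshold_method = "otsu", od_floor = 0.15,
                           min_nucleus_area_px = 40,
                           seed_min_distance_px = 7,
                           opening_radius_px = 1, watershed_tolerance = 1),
       features = list(glcm_levels = 32L, glcm_distances = c(1L, 2L, 4L),
                       glcm_angles = c(0, 45, 90, 135)),
       selection = list(visual_target = 11L, subvisual_targets = c(50L, 15L),
                        drop_fraction = 0.2, cv_folds = 5L, num_trees = 500L),
       split = list(train_fraction = 0.75, n_repeats = 30L,
                    external_holdout = 30L),
       models = c("SVM", "RF", "GBDT", "NN"),
       explain = list(n_samples = 5000L, K = 8L, ridge = 1.0,
                      cases_per_grade = 1L),
       master_seed = as.integer(master_seed))
}

required_config_keys <- function() {
  c("mode", "cohort", "tile_size_px", "roi", "segmentation", "features",
    "selection", "split", "models", "explain", "master_seed")
}

#' Validate a pipeline configuration before any stage runs
#' @param config A pipeline configuration list.
#' @return The config, invisibly; errors name the offending key.
#' @export
validate_pipeline_config <- function(config) {
  missing <- setdiff(required_config_keys(), names(config))
  if (length(missing)) {
    stop("pipeline config missing required key(s): ",
         paste(missing, collapse = ", "))
  }
  stopifnot(config$tile_size_px >= 64, config$roi$k >= 1,
            config$split$train_fraction > 0, config$split$train_fraction < 1,
            config$split$n_repeats >= 1,
            all(config$models %in% c("SVM", "RF", "GBDT", "NN")))
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys are filled from [default_pipeline_config()]; the result is
#' validated.
#' @param path YAML file.
#' @return A validated pipeline configuration.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(default_pipeline_config(), user)
  validate_pipeline_config(config)
  config
}

seg_params_from_config <- function(config) {
  s <- config$segmentation
  seg_params(threshold_method = s$threshold_method %||% "otsu",
             od_floor = s$od_floor %||% 0.15,
             min_nucleus_area_px = s$min_nucleus_area_px %||% 40,
             seed_min_distance_px = s$seed_min_distance_px %||% 7,
             opening_radius_px = s$opening_radius_px %||% 1,
             watershed_tolerance = s$watershed_tolerance %||% 1)
}

stage_cached <- function(out_dir, stage, key) {
  keyfile <- file.path(out_dir, paste0(".", stage, ".key"))
  file.exists(keyfile) && identical(readLines(keyfile, warn = FALSE)[1], key)
}

stage_done <- function(out_dir, stage, key) {
  writeLines(key, file.path(out_dir, paste0(".", stage, ".key")))
}

#' Run the full grading pipeline
#'
#' Executes, in order: cohort simulation (synthetic mode), per-case feature
#' extraction (tiling, segmentation, ROI selection, 24+171+1 features),
#' two-stage feature selection, model training/evaluation under repeated
#' stratified hold-out with an external 30-case validation, per-case
#' explanations of representative cases, and report generation. Stages are
#' cached: a stage whose configuration and inputs are unchanged is skipped
#' on re-run. All randomness derives from `config$master_seed`.
#'
#' @param config A pipeline configuration ([default_pipeline_config()]).
#' @param out_dir Output directory for all artifacts.
#' @param verbose Log stage progress (default TRUE).
#' @return A `run_manifest` list: config hash, package version, seed, per
#'   stage the outputs with md5 checksums and timestamps. Also written to
#'   `run_manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         verbose = TRUE) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old_verb <- options(gliograde.verbose = verbose); on.exit(options(old_verb))
  cfg_hash <- object_md5(config)
  stages <- list()
  t_stage <- function(name, outputs, t0) {
    list(stage = name, outputs = outputs,
         checksums = as.list(tools::md5sum(outputs)),
         started = format(t0), finished = format(Sys.time()))
  }

  ## -- simulate ------------------------------------------------------------
  cohort_dir <- file.path(out_dir, "cohort")
  key <- object_md5(list(config$cohort, config$tile_size_px, config$master_seed))
  if (config$mode == "synthetic") {
    if (!stage_cached(out_dir, "simulate", key)) {
      t0 <- Sys.time(); gg_log("stage simulate: generating cohort")
      cc <- cohort_config(n_per_grade = unlist(config$cohort$n_per_grade),
                          tile_size_px = config$tile_size_px,
                          slide_tiles = config$cohort$slide_tiles,
                          profiles = config$cohort$profiles %||%
                            default_grade_profiles())
      generate_cohort(cc, master_seed = config$master_seed, out_dir = cohort_dir)
      stage_done(out_dir, "simulate", key)
      stages$simulate <- t_stage("simulate",
                                 file.path(cohort_dir, "manifest.csv"), t0)
    } else gg_log("stage simulate: cached")
  }
  cohort <- read_cohort(cohort_dir)

  ## -- features ------------------------------------------------------------
  features_csv <- file.path(out_dir, "features.csv")
  key <- object_md5(list(config$segmentation, config$features, config$roi,
                         config$tile_size_px,
                         unname(tools::md5sum(file.path(cohort_dir, "manifest.csv")))))
  if (!stage_cached(out_dir, "features", key) || !file.exists(features_csv)) {
    t0 <- Sys.time(); gg_log("stage features: extracting %d cases", nrow(cohort$cases))
    tab <- build_feature_table(cohort,
                               tile_size_px = config$tile_size_px,
                               roi_k = config$roi$k,
                               params = seg_params_from_config(config),
                               glcm_levels = config$features$glcm_levels,
                               glcm_distances = config$features$glcm_distances,
                               glcm_angles = config$features$glcm_angles,
                               out_csv = features_csv, verbose = verbose)
    if (length(attr(tab, "skipped"))) {
      jsonlite::write_json(attr(tab, "skipped"),
                           file.path(out_dir, "skipped_cases.json"),
                           auto_unbox = TRUE)
    }
    jsonlite::write_json(feature_ledger(),
                         file.path(out_dir, "feature_ledger.json"),
                         auto_unbox = TRUE)
    stage_done(out_dir, "features", key)
    stages$features <- t_stage("features", features_csv, t0)
  } else gg_log("stage features: cached")
  tab <- read_feature_table(features_csv)

  ## -- select --------------------------------------------------------------
  selected_json <- file.path(out_dir, "selected.json")
  selected_csv <- file.path(out_dir, "selected.csv")
  key <- object_md5(list(config$selection, config$master_seed,
                         unname(tools::md5sum(features_csv))))
  if (!stage_cached(out_dir, "select", key) || !file.exists(selected_csv)) {
    t0 <- Sys.time(); gg_log("stage select: backward elimination")
    sel <- select_paper_battery(tab, seed = derive_seed(config$master_seed, 101L),
                                visual_target = config$selection$visual_target,
                                subvisual_targets = unlist(config$selection$subvisual_targets),
                                drop_fraction = config$selection$drop_fraction,
                                cv_folds = config$selection$cv_folds,
                                num_trees = config$selection$num_trees)
    write_selection(sel, selected_json)
    write_feature_table(sel$model_table, selected_csv)
    stage_done(out_dir, "select", key)
    stages$select <- t_stage("select", c(selected_json, selected_csv), t0)
  } else gg_log("stage select: cached")
  model_tab <- read_feature_table(selected_csv)

  ## -- train ---------------------------------------------------------------
  metrics_json <- file.path(out_dir, "metrics.json")
  key <- object_md5(list(config$split, config$models, config$master_seed,
                         unname(tools::md5sum(selected_csv))))
  train_result <- NULL
  if (!stage_cached(out_dir, "train", key) || !file.exists(metrics_json)) {
    t0 <- Sys.time(); gg_log("stage train: %s", paste(config$models, collapse = ","))
    train_result <- train_stage(model_tab, config, out_dir, verbose)
    stage_done(out_dir, "train", key)
    stages$train <- t_stage("train", metrics_json, t0)
  } else gg_log("stage train: cached")
  if (is.null(train_result)) {
    train_result <- readRDS(file.path(out_dir, "train_result.rds"))
  }

  ## -- explain -------------------------------------------------------------
  explain_json <- file.path(out_dir, "explanations.json")
  t0 <- Sys.time(); gg_log("stage explain: representative cases")
  reports <- explain_stage(model_tab, train_result, config)
  write_explanations(reports, explain_json)
  stages$explain <- t_stage("explain", explain_json, t0)

  ## -- report --------------------------------------------------------------
  t0 <- Sys.time()
  report_files <- write_report(train_result$metrics, train_result$selection_info,
                               reports, out_dir,
                               external = train_result$external)
  stages$report <- t_stage("report", report_files, t0)

  manifest <- list(config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("gliograde")),
                   seed = config$master_seed,
                   stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

## Hold out `external_holdout` cases (stratified, proportional), run the
## repeated 75/25 evaluation on the remainder, then score the held-out
## cases with each repeat's refitted best model.
train_stage <- function(model_tab, config, out_dir, verbose = FALSE) {
  y <- factor(model_tab$grade)
  n_ext <- config$split$external_holdout %||% 0L
  ext_idx <- integer(0)
  if (n_ext > 0 && n_ext < nrow(model_tab)) {
    cnt <- table(y)
    per_class <- round(n_ext * cnt / sum(cnt))
    ext_idx <- with_seed(derive_seed(config$master_seed, 303L), {
      unlist(lapply(levels(y), function(lv)
        sample(which(y == lv), per_class[lv])))
    })
  }
  dev_tab <- if (length(ext_idx)) model_tab[-ext_idx, , drop = FALSE] else model_tab
  ext_tab <- if (length(ext_idx)) model_tab[ext_idx, , drop = FALSE] else NULL
  scheme <- split_scheme(train_fraction = config$split$train_fraction,
                         n_repeats = config$split$n_repeats,
                         master_seed = derive_seed(config$master_seed, 404L))
  feature_cols <- setdiff(colnames(model_tab),
                          c("case_id", "grade"))
  inner_folds <- config$split$inner_folds %||% 5L
  metrics <- evaluate(config$models, dev_tab, scheme,
                      feature_cols = feature_cols,
                      inner_folds = inner_folds, verbose = verbose)

  ## external validation: 30 held-out cases scored by a model refit on each
  ## repeat's training rows of the best family (by mean accuracy)
  best_fam <- names(metrics)[which.max(vapply(metrics, function(m)
    m$aggregate$mean[m$aggregate$metric == "accuracy"], numeric(1)))]
  external <- NULL
  final_model <- tune_and_train(model_spec(best_fam),
                                dev_tab[, feature_cols], factor(dev_tab$grade),
                                seed = derive_seed(config$master_seed, 505L))
  if (!is.null(ext_tab)) {
    splits <- make_splits(factor(dev_tab$grade), scheme)
    accs <- vapply(seq_along(splits), function(r) {
      m <- tune_and_train(model_spec(best_fam),
                          dev_tab[splits[[r]]$train, feature_cols],
                          factor(dev_tab$grade)[splits[[r]]$train],
                          seed = derive_seed(scheme$master_seed, 20000L + r))
      p <- stats::predict(m, ext_tab[, feature_cols])
      mean(attr(p, "class_pred") == ext_tab$grade)
    }, numeric(1))
    external <- list(family = best_fam, n_cases = nrow(ext_tab),
                     accuracy_mean = mean(accs), accuracy_sd = stats::sd(accs),
                     per_repeat = accs)
  }
  ## persist artifacts
  cmats <- lapply(metrics, `[[`, "confusion")
  for (fam in names(cmats)) {
    utils::write.csv(as.data.frame.matrix(cmats[[fam]]),
                     file.path(out_dir, sprintf("confusion_%s.csv", fam)))
  }
  predlog <- do.call(rbind, lapply(names(metrics), function(fam)
    cbind(family = fam, metrics[[fam]]$predictions)))
  utils::write.csv(predlog, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  agg <- lapply(metrics, function(m)
    list(aggregate = m$aggregate,
         per_grade_accuracy = as.list(m$per_grade_accuracy),
         confusion = as.data.frame.matrix(m$confusion)))
  jsonlite::write_json(list(models = agg, external = external,
                            best_family = best_fam),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- list(metrics = metrics, external = external, best_family = best_fam,
              final_model = final_model,
              selection_info = list(feature_cols = feature_cols))
  saveRDS(res, file.path(out_dir, "train_result.rds"))
  res
}

explain_stage <- function(model_tab, train_result, config) {
  per_grade <- config$explain$cases_per_grade %||% 1L
  ids <- unlist(lapply(grade_levels(), function(g) {
    utils::head(model_tab$case_id[model_tab$grade == g], per_grade)
  }))
  lapply(ids, function(id)
    explain_case(id, train_result$final_model, model_tab,
                 n = config$explain$n_samples, K = config$explain$K,
                 ridge = config$explain$ridge,
                 seed = derive_seed(config$master_seed, 606L)))
}

#' Write the human-readable and JSON run report
#'
#' Produces `report.md` (model comparison table as mean +/- SD, per-grade
#' accuracies, pooled confusion matrices, selected features, per-case
#' explanation summaries) and `report.json` with the same content. The
#' report is regenerable from cached stage outputs without recomputation.
#'
#' @param metrics Named list of `cv_metrics` from [evaluate()].
#' @param selections Selection info (list with `feature_cols`).
#' @param explanations List of `explanation_report`s.
#' @param out_dir Output directory.
#' @param external Optional external-validation summary.
#' @return Character vector of the files written.
#' @export
write_report <- function(metrics, selections, explanations, out_dir,
                         external = NULL) {
  md <- c("# Glioma grading run report", "")
  md <- c(md, "## Model comparison (mean ± SD over repeats)", "",
          "| model | F1 | accuracy | precision | recall |",
          "|-------|----|----------|-----------|--------|")
  fmt <- function(m, metric) {
    i <- match(metric, m$aggregate$metric)
    sprintf("%.2f ± %.2f", m$aggregate$mean[i], m$aggregate$sd[i])
  }
  for (fam in names(metrics)) {
    m <- metrics[[fam]]
    md <- c(md, sprintf("| %s | %s | %s | %s | %s |", fam,
                        fmt(m, "f1_macro"), fmt(m, "accuracy"),
                        fmt(m, "precision_macro"), fmt(m, "recall_macro")))
  }
  md <- c(md, "", "## Per-grade accuracy (pooled over repeats)", "")
  for (fam in names(metrics)) {
    pg <- metrics[[fam]]$per_grade_accuracy
    md <- c(md, sprintf("- %s: %s", fam,
                        paste(sprintf("%s = %.2f", names(pg), pg), collapse = ", ")))
  }
  md <- c(md, "", "## Confusion matrices (rows = true grade)", "")
  for (fam in names(metrics)) {
    cm <- metrics[[fam]]$confusion
    md <- c(md, sprintf("### %s", fam), "",
            paste("|  |", paste(colnames(cm), collapse = " | "), "|"),
            paste0("|", paste(rep("---", ncol(cm) + 1), collapse = "|"), "|"))
    for (r in rownames(cm)) {
      md <- c(md, paste("|", r, "|", paste(cm[r, ], collapse = " | "), "|"))
    }
    md <- c(md, "")
  }
  if (!is.null(external)) {
    md <- c(md, "## External validation", "",
            sprintf("%s on %d held-out cases: %.2f ± %.2f", external$family,
                    external$n_cases, external$accuracy_mean, external$accuracy_sd), "")
  }
  md <- c(md, "## Selected features", "",
          paste("-", selections$feature_cols), "")
  md <- c(md, "## Case explanations", "")
  for (r in explanations) {
    top <- r$per_class[[r$predicted_class]]
    ord <- order(-abs(top$contribution))[1:min(3, length(top$contribution))]
    md <- c(md, sprintf("- %s: predicted %s (p = %.2f); top contributors: %s",
                        r$case_id, r$predicted_class,
                        max(r$predicted_probs),
                        paste(sprintf("%s (%+.3f)", top$features[ord],
                                      top$contribution[ord]), collapse = ", ")))
  }
  md_file <- file.path(out_dir, "report.md")
  writeLines(md, md_file)
  json_file <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(models = lapply(metrics, function(m)
           list(aggregate = m$aggregate,
                per_grade_accuracy = as.list(m$per_grade_accuracy),
                confusion = as.data.frame.matrix(m$confusion))),
         external = external,
         selected_features = selections$feature_cols,
         explanations = lapply(explanations, function(r)
           list(case_id = r$case_id, predicted_class = r$predicted_class,
                predicted_probs = as.list(r$predicted_probs)))),
    json_file, auto_unbox = TRUE, digits = NA)
  c(md_file, json_file)
}
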