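#' Random-forest importance ranking
#'
#' Fits a random forest of `num_trees` trees on the given feature columns
#' (all rows) and returns mean-decrease-in-impurity (Gini) importances
#' normalized to sum to 1. Deterministic given `seed`.
#'
#' @param table Feature table with a `grade` factor column.
#' @param columns Character vector of feature columns to rank.
#' @param seed Integer seed.
#' @param num_trees Forest size (default 500).
#' @return `importance_ranking`: list with `scores` (named, sorted
#'   decreasing, sums to 1), `forest_size`, `seed`.
#' @export
rank_importance <- function(table, columns, seed = 1L, num_trees = 500L) {
  y <- droplevels(factor(table$grade))
  if (nlevels(y) < 2) stop("importance ranking requires >= 2 classes")
  if (length(columns) < 2) stop("importance ranking requires >= 2 features")
  x <- table[, columns, drop = FALSE]
  fit <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = num_trees))
  imp <- randomForest::importance(fit, type = 2)[, 1]
  total <- sum(imp)
  scores <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))
  names(scores) <- columns
  structure(list(scores = sort(scores, decreasing = TRUE),
                 forest_size = num_trees, seed = seed),
            class = "importance_ranking")
}

## Stratified k-fold assignment (1..k per row), deterministic given the RNG
## state of the caller.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

rf_cv_accuracy <- function(table, columns, cv_folds, num_trees) {
  y <- droplevels(factor(table$grade))
  folds <- stratified_folds(y, cv_folds)
  correct <- 0L
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    if (all(tr)) next
    fit <- randomForest::randomForest(x = table[tr, columns, drop = FALSE],
                                      y = y[tr], ntree = num_trees)
    pred <- stats::predict(fit, table[!tr, columns, drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Backward feature elimination guided by random-forest importance
#'
#' Iteratively ranks the surviving features with a random forest and drops
#' the least important `ceiling(drop_fraction * current)` of them (capped
#' so the count never falls below `target_count`), recording stratified
#' cross-validated accuracy per round. The surviving set is ordered by the
#' final round's importance.
#'
#' @inheritParams rank_importance
#' @param target_count Number of features to retain.
#' @param drop_fraction Fraction dropped per round (default 0.2).
#' @param cv_folds Folds for the per-round CV accuracy trace (default 5;
#'   `0` skips the trace accuracy, recorded as `NA`).
#' @return `selection_result`: list with `selected` (ordered names),
#'   `elimination_trace` (data.frame: round, n_features, cv_accuracy,
#'   dropped), `target_count`, `seed`.
#' @export
backward_eliminate <- function(table, columns, target_count,
                               drop_fraction = 0.2, cv_folds = 5L,
                               seed = 1L, num_trees = 500L) {
  stopifnot(target_count >= 1)
  if (target_count > length(columns)) {
    warning("target_count exceeds number of features; returning all columns")
    return(structure(list(selected = columns,
                          elimination_trace = data.frame(),
                          target_count = target_count, seed = seed),
                     class = "selection_result"))
  }
  current <- columns
  trace <- list()
  round_i <- 0L
  with_seed(seed, {
    while (length(current) > target_count) {
      round_i <- round_i + 1L
      rk <- rank_importance(table, current, seed = NULL, num_trees = num_trees)
      cv_acc <- if (cv_folds > 0)
        rf_cv_accuracy(table, current, cv_folds, num_trees) else NA_real_
      n_drop <- min(ceiling(drop_fraction * length(current)),
                    length(current) - target_count)
      dropped <- names(utils::tail(rk$scores, n_drop))
      current <- names(rk$scores)[seq_len(length(current) - n_drop)]
      trace[[round_i]] <- data.frame(round = round_i,
                                     n_features = length(current),
                                     cv_accuracy = cv_acc,
                                     dropped = paste(dropped, collapse = ";"))
    }
    final <- rank_importance(table, current, seed = NULL, num_trees = num_trees)
    structure(list(selected = names(final$scores),
                   elimination_trace = if (length(trace)) do.call(rbind, trace)
                                       else data.frame(),
                   target_count = target_count, seed = seed),
              class = "selection_result")
  })
}

## rank_importance with seed = NULL uses the ambient RNG stream (needed
## inside backward_eliminate's single seeded stream).

#' Select the standard grading battery (11 visual + 15 sub-visual + Ki-67)
#'
#' Applies random-forest backward elimination twice to the 171 sub-visual
#' features (171 -> `subvisual_stage1` -> 15 by default) and once to the 24
#' visual features (24 -> 11). Ki-67 is a fixed IHC covariate: it is always
#' retained and never enters elimination. The result is a 27-feature model
#' table.
#'
#' @inheritParams backward_eliminate
#' @param visual_target Visual features retained (default 11).
#' @param subvisual_targets Two-stage sub-visual targets (default `c(50, 15)`).
#' @return List with `visual_selected`, `subvisual_selected`, `selected`
#'   (visual + sub-visual + `ki67_pi`), `model_table` (case_id, grade, 27
#'   features), and the two `selection_result` traces.
#' @export
select_paper_battery <- function(table, seed = 1L, visual_target = 11L,
                                 subvisual_targets = c(50L, 15L),
                                 drop_fraction = 0.2, cv_folds = 5L,
                                 num_trees = 500L) {
  fn <- feature_names()
  stopifnot(all(c(fn$visual, fn$subvisual, fn$ki67) %in% colnames(table)))
  stage1 <- backward_eliminate(table, fn$subvisual, subvisual_targets[1],
                               drop_fraction, cv_folds,
                               seed = derive_seed(seed, 11L), num_trees = num_trees)
  stage2 <- backward_eliminate(table, stage1$selected, subvisual_targets[2],
                               drop_fraction, cv_folds,
                               seed = derive_seed(seed, 13L), num_trees = num_trees)
  vis <- backward_eliminate(table, fn$visual, visual_target,
                            drop_fraction, cv_folds,
                            seed = derive_seed(seed, 17L), num_trees = num_trees)
  selected <- c(vis$selected, stage2$selected, fn$ki67)
  list(visual_selected = vis$selected,
       subvisual_selected = stage2$selected,
       selected = selected,
       model_table = table[, c("case_id", "grade", selected)],
       visual_trace = vis, subvisual_traces = list(stage1, stage2))
}

#' Write a selection result (names + trace) as JSON
#' @param selection Output of [select_paper_battery()].
#' @param path JSON path.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(
    list(visual_selected = selection$visual_selected,
         subvisual_selected = selection$subvisual_selected,
         selected = selection$selected,
         visual_trace = selection$visual_trace$elimination_trace,
         subvisual_trace_1 = selection$subvisual_traces[[1]]$elimination_trace,
         subvisual_trace_2 = selection$subvisual_traces[[2]]$elimination_trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
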