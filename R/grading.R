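#' Split scheme for repeated stratified hold-out validation
#'
#' @param train_fraction Fraction of each class used for training
#'   (default 0.75).
#' @param n_repeats Number of repeated random splits (default 30).
#' @param stratified Stratify by grade (default TRUE).
#' @param master_seed Seed from which per-repeat seeds are derived.
#' @return A `split_scheme` list.
#' @export
split_scheme <- function(train_fraction = 0.75, n_repeats = 30L,
                         stratified = TRUE, master_seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1)
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 stratified = stratified,
                 master_seed = master_seed),
            class = "split_scheme")
}

#' Generate repeated stratified train/test splits
#'
#' Each repeat draws `round(train_fraction * n_c)` training cases per class
#' `c`, clamped to leave at least one case on each side (so e.g. 116 cases
#' split 39/36/41 give 29+27+31 = 87 training and 29 test cases); train and
#' test partition the cases. Per-repeat seeds are `master_seed + repeat`.
#'
#' @param labels Factor (or character) vector of class labels.
#' @param scheme A [split_scheme()].
#' @return List of `n_repeats` lists with integer `train` and `test`
#'   indices.
#' @export
make_splits <- function(labels, scheme = split_scheme()) {
  y <- factor(labels)
  cnt <- table(y)
  if (any(cnt < 2)) {
    stop("every class needs >= 2 cases; got: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  }
  lapply(seq_len(scheme$n_repeats), function(r) {
    with_seed(derive_seed(scheme$master_seed, r), {
      train <- integer(0)
      if (scheme$stratified) {
        for (lv in levels(y)) {
          idx <- which(y == lv)
          n_tr <- min(length(idx) - 1L,
                      max(1L, round(scheme$train_fraction * length(idx))))
          train <- c(train, sample(idx, n_tr))
        }
      } else {
        n_tr <- min(length(y) - 1L,
                    max(1L, round(scheme$train_fraction * length(y))))
        train <- sample(seq_along(y), n_tr)
      }
      train <- sort(train)
      list(train = train, test = setdiff(seq_along(y), train))
    })
  })
}

#' Model specification for one classifier family
#'
#' @param family `"SVM"`, `"RF"`, `"GBDT"` or `"NN"`.
#' @param grid Named list of hyperparameter candidate vectors; `NULL` uses
#'   the family's default grid (see [default_model_grids()]).
#' @param standardize Standardize features using training-set statistics
#'   (default TRUE).
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("SVM", "RF", "GBDT", "NN"),
                       grid = NULL, standardize = TRUE) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_model_grids()[[family]]
  stopifnot(length(grid) > 0, all(lengths(grid) > 0))
  structure(list(family = family, grid = grid, standardize = standardize),
            class = "model_spec")
}

#' Default hyperparameter grids
#'
#' Small, honest grids per family: SVM (RBF kernel) cost x gamma, random
#' forest trees x depth, gradient boosting learning rate x rounds, and a
#' one-hidden-layer neural network size x weight decay. `gamma = "scale"`
#' is `1 / (p * var(X))` on the (standardized) training matrix.
#'
#' @return Named list of grids.
#' @export
default_model_grids <- function() {
  list(SVM = list(cost = c(0.1, 1, 10, 100), gamma = c("scale", "0.01", "0.1")),
       RF = list(ntree = c(200, 500), depth = c(Inf, 10)),
       GBDT = list(eta = c(0.05, 0.1), nrounds = c(100, 300)),
       NN = list(size = c(16, 64), decay = c(1e-4, 1e-2)))
}

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$mean, scale = scaler$sd)
}

fit_one <- function(family, x, y, hp) {
  switch(family,
    SVM = {
      gamma <- if (identical(hp$gamma, "scale"))
        1 / (ncol(x) * stats::var(as.vector(x))) else as.numeric(hp$gamma)
      ## standardization is handled by the harness scaler; e1071's own
      ## scaling would divide by zero on within-fold-constant columns
      e1071::svm(x = x, y = y, kernel = "radial", cost = hp$cost,
                 gamma = gamma, probability = TRUE, scale = FALSE)
    },
    RF = {
      maxnodes <- if (is.finite(hp$depth)) min(2^hp$depth, nrow(x)) else NULL
      randomForest::randomForest(x = x, y = y, ntree = hp$ntree,
                                 maxnodes = maxnodes)
    },
    GBDT = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L, nthread = 1)
      xgboost::xgb.train(params = list(objective = "multi:softprob",
                                       num_class = nlevels(y),
                                       eta = hp$eta, max_depth = 3,
                                       nthread = 1,
                                       seed = sample.int(1e9, 1)),
                         data = dtrain, nrounds = hp$nrounds, verbose = 0)
    },
    NN = {
      nnet::nnet(x = x, y = stats::model.matrix(~ y - 1),
                 size = hp$size, decay = hp$decay, softmax = TRUE,
                 maxit = 200, trace = FALSE, MaxNWts = 10000)
    })
}

predict_probs <- function(family, fit, x, levels) {
  p <- switch(family,
    SVM = {
      ## pairwise-coupling probabilities; degenerate tiny training sets can
      ## break e1071's internal calibration, in which case fall back to a
      ## one-hot encoding of the predicted class
      pr <- tryCatch(stats::predict(fit, x, probability = TRUE),
                     error = function(e) NULL)
      if (!is.null(pr) && !is.null(attr(pr, "probabilities"))) {
        attr(pr, "probabilities")[, levels, drop = FALSE]
      } else {
        cls <- stats::predict(fit, x)
        m <- diag(length(levels))[match(as.character(cls), levels), ,
                                  drop = FALSE]
        colnames(m) <- levels
        m
      }
    },
    RF = stats::predict(fit, x, type = "prob")[, levels, drop = FALSE],
    GBDT = {
      pr <- stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
      m <- if (is.matrix(pr) && ncol(pr) == length(levels)) pr else
        matrix(pr, ncol = length(levels), byrow = TRUE)
      colnames(m) <- levels
      m
    },
    NN = {
      m <- stats::predict(fit, x, type = "raw")
      colnames(m) <- sub("^y", "", colnames(m))
      m[, levels, drop = FALSE]
    })
  p / rowSums(p)
}

#' Tune and train one classifier family
#'
#' Grid search over the family's hyperparameter grid with stratified
#' `inner_folds`-fold cross-validation on the training rows only, then a
#' refit of the best cell on all training rows. Feature standardization is
#' fitted on the training rows and stored for application at predict time,
#' so no test information leaks into training.
#'
#' @param spec A [model_spec()].
#' @param x Numeric training matrix (rows = cases).
#' @param y Factor of training labels.
#' @param inner_folds Inner CV folds (default 5).
#' @param seed Seed for fold assignment and stochastic learners.
#' @return A `graded_model`: list with `family`, `fit`, `scaler`,
#'   `best_params`, `cv_table` (per-cell inner accuracy), `levels`.
#' @export
tune_and_train <- function(spec, x, y, inner_folds = 5L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  y <- factor(y)
  scaler <- if (spec$standardize) fit_scaler(x) else
    list(mean = rep(0, ncol(x)), sd = rep(1, ncol(x)))
  xs <- apply_scaler(x, scaler)
  cells <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  with_seed(seed, {
    acc <- rep(NA_real_, nrow(cells))
    if (nrow(cells) > 1L) {
      folds <- stratified_folds(y, inner_folds)
      for (ci in seq_len(nrow(cells))) {
        hp <- as.list(cells[ci, , drop = FALSE])
        ok <- TRUE
        correct <- 0L
        for (f in seq_len(inner_folds)) {
          tr <- folds != f
          if (all(tr)) next   # fold can be empty when classes are tiny
          fit <- tryCatch(fit_one(spec$family, xs[tr, , drop = FALSE],
                                  droplevels(y[tr]), hp),
                          error = function(e) NULL)
          if (is.null(fit)) { ok <- FALSE; break }
          p <- predict_probs(spec$family, fit, xs[!tr, , drop = FALSE],
                             levels(droplevels(y[tr])))
          correct <- correct + sum(colnames(p)[max.col(p, "first")] == y[!tr])
        }
        acc[ci] <- if (ok) correct / length(y) else NA_real_
      }
      if (all(is.na(acc))) stop("all hyperparameter cells failed")
      best <- which.max(acc)
    } else {
      best <- 1L
    }
    hp <- as.list(cells[best, , drop = FALSE])
    fit <- fit_one(spec$family, xs, y, hp)
    structure(list(family = spec$family, fit = fit, scaler = scaler,
                   best_params = hp,
                   cv_table = cbind(cells, inner_cv_accuracy = acc),
                   levels = levels(y), feature_names = colnames(x)),
              class = "graded_model")
  })
}

#' Predict class probabilities with a tuned model
#' @param object A `graded_model` from [tune_and_train()].
#' @param newdata Numeric matrix/data.frame of features (original scale).
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1) with an attribute
#'   `"class"` holding the argmax labels.
#' @export
predict.graded_model <- function(object, newdata, ...) {
  x <- apply_scaler(as.matrix(newdata[, object$feature_names, drop = FALSE]),
                    object$scaler)
  p <- predict_probs(object$family, object$fit, x, object$levels)
  structure(p, class_pred = factor(object$levels[max.col(p, "first")],
                                   levels = object$levels))
}

#' Confusion matrix and derived metrics
#'
#' @param true,pred Factors (coerced) of true and predicted labels.
#' @param levels Class levels (default: union).
#' @return Integer matrix `levels x levels`, rows = true classes.
#' @export
confusion_matrix <- function(true, pred, levels = NULL) {
  if (is.null(levels)) levels <- union(levels(factor(true)), levels(factor(pred)))
  table(true = factor(true, levels), predicted = factor(pred, levels))
}

metrics_from_cm <- function(cm) {
  tp <- diag(cm)
  prec <- tp / colSums(cm)
  rec <- tp / rowSums(cm)
  f1 <- 2 * prec * rec / (prec + rec)
  f1[is.nan(f1)] <- 0
  wts <- rowSums(cm) / sum(cm)
  list(accuracy = sum(tp) / sum(cm),
       precision_macro = mean(prec, na.rm = TRUE),
       recall_macro = mean(rec, na.rm = TRUE),
       f1_macro = mean(f1, na.rm = TRUE),
       precision_weighted = sum(wts * ifelse(is.na(prec), 0, prec)),
       recall_weighted = sum(wts * ifelse(is.na(rec), 0, rec)),
       f1_weighted = sum(wts * f1))
}

#' Per-grade accuracy (class-conditional recall)
#'
#' The accuracy for each grade obtained by separating results by true
#' grade: `CM[g, g] / sum(CM[g, ])`. Empty rows give `NA` (reported as
#' missing, not 0).
#'
#' @param cm Square confusion matrix (rows = true classes).
#' @return Named numeric vector, one value per grade.
#' @export
per_grade_accuracy <- function(cm) {
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  rs <- rowSums(cm)
  out <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  stats::setNames(as.numeric(out), rownames(cm))
}

#' Evaluate classifier families under repeated stratified hold-out
#'
#' Reuses identical train/test partitions across families (paired
#' comparison). For each repeat, each family is tuned on the training rows
#' (inner stratified CV) and scored on the held-out rows; metrics are
#' aggregated as mean +/- SD over repeats, and confusion matrices are
#' pooled over repeats.
#'
#' @param specs List of [model_spec()]s (or family name strings).
#' @param table Feature table with `case_id`, `grade`, feature columns.
#' @param scheme A [split_scheme()].
#' @param feature_cols Feature columns (default: all numeric except labels).
#' @param inner_folds Inner tuning folds (default 5).
#' @param fit_fun Optional override `function(spec, x, y, seed)` returning
#'   an object with a `predict` method as in [tune_and_train()] (used to
#'   inject oracle/dummy classifiers in tests).
#' @param verbose Log per-repeat progress.
#' @return Named list (per family) of `cv_metrics`: `per_repeat`
#'   (data.frame of per-repeat metrics), `aggregate` (mean/sd), `confusion`
#'   (pooled matrix), `per_grade_accuracy` (from pooled matrix, plus
#'   per-repeat mean/sd), `predictions` (case_id, repeat, true, predicted,
#'   class probabilities).
#' @export
evaluate <- function(specs, table, scheme = split_scheme(),
                     feature_cols = NULL, inner_folds = 5L,
                     fit_fun = NULL, verbose = FALSE) {
  if (is.character(specs)) specs <- lapply(specs, model_spec)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- vapply(specs, function(s)
      if (inherits(s, "model_spec")) s$family else "custom", character(1))
  }
  y <- factor(table$grade)
  if (nlevels(droplevels(y)) < 3) stop("evaluation requires all 3 grades present")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(colnames(table)[vapply(table, is.numeric, logical(1))],
                            c())
  }
  x <- as.matrix(table[, feature_cols, drop = FALSE])
  splits <- make_splits(y, scheme)
  out <- list()
  for (fam in names(specs)) {
    per_rep <- vector("list", length(splits))
    preds <- vector("list", length(splits))
    pooled <- NULL
    for (r in seq_along(splits)) {
      sp <- splits[[r]]
      seed_r <- derive_seed(scheme$master_seed, 10000L * match(fam, names(specs)) + r)
      model <- if (is.null(fit_fun)) {
        tune_and_train(specs[[fam]], x[sp$train, , drop = FALSE], y[sp$train],
                       inner_folds = inner_folds, seed = seed_r)
      } else {
        fit_fun(specs[[fam]], x[sp$train, , drop = FALSE], y[sp$train], seed_r)
      }
      p <- stats::predict(model, x[sp$test, , drop = FALSE])
      cls <- attr(p, "class_pred")
      cm <- confusion_matrix(y[sp$test], cls, levels(y))
      pooled <- if (is.null(pooled)) cm else pooled + cm
      per_rep[[r]] <- data.frame(repeat_ = r, as.list(unlist(metrics_from_cm(cm))),
                                 t(per_grade_accuracy(cm)))
      preds[[r]] <- data.frame(case_id = table$case_id[sp$test], repeat_ = r,
                               true = y[sp$test], predicted = cls,
                               as.data.frame(unclass(p)))
      if (verbose) gg_log("evaluate: %s repeat %d/%d", fam, r, length(splits))
    }
    per_rep <- do.call(rbind, per_rep)
    metric_cols <- setdiff(colnames(per_rep), "repeat_")
    aggregate <- data.frame(metric = metric_cols,
                            mean = colMeans(per_rep[metric_cols], na.rm = TRUE),
                            sd = apply(per_rep[metric_cols], 2, stats::sd, na.rm = TRUE),
                            row.names = NULL)
    out[[fam]] <- structure(list(per_repeat = per_rep, aggregate = aggregate,
                                 confusion = pooled,
                                 per_grade_accuracy = per_grade_accuracy(pooled),
                                 predictions = do.call(rbind, preds)),
                            class = "cv_metrics")
  }
  out
}
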