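blob_table <- function(n_per_class = 25, sep = 5, seed = 1, p = 4) {
  withr::with_seed(seed, {
    g <- rep(1:3, each = n_per_class)
    x <- matrix(rnorm(length(g) * p), ncol = p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    x[, 1] <- x[, 1] + sep * g
    x[, 2] <- x[, 2] - sep * g
    data.frame(case_id = sprintf("c%03d", seq_along(g)),
               grade = factor(grade_levels()[g], grade_levels()), x,
               truth_code = g)
  })
}

test_that("stratified splits partition cases with the documented sizes", {
  y <- factor(rep(grade_levels(), c(39, 36, 41)))
  scheme <- split_scheme(master_seed = 3)
  expect_equal(scheme$n_repeats, 30L)
  expect_equal(scheme$train_fraction, 0.75)
  splits <- make_splits(y, scheme)
  expect_length(splits, 30)
  for (sp in splits) {
    expect_length(sp$train, 87)   # 29 + 27 + 31
    expect_length(sp$test, 29)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_along(y))
    # stratification: per-class train counts fixed
    expect_equal(as.vector(table(y[sp$train])), c(29, 27, 31))
  }
  # different repeats differ; same scheme reproduces identical splits
  expect_false(identical(splits[[1]]$train, splits[[2]]$train))
  expect_identical(make_splits(y, scheme), splits)
  expect_error(make_splits(factor(c("II", "III", "III", "IV", "IV")),
                           scheme), ">= 2 cases")
})

test_that("tuning obeys the argmax contract and a single cell is plain training", {
  tab <- blob_table()
  x <- as.matrix(tab[, paste0("f", 1:4)])
  m <- tune_and_train(model_spec("SVM"), x, tab$grade, seed = 2)
  cv <- m$cv_table$inner_cv_accuracy
  best_idx <- which(!is.na(cv) & cv == max(cv, na.rm = TRUE))
  expect_true(all(cv <= max(cv, na.rm = TRUE), na.rm = TRUE))
  expect_true(list(m$best_params)[[1]]$cost %in% m$cv_table$cost[best_idx])

  single <- tune_and_train(model_spec("SVM", grid = list(cost = 1, gamma = "scale")),
                           x, tab$grade, seed = 2)
  expect_equal(nrow(single$cv_table), 1)
  p <- predict(single, x)
  expect_equal(dim(unclass(p)), c(nrow(x), 3L))
  expect_equal(unname(rowSums(unclass(p))), rep(1, nrow(x)), tolerance = 1e-6)
})

test_that("all four families learn separable blobs", {
  tab <- blob_table(sep = 6)
  x <- as.matrix(tab[, paste0("f", 1:4)])
  split <- make_splits(tab$grade, split_scheme(n_repeats = 1, master_seed = 1))[[1]]
  for (fam in c("SVM", "RF", "GBDT", "NN")) {
    m <- tune_and_train(model_spec(fam), x[split$train, ], tab$grade[split$train],
                        seed = 3)
    p <- predict(m, x[split$test, ])
    acc <- mean(attr(p, "class_pred") == tab$grade[split$test])
    if (fam == "SVM") {
      expect_equal(acc, 1.0, label = "SVM accuracy")     # separable case
    } else {
      expect_gte(acc, 0.9)   # tree/net learners may clip one boundary case
    }
  }
})

test_that("standardization statistics come from training rows only", {
  tab <- blob_table()
  x <- as.matrix(tab[, paste0("f", 1:4)])
  tr <- 1:50
  m <- tune_and_train(model_spec("SVM", grid = list(cost = 1, gamma = "scale")),
                      x[tr, ], tab$grade[tr], seed = 1)
  expect_equal(unname(m$scaler$mean), unname(colMeans(x[tr, ])))
  # canary: shifting would-be test rows cannot change the fitted scaler
  x2 <- x
  x2[51:75, "f3"] <- x2[51:75, "f3"] + 1000
  m2 <- tune_and_train(model_spec("SVM", grid = list(cost = 1, gamma = "scale")),
                       x2[tr, ], tab$grade[tr], seed = 1)
  expect_equal(m2$scaler$mean, m$scaler$mean)
  expect_equal(m2$scaler$sd, m$scaler$sd)
})

test_that("per-grade accuracy is class-conditional recall", {
  cm <- matrix(c(8, 2, 0,
                 1, 7, 2,
                 0, 3, 9), 3, byrow = TRUE,
               dimnames = list(grade_levels(), grade_levels()))
  pg <- per_grade_accuracy(cm)
  expect_equal(unname(pg), c(0.8, 0.7, 0.75))
  diagm <- diag(c(5, 5, 5)); dimnames(diagm) <- dimnames(cm)
  expect_equal(unname(per_grade_accuracy(diagm)), c(1, 1, 1))
  empty_row <- cm; empty_row[2, ] <- 0
  expect_true(is.na(per_grade_accuracy(empty_row)[2]))
})

test_that("an oracle classifier scores perfectly and a dummy scores the class share", {
  tab <- blob_table(n_per_class = 20)
  scheme <- split_scheme(n_repeats = 5, master_seed = 7)
  oracle_fit <- function(spec, x, y, seed) {
    structure(list(levels = levels(y)), class = "test_oracle")
  }
  .S3method("predict", "test_oracle", function(object, newdata, ...) {
    cls <- factor(object$levels[newdata[, "truth_code"]], object$levels)
    p <- diag(3)[as.integer(cls), , drop = FALSE]
    colnames(p) <- object$levels
    structure(p, class_pred = cls)
  })
  res <- evaluate(list(ORACLE = model_spec("SVM")), tab, scheme,
                  fit_fun = oracle_fit)$ORACLE
  agg <- res$aggregate
  for (metric in c("accuracy", "precision_macro", "recall_macro", "f1_macro")) {
    expect_equal(agg$mean[agg$metric == metric], 1.0)
  }
  expect_equal(unname(res$per_grade_accuracy), c(1, 1, 1))
  expect_true(all(res$confusion == diag(diag(res$confusion))))

  dummy_fit <- function(spec, x, y, seed) {
    structure(list(levels = levels(y)), class = "test_dummy")
  }
  .S3method("predict", "test_dummy", function(object, newdata, ...) {
    cls <- factor(rep("IV", nrow(newdata)), object$levels)
    p <- matrix(rep(c(0, 0, 1), each = nrow(newdata)), ncol = 3,
                dimnames = list(NULL, object$levels))
    structure(p, class_pred = cls)
  })
  res_d <- evaluate(list(DUMMY = model_spec("SVM")), tab, scheme,
                    fit_fun = dummy_fit)$DUMMY
  # 5 test cases per class each repeat -> accuracy exactly one third
  expect_equal(res_d$aggregate$mean[res_d$aggregate$metric == "accuracy"],
               1 / 3, tolerance = 1e-9)
})

test_that("confusion matrices conserve cases and pair identical splits", {
  tab <- blob_table(n_per_class = 15, sep = 2)
  scheme <- split_scheme(n_repeats = 3, master_seed = 5)
  res <- evaluate(c("RF", "GBDT"), tab, scheme,
                  feature_cols = paste0("f", 1:4), inner_folds = 3)
  splits <- make_splits(tab$grade, scheme)
  test_counts <- table(tab$grade[unlist(lapply(splits, `[[`, "test"))])
  for (fam in names(res)) {
    cm <- res[[fam]]$confusion
    # row sums equal the true class counts pooled over repeats
    expect_equal(as.vector(rowSums(cm)), as.vector(test_counts))
    expect_equal(sum(cm), length(unlist(lapply(splits, `[[`, "test"))))
  }
  # paired comparison: both families scored the same cases per repeat
  p1 <- res$RF$predictions; p2 <- res$GBDT$predictions
  expect_equal(p1[, c("case_id", "repeat_", "true")],
               p2[, c("case_id", "repeat_", "true")], ignore_attr = TRUE)
  # macro F1 is recomputable from the stored confusion matrix
  m <- gliograde:::metrics_from_cm(res$RF$confusion)
  prec <- diag(res$RF$confusion) / colSums(res$RF$confusion)
  rec <- diag(res$RF$confusion) / rowSums(res$RF$confusion)
  f1 <- 2 * prec * rec / (prec + rec); f1[is.nan(f1)] <- 0
  expect_equal(m$f1_macro, mean(f1, na.rm = TRUE))
})
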