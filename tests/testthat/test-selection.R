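make_planted_table <- function(n_per_class = 40, n_noise = 9, effect = 2,
                               seed = 1) {
  withr::with_seed(seed, {
    g <- rep(1:3, each = n_per_class)
    n <- length(g)
    x <- matrix(rnorm(n * (n_noise + 1)), n)
    colnames(x) <- c("signal", paste0("noise", seq_len(n_noise)))
    x[, "signal"] <- x[, "signal"] + effect * g
    data.frame(grade = factor(grade_levels()[g], grade_levels()), x)
  })
}

test_that("importance ranking is normalized, deterministic, and finds signal", {
  tab <- make_planted_table()
  cols <- setdiff(colnames(tab), "grade")
  r1 <- rank_importance(tab, cols, seed = 5)
  r2 <- rank_importance(tab, cols, seed = 5)
  expect_equal(r1$scores, r2$scores)
  expect_equal(sum(r1$scores), 1, tolerance = 1e-9)
  expect_true(all(r1$scores >= 0))
  expect_equal(names(r1$scores)[1], "signal")

  expect_error(rank_importance(tab[tab$grade == "II", ], cols), "2 classes")
  expect_error(rank_importance(tab, "signal"), "2 features")
})

test_that("a planted informative feature ranks first in almost all runs", {
  hits <- vapply(1:100, function(s) {
    tab <- make_planted_table(n_per_class = 30, seed = s)
    cols <- setdiff(colnames(tab), "grade")
    rk <- rank_importance(tab, cols, seed = s, num_trees = 200)
    names(rk$scores)[1] == "signal"
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("duplicating a feature splits its importance between the copies", {
  splits <- sapply(1:5, function(s) {
    tab <- make_planted_table(n_per_class = 60, effect = 2, seed = s)
    cols <- setdiff(colnames(tab), "grade")
    base <- rank_importance(tab, cols, seed = s, num_trees = 500)
    tab2 <- tab
    tab2$signal_copy <- tab2$signal
    dup <- rank_importance(tab2, c(cols, "signal_copy"), seed = s,
                           num_trees = 500)
    noise_max <- max(dup$scores[grep("^noise", names(dup$scores))])
    c(single = unname(base$scores["signal"]),
      copy1 = unname(dup$scores["signal"]),
      copy2 = unname(dup$scores["signal_copy"]),
      noise_max = noise_max)
  })
  m <- rowMeans(splits)
  # each copy carries clearly less than the undivided original ...
  expect_lt(m["copy1"], 0.8 * m["single"])
  expect_lt(m["copy2"], 0.8 * m["single"])
  # ... the split is roughly even between identical copies ...
  expect_lt(max(m["copy1"], m["copy2"]) / min(m["copy1"], m["copy2"]), 1.5)
  # ... and both copies still dominate every noise feature
  expect_true(all(splits["copy1", ] > splits["noise_max", ]))
  expect_true(all(splits["copy2", ] > splits["noise_max", ]))
})

test_that("backward elimination reaches the target with a monotone trace", {
  tab <- make_planted_table(n_per_class = 25, n_noise = 19)
  cols <- setdiff(colnames(tab), "grade")
  sel <- backward_eliminate(tab, cols, target_count = 5, cv_folds = 2,
                            seed = 2, num_trees = 100)
  expect_length(sel$selected, 5)
  expect_true("signal" %in% sel$selected)
  tr <- sel$elimination_trace
  expect_true(all(diff(tr$n_features) < 0))
  expect_equal(tr$n_features[nrow(tr)], 5)
  expect_true(all(tr$cv_accuracy >= 0 & tr$cv_accuracy <= 1))

  # identity selection: target equals input size
  ident <- backward_eliminate(tab, cols, target_count = length(cols),
                              cv_folds = 0, seed = 2, num_trees = 50)
  expect_setequal(ident$selected, cols)
  expect_equal(nrow(ident$elimination_trace), 0)

  # over-large target returns everything with a warning
  expect_warning(over <- backward_eliminate(tab, cols, target_count = 99,
                                            seed = 1),
                 "returning all")
  expect_equal(over$selected, cols)
})

test_that("elimination is deterministic and stable across seeds", {
  tab <- fake_feature_table(n_per_grade = 20, effect = 2.5)
  fn <- feature_names()
  s1 <- backward_eliminate(tab, fn$visual, 11, cv_folds = 0, seed = 4,
                           num_trees = 150)
  s2 <- backward_eliminate(tab, fn$visual, 11, cv_folds = 0, seed = 4,
                           num_trees = 150)
  expect_identical(s1$selected, s2$selected)

  # Jaccard overlap of selected sets across seeds (strong planted effects)
  sets <- lapply(1:10, function(s)
    backward_eliminate(tab, fn$visual, 11, cv_folds = 0, seed = s,
                       num_trees = 150)$selected)
  jac <- combn(10, 2, function(ij)
    length(intersect(sets[[ij[1]]], sets[[ij[2]]])) /
      length(union(sets[[ij[1]]], sets[[ij[2]]])))
  expect_gte(mean(jac), 0.6)
})

test_that("the standard battery selection returns 11 + 15 + Ki-67", {
  tab <- fake_feature_table(n_per_grade = 20, effect = 2)
  sel <- select_paper_battery(tab, seed = 9, cv_folds = 0, num_trees = 100)
  expect_length(sel$visual_selected, 11)
  expect_length(sel$subvisual_selected, 15)
  expect_true(all(sel$visual_selected %in% feature_names()$visual))
  expect_true(all(sel$subvisual_selected %in% feature_names()$subvisual))
  # Ki-67 is retained unconditionally, and the model table is 27 + labels
  expect_true("ki67_pi" %in% sel$selected)
  expect_length(sel$selected, 27)
  expect_equal(ncol(sel$model_table), 29)
  # two-stage sub-visual trace: first stage ends at the intermediate size
  tr1 <- sel$subvisual_traces[[1]]$elimination_trace
  expect_equal(tr1$n_features[nrow(tr1)], 50)
})

test_that("Ki-67 is retained even when it carries no class signal", {
  tab <- fake_feature_table(n_per_grade = 15, effect = 2.5)
  withr::with_seed(1, tab$ki67_pi <- rnorm(nrow(tab)))  # pure noise
  sel <- select_paper_battery(tab, seed = 2, cv_folds = 0, num_trees = 80)
  expect_true("ki67_pi" %in% colnames(sel$model_table))
})
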