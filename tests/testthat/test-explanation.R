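linear_predictor <- function(beta, intercept = 0.2) {
  function(Z) cbind(target = drop(Z %*% beta) + intercept)
}

test_that("perturbation sampling centres on the training distribution", {
  p <- 6
  case <- stats::setNames(rnorm(p), paste0("x", seq_len(p)))
  s <- sample_perturbations(case, n = 50000,
                            predict_fun = linear_predictor(rep(1, p)),
                            seed = 3)
  # sample 1 is the case itself, with unit weight
  expect_equal(unname(s$X[1, ]), unname(case))
  expect_equal(s$weights[1], 1)
  # weights decrease monotonically with distance to the case
  d <- sqrt(rowSums(sweep(s$X, 2, case)^2))
  ord <- order(d)
  expect_true(all(diff(s$weights[ord]) <= 1e-12))
  expect_true(all(s$weights > 0 & s$weights <= 1))
  # feature means ~ 0 in standardized space (law of large numbers)
  expect_true(all(abs(colMeans(s$X)) < 0.02))
  expect_error(sample_perturbations(case, n = 10, linear_predictor(rep(1, p))),
               "n >= 100")
  # zero-variance features are frozen at the case value
  expect_warning(
    sf <- sample_perturbations(case, n = 200, linear_predictor(rep(1, p)),
                               train_sd = c(0, rep(1, p - 1)), seed = 1),
    "zero-variance")
  expect_true(all(sf$X[, 1] == case[1]))
})

test_that("the surrogate recovers a linear model's coefficients", {
  beta <- c(2, -1, 0.5, 0, 1, -2)
  case <- stats::setNames(rnorm(length(beta)), paste0("x", seq_along(beta)))
  s <- sample_perturbations(case, n = 20000, linear_predictor(beta), seed = 11)
  fit <- fit_local_surrogate(s, "target", K = 8)
  got <- fit$coef[paste0("x", seq_along(beta))]
  got[is.na(got)] <- 0  # a zero-coefficient feature may not be screened in
  cosine <- sum(got * beta) / sqrt(sum(got^2) * sum(beta^2))
  expect_gte(cosine, 0.98)
  # per-coefficient relative error within 5% on the non-null features
  for (j in which(beta != 0)) {
    expect_equal(unname(got[j]), beta[j], tolerance = 0.05)
  }
  expect_gte(fit$r2_weighted, 0.99)
})

test_that("a constant-output model yields null contributions", {
  case <- stats::setNames(rnorm(4), paste0("x", 1:4))
  s <- sample_perturbations(case, n = 2000,
                            function(Z) cbind(target = rep(0.5, nrow(Z))),
                            seed = 2)
  fit <- fit_local_surrogate(s, "target")
  expect_true(all(abs(fit$coef) < 1e-6))
  expect_true(all(abs(fit$contribution) < 1e-6))
})

test_that("flipping a feature's effect flips the sign of its contribution", {
  beta <- c(1.5, -0.8, 0.3)
  case <- stats::setNames(c(0.5, -1, 2), paste0("x", 1:3))
  s1 <- sample_perturbations(case, n = 5000, linear_predictor(beta), seed = 4)
  f1 <- fit_local_surrogate(s1, "target")
  beta2 <- beta * c(-1, 1, 1)
  s2 <- sample_perturbations(case, n = 5000, linear_predictor(beta2), seed = 4)
  f2 <- fit_local_surrogate(s2, "target")
  expect_lt(f1$coef["x1"] * f2$coef["x1"], 0)
  expect_equal(unname(f1$coef["x2"]), unname(f2$coef["x2"]), tolerance = 0.05)
})

test_that("explanations are deterministic and stable across seeds", {
  beta <- c(2, -1, 0.5, 1)
  case <- stats::setNames(rnorm(4), paste0("x", 1:4))
  s1 <- sample_perturbations(case, n = 5000, linear_predictor(beta), seed = 9)
  s1b <- sample_perturbations(case, n = 5000, linear_predictor(beta), seed = 9)
  expect_identical(s1$X, s1b$X)
  f1 <- fit_local_surrogate(s1, "target")
  f1b <- fit_local_surrogate(s1b, "target")
  expect_identical(f1$coef, f1b$coef)
  # two different seeds agree within 10% of the largest contribution
  s2 <- sample_perturbations(case, n = 5000, linear_predictor(beta), seed = 10)
  f2 <- fit_local_surrogate(s2, "target")
  diffs <- abs(f1$coef[names(f2$coef)] - f2$coef)
  expect_lt(mean(diffs, na.rm = TRUE), 0.1 * max(abs(f1$coef)))
})

test_that("locality: a shrinking kernel tracks the local piece of a kinked model", {
  # piecewise-linear in x1: slope +2 left of the case, slope -2 far right
  pw <- function(Z) cbind(target = ifelse(Z[, 1] < 1.5, 2 * Z[, 1],
                                          6 - 2 * Z[, 1]))
  case <- stats::setNames(c(0, 0), c("x1", "x2"))  # sits on the +2 piece
  s_wide <- sample_perturbations(case, n = 20000, pw, sigma = 5, seed = 6)
  s_narrow <- sample_perturbations(case, n = 20000, pw, sigma = 0.5, seed = 6)
  f_wide <- fit_local_surrogate(s_wide, "target", K = 2)
  f_narrow <- fit_local_surrogate(s_narrow, "target", K = 2)
  # the narrow kernel recovers the local gradient much more faithfully
  expect_equal(unname(f_narrow$coef["x1"]), 2, tolerance = 0.05)
  expect_gt(abs(f_wide$coef["x1"] - 2), abs(f_narrow$coef["x1"] - 2))
})

test_that("explaining a fitted grader produces per-class reports", {
  tab <- fake_feature_table(n_per_grade = 15, effect = 2.5, seed = 3)
  feats <- setdiff(colnames(tab), c("case_id", "grade"))[c(1:10, 196)]
  m <- tune_and_train(model_spec("SVM", grid = list(cost = 1, gamma = "scale")),
                      as.matrix(tab[, feats]), tab$grade, seed = 1)
  rep1 <- explain_case(tab$case_id[1], m, tab, n = 800, seed = 5)
  expect_named(rep1$per_class, grade_levels())
  expect_equal(sum(rep1$predicted_probs), 1, tolerance = 1e-6)
  expect_length(rep1$per_class$II$coef, 8)
  rep2 <- explain_case(tab$case_id[1], m, tab, n = 800, seed = 5)
  expect_equal(rep1$per_class$II$coef, rep2$per_class$II$coef)
  expect_error(explain_case("nope", m, tab), "unknown case_id")
  # report is serializable
  f <- withr::local_tempfile(fileext = ".json")
  write_explanations(rep1, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})

test_that("a planted low-Ki-67 grade II case is explained by Ki-67", {
  # model: P(II) driven down by ki67 (the planted cohort signal)
  tab <- fake_feature_table(n_per_grade = 20, effect = 2, seed = 8)
  feats <- c("nuclei_count", "mean_area", "ki67_pi")
  m <- tune_and_train(model_spec("SVM", grid = list(cost = 10, gamma = "scale")),
                      as.matrix(tab[, feats]), tab$grade, seed = 2)
  # the most II-typical case: lowest Ki-67 among grade II
  ii <- tab[tab$grade == "II", ]
  easy <- ii$case_id[which.min(ii$ki67_pi)]
  hits <- vapply(1:20, function(s) {
    r <- explain_case(easy, m, tab, n = 2000, seed = s)
    f <- r$per_class$II
    top3 <- names(sort(f$contribution[f$contribution > 0], decreasing = TRUE))[1:3]
    "ki67_pi" %in% top3
  }, logical(1))
  expect_gte(sum(hits), 18)
})
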