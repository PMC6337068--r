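#' Sample perturbations around a case for local explanation
#'
#' Draws `n` perturbation samples in standardized feature space: each
#' feature is resampled independently from the training distribution
#' (standard normal after standardization); the case itself is included as
#' sample 1 with kernel weight 1. Proximity weights are
#' `exp(-d^2 / sigma^2)` with `d` the Euclidean distance to the case.
#' Zero-variance training features are held fixed at the case value (with
#' a warning).
#'
#' @param case Named numeric vector: the case in standardized space.
#' @param n Number of samples (`>= 100`; default 5000).
#' @param predict_fun Function mapping a numeric matrix (standardized
#'   space) to a matrix of per-class model outputs (e.g. probabilities).
#' @param sigma Kernel width; default `0.75 * sqrt(p)` with `p` features.
#' @param train_sd Per-feature training SDs in standardized space
#'   (default 1); features with `train_sd == 0` are frozen.
#' @param seed Integer seed.
#' @return `perturbation_samples`: list with `X` (n x p), `weights`
#'   (in (0, 1]), `probs` (n x classes), `case`, `sigma`.
#' @export
sample_perturbations <- function(case, n = 5000L, predict_fun,
                                 sigma = NULL, train_sd = NULL, seed = 1L) {
  stopifnot(n >= 100)
  p <- length(case)
  if (is.null(sigma)) sigma <- 0.75 * sqrt(p)
  if (is.null(train_sd)) train_sd <- rep(1, p)
  frozen <- train_sd == 0
  if (any(frozen)) {
    warning("zero-variance feature(s) held fixed at case value: ",
            paste(names(case)[frozen], collapse = ", "))
  }
  X <- with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    X[, frozen] <- matrix(case[frozen], n, sum(frozen), byrow = TRUE)
    X[1, ] <- case
    X
  })
  colnames(X) <- names(case)
  d2 <- rowSums(sweep(X, 2, case)^2)
  w <- exp(-d2 / sigma^2)
  probs <- as.matrix(predict_fun(X))
  structure(list(X = X, weights = w, probs = probs, case = case,
                 sigma = sigma, seed = seed),
            class = "perturbation_samples")
}

weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(0)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Fit a sparse local linear surrogate
#'
#' Screens the features to the `K` largest absolute weighted correlations
#' with the target-class model output, then fits a weighted ridge
#' regression (penalty on slopes only, intercept free) of the target
#' output on the screened features. Coefficients are the signed local
#' feature effects; `contribution = coef * case value` gives the signed
#' per-case contribution. If the penalized system is singular the penalty
#' is increased tenfold and the fit retried once.
#'
#' @param samples A `perturbation_samples` object.
#' @param target_class Column (index or name) of `samples$probs` to explain.
#' @param K Number of features kept (default 8).
#' @param ridge Ridge penalty (default 1).
#' @return `explanation_fit`: list with `features`, `coef` (named),
#'   `contribution` (coef x case value), `intercept`, `r2_weighted`,
#'   `target_class`, `n_samples`, `seed`.
#' @export
fit_local_surrogate <- function(samples, target_class, K = 8L, ridge = 1.0) {
  X <- samples$X; w <- samples$weights
  y <- samples$probs[, target_class]
  p <- ncol(X)
  cors <- vapply(seq_len(p), function(j) weighted_cor(X[, j], y, w), numeric(1))
  keep <- order(-abs(cors))[seq_len(min(K, p))]
  Xk <- cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])
  pen <- diag(c(0, rep(1, length(keep))))
  XtW <- t(Xk * w)
  beta <- NULL
  lambda <- ridge
  for (attempt in 1:2) {
    beta <- tryCatch(solve(XtW %*% Xk + lambda * pen, XtW %*% y),
                     error = function(e) NULL)
    if (!is.null(beta)) break
    lambda <- lambda * 10
  }
  if (is.null(beta)) stop("singular local design even after penalty increase")
  beta <- drop(beta)
  yhat <- drop(Xk %*% beta)
  wbar <- w / sum(w)
  ssr <- sum(wbar * (y - yhat)^2)
  sst <- sum(wbar * (y - sum(wbar * y))^2)
  cf <- stats::setNames(beta[-1], colnames(X)[keep])
  structure(list(features = colnames(X)[keep],
                 coef = cf,
                 contribution = cf * samples$case[keep],
                 intercept = beta[1],
                 r2_weighted = if (sst > 0) 1 - ssr / sst else 1,
                 target_class = target_class,
                 n_samples = nrow(X), seed = samples$seed),
            class = "explanation_fit")
}

#' Explain one case's grading decision
#'
#' Builds a local surrogate explanation of a fitted grading model for one
#' case: the case is standardized with the model's training scaler,
#' perturbation samples are drawn around it, and one sparse weighted-ridge
#' surrogate per grade is fitted to the model's class probabilities. All
#' feature types (visual, sub-visual, Ki-67) are eligible.
#'
#' @param case_id Case identifier present in `table`.
#' @param model A `graded_model` from [tune_and_train()].
#' @param table Feature table containing the case row.
#' @param n Perturbation samples (default 5000).
#' @param K Features per explanation (default 8).
#' @param ridge Ridge penalty (default 1).
#' @param sigma Kernel width (default `0.75 * sqrt(p)`).
#' @param seed Integer seed.
#' @return `explanation_report`: list with `case_id`, `predicted_probs`
#'   (the model's probability vector for the case), `predicted_class`, and
#'   `per_class` (named list of `explanation_fit`s, one per grade).
#' @export
explain_case <- function(case_id, model, table, n = 5000L, K = 8L,
                         ridge = 1.0, sigma = NULL, seed = 1L) {
  row <- which(table$case_id == case_id)
  if (length(row) != 1L) stop("unknown case_id: ", case_id)
  x <- as.numeric(table[row, model$feature_names])
  names(x) <- model$feature_names
  case_std <- drop(apply_scaler(matrix(x, 1), model$scaler))
  names(case_std) <- model$feature_names
  predict_fun <- function(Z) {
    orig <- sweep(sweep(Z, 2, model$scaler$sd, `*`), 2, model$scaler$mean, `+`)
    colnames(orig) <- model$feature_names
    unclass(stats::predict(model, orig))
  }
  samples <- sample_perturbations(case_std, n = n, predict_fun = predict_fun,
                                  sigma = sigma, seed = seed)
  fits <- lapply(stats::setNames(model$levels, model$levels), function(cl)
    fit_local_surrogate(samples, cl, K = K, ridge = ridge))
  probs <- drop(samples$probs[1, ])
  names(probs) <- colnames(samples$probs)
  structure(list(case_id = case_id,
                 predicted_probs = probs,
                 predicted_class = names(probs)[which.max(probs)],
                 per_class = fits,
                 n_samples = n, seed = seed),
            class = "explanation_report")
}

#' @export
print.explanation_report <- function(x, ...) {
  cat(sprintf("Explanation for %s (predicted %s)\n", x$case_id, x$predicted_class))
  cat("  P(grade):", paste(sprintf("%s=%.3f", names(x$predicted_probs),
                                   x$predicted_probs), collapse = "  "), "\n")
  for (cl in names(x$per_class)) {
    f <- x$per_class[[cl]]
    ord <- order(-abs(f$contribution))
    cat(sprintf("  grade %s (local R2 %.2f):\n", cl, f$r2_weighted))
    for (i in ord) {
      cat(sprintf("    %+8.4f  %s\n", f$contribution[i], f$features[i]))
    }
  }
  invisible(x)
}

#' Write explanation reports as JSON
#' @param reports List of `explanation_report`s (or a single one).
#' @param path JSON path.
#' @export
write_explanations <- function(reports, path) {
  if (inherits(reports, "explanation_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) {
    list(case_id = r$case_id,
         predicted_probs = as.list(r$predicted_probs),
         predicted_class = r$predicted_class,
         per_class = lapply(r$per_class, function(f)
           list(features = f$features, coef = as.list(f$coef),
                contribution = as.list(f$contribution),
                intercept = f$intercept, r2_weighted = f$r2_weighted)),
         n_samples = r$n_samples, seed = r$seed)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
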