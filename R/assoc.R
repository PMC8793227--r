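#' McFadden pseudo-R-squared
#'
#' `1 - model_loglik / null_loglik` for a fitted logistic model against the
#' intercept-only model.
#'
#' @param model_loglik log-likelihood of the fitted model (must be >= the
#'   null's and negative or zero).
#' @param null_loglik log-likelihood of the intercept-only model (< 0).
#' @return value in [0, 1).
#' @export
mcfadden_r2 <- function(model_loglik, null_loglik) {
  if (null_loglik >= 0 || model_loglik > 0)
    stop("log-likelihoods must be negative")
  if (model_loglik < null_loglik - 1e-8)
    stop("model log-likelihood below the null's")
  1 - model_loglik / null_loglik
}

#' PRS-phenotype association model
#'
#' Logistic regression of comorbidity status on the standardized PRS,
#' either unadjusted (`status ~ PRS`) or adjusted for sex, age, marital
#' status and disease subtype (`status ~ PRS + covariates`). Reports the
#' PRS log odds ratio (per SD of the score), Wald SE and P, and McFadden
#' pseudo-R-squared against the intercept-only model.
#'
#' @param prs standardized PRS vector aligned to `cohort` rows.
#' @param cohort a `cohort_table`.
#' @param adjusted include the demographic covariates (default FALSE).
#' @return one-row data.frame: model, log_or, se, p, r2, n, converged.
#' @export
fit_prs_association <- function(prs, cohort, adjusted = FALSE) {
  y <- cohort$pc_status
  df <- data.frame(y = y, prs = prs)
  if (adjusted) {
    covars <- covariate_design(cohort, n_mds = 0)
    keep <- apply(covars, 2, function(v) stats::var(v) > 0)
    df <- cbind(df, as.data.frame(covars[, keep, drop = FALSE]))
  }
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  null <- stats::glm(y ~ 1, family = stats::binomial())
  cf <- summary(fit)$coefficients
  sep <- any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8)
  data.frame(model = if (adjusted) "adjusted" else "unadjusted",
             log_or = cf["prs", 1], se = cf["prs", 2],
             p = cf["prs", 4],
             r2 = mcfadden_r2(as.numeric(stats::logLik(fit)),
                              as.numeric(stats::logLik(null))),
             n = length(y), converged = fit$converged && !sep,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney concordance probability (probability that a
#' random case scores above a random control, ties counting one half),
#' computed from ranks. ROC points are given at every distinct score
#' threshold.
#'
#' @param scores numeric predictor (higher = more case-like).
#' @param labels 0/1 class labels; both classes must be present.
#' @return list: `auc`, `points` (data.frame threshold, fpr, tpr).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0) / n0, tpr = sum(pred & labels == 1) / n1)
  }, numeric(2)))
  list(auc = auc,
       points = rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
                      data.frame(threshold = thr, fpr = pts[, "fpr"],
                                 tpr = pts[, "tpr"])))
}

# Stratified k-fold assignment: shuffles within each class and deals folds
# round-robin so the case fraction is preserved.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated prediction of comorbidity status
#'
#' Stratified k-fold cross-validation of either a logistic regression or a
#' linear-kernel support vector machine (cost 1, features standardized by
#' the fitter). Each held-out individual receives exactly one out-of-fold
#' score (class probability for logistic, signed margin distance for the
#' SVM); the ROC/AUC is computed on the pooled out-of-fold scores.
#'
#' @param features numeric matrix or data.frame of predictors (e.g.
#'   standardized PRS alone, or PRS plus the covariate design).
#' @param pc_status 0/1 outcome.
#' @param model `"logistic"` or `"svm"` (linear kernel).
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return list of class `prediction_result`: `auc`, `roc` (points),
#'   `oof_scores`, `fold`, `model`, `k`, `seed`.
#' @export
crossval_predict <- function(features, pc_status, model = c("logistic", "svm"),
                             k = 10, seed = 1) {
  model <- match.arg(model)
  X <- as.matrix(features)
  y <- as.integer(pc_status)
  if (length(y) < k) stop("n must be at least k")
  fold <- stratified_folds(y, k, seed)
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2)) {
    fold <- stratified_folds(y, k, seed + 1)
    if (any(tapply(y, fold, function(v) length(unique(v))) < 2))
      stop("a fold lost a class twice; reduce k")
  }
  oof <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (model == "logistic") {
      dtr <- data.frame(y = y[tr], X[tr, , drop = FALSE])
      fit <- stats::glm(y ~ ., data = dtr, family = stats::binomial())
      oof[te] <- stats::predict(fit, data.frame(X[te, , drop = FALSE]),
                                type = "response")
    } else {
      fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr], levels = 0:1),
                        kernel = "linear", cost = 1, scale = TRUE)
      dv <- attr(stats::predict(fit, X[te, , drop = FALSE],
                                decision.values = TRUE), "decision.values")
      # orient the margin so larger = more case-like
      sign_flip <- if (colnames(dv)[1] == "0/1") -1 else 1
      oof[te] <- sign_flip * dv[, 1]
    }
  }
  roc <- roc_curve(oof, y)
  structure(list(auc = roc$auc, roc = roc$points, oof_scores = oof,
                 fold = fold, model = model, k = k, seed = seed),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s, %d-fold CV (seed %s): pooled out-of-fold AUC = %.3f\n",
              x$model, x$k, format(x$seed), x$auc))
  invisible(x)
}
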