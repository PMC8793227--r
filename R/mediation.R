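#' Outcome model of the mediation decomposition
#'
#' Logistic regression of comorbidity status on the standardized PRS, the
#' mediator expression level and the demographic covariates:
#' `logit(status) = theta0 + theta1 * PRS + theta2 * mediator + covariates`.
#' `theta1` is the direct effect of the score with the mediator held in
#' the model; `theta2` is the mediator effect, both on the log-odds scale.
#'
#' @param prs standardized PRS aligned to `cohort` rows.
#' @param cohort a `cohort_table` with the `mediator` column populated.
#' @return list: `theta1`, `theta2`, `se_theta1`, `se_theta2`, `coef`
#'   (full vector), `converged`, `n`.
#' @export
fit_outcome_model <- function(prs, cohort) {
  covars <- covariate_design(cohort, n_mds = 0)
  keep <- apply(covars, 2, function(v) stats::var(v) > 0)
  df <- data.frame(y = cohort$pc_status, prs = prs,
                   mediator = cohort$mediator,
                   as.data.frame(covars[, keep, drop = FALSE]))
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  sep <- any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8)
  cf <- summary(fit)$coefficients
  list(theta1 = cf["prs", 1], theta2 = cf["mediator", 1],
       se_theta1 = cf["prs", 2], se_theta2 = cf["mediator", 2],
       coef = stats::coef(fit), converged = fit$converged && !sep,
       complete = cc, n = nrow(df))
}

#' Mediator model of the mediation decomposition
#'
#' Ordinary least squares of the mediator on the standardized PRS and the
#' demographic covariates:
#' `mediator = phi0 + phi1 * PRS + covariates`. `phi1` is the
#' exposure-to-mediator path coefficient.
#'
#' @inheritParams fit_outcome_model
#' @return list: `phi1`, `se_phi1`, `coef`, `sigma` (residual SD), `n`.
#' @export
fit_mediator_model <- function(prs, cohort) {
  covars <- covariate_design(cohort, n_mds = 0)
  keep <- apply(covars, 2, function(v) stats::var(v) > 0)
  df <- data.frame(mediator = cohort$mediator, prs = prs,
                   as.data.frame(covars[, keep, drop = FALSE]))
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  fit <- stats::lm(mediator ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient mediator design; collinear column(s): ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  cf <- summary(fit)$coefficients
  list(phi1 = cf["prs", 1], se_phi1 = cf["prs", 2],
       coef = stats::coef(fit), sigma = summary(fit)$sigma,
       complete = cc, n = nrow(df))
}

#' Product-of-coefficients effect decomposition
#'
#' Direct effect = `theta1`; indirect (mediated) effect =
#' `phi1 * theta2`; total = direct + indirect; proportion mediated =
#' indirect / total. When direct and indirect effects have opposite
#' signs the proportion is reported unclipped with an `opposite_sign`
#' warning flag; when the total is zero the proportion is `NA`.
#'
#' @param theta1 direct-effect coefficient (outcome model, log-odds).
#' @param theta2 mediator coefficient (outcome model, log-odds).
#' @param phi1 exposure-to-mediator coefficient (mediator model).
#' @return list: `direct`, `indirect`, `total`, `proportion_mediated`,
#'   `opposite_sign`.
#' @export
decompose_effects <- function(theta1, theta2, phi1) {
  stopifnot(is.finite(theta1), is.finite(theta2), is.finite(phi1))
  indirect <- phi1 * theta2
  total <- theta1 + indirect
  list(direct = theta1, indirect = indirect, total = total,
       proportion_mediated = if (total == 0) NA_real_ else indirect / total,
       opposite_sign = (theta1 * indirect) < 0)
}

#' Bootstrap confidence intervals for the mediation effects
#'
#' Resamples individuals with replacement (n fixed), refits both models on
#' each resample and takes percentile confidence intervals (empirical
#' type-1 quantiles, so B = 2 yields the min/max) of the direct and
#' indirect effects. Resamples where the outcome model fails to converge
#' are dropped and counted: a warning is raised above 10% dropped, an
#' error above 50%.
#'
#' @param prs standardized PRS aligned to `cohort`.
#' @param cohort a `cohort_table`.
#' @param B number of bootstrap replications (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @param stratified resample within case/control strata (default FALSE).
#' @return list: `ci_direct`, `ci_indirect`, `ci_proportion` (each a
#'   2-vector), `replicates` (B x 3 matrix of direct/indirect/proportion),
#'   `n_dropped`, `B`, `seed`.
#' @export
bootstrap_mediation <- function(prs, cohort, B = 1000, seed = 1,
                                level = 0.95, stratified = FALSE) {
  stopifnot(B >= 2)
  set.seed(seed)
  # Build both designs once; resamples only permute rows. Refits use the
  # package IRLS (oracle-checked against glm) and .lm.fit for speed.
  covars <- covariate_design(cohort, n_mds = 0)
  keep <- apply(covars, 2, function(v) stats::var(v) > 0)
  Xout <- cbind(`(Intercept)` = 1, prs = prs, mediator = cohort$mediator,
                covars[, keep, drop = FALSE])
  Xmed <- cbind(`(Intercept)` = 1, prs = prs, covars[, keep, drop = FALSE])
  y <- cohort$pc_status
  med_y <- cohort$mediator
  cc <- stats::complete.cases(Xout) & !is.na(y)
  Xout <- Xout[cc, , drop = FALSE]; Xmed <- Xmed[cc, , drop = FALSE]
  y <- y[cc]; med_y <- med_y[cc]
  n <- length(y)
  start <- logistic_irls(Xout, y)$beta
  if (anyNA(start)) start <- NULL
  cases <- which(y == 1); controls <- which(y == 0)
  reps <- matrix(NA_real_, nrow = B, ncol = 3,
                 dimnames = list(NULL, c("direct", "indirect", "proportion")))
  for (b in seq_len(B)) {
    idx <- if (stratified) {
      c(sample(cases, replace = TRUE), sample(controls, replace = TRUE))
    } else sample.int(n, replace = TRUE)
    out <- logistic_irls(Xout[idx, , drop = FALSE], y[idx], start = start)
    if (!out$converged) next
    mfit <- .lm.fit(Xmed[idx, , drop = FALSE], med_y[idx])
    phi1 <- mfit$coefficients[2L]
    if (!all(is.finite(c(out$beta[["prs"]], out$beta[["mediator"]], phi1))))
      next
    dec <- decompose_effects(out$beta[["prs"]], out$beta[["mediator"]], phi1)
    reps[b, ] <- c(dec$direct, dec$indirect, dec$proportion_mediated)
  }
  ok <- stats::complete.cases(reps[, 1:2])
  n_dropped <- sum(!ok)
  if (n_dropped > 0.5 * B)
    stop("more than half of bootstrap resamples failed to converge")
  if (n_dropped > 0.1 * B)
    warning(n_dropped, " of ", B, " bootstrap resamples dropped (non-convergence)")
  a <- (1 - level) / 2
  q <- function(v) unname(stats::quantile(v[is.finite(v)], c(a, 1 - a), type = 1))
  list(ci_direct = q(reps[ok, "direct"]),
       ci_indirect = q(reps[ok, "indirect"]),
       ci_proportion = q(reps[ok, "proportion"]),
       replicates = reps, n_dropped = n_dropped, B = B, seed = seed,
       level = level)
}

# significance stars from whether the bootstrap CI at the matching level
# excludes zero: * 95%, ** 99%, *** 99.9%
ci_stars <- function(reps) {
  excl <- function(level) {
    a <- (1 - level) / 2
    ci <- stats::quantile(reps[is.finite(reps)], c(a, 1 - a), type = 1)
    ci[1] > 0 || ci[2] < 0
  }
  if (excl(0.999)) "***" else if (excl(0.99)) "**" else if (excl(0.95)) "*" else ""
}

#' Full causal mediation analysis for one PRS threshold
#'
#' Fits the outcome and mediator models, decomposes the PRS effect on
#' comorbidity status into direct and mediated components, and attaches
#' bootstrap percentile confidence intervals and significance stars
#' (whether the CI at the 95/99/99.9% level excludes zero).
#'
#' @param prs standardized PRS at the chosen threshold.
#' @param cohort a `cohort_table` with mediator values.
#' @param B bootstrap replications (default 1000).
#' @param seed RNG seed.
#' @param stratified passed to [bootstrap_mediation()].
#' @return object of class `mediation_result`: point estimates (`direct`,
#'   `indirect`, `total`, `proportion_mediated`, `theta1`, `theta2`,
#'   `phi1`), `ci_direct`/`ci_indirect`/`ci_proportion`,
#'   `stars_direct`/`stars_indirect`, `opposite_sign`, `n_dropped`, `B`,
#'   `seed`.
#' @export
run_mediation <- function(prs, cohort, B = 1000, seed = 1,
                          stratified = FALSE) {
  out <- fit_outcome_model(prs, cohort)
  if (!out$converged)
    stop("outcome model did not converge (possible separation); mediation aborted")
  med <- fit_mediator_model(prs, cohort)
  dec <- decompose_effects(out$theta1, out$theta2, med$phi1)
  boot <- bootstrap_mediation(prs, cohort, B = B, seed = seed,
                              stratified = stratified)
  structure(c(dec,
              list(theta1 = out$theta1, theta2 = out$theta2, phi1 = med$phi1,
                   ci_direct = boot$ci_direct,
                   ci_indirect = boot$ci_indirect,
                   ci_proportion = boot$ci_proportion,
                   stars_direct = ci_stars(boot$replicates[, "direct"]),
                   stars_indirect = ci_stars(boot$replicates[, "indirect"]),
                   n_dropped = boot$n_dropped, B = B, seed = seed,
                   n = out$n)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("direct effect    %.4f [%.4f, %.4f] %s\n", x$direct,
              x$ci_direct[1], x$ci_direct[2], x$stars_direct))
  cat(sprintf("indirect effect  %.4f [%.4f, %.4f] %s\n", x$indirect,
              x$ci_indirect[1], x$ci_indirect[2], x$stars_indirect))
  cat(sprintf("total effect     %.4f\n", x$total))
  pm <- x$proportion_mediated
  cat(sprintf("proportion mediated %.3f%s\n",
              pm, if (isTRUE(x$opposite_sign)) " (opposite-sign warning)" else ""))
  invisible(x)
}
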