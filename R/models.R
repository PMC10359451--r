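#' Specify an association model
#'
#' Builds the model specification used by [fit_logistic()] /
#' [fit_linear_composite()]: thalamus volume is always the first
#' predictor; adjusted models add age, sex and intracranial volume; the
#' surgery sensitivity flag further adds surgery severity, type and
#' duration.
#'
#' @param outcome One of `"preCI"`, `"POCD"`, `"composite_z_baseline"`,
#'   `"composite_z_followup"`, `"composite_z_change"`.
#' @param adjusted Add age, sex and intracranial volume.
#' @param surgery_sensitivity Also add surgery severity, type and
#'   duration (sensitivity analysis).
#' @return A list of class `model_spec` with `outcome`, `predictors` and
#'   `family` (`"logistic"` for the dichotomous outcomes, `"linear"`
#'   otherwise).
#' @export
model_spec <- function(outcome = c("preCI", "POCD", "composite_z_baseline",
                                   "composite_z_followup", "composite_z_change"),
                       adjusted = TRUE, surgery_sensitivity = FALSE) {
  outcome <- match.arg(outcome)
  predictors <- "thalamus_cm3"
  if (adjusted) predictors <- c(predictors, "age_years", "sex", "icv_cm3")
  if (surgery_sensitivity)
    predictors <- c(predictors, "surgery_severity", "surgery_type",
                    "surgery_duration_min")
  family <- if (outcome %in% c("preCI", "POCD")) "logistic" else "linear"
  structure(list(outcome = outcome, predictors = predictors, family = family),
            class = "model_spec")
}

# complete-case design/outcome extraction shared by both families
model_frame <- function(data, outcome, predictors) {
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- data[c(outcome, predictors)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df
}

#' Maximum-likelihood logistic regression with Wald inference
#'
#' Fits a logistic regression (IRLS via [stats::glm()]) of a dichotomous
#' outcome on the specified predictors, using complete cases, and reports
#' per-predictor log-odds, Wald standard errors, odds ratios per unit
#' increment, 95% Wald confidence intervals (`exp(beta +/- 1.96 SE)`),
#' Wald p-values, the ROC AUC of the fitted probabilities, per-predictor
#' variance inflation factors, and an honest convergence flag (perfect
#' separation is reported, never silently returned as converged).
#'
#' @param data Data frame holding outcome and predictors.
#' @param spec A [model_spec()] with `family = "logistic"`, or `NULL` to
#'   pass `outcome`/`predictors` directly.
#' @param outcome,predictors Used when `spec` is `NULL`.
#' @return An object of class `logistic_fit`: a list with `coefficients`
#'   (a per-predictor table with `beta`, `se`, `or`, `ci_low`, `ci_high`,
#'   `p`), `auc`, `auc_p`, `vif`, `n_used`, `converged`, `separation`.
#' @export
fit_logistic <- function(data, spec = NULL, outcome = NULL, predictors = NULL) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "model_spec"), spec$family == "logistic")
    outcome <- spec$outcome; predictors <- spec$predictors
  }
  df <- model_frame(data, outcome, predictors)
  y <- df[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("outcome '", outcome, "' has a single class among complete cases")
  if (!all(y %in% c(0, 1))) stop("logistic outcome must be dichotomous (0/1)")
  df[[outcome]] <- y

  fml <- stats::reformulate(predictors, response = outcome)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1L]
  beta <- sm[-1L, 1L]; se <- sm[-1L, 2L]
  coef_tab <- data.frame(
    term = terms, beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    row.names = NULL, stringsAsFactors = FALSE)

  scores <- stats::fitted(fit)
  roc <- roc_auc(scores, df[[outcome]])
  X <- stats::model.matrix(fit)[, -1L, drop = FALSE]
  vifs <- if (ncol(X) >= 2L) vif(X) else stats::setNames(rep(NA_real_, ncol(X)),
                                                         colnames(X))
  structure(list(
    coefficients = coef_tab, auc = roc$auc, auc_p = roc$p,
    vif = vifs, vif_flag = any(is.finite(vifs) & vifs > 2.5) ||
      any(is.infinite(vifs)),
    n_used = nrow(df), converged = fit$converged && !sep_warn,
    separation = sep_warn, outcome = outcome, predictors = predictors,
    glm = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic model: %s ~ %s  (n = %d%s)\n", x$outcome,
              paste(x$predictors, collapse = " + "), x$n_used,
              if (!x$converged) "; NOT converged" else ""))
  tab <- x$coefficients
  tab[-1L] <- lapply(tab[-1L], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("AUC %.3f (p = %.4g)%s\n", x$auc, x$auc_p,
              if (x$vif_flag) "; VIF > 2.5 flagged" else ""))
  invisible(x)
}

#' ROC area under the curve via Mann-Whitney concordance
#'
#' AUC is the probability that a randomly chosen case scores higher than a
#' randomly chosen non-case, with ties counted half — computed from mid
#' ranks, which is exactly the Mann-Whitney U statistic scaled to `[0,1]`.
#' The p-value tests AUC = 0.5 by the normal approximation to the
#' Mann-Whitney U test with tie correction.
#'
#' @param scores Numeric model scores (any monotone transform of risk).
#' @param labels Dichotomous labels (0/1 or logical); both classes
#'   required.
#' @return A list with `auc` and `p`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                       # mid ranks handle ties (half credit)
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  n <- n1 + n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties)
  var_u <- n1 * n0 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  p <- if (var_u <= 0) 1 else
    2 * stats::pnorm(-abs(u - n1 * n0 / 2) / sqrt(var_u))
  list(auc = auc, p = p)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the OLS regression (with intercept) of
#' predictor `j` on the remaining predictors. Exact collinearity yields
#' `Inf`. Values above 2.5 are conventionally flagged as multicollinear in
#' this pipeline.
#'
#' @param design A numeric matrix or data.frame of predictors (no
#'   intercept column; factors must already be expanded).
#' @return Named vector of VIFs (all `>= 1`, `Inf` under exact
#'   collinearity).
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  stopifnot(is.numeric(X), ncol(X) >= 2L)
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("predictor(s) with zero variance: ",
         paste(colnames(X)[apply(X, 2L, stats::sd) == 0], collapse = ", "))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- colnames(X)
  out
}

#' Ordinary least squares for the continuous composite outcomes
#'
#' Complete-case OLS with intercept; per-predictor estimates with Wald
#' 95% intervals (`beta +/- 1.96 SE`) and t-test p-values. A
#' rank-deficient design is rejected.
#'
#' @inheritParams fit_logistic
#' @return A list of class `linear_fit` with a `coefficients` table
#'   (`term`, `beta`, `se`, `ci_low`, `ci_high`, `p`) and `n_used`.
#' @export
fit_linear_composite <- function(data, spec = NULL, outcome = NULL,
                                 predictors = NULL) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "model_spec"), spec$family == "linear")
    outcome <- spec$outcome; predictors <- spec$predictors
  }
  df <- model_frame(data, outcome, predictors)
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: aliased term(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  sm <- summary(fit)$coefficients
  beta <- sm[-1L, 1L]; se <- sm[-1L, 2L]
  structure(list(
    coefficients = data.frame(term = rownames(sm)[-1L], beta = beta, se = se,
                              ci_low = beta - 1.96 * se,
                              ci_high = beta + 1.96 * se, p = sm[-1L, 4L],
                              row.names = NULL, stringsAsFactors = FALSE),
    n_used = nrow(df), outcome = outcome, predictors = predictors, lm = fit
  ), class = "linear_fit")
}

#' Composite z-score against a reference population
#'
#' Standardizes each battery parameter against the reference population's
#' mean and SD, then averages the available per-parameter z's into a
#' composite (missing parameters are dropped from the average; a subject
#' with no available parameter gets a missing composite). Used for the
#' continuous-cognition sensitivity analyses, where the reference is a
#' large surgical population rather than the control group.
#'
#' @param scores Data frame of per-subject oriented parameter values
#'   (columns = parameters, plus optionally `subject_id`).
#' @param reference Data frame of the reference population on the same
#'   columns.
#' @return Numeric vector of composite z-scores, one per row of `scores`.
#' @export
standardize_composite <- function(scores, reference) {
  params <- setdiff(names(scores), "subject_id")
  stopifnot(all(params %in% names(reference)))
  z <- sapply(params, function(p) {
    m <- mean(reference[[p]], na.rm = TRUE)
    s <- stats::sd(reference[[p]], na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("zero-variance reference parameter: ", p)
    (scores[[p]] - m) / s
  })
  z <- matrix(z, nrow = nrow(scores), dimnames = list(NULL, params))
  out <- rowMeans(z, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_                 # no parameter available
  out
}
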