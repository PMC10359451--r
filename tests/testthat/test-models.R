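# 2x2 table expanded to subject-level rows
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
    x = rep(c(1, 1, 0, 0), c(a, b, c, d)))
}

test_that("one-binary-predictor logistic OR equals ad/bc", {
  fit <- fit_logistic(expand_2x2(10, 20, 5, 40), outcome = "y", predictors = "x")
  expect_equal(fit$coefficients$or, 4.0, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_used, 75L)

  set.seed(10)
  for (i in 1:5) {
    k <- sample(5:40, 4, replace = TRUE)
    f <- fit_logistic(expand_2x2(k[1], k[2], k[3], k[4]),
                      outcome = "y", predictors = "x")
    expect_equal(f$coefficients$or, k[1] * k[4] / (k[2] * k[3]),
                 tolerance = 1e-6)
  }
})

test_that("independence in a balanced table gives OR exactly 1", {
  fit <- fit_logistic(expand_2x2(25, 25, 25, 25), outcome = "y",
                      predictors = "x")
  expect_equal(fit$coefficients$or, 1.0, tolerance = 1e-8)
})

test_that("degenerate logistic inputs are rejected or flagged honestly", {
  df <- data.frame(y = rep(1, 10), x = rnorm(10))
  expect_error(fit_logistic(df, outcome = "y", predictors = "x"),
               "single class")
  sep <- data.frame(y = rep(c(0, 1), each = 20),
                    x = c(rnorm(20, -5), rnorm(20, 5)))
  fit <- fit_logistic(sep, outcome = "y", predictors = "x")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("AUC equals the Mann-Whitney concordance with ties counted half", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  # brute force over all case-control pairs on random tied data
  set.seed(11)
  for (i in 1:20) {
    scores <- sample(1:5, 30, replace = TRUE)
    labels <- rbinom(30, 1, 0.4)
    if (length(unique(labels)) < 2) next
    pairs <- expand.grid(i = which(labels == 1), j = which(labels == 0))
    brute <- mean(ifelse(scores[pairs$i] > scores[pairs$j], 1,
                         ifelse(scores[pairs$i] == scores[pairs$j], 0.5, 0)))
    expect_equal(roc_auc(scores, labels)$auc, brute)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(12)
  scores <- rnorm(50); labels <- rbinom(50, 1, 0.5)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(stats::plogis(3 * scores - 1), labels)$auc, a0)
})

test_that("VIF matches the two-predictor closed form", {
  n <- 100
  x <- scale(seq_len(n))[, 1]
  e <- stats::residuals(stats::lm(rnorm(n) ~ x))
  e <- e / stats::sd(e) * stats::sd(x)        # same scale, exactly orthogonal
  expect_equal(unname(vif(cbind(a = x, b = e))), c(1, 1), tolerance = 1e-10)

  y <- 0.8 * x + sqrt(1 - 0.64) * e           # sample correlation exactly 0.8
  v <- vif(cbind(a = x, b = y))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  expect_equal(unname(v[1]), 2.7778, tolerance = 1e-4)

  dup <- cbind(a = x, b = y, c = y)
  expect_true(all(is.infinite(vif(dup)[c("b", "c")])))
  expect_error(vif(cbind(a = x, b = rep(1, n))), "zero variance")
})

test_that("linear composite models recover exact coefficients", {
  df <- data.frame(thalamus_cm3 = runif(40, 10, 16))
  df$composite_z_baseline <- 0.15 * df$thalamus_cm3
  df$age_years <- rnorm(40, 72); df$sex <- rbinom(40, 1, 0.4)
  df$icv_cm3 <- rnorm(40, 1339, 200)
  fit <- suppressWarnings(
    fit_linear_composite(df, model_spec("composite_z_baseline",
                                        adjusted = FALSE)))
  expect_equal(fit$coefficients$beta[1], 0.15, tolerance = 1e-10)

  toy <- data.frame(y = c(2, 4, 6), x = c(1, 2, 3))
  f2 <- suppressWarnings(fit_linear_composite(toy, outcome = "y",
                                              predictors = "x"))
  expect_equal(f2$coefficients$beta, 2)
  expect_equal(sum(stats::residuals(f2$lm)^2), 0)

  bad <- data.frame(y = rnorm(10), x1 = 1:10, x2 = 2 * (1:10))
  expect_error(fit_linear_composite(bad, outcome = "y",
                                    predictors = c("x1", "x2")),
               "rank-deficient")
})

test_that("null linear association vanishes at large n", {
  set.seed(13)
  df <- data.frame(y = rnorm(5000), x = rnorm(5000))
  fit <- fit_linear_composite(df, outcome = "y", predictors = "x")
  expect_lt(abs(fit$coefficients$beta), 3 * fit$coefficients$se)
})

test_that("standardize_composite centers, scales and propagates missingness", {
  ref <- data.frame(PAL_memory = c(8, 10, 12))
  ref$PAL_memory <- c(8, 10, 12)
  refdf <- make_oriented(matrix(rnorm(30 * 7), ncol = 7))
  expect_equal(standardize_composite(refdf[1:5, ], refdf)[1],
               mean((as.numeric(refdf[1, params]) -
                       colMeans(refdf[params])) /
                      apply(refdf[params], 2, stats::sd)))

  one <- data.frame(subject_id = "s", PAL_memory = 13)
  rp <- data.frame(PAL_memory = c(8, 10, 12))
  rp_sd <- stats::sd(rp$PAL_memory)
  expect_equal(standardize_composite(one, rp), (13 - 10) / rp_sd)

  gone <- make_oriented(matrix(NA_real_, 1, 7))
  expect_true(is.na(standardize_composite(gone, refdf)))
  flat <- refdf; flat$SSP_span <- 1
  expect_error(standardize_composite(refdf[1:2, ], flat), "zero-variance")
})

test_that("model_spec orders thalamus first and picks the right family", {
  s <- model_spec("POCD")
  expect_equal(s$predictors[1], "thalamus_cm3")
  expect_setequal(s$predictors[-1], c("age_years", "sex", "icv_cm3"))
  expect_equal(s$family, "logistic")
  expect_equal(model_spec("composite_z_change")$family, "linear")
  expect_true("surgery_severity" %in%
                model_spec("POCD", surgery_sensitivity = TRUE)$predictors)
})

test_that("run_associations assembles the full results table", {
  set.seed(15)
  study <- simulate_study(sim_config(n_surgical = 250, n_control = 150,
                                     missing_rate_item = 0.02, seed = 44))
  cls <- classify_cohort(study$control, study$surgical$assessments)
  res <- run_associations(cls$outcomes, study$surgical$covariates,
                          surgical_assessments = study$surgical$assessments,
                          surgery_sensitivity = TRUE)
  expect_true(all(c("preCI_unadjusted", "preCI_adjusted", "POCD_adjusted",
                    "POCD_surgery_adjusted", "composite_z_baseline",
                    "composite_z_change") %in% names(res$fits)))
  tab <- res$table
  expect_true(all(c("model", "predictor", "or", "ci_low", "ci_high", "p",
                    "auc", "vif", "n_used", "converged") %in% names(tab)))
  adj <- res$fits$POCD_adjusted
  expect_equal(adj$coefficients$term[1], "thalamus_cm3")
  expect_true(all(adj$coefficients$ci_low <= adj$coefficients$or &
                    adj$coefficients$or <= adj$coefficients$ci_high))
  expect_true(all(is.finite(adj$vif) & adj$vif >= 1))
  # surgery-adjusted sensitivity model uses fewer complete cases at most n
  expect_lte(res$fits$POCD_surgery_adjusted$n_used, adj$n_used)
})
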