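test_that("control reference computes sample moments with n-1 denominator", {
  ch <- data.frame(subject_id = c("a", "b", "c"), PAL_memory = c(0, 1, 2),
                   stringsAsFactors = FALSE)
  ref <- fit_control_reference(ch, ch, min_available = 1L)
  expect_equal(unname(ref$mean_change["PAL_memory"]), 1)
  expect_equal(unname(ref$sd_change["PAL_memory"]), 1)
  expect_equal(ref$n_control, 3L)
})

test_that("zero control variance is rejected", {
  ch <- data.frame(subject_id = c("a", "b", "c"), PAL_memory = c(1, 1, 1))
  expect_error(fit_control_reference(ch, ch, min_available = 1L),
               "zero control variance")
  one <- data.frame(subject_id = "a", PAL_memory = 1)
  expect_error(fit_control_reference(one, one, min_available = 1L),
               "fewer than 2")
})

test_that("composite scaling recovers sqrt(7) for independent standard normals", {
  set.seed(31)
  ch <- make_oriented(matrix(rnorm(5000 * 7), ncol = 7))
  ref <- fit_control_reference(ch, ch)
  expect_lt(abs(ref$sd_sum_z_change / sqrt(7) - 1), 0.05)
})

test_that("Z-scores center on the control mean and orient deterioration positive", {
  set.seed(5)
  ctrl <- make_oriented(matrix(rnorm(200 * 7, sd = 2), ncol = 7))
  ref <- fit_control_reference(ctrl, ctrl)

  at_mean <- make_oriented(matrix(ref$mean_change, nrow = 1), ids = "p1")
  z <- zscore_change(at_mean, ref)
  expect_true(all(abs(as.numeric(z[1, params])) < 1e-12))
  expect_equal(z$composite_z, 0)
  expect_equal(z$n_available, 7L)

  # single-parameter reference: control mean 1, sd 1, patient change -1.5
  ch1 <- data.frame(subject_id = c("a", "b", "c"), PAL_memory = c(0, 1, 2))
  ref1 <- fit_control_reference(ch1, ch1, min_available = 1L)
  z1 <- zscore_change(data.frame(subject_id = "p", PAL_memory = -1.5), ref1)
  expect_equal(unname(z1$PAL_memory), 2.5)

  # improvement beyond controls on every parameter: all z negative
  better <- make_oriented(matrix(ref$mean_change + 5 * ref$sd_change, nrow = 1))
  zb <- zscore_change(better, ref)
  expect_true(all(as.numeric(zb[1, params]) < 0))
  expect_lt(zb$composite_z, 0)
  expect_false(classify(zb)$impaired)
})

test_that("baseline Z uses the control baseline distribution", {
  b1 <- data.frame(subject_id = c("a", "b", "c"), PAL_memory = c(8, 10, 12))
  ref <- fit_control_reference(b1, b1, min_available = 1L)
  z <- zscore_baseline(data.frame(subject_id = "p", PAL_memory = 5), ref)
  expect_equal(unname(z$PAL_memory), (10 - 5) / 2)
})

test_that("too many missing items flags the subject unclassifiable", {
  set.seed(6)
  ctrl <- make_oriented(matrix(rnorm(100 * 7), ncol = 7))
  ref <- fit_control_reference(ctrl, ctrl, min_available = 5L)
  x <- make_oriented(matrix(0, nrow = 1, ncol = 7))
  x[1, params[1:3]] <- NA
  z <- zscore_baseline(x, ref)
  expect_false(z$classifiable)
  expect_true(is.na(z$composite_z))
  out <- classify(z)
  expect_true(is.na(out$impaired))
  expect_equal(out$criterion, "unclassifiable")
})

test_that("subset composites are renormalized so the control null SD stays 1", {
  set.seed(7)
  ctrl <- make_oriented(matrix(rnorm(3000 * 7), ncol = 7))
  ref <- fit_control_reference(ctrl, ctrl)
  sub <- params[1:5]
  x <- ctrl
  for (p in setdiff(params, sub)) x[[p]] <- NA_real_
  z <- zscore_change(x, ref)
  expect_true(all(z$n_available == 5L))
  expect_lt(abs(stats::sd(z$composite_z) - 1), 0.06)
})

test_that("classify applies both clauses with strict inequality", {
  z <- rbind(rep(0, 7),                      # composite forced high
             c(2.0, 2.0, rep(0, 5)),         # two individual exceedances
             c(3.5, rep(0, 6)),              # one exceedance, composite at bound
             c(2.5, 2.5, rep(0, 5)))         # both clauses
  comp <- c(2.5, 1.0, 1.96, 2.6)
  out <- classify(make_panel(z, comp))
  expect_equal(out$impaired, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$criterion,
               c("composite_only", "multi_test_only", "none", "both"))
  expect_equal(out$outcome_kind, rep("POCD", 4))
})

test_that("exactly-at-threshold values never trigger either clause", {
  z <- matrix(1.96, nrow = 1, ncol = 7)
  out <- classify(make_panel(z, 1.96))
  expect_false(out$impaired)
  expect_equal(out$criterion, "none")
})

test_that("worsening one parameter never rescues a subject (monotonicity)", {
  set.seed(8)
  for (rep in 1:200) {
    z <- rnorm(7, sd = 1.5)
    comp <- sum(z) / sqrt(7)
    before <- classify(make_panel(matrix(z, 1), comp))
    j <- sample(7, 1)
    z2 <- z; z2[j] <- z2[j] + runif(1, 0, 3)
    comp2 <- sum(z2) / sqrt(7)
    after <- classify(make_panel(matrix(z2, 1), comp2))
    expect_false(isTRUE(before$impaired) && !isTRUE(after$impaired))
  }
})

test_that("control self-consistency: controls score mean 0, SD 1 against themselves", {
  cohort <- generate_control_cohort(sim_config(n_control = 600,
                                               missing_rate_item = 0, seed = 14))
  ref <- fit_control_reference(oriented_change(cohort),
                               oriented_baseline(cohort))
  z <- zscore_change(oriented_change(cohort), ref)
  # the TMT-B timeout leaves a handful of item gaps even at zero configured
  # missingness, so moments are over available values
  for (p in params) {
    expect_lt(abs(mean(z[[p]], na.rm = TRUE)), 1e-10)
    expect_equal(stats::sd(z[[p]], na.rm = TRUE), 1, tolerance = 1e-10)
  }
  # complete-battery controls carry the exact full-battery scaling; the few
  # subset-scaled subjects move the overall SD only marginally
  expect_equal(stats::sd(z$composite_z, na.rm = TRUE), 1, tolerance = 0.01)
})

test_that("null false-positive rate has the right limits and closed form", {
  expect_equal(null_false_positive_rate(threshold = 100, n_sims = 2000, seed = 1), 0)
  p_closed <- 1 - 0.975^7 - 7 * 0.025 * 0.975^6
  est <- null_false_positive_rate(n_sims = 2e4, seed = 2, rule = "multi_only")
  expect_lt(abs(est - p_closed), 3 * sqrt(p_closed * (1 - p_closed) / 2e4))
  comp <- null_false_positive_rate(n_sims = 2e4, seed = 3, rule = "composite_only")
  expect_lt(abs(comp - 0.025), 3 * sqrt(0.025 * 0.975 / 2e4))
})

test_that("serialized control reference round-trips at full precision", {
  set.seed(9)
  ctrl <- make_oriented(matrix(rnorm(50 * 7), ncol = 7))
  ref <- fit_control_reference(ctrl, ctrl)
  path <- withr::local_tempfile(fileext = ".json")
  write_control_reference(ref, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$sd_sum_z_change, ref$sd_sum_z_change)
  expect_equal(unlist(back$mean_change), ref$mean_change)
  expect_equal(back$n_control, 50L)
})
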