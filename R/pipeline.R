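#' Run the RCI classification end to end on two assessment tables
#'
#' Fits the control reference from the control cohort's oriented baseline
#' and retest-change vectors, then classifies every surgical subject:
#' preCI from baseline levels, POCD from pre-to-post change (subjects
#' without a follow-up session receive no POCD row).
#'
#' @param control_assessments,surgical_assessments Assessment tables in
#'   the standard schema (`subject_id`, `session`, raw parameter columns).
#' @param threshold Dichotomization threshold (default 1.96).
#' @param min_available Minimum available parameters for classification.
#' @param battery Battery definition.
#' @return A list with `reference` (the [fit_control_reference()] object)
#'   and `outcomes` (stacked preCI and POCD rows from [classify()]).
#' @export
classify_cohort <- function(control_assessments, surgical_assessments,
                            threshold = 1.96, min_available = 5L,
                            battery = cog_battery()) {
  ref <- fit_control_reference(
    change = oriented_change(control_assessments, battery),
    baseline = oriented_baseline(control_assessments, battery),
    min_available = min_available)
  base_panel <- zscore_baseline(oriented_baseline(surgical_assessments, battery), ref)
  change_panel <- zscore_change(oriented_change(surgical_assessments, battery), ref)
  outcomes <- rbind(classify(base_panel, threshold, outcome_kind = "preCI"),
                    classify(change_panel, threshold, outcome_kind = "POCD"))
  list(reference = ref, outcomes = outcomes)
}

#' Serialize a control reference to JSON at full precision
#'
#' @param ref A [fit_control_reference()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_control_reference <- function(ref, path) {
  fields <- list(
    params = ref$params,
    mean_change = as.list(ref$mean_change),
    sd_change = as.list(ref$sd_change),
    mean_baseline = as.list(ref$mean_baseline),
    sd_baseline = as.list(ref$sd_baseline),
    sd_sum_z_change = ref$sd_sum_z_change,
    sd_sum_z_baseline = ref$sd_sum_z_baseline,
    n_control = ref$n_control,
    min_available = ref$min_available,
    subset_scalings = as.list(ref$cache)
  )
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fit the full set of association models
#'
#' Runs the unadjusted and covariate-adjusted (age, sex, intracranial
#' volume) logistic regressions of preCI and POCD on thalamus volume —
#' optionally the surgery-adjusted sensitivity model — and the three
#' linear sensitivity models of the continuous composite z-scores
#' (baseline, follow-up, change) standardized against a reference
#' surgical population.
#'
#' @param outcomes Stacked outcome table from [classify_cohort()].
#' @param covariates Covariate table (`subject_id`, `thalamus_cm3`,
#'   `age_years`, `sex`, `icv_cm3`, surgery descriptors).
#' @param surgical_assessments Optional assessments table enabling the
#'   composite-z linear models.
#' @param composite_reference Optional oriented reference population for
#'   [standardize_composite()]; defaults to the surgical cohort itself (a
#'   stand-in for the larger surgical population used in the emulated
#'   study).
#' @param surgery_sensitivity Also fit the surgery-adjusted POCD model.
#' @param battery Battery definition.
#' @return A list of class `association_results`: `fits` (named list) and
#'   `table` (one row per model x predictor, the `model_results.csv`
#'   schema).
#' @export
run_associations <- function(outcomes, covariates,
                             surgical_assessments = NULL,
                             composite_reference = NULL,
                             surgery_sensitivity = FALSE,
                             battery = cog_battery()) {
  wide <- function(kind) {
    o <- outcomes[outcomes$outcome_kind == kind, ]
    df <- merge(covariates, o[c("subject_id", "impaired", "composite_z")],
                by = "subject_id")
    df[[kind]] <- df$impaired
    df
  }
  fits <- list()
  for (kind in c("preCI", "POCD")) {
    df <- wide(kind)
    fits[[paste0(kind, "_unadjusted")]] <-
      fit_logistic(df, model_spec(kind, adjusted = FALSE))
    fits[[paste0(kind, "_adjusted")]] <-
      fit_logistic(df, model_spec(kind, adjusted = TRUE))
  }
  if (surgery_sensitivity) {
    df <- wide("POCD")
    fits$POCD_surgery_adjusted <-
      fit_logistic(df, model_spec("POCD", surgery_sensitivity = TRUE))
  }
  if (!is.null(surgical_assessments)) {
    base <- oriented_baseline(surgical_assessments, battery)
    post <- orient_assessments(surgical_assessments, battery)
    post <- post[post$session == "followup", c("subject_id", battery$name)]
    ref_pop <- composite_reference %||% base
    comp <- data.frame(subject_id = base$subject_id,
                       composite_z_baseline = standardize_composite(base, ref_pop),
                       stringsAsFactors = FALSE)
    post$composite_z_followup <- standardize_composite(post, ref_pop)
    comp <- merge(comp, post[c("subject_id", "composite_z_followup")],
                  all.x = TRUE, by = "subject_id")
    comp$composite_z_change <- comp$composite_z_followup - comp$composite_z_baseline
    df <- merge(covariates, comp, by = "subject_id")
    for (oc in c("composite_z_baseline", "composite_z_followup",
                 "composite_z_change"))
      fits[[oc]] <- fit_linear_composite(df, model_spec(oc))
  }

  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    tab <- f$coefficients
    logistic <- inherits(f, "logistic_fit")
    data.frame(model = id, predictor = tab$term, beta = tab$beta, se = tab$se,
               or = if (logistic) tab$or else NA_real_,
               ci_low = tab$ci_low, ci_high = tab$ci_high, p = tab$p,
               auc = if (logistic) f$auc else NA_real_,
               auc_p = if (logistic) f$auc_p else NA_real_,
               vif = if (logistic) unname(f$vif[match(tab$term, names(f$vif))])
                     else NA_real_,
               n_used = f$n_used,
               converged = if (logistic) f$converged else TRUE,
               stringsAsFactors = FALSE)
  })
  structure(list(fits = fits, table = do.call(rbind, rows)),
            class = "association_results")
}

#' @export
print.association_results <- function(x, ...) {
  for (nm in names(x$fits)) {
    cat("==", nm, "==\n")
    print(x$fits[[nm]])
    cat("\n")
  }
  invisible(x)
}

#' Plain-text model report
#'
#' @param results An [run_associations()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_report <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(results)
  invisible(path)
}
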