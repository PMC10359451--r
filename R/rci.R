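#' Fit the control-group reference for the Reliable Change Index
#'
#' Estimates, from a non-surgical control cohort, the normalizers of the
#' RCI: per-parameter mean and SD of the oriented retest change (capturing
#' natural variability and practice effects) and of the oriented baseline
#' level, plus the control-group SD of the sum of per-parameter Z-scores,
#' which rescales the composite ("total") Z so its null SD is 1. Subset
#' scalings, used when a subject misses battery items, are computed on
#' demand from the stored control Z-scores and cached.
#'
#' @param change Oriented change vectors for the controls
#'   (see [oriented_change()]).
#' @param baseline Oriented baseline vectors for the controls.
#' @param min_available Minimum number of non-missing parameters (of 7) a
#'   subject needs to receive a composite Z and a classification.
#' @return An object of class `control_reference`.
#' @export
fit_control_reference <- function(change, baseline, min_available = 5L) {
  params <- setdiff(names(change), "subject_id")
  stopifnot(identical(params, setdiff(names(baseline), "subject_id")))
  moments <- function(df, what) {
    m <- vapply(params, function(p) mean(df[[p]], na.rm = TRUE), 0)
    s <- vapply(params, function(p) stats::sd(df[[p]], na.rm = TRUE), 0)
    n <- vapply(params, function(p) sum(!is.na(df[[p]])), 0L)
    if (any(n < 2L))
      stop("fewer than 2 control observations for parameter(s): ",
           paste(params[n < 2L], collapse = ", "))
    if (any(!is.finite(s)) || any(s <= 0))
      stop("zero control variance for parameter(s): ",
           paste(params[!is.finite(s) | s <= 0], collapse = ", "),
           " - Z-scores undefined (", what, ")")
    list(mean = m, sd = s, n = n)
  }
  mc <- moments(change, "change")
  mb <- moments(baseline, "baseline")

  zmat <- function(df, m, s) {
    z <- sapply(params, function(p) (m[[p]] - df[[p]]) / s[[p]])
    z <- matrix(z, ncol = length(params), dimnames = list(NULL, params))
    z
  }
  z_change <- zmat(change, mc$mean, mc$sd)
  z_baseline <- zmat(baseline, mb$mean, mb$sd)

  sum_sd <- function(z) {
    complete <- stats::complete.cases(z)
    if (sum(complete) < 2L)
      stop("fewer than 2 controls with a complete battery; cannot scale the composite Z")
    stats::sd(rowSums(z[complete, , drop = FALSE]))
  }
  ref <- structure(list(
    params = params,
    mean_change = mc$mean, sd_change = mc$sd,
    mean_baseline = mb$mean, sd_baseline = mb$sd,
    sd_sum_z_change = sum_sd(z_change),
    sd_sum_z_baseline = sum_sd(z_baseline),
    n_control = nrow(change),
    min_available = as.integer(min_available),
    z_change_control = z_change,
    z_baseline_control = z_baseline,
    cache = new.env(parent = emptyenv())
  ), class = "control_reference")
  ref
}

#' @export
print.control_reference <- function(x, ...) {
  cat("Control reference (RCI normalizers), n =", x$n_control, "controls\n")
  tab <- data.frame(mean_change = x$mean_change, sd_change = x$sd_change,
                    mean_baseline = x$mean_baseline, sd_baseline = x$sd_baseline)
  print(round(tab, 4))
  cat(sprintf("SD of summed Z over controls: change %.4f, baseline %.4f\n",
              x$sd_sum_z_change, x$sd_sum_z_baseline))
  invisible(x)
}

# Control SD of the Z-sum over a parameter subset, computed over controls
# complete on that subset; cached by subset signature.
subset_scaling <- function(ref, params, kind = c("change", "baseline")) {
  kind <- match.arg(kind)
  params <- sort(params)
  if (length(params) == length(ref$params))
    return(if (kind == "change") ref$sd_sum_z_change else ref$sd_sum_z_baseline)
  key <- paste(kind, paste(params, collapse = "|"), sep = ":")
  if (!is.null(ref$cache[[key]])) return(ref$cache[[key]])
  z <- if (kind == "change") ref$z_change_control else ref$z_baseline_control
  z <- z[, params, drop = FALSE]
  complete <- stats::complete.cases(z)
  if (sum(complete) < 2L)
    stop("fewer than 2 controls complete on subset {",
         paste(params, collapse = ", "), "}; cannot scale composite")
  s <- stats::sd(rowSums(z[complete, , drop = FALSE]))
  ref$cache[[key]] <- s
  s
}

# Shared Z-panel constructor: z = (control mean - observed)/control SD on
# the oriented scale, so deterioration relative to controls is positive.
zscore_panel <- function(ov, ref, kind) {
  m <- if (kind == "change") ref$mean_change else ref$mean_baseline
  s <- if (kind == "change") ref$sd_change else ref$sd_baseline
  params <- ref$params
  stopifnot(all(params %in% names(ov)))
  z <- sapply(params, function(p) (m[[p]] - ov[[p]]) / s[[p]])
  z <- matrix(z, ncol = length(params), dimnames = list(NULL, params))
  n_avail <- rowSums(!is.na(z))
  composite <- rep(NA_real_, nrow(z))
  ok <- n_avail >= ref$min_available
  for (i in which(ok)) {
    avail <- params[!is.na(z[i, ])]
    composite[i] <- sum(z[i, avail]) / subset_scaling(ref, avail, kind)
  }
  out <- data.frame(subject_id = ov$subject_id, stringsAsFactors = FALSE)
  for (p in params) out[[p]] <- z[, p]
  out$composite_z <- composite
  out$n_available <- as.integer(n_avail)
  out$classifiable <- ok
  structure(out, kind = kind, class = c("z_panel", "data.frame"))
}

#' Control-referenced Z-scores of pre-to-post change (the RCI)
#'
#' For each parameter, `z = (control mean change - observed change) /
#' control SD of change`, so that deterioration beyond the control group's
#' practice effect yields a positive Z. The composite ("total") Z is the
#' sum of the available per-parameter Z's divided by the control-group SD
#' of that sum over the same parameter subset, keeping the composite's
#' null SD at 1. Subjects with fewer than `min_available` parameters are
#' flagged unclassifiable.
#'
#' @param change Oriented change vectors ([oriented_change()]).
#' @param ref A fitted [fit_control_reference()] object.
#' @return A data.frame with one Z column per parameter, `composite_z`,
#'   `n_available` and `classifiable`.
#' @export
zscore_change <- function(change, ref) zscore_panel(change, ref, "change")

#' Control-referenced Z-scores of baseline performance (preCI construction)
#'
#' Identical formula to [zscore_change()] with the control baseline
#' distribution in place of the change distribution: positive Z means
#' worse-than-control baseline performance.
#'
#' @param baseline Oriented baseline vectors ([oriented_baseline()]).
#' @inheritParams zscore_change
#' @return As [zscore_change()].
#' @export
zscore_baseline <- function(baseline, ref) zscore_panel(baseline, ref, "baseline")

#' Dichotomize a Z-panel into impaired / not impaired
#'
#' A subject is impaired when the composite Z exceeds the threshold
#' (strictly) and/or at least two individual parameter Z's exceed it
#' (strictly). The `criterion` column records which clause fired. Panels
#' flagged unclassifiable (too many missing items) receive an explicit
#' `"unclassifiable"` outcome with `impaired = NA`, never a silent
#' "not impaired".
#'
#' @param panel A Z-panel from [zscore_change()] or [zscore_baseline()].
#' @param threshold Decision threshold, default 1.96.
#' @param outcome_kind Label stored with the outcome: `"POCD"` for change
#'   panels, `"preCI"` for baseline panels (defaulted from the panel kind).
#' @return A data.frame with `subject_id`, `impaired`, `criterion`
#'   (`composite_only`, `multi_test_only`, `both`, `none`,
#'   `unclassifiable`), `threshold`, `outcome_kind`, `composite_z`,
#'   `n_available`.
#' @export
classify <- function(panel, threshold = 1.96, outcome_kind = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (is.null(outcome_kind))
    outcome_kind <- switch(attr(panel, "kind", exact = TRUE) %||% "change",
                           change = "POCD", baseline = "preCI")
  params <- setdiff(names(panel),
                    c("subject_id", "composite_z", "n_available", "classifiable"))
  z <- as.matrix(panel[params])
  n_exceed <- rowSums(z > threshold, na.rm = TRUE)
  comp_hit <- !is.na(panel$composite_z) & panel$composite_z > threshold
  multi_hit <- n_exceed >= 2L
  criterion <- ifelse(comp_hit & multi_hit, "both",
               ifelse(comp_hit, "composite_only",
               ifelse(multi_hit, "multi_test_only", "none")))
  impaired <- comp_hit | multi_hit
  unclass <- !panel$classifiable
  criterion[unclass] <- "unclassifiable"
  impaired[unclass] <- NA
  data.frame(subject_id = panel$subject_id,
             outcome_kind = outcome_kind,
             impaired = impaired,
             criterion = criterion,
             threshold = threshold,
             composite_z = panel$composite_z,
             n_available = panel$n_available,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' False-positive rate of the dichotomization rule under the null
#'
#' Monte-Carlo estimate of the probability that a subject whose parameter
#' Z-scores are i.i.d. standard normal (the independent-parameter null) is
#' classified impaired. Under this null the composite is the Z-sum divided
#' by `sqrt(n_params)`. Useful to surface the family-wise behaviour of the
#' strict 1.96 cut-off.
#'
#' @param n_params Number of battery parameters (default 7).
#' @param threshold Decision threshold (default 1.96).
#' @param n_sims Number of simulated subjects (>= 1000).
#' @param seed RNG seed.
#' @param rule `"full"` (both clauses), `"multi_only"` (>= 2 individual
#'   exceedances alone) or `"composite_only"`.
#' @return Estimated classification rate (a fraction).
#' @export
null_false_positive_rate <- function(n_params = 7L, threshold = 1.96,
                                     n_sims = 1e5, seed = 1L,
                                     rule = c("full", "multi_only", "composite_only")) {
  rule <- match.arg(rule)
  stopifnot(n_sims >= 1000)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_sims * n_params), nrow = n_sims)
  multi <- rowSums(z > threshold) >= 2L
  comp <- rowSums(z) / sqrt(n_params) > threshold
  hit <- switch(rule, full = multi | comp, multi_only = multi,
                composite_only = comp)
  mean(hit)
}
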