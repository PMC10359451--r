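#' Default generative moments for the seven battery parameters
#'
#' Per-parameter targets used by the cohort generator, on both the raw and
#' the oriented ("higher = better", timed measures log-reversed) scales.
#' Raw levels and spreads follow the unimpaired patient stratum of the
#' study population this package emulates; retest learning effects are the
#' unimpaired baseline-to-follow-up mean shifts expressed in oriented
#' units; retest noise defaults to `sqrt(0.5)` times the cross-sectional
#' oriented SD, i.e. a test-retest reliability of about 0.75.
#'
#' @return A data.frame with one row per parameter: `name`, `raw_mean`,
#'   `raw_sd`, `oriented_mean`, `oriented_sd`, `learning_effect`,
#'   `noise_sd`.
#' @export
default_battery_moments <- function() {
  raw_mean <- c(PAL_memory = 14.0, VRM_free_recall = 6.3,
                VRM_delayed_recognition = 21.8, SSP_span = 4.9,
                GPT_time = 93.1, SRT_time = 309.0, TMTB_time = 112.3)
  raw_sd <- c(4.2, 1.9, 1.9, 0.9, 24.7, 89.6, 39.1)
  names(raw_sd) <- names(raw_mean)
  timed <- c("GPT_time", "SRT_time", "TMTB_time")
  o_mean <- ifelse(names(raw_mean) %in% timed, -log(raw_mean), raw_mean)
  # delta method: sd(log X) ~ sd(X)/mean(X) for the timed measures
  o_sd <- ifelse(names(raw_mean) %in% timed, raw_sd / raw_mean, raw_sd)
  learning <- c(PAL_memory = 1.5, VRM_free_recall = 0.1,
                VRM_delayed_recognition = 0.0, SSP_span = 0.1,
                GPT_time = log(93.1 / 88.0), SRT_time = -log(309.4 / 309.0),
                TMTB_time = log(112.3 / 102.7))
  data.frame(name = names(raw_mean), raw_mean = unname(raw_mean),
             raw_sd = unname(raw_sd), oriented_mean = unname(o_mean),
             oriented_sd = unname(o_sd),
             learning_effect = unname(learning[names(raw_mean)]),
             noise_sd = unname(sqrt(0.5) * o_sd),
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic cohort generator
#'
#' Builds and validates a simulation configuration. Defaults mirror the
#' emulated study: 301 surgical patients, 114 non-surgical controls,
#' preCI prevalence 11.3%, POCD prevalence 11.8%, 70.4% follow-up,
#' age 72.4 (SD 4.9) years, 43.5% female, thalamus 12.9 (SD 1.6) cm^3 and
#' intracranial volume 1339.0 (SD 212.4) cm^3.
#'
#' @param n_surgical,n_control Cohort sizes.
#' @param prevalence_preCI,prevalence_POCD Fractions of surgical subjects
#'   carrying the respective ground-truth impairment (must sum to <= 1;
#'   assigned disjointly).
#' @param followup_rate Fraction of surgical subjects retaining the
#'   follow-up session (loss is completely at random unless
#'   `dropout_age_weight` is nonzero).
#' @param learning_effect,noise_sd Named per-parameter mean retest
#'   improvement and retest SD, oriented units; default from
#'   [default_battery_moments()].
#' @param intertest_corr Equicorrelation shared by all parameters, in
#'   `[0, 1)` (the equicorrelated matrix is positive definite there).
#' @param decline_magnitude Injected impairment shift per affected
#'   parameter, in control-SD units (baseline SDs for preCI, change SDs
#'   for POCD).
#' @param n_affected_params Number of parameters affected per impaired
#'   subject, in 2..7.
#' @param missing_rate_item Independent item-level missingness rate.
#' @param thalamus_effect_logOR Log-odds change of impairment per cm^3 of
#'   thalamus volume; 0 is the null.
#' @param dropout_age_weight Optional log-odds of follow-up loss per SD of
#'   age (0 = missing completely at random, the default analysis
#'   assumption).
#' @param seed Integer seed (< 2^30); all generator randomness derives
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_surgical = 301L, n_control = 114L,
                       prevalence_preCI = 0.113, prevalence_POCD = 0.118,
                       followup_rate = 0.704,
                       learning_effect = NULL, noise_sd = NULL,
                       intertest_corr = 0.3, decline_magnitude = 3.0,
                       n_affected_params = 3L, missing_rate_item = 0.05,
                       thalamus_effect_logOR = 0, dropout_age_weight = 0,
                       seed = 20140101L) {
  mom <- default_battery_moments()
  le <- stats::setNames(mom$learning_effect, mom$name)
  ns <- stats::setNames(mom$noise_sd, mom$name)
  if (!is.null(learning_effect)) le[names(learning_effect)] <- learning_effect
  if (!is.null(noise_sd)) ns[names(noise_sd)] <- noise_sd
  cfg <- structure(list(
    n_surgical = as.integer(n_surgical), n_control = as.integer(n_control),
    prevalence_preCI = prevalence_preCI, prevalence_POCD = prevalence_POCD,
    followup_rate = followup_rate,
    learning_effect = le, noise_sd = ns,
    baseline_mean = stats::setNames(mom$oriented_mean, mom$name),
    baseline_sd = stats::setNames(mom$oriented_sd, mom$name),
    intertest_corr = intertest_corr,
    decline_magnitude = decline_magnitude,
    n_affected_params = as.integer(n_affected_params),
    missing_rate_item = missing_rate_item,
    thalamus_effect_logOR = thalamus_effect_logOR,
    dropout_age_weight = dropout_age_weight,
    age_mean = 72.4, age_sd = 4.9, p_female = 0.435,
    thalamus_mean = 12.9, thalamus_sd = 1.6,
    icv_mean = 1339.0, icv_sd = 212.4, thalamus_icv_corr = 0.5,
    seed = suppressWarnings(as.integer(seed))
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  frac <- c("prevalence_preCI", "prevalence_POCD", "followup_rate",
            "missing_rate_item")
  for (f in frac)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must be a fraction in [0, 1]")
  if (cfg$prevalence_preCI + cfg$prevalence_POCD > 1)
    stop("prevalence_preCI + prevalence_POCD exceeds 1")
  if (cfg$intertest_corr < 0 || cfg$intertest_corr >= 1)
    stop("intertest_corr must lie in [0, 1): the equicorrelated ",
         "correlation matrix is not positive definite otherwise")
  if (cfg$n_affected_params < 2L || cfg$n_affected_params > 7L)
    stop("n_affected_params must be in 2..7")
  if (cfg$n_surgical < 1L || cfg$n_control < 2L)
    stop("cohort sizes too small")
  if (any(cfg$noise_sd < 0) || any(cfg$baseline_sd <= 0))
    stop("noise_sd must be >= 0 and baseline_sd > 0")
  if (!is.finite(cfg$seed) || abs(cfg$seed) >= 2^30)
    stop("seed must be an integer with |seed| < 2^30")
  cfg
}

#' Read a simulation configuration from a JSON file
#'
#' The file holds a JSON object whose keys mirror the [sim_config()]
#' arguments; omitted fields keep their defaults. Per-parameter fields
#' (`learning_effect`, `noise_sd`) are objects keyed by parameter name.
#'
#' @param path Path to the JSON configuration.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  for (f in c("learning_effect", "noise_sd"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(sim_config, raw)
}

# n x k equicorrelated standard-normal draws scaled to per-column sd
equicorr_noise <- function(n, sds, rho) {
  k <- length(sds)
  shared <- stats::rnorm(n)
  z <- sqrt(rho) * matrix(shared, n, k) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
  sweep(z, 2L, sds, `*`)
}

timed_params <- c("GPT_time", "SRT_time", "TMTB_time")

# oriented matrix -> raw-unit data.frame columns (timed: exp(-v); counts:
# floored at 0 to keep scores non-negative)
oriented_to_raw <- function(mat, params) {
  out <- as.data.frame(mat)
  names(out) <- params
  for (p in params) {
    out[[p]] <- if (p %in% timed_params) exp(-out[[p]]) else pmax(out[[p]], 0)
  }
  out
}

assessments_frame <- function(ids, base_or, post_or, params) {
  base <- cbind(data.frame(subject_id = ids, session = "baseline",
                           stringsAsFactors = FALSE),
                oriented_to_raw(base_or, params))
  post <- cbind(data.frame(subject_id = ids, session = "followup",
                           stringsAsFactors = FALSE),
                oriented_to_raw(post_or, params))
  rbind(base, post)
}

#' Generate the non-surgical control cohort
#'
#' Draws paired baseline/retest assessments for `n_control` subjects: the
#' oriented baseline is equicorrelated Gaussian around the configured
#' parameter means, and the retest equals baseline plus the per-parameter
#' learning effect plus equicorrelated Gaussian retest noise. No
#' impairment is injected. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A data.frame in the `assessments` schema (`subject_id`,
#'   `session`, one raw-unit column per parameter).
#' @export
generate_control_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  params <- names(config$baseline_mean)
  n <- config$n_control
  base <- sweep(equicorr_noise(n, config$baseline_sd, config$intertest_corr),
                2L, config$baseline_mean, `+`)
  change <- sweep(equicorr_noise(n, config$noise_sd, config$intertest_corr),
                  2L, config$learning_effect, `+`)
  ids <- sprintf("C%04d", seq_len(n))
  assessments_frame(ids, base, base + change, params)
}

#' Generate the surgical cohort with known ground truth
#'
#' Draws covariates (age, sex, correlated thalamus and intracranial
#' volumes, surgery descriptors), assigns disjoint ground-truth preCI and
#' POCD labels whose probabilities depend on thalamus volume through
#' `thalamus_effect_logOR` (0 gives the null), injects the configured
#' decline on `n_affected_params` randomly chosen parameters of each
#' impaired subject (baseline shift for preCI, change shift for POCD), and
#' withholds the follow-up session for a fraction `1 - followup_rate`.
#' The POCD truth follows an exact logistic law in thalamus volume:
#' `logit P(true_POCD) = qlogis(prevalence_POCD) +
#' thalamus_effect_logOR * (thalamus - mean)`.
#'
#' @param config A [sim_config()].
#' @return A list with `assessments` (follow-up rows only for followed
#'   subjects), `covariates`, `truth` (`subject_id`, `true_preCI`,
#'   `true_POCD`, `affected_parameters`, `followed`) and `status` (one
#'   terminal flow state per subject).
#' @export
generate_surgical_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  params <- names(config$baseline_mean)
  n <- config$n_surgical
  ids <- sprintf("S%04d", seq_len(n))

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1L, config$p_female)          # 1 = female
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  rho <- config$thalamus_icv_corr
  thal <- config$thalamus_mean + config$thalamus_sd * z1
  icv <- config$icv_mean + config$icv_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  thal <- pmax(thal, 1); icv <- pmax(icv, 400)
  sev_levels <- c("minor", "moderate", "major", "major_plus")
  severity <- sample(sev_levels, n, replace = TRUE,
                     prob = c(0.15, 0.35, 0.35, 0.15))
  type_levels <- c("musculoskeletal", "gastrointestinal", "cardiothoracic",
                   "genitourinary", "otorhinolaryngology", "maxillofacial",
                   "ophthalmology", "neurosurgery", "other")
  type_prob <- c(85, 51, 17, 66, 23, 16, 22, 6, 15) / 301
  stype <- sample(type_levels, n, replace = TRUE, prob = type_prob)
  duration <- pmax(stats::rnorm(n, 183.9, 116.3), 30)

  # disjoint truth assignment; POCD drawn first so its law is exactly logistic
  eta <- config$thalamus_effect_logOR * (thal - config$thalamus_mean)
  p_pocd <- if (config$prevalence_POCD == 0) rep(0, n) else
    stats::plogis(stats::qlogis(config$prevalence_POCD) + eta)
  true_pocd <- stats::runif(n) < p_pocd
  p_pre_base <- if (config$prevalence_preCI == 0) 0 else
    config$prevalence_preCI / (1 - config$prevalence_POCD)
  p_pre <- if (p_pre_base == 0) rep(0, n) else
    stats::plogis(stats::qlogis(min(p_pre_base, 1 - 1e-12)) + eta)
  true_preci <- !true_pocd & (stats::runif(n) < p_pre)

  affected <- replicate(n, character(0), simplify = FALSE)
  impaired <- which(true_preci | true_pocd)
  for (i in impaired)
    affected[[i]] <- sample(params, config$n_affected_params)

  base <- sweep(equicorr_noise(n, config$baseline_sd, config$intertest_corr),
                2L, config$baseline_mean, `+`)
  change <- sweep(equicorr_noise(n, config$noise_sd, config$intertest_corr),
                  2L, config$learning_effect, `+`)
  for (i in which(true_preci)) {
    p <- affected[[i]]
    base[i, match(p, params)] <- base[i, match(p, params)] -
      config$decline_magnitude * config$baseline_sd[p]
  }
  for (i in which(true_pocd)) {
    p <- affected[[i]]
    change[i, match(p, params)] <- change[i, match(p, params)] -
      config$decline_magnitude * config$noise_sd[p]
  }

  p_follow <- if (config$dropout_age_weight == 0) rep(config$followup_rate, n)
    else stats::plogis(stats::qlogis(config$followup_rate) -
                       config$dropout_age_weight *
                         (age - config$age_mean) / config$age_sd)
  followed <- stats::runif(n) < p_follow

  assessments <- assessments_frame(ids, base, base + change, params)
  assessments <- assessments[assessments$session == "baseline" |
                               assessments$subject_id %in% ids[followed], ]
  rownames(assessments) <- NULL

  # presentational loss reasons in the emulated study's proportions
  loss_reasons <- c("dropped_out", "died_pre_followup", "not_reachable",
                    "alive_not_tested", "paused")
  status <- ifelse(followed, "followup_tested",
                   sample(loss_reasons, n, replace = TRUE,
                          prob = c(19, 15, 19, 26, 10) / 89))

  list(
    assessments = assessments,
    covariates = data.frame(subject_id = ids, age_years = age, sex = sex,
                            thalamus_cm3 = thal, icv_cm3 = icv,
                            surgery_duration_min = duration,
                            surgery_type = stype, surgery_severity = severity,
                            stringsAsFactors = FALSE),
    truth = data.frame(subject_id = ids, true_preCI = true_preci,
                       true_POCD = true_pocd,
                       affected_parameters = vapply(affected, paste, "",
                                                    collapse = ";"),
                       followed = followed, stringsAsFactors = FALSE),
    status = data.frame(subject_id = ids, status = status,
                        stringsAsFactors = FALSE)
  )
}

#' Blank individual test items completely at random
#'
#' Each parameter value of each assessment row is independently set to
#' missing with the given rate; subject identity, session and covariates
#' are never blanked.
#'
#' @param assessments An assessments data.frame.
#' @param missing_rate_item Blanking probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param battery Battery definition naming the parameter columns.
#' @return The assessments data.frame with item-level gaps.
#' @export
apply_missingness <- function(assessments, missing_rate_item, seed,
                              battery = cog_battery()) {
  stopifnot(missing_rate_item >= 0, missing_rate_item <= 1)
  if (missing_rate_item == 0) return(assessments)
  set.seed(as.integer(seed))
  for (p in intersect(battery$name, names(assessments))) {
    gap <- stats::runif(nrow(assessments)) < missing_rate_item
    assessments[[p]][gap] <- NA_real_
  }
  assessments
}

#' Generate a full synthetic study (controls + surgical cohort)
#'
#' Convenience wrapper: control cohort, surgical cohort, then item-level
#' missingness applied to both (surgical missingness uses `seed + 2`,
#' control missingness `seed + 3`, keeping every stream derived from the
#' one configured seed).
#'
#' @param config A [sim_config()].
#' @return A list `control` (assessments) and `surgical` (list as returned
#'   by [generate_surgical_cohort()]), plus the `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  control <- generate_control_cohort(config)
  surgical <- generate_surgical_cohort(config)
  if (config$missing_rate_item > 0) {
    surgical$assessments <- apply_missingness(surgical$assessments,
                                              config$missing_rate_item,
                                              config$seed + 2L)
    control <- apply_missingness(control, config$missing_rate_item,
                                 config$seed + 3L)
  }
  list(control = control, surgical = surgical, config = config)
}

#' Write a simulated study to delimited text files
#'
#' Writes `control_assessments.csv`, `assessments.csv`, `covariates.csv`,
#' `truth.csv` and `status.csv` (UTF-8, comma-separated, header row) to a
#' directory.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(control_assessments = study$control,
               assessments = study$surgical$assessments,
               covariates = study$surgical$covariates,
               truth = study$surgical$truth,
               status = study$surgical$status)
  paths <- character(0)
  for (nm in names(tabs)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
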