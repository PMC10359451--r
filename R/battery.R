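#' The canonical seven-parameter neuropsychological battery
#'
#' Returns the battery definition used throughout the package: one row per
#' analysis parameter with its orientation, transform and (for the
#' trail-making test) the termination limit. The four untimed parameters
#' (paired-associates memory score, verbal free recall, delayed recognition,
#' spatial span) are scored so that higher raw values mean better
#' performance and enter the analysis untransformed. The three timed
#' parameters (grooved pegboard, simple reaction time, trail-making part B)
#' are log-transformed and reversed so that, on the oriented scale, higher
#' is better for every parameter.
#'
#' @return A data.frame with columns `name`, `direction`
#'   (`"higher_better"`/`"lower_better"`), `transform` (`"none"`/`"log"`),
#'   `timeout_s` (NA except TMT-B) and `units`.
#' @examples
#' cog_battery()
#' @export
cog_battery <- function() {
  data.frame(
    name = c("PAL_memory", "VRM_free_recall", "VRM_delayed_recognition",
             "SSP_span", "GPT_time", "SRT_time", "TMTB_time"),
    direction = c(rep("higher_better", 4L), rep("lower_better", 3L)),
    transform = c(rep("none", 4L), rep("log", 3L)),
    timeout_s = c(NA, NA, NA, NA, NA, NA, 300),
    units = c("score", "words", "responses", "span length",
              "s", "ms", "s"),
    stringsAsFactors = FALSE
  )
}

battery_names <- function(battery = cog_battery()) battery$name

#' Orient a raw test value onto the common "higher = better" scale
#'
#' Applies the parameter's transform (natural log for the timed measures,
#' identity otherwise) and then reverses lower-is-better parameters by
#' negation, so that on the returned scale a worse performance is always a
#' smaller number. Non-positive inputs to the log transform are invalid
#' measurements: they are returned as `NA` with a warning rather than
#' propagated.
#'
#' @param raw Numeric vector of raw values (may contain `NA`).
#' @param spec A single-row slice of [cog_battery()] (or a list with
#'   `transform` and `direction` elements).
#' @return Numeric vector of oriented values, `NA` where the input was
#'   missing or invalid.
#' @examples
#' gpt <- cog_battery()[5, ]
#' orient_value(93.1, gpt)   # -log(93.1)
#' @export
orient_value <- function(raw, spec) {
  stopifnot(is.numeric(raw))
  out <- as.numeric(raw)
  if (identical(spec$transform, "log")) {
    bad <- !is.na(out) & out <= 0
    if (any(bad)) {
      warning(sprintf("%d non-positive value(s) for log-transformed parameter %s treated as missing",
                      sum(bad), spec$name), call. = FALSE)
      out[bad] <- NA_real_
    }
    out <- log(out)
  }
  if (identical(spec$direction, "lower_better")) out <- -out
  out
}

#' Trail-making test termination rule
#'
#' The trail-making test is terminated at 180 s (part A) or 300 s (part B);
#' a terminated administration carries no usable completion time and is
#' excluded from analysis. Values at or beyond the limit are therefore
#' returned as `NA` ("excluded-missing"); values below the limit pass
#' through unchanged.
#'
#' @param raw_seconds Numeric vector of completion times in seconds (> 0).
#' @param part `"A"` or `"B"`.
#' @return Numeric vector with timed-out administrations set to `NA`.
#' @export
apply_timeout_rule <- function(raw_seconds, part = c("B", "A")) {
  part <- match.arg(part)
  stopifnot(is.numeric(raw_seconds), all(is.na(raw_seconds) | raw_seconds > 0))
  limit <- c(A = 180, B = 300)[[part]]
  ifelse(!is.na(raw_seconds) & raw_seconds >= limit, NA_real_, raw_seconds)
}

# Orient a whole assessments table (long over sessions, wide over
# parameters). The TMT-B timeout rule runs before orientation; invalid
# log inputs become missing. Returns subject_id, session + oriented columns.
orient_assessments <- function(assessments, battery = cog_battery()) {
  stopifnot(all(c("subject_id", "session") %in% names(assessments)))
  missing_cols <- setdiff(battery$name, names(assessments))
  if (length(missing_cols))
    stop("assessments table lacks parameter column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- assessments[c("subject_id", "session")]
  for (i in seq_len(nrow(battery))) {
    spec <- battery[i, ]
    v <- assessments[[spec$name]]
    if (!is.na(spec$timeout_s)) v <- apply_timeout_rule(v, part = "B")
    out[[spec$name]] <- orient_value(v, spec)
  }
  out
}

#' Assemble per-subject oriented baseline vectors
#'
#' @param assessments Data frame with columns `subject_id`, `session`
#'   (`"baseline"`/`"followup"`) and one raw-unit column per battery
#'   parameter.
#' @param battery Battery definition, see [cog_battery()].
#' @return A data.frame (one row per subject with a baseline session) of
#'   oriented values, attribute `kind = "baseline_level"`.
#' @export
oriented_baseline <- function(assessments, battery = cog_battery()) {
  or <- orient_assessments(assessments, battery)
  out <- or[or$session == "baseline", c("subject_id", battery$name)]
  if (anyDuplicated(out$subject_id))
    stop("duplicate baseline session for subject(s): ",
         paste(unique(out$subject_id[duplicated(out$subject_id)]), collapse = ", "))
  rownames(out) <- NULL
  structure(out, kind = "baseline_level")
}

#' Assemble per-subject oriented pre-to-post change vectors
#'
#' Change is oriented follow-up minus oriented baseline, computed only for
#' subjects with both sessions; orientation is applied before differencing
#' so a decline is negative on every parameter. A parameter missing at
#' either session is missing in the change vector.
#'
#' @inheritParams oriented_baseline
#' @return A data.frame of per-parameter oriented changes, attribute
#'   `kind = "pre_post_change"`.
#' @export
oriented_change <- function(assessments, battery = cog_battery()) {
  or <- orient_assessments(assessments, battery)
  base <- or[or$session == "baseline", , drop = FALSE]
  post <- or[or$session == "followup", , drop = FALSE]
  if (anyDuplicated(base$subject_id) || anyDuplicated(post$subject_id))
    stop("duplicate session rows detected")
  keep <- intersect(base$subject_id, post$subject_id)
  base <- base[match(keep, base$subject_id), ]
  post <- post[match(keep, post$subject_id), ]
  out <- data.frame(subject_id = keep, stringsAsFactors = FALSE)
  for (p in battery$name) out[[p]] <- post[[p]] - base[[p]]
  structure(out, kind = "pre_post_change")
}

#' Change vector for a single subject
#'
#' Single-record form of [oriented_change()]: both records must belong to
#' the same subject and carry the expected sessions.
#'
#' @param baseline,followup One-row data.frames (or named lists) with
#'   `subject_id`, `session` and the raw parameter columns.
#' @inheritParams oriented_baseline
#' @return One-row data.frame of oriented changes.
#' @export
assemble_change_vector <- function(baseline, followup, battery = cog_battery()) {
  baseline <- as.data.frame(baseline, stringsAsFactors = FALSE)
  followup <- as.data.frame(followup, stringsAsFactors = FALSE)
  if (!identical(baseline$subject_id, followup$subject_id))
    stop("baseline and follow-up records belong to different subjects")
  if (!identical(baseline$session, "baseline") ||
      !identical(followup$session, "followup"))
    stop("records must carry sessions 'baseline' and 'followup'")
  oriented_change(rbind(baseline, followup), battery)
}
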