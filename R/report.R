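#' Percentage rounded half-up to one decimal
#'
#' `100 * numerator / denominator`, rounded half-up (0.05 rounds away from
#' zero) to one decimal place — the single rounding path used everywhere a
#' percentage is printed, so reported percentages are always reproducible
#' from their count pair.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @return The rounded percentage as a number (e.g. `11.3`).
#' @examples
#' percentage(34, 301)  # 11.3
#' @export
percentage <- function(numerator, denominator) {
  stopifnot(denominator > 0, numerator >= 0, numerator <= denominator)
  x <- 100 * numerator / denominator
  floor(x * 10 + 0.5) / 10
}

flow_loss_reasons <- c("dropped_out", "died_pre_followup", "not_reachable",
                       "alive_not_tested", "paused")

#' Build the cohort flow ledger (STROBE accounting)
#'
#' Counts subjects into terminal flow states purely from a per-subject
#' status table, checks conservation (every subject in exactly one state;
#' loss subcategories sum to the total lost; followed + lost = baseline
#' tested), and attaches outcome/overlap counts when outcome tables are
#' supplied. Inconsistent inputs (duplicate or conflicting statuses, a
#' POCD label on a subject without follow-up) are rejected with the
#' offending subject ids.
#'
#' @param status Data frame `subject_id`, `status` with one row per
#'   subject; `status` is `"followup_tested"` or one of
#'   `r paste(flow_loss_reasons, collapse = ", ")`.
#' @param outcomes Optional outcome table (rows from [classify()], both
#'   outcome kinds may be stacked) used for the group counts.
#' @param pod Optional data.frame `subject_id`, `pod` (logical) of
#'   postoperative delirium as a reported characteristic.
#' @return A list of class `flow_ledger` with stage counts, loss
#'   subcategory counts, group counts and overlap counts.
#' @export
build_flow <- function(status, outcomes = NULL, pod = NULL) {
  stopifnot(all(c("subject_id", "status") %in% names(status)))
  dup <- unique(status$subject_id[duplicated(status$subject_id)])
  if (length(dup)) {
    conflicting <- vapply(dup, function(id)
      length(unique(status$status[status$subject_id == id])) > 1L, TRUE)
    if (any(conflicting))
      stop("conflicting statuses for subject(s): ",
           paste(dup[conflicting], collapse = ", "))
    status <- status[!duplicated(status$subject_id), ]
  }
  valid <- c("followup_tested", flow_loss_reasons)
  bad <- setdiff(unique(status$status), valid)
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))

  counts <- table(factor(status$status, levels = valid))
  ledger <- list(
    enrolled = nrow(status),
    baseline_tested = nrow(status),
    followup_tested = unname(counts[["followup_tested"]]),
    lost_total = sum(counts[flow_loss_reasons])
  )
  for (r in flow_loss_reasons) ledger[[r]] <- unname(counts[[r]])

  followed_ids <- status$subject_id[status$status == "followup_tested"]
  groups <- list(preCI = character(0), POCD = character(0),
                 POD = character(0))
  if (!is.null(outcomes)) {
    for (kind in c("preCI", "POCD")) {
      sub <- outcomes[outcomes$outcome_kind == kind & !is.na(outcomes$impaired) &
                        outcomes$impaired, , drop = FALSE]
      groups[[kind]] <- unique(sub$subject_id)
    }
    bad_pocd <- setdiff(groups$POCD, followed_ids)
    if (length(bad_pocd))
      stop("POCD label without follow-up testing for subject(s): ",
           paste(bad_pocd, collapse = ", "))
  }
  if (!is.null(pod)) groups$POD <- pod$subject_id[as.logical(pod$pod)]
  ledger$preCI <- length(groups$preCI)
  ledger$POCD <- length(groups$POCD)
  ledger$POD <- length(groups$POD)
  ledger$preCI_and_POCD <- length(intersect(groups$preCI, groups$POCD))
  ledger$preCI_and_POD <- length(intersect(groups$preCI, groups$POD))
  ledger$POCD_and_POD <- length(intersect(groups$POCD, groups$POD))
  ledger$preCI_and_followup <- length(intersect(groups$preCI, followed_ids))
  structure(ledger, class = "flow_ledger")
}

#' @export
print.flow_ledger <- function(x, ...) {
  cat("Cohort flow\n")
  cat(sprintf("  baseline tested %d; followed up %d (%.1f%%); lost %d (%.1f%%)\n",
              x$baseline_tested, x$followup_tested,
              percentage(x$followup_tested, x$baseline_tested),
              x$lost_total, percentage(x$lost_total, x$baseline_tested)))
  for (r in flow_loss_reasons)
    cat(sprintf("    %-18s %d\n", r, x[[r]]))
  cat(sprintf("  preCI %d, POCD %d, POD %d\n", x$preCI, x$POCD, x$POD))
  invisible(x)
}

#' Flow percentages against an explicit denominator
#'
#' The source material mixes denominators when quoting loss percentages,
#' so the ledger stores raw counts only and percentages are always
#' computed here against a named denominator.
#'
#' @param ledger A [build_flow()] ledger.
#' @param denominator `"baseline"` (the baseline-tested N),
#'   `"followup"` or `"lost"`.
#' @return Named vector of one-decimal percentages for the loss
#'   subcategories and the follow-up/lost totals.
#' @export
flow_percentages <- function(ledger, denominator = c("baseline", "lost")) {
  denominator <- match.arg(denominator)
  d <- switch(denominator, baseline = ledger$baseline_tested,
              lost = ledger$lost_total)
  items <- if (denominator == "lost") flow_loss_reasons
           else c("followup_tested", "lost_total", flow_loss_reasons)
  vapply(stats::setNames(items, items),
         function(i) percentage(ledger[[i]], d), 0)
}

# linear-interpolation quartiles ((n+1)p convention, SPSS-style): with
# values {1,2,3,4,100} the IQR is 1.5 to 52
quartiles <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75),
                                         type = 6, na.rm = TRUE, names = FALSE)

#' Per-group characteristics summary (Table-1 style)
#'
#' Summarizes covariates by group (`all`, `neither`, `preCI`, `POCD`):
#' continuous variables as mean (SD) — or median (IQR) for the variables
#' named in `iqr_vars` —, categorical/logical variables as n (%), with the
#' available N annotated when data are missing. Percentages use
#' [percentage()] so they are never re-rounded elsewhere.
#'
#' @param covariates Data frame with `subject_id` and covariate columns.
#' @param outcomes Outcome table (stacked [classify()] rows) defining the
#'   preCI and POCD groups; subjects impaired on neither form `neither`.
#' @param iqr_vars Columns summarized as median (IQR).
#' @return A data.frame: one row per variable (categorical variables one
#'   row per level), one column per group, values as formatted strings,
#'   plus a `statistic` column naming the summary used.
#' @export
characteristics_table <- function(covariates, outcomes,
                                  iqr_vars = c("bmi", "mmse",
                                               "length_of_stay_days")) {
  grp_ids <- function(kind) {
    s <- outcomes[outcomes$outcome_kind == kind & !is.na(outcomes$impaired) &
                    outcomes$impaired, , drop = FALSE]
    unique(s$subject_id)
  }
  preci <- grp_ids("preCI"); pocd <- grp_ids("POCD")
  groups <- list(
    all = covariates$subject_id,
    neither = setdiff(covariates$subject_id, union(preci, pocd)),
    preCI = preci, POCD = pocd)

  vars <- setdiff(names(covariates), "subject_id")
  rows <- list()
  for (v in vars) {
    col <- covariates[[v]]
    if (is.numeric(col) && !all(col %in% c(0, 1, NA))) {
      cells <- vapply(groups, function(ids) {
        x <- col[covariates$subject_id %in% ids]
        n_avail <- sum(!is.na(x))
        if (length(x) == 0L) return("n=0")
        if (n_avail == 0L) return("n=0")
        note <- if (n_avail < length(x)) sprintf(" [N=%d]", n_avail) else ""
        if (v %in% iqr_vars) {
          q <- quartiles(x)
          sprintf("%.1f (%.1f-%.1f)%s", q[2], q[1], q[3], note)
        } else {
          sprintf("%.1f (%.1f)%s", mean(x, na.rm = TRUE),
                  stats::sd(x, na.rm = TRUE), note)
        }
      }, "")
      rows[[length(rows) + 1L]] <- c(variable = v,
        statistic = if (v %in% iqr_vars) "median (IQR)" else "mean (SD)",
        cells)
    } else {
      lev <- if (is.numeric(col)) c(1) else sort(unique(col[!is.na(col)]))
      for (l in lev) {
        cells <- vapply(groups, function(ids) {
          x <- col[covariates$subject_id %in% ids]
          if (length(x) == 0L) return("n=0")
          n <- sum(!is.na(x) & x == l)
          sprintf("%d (%.1f%%)", n, percentage(n, length(x)))
        }, "")
        label <- if (is.numeric(col) || is.logical(col)) v
                 else paste(v, l, sep = ": ")
        rows[[length(rows) + 1L]] <- c(variable = label, statistic = "n (%)",
                                       cells)
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("variable", "statistic", names(groups))
  out
}

#' Boxplots of thalamus volume across outcome groups
#'
#' One box per group (whole cohort, preCI, POCD) in a colorblind-safe
#' palette (black / pink / green, Okabe-Ito), y-axis in cm^3, group sizes
#' annotated under each box; written as a vector-graphics file (PDF or
#' SVG by file extension). Empty groups are dropped with a warning.
#'
#' @param volumes Numeric thalamus volumes (cm^3) for the whole cohort.
#' @param group_masks Named list of logical masks (or id vectors matching
#'   `names(volumes)`) defining the non-`all` groups, e.g.
#'   `list(preCI = ..., POCD = ...)`.
#' @param file Output path ending in `.pdf` or `.svg`.
#' @return Invisibly, `file`.
#' @export
boxplot_groups <- function(volumes, group_masks, file) {
  series <- c(list(all = volumes),
              lapply(group_masks, function(m) volumes[m]))
  empty <- vapply(series, function(s) length(s) == 0L, TRUE)
  if (any(empty)) {
    warning("dropping empty group(s): ",
            paste(names(series)[empty], collapse = ", "), call. = FALSE)
    series <- series[!empty]
  }
  stopifnot(length(series) >= 1L)
  ext <- tolower(tools::file_ext(file))
  switch(ext, pdf = grDevices::pdf(file, width = 5, height = 4),
         svg = grDevices::svg(file, width = 5, height = 4),
         stop("file must end in .pdf or .svg"))
  on.exit(grDevices::dev.off())
  pal <- c("#000000", "#CC79A7", "#009E73", "#0072B2")[seq_along(series)]
  graphics::boxplot(series, border = pal, col = NA,
                    ylab = expression("Thalamus volume " * (cm^3)),
                    names = sprintf("%s\n(n=%d)", names(series),
                                    vapply(series, length, 0L)))
  invisible(file)
}
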