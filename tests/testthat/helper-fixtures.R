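# shared fixtures, all built in code

battery <- cog_battery()
params <- battery$name

battery_row <- function(name) battery[battery$name == name, ]

# one-subject assessment record with defaults at plausible raw values
make_record <- function(subject_id = "S1", session = "baseline", ...) {
  vals <- list(PAL_memory = 14, VRM_free_recall = 6, VRM_delayed_recognition = 22,
               SSP_span = 5, GPT_time = 93, SRT_time = 310, TMTB_time = 112)
  override <- list(...)
  vals[names(override)] <- override
  cbind(data.frame(subject_id = subject_id, session = session,
                   stringsAsFactors = FALSE),
        as.data.frame(vals))
}

# oriented-vector data.frame straight from a matrix (controls etc.)
make_oriented <- function(mat, ids = sprintf("X%03d", seq_len(nrow(mat)))) {
  df <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[params[j]]] <- mat[, j]
  df
}

# hand-built Z panel (bypasses the scoring path) for classify() tests
make_panel <- function(z, composite, min_available = 5L, kind = "change") {
  z <- matrix(z, ncol = length(params), dimnames = list(NULL, params))
  df <- data.frame(subject_id = sprintf("P%03d", seq_len(nrow(z))),
                   stringsAsFactors = FALSE)
  for (p in params) df[[p]] <- z[, p]
  df$composite_z <- composite
  df$n_available <- rowSums(!is.na(z))
  df$classifiable <- df$n_available >= min_available
  df$composite_z[!df$classifiable] <- NA_real_
  structure(df, kind = kind, class = c("z_panel", "data.frame"))
}

# independent brute-force reimplementation of the dichotomization rule
oracle_classify <- function(z, composite, threshold = 1.96, min_available = 5L) {
  if (sum(!is.na(z)) < min_available) return("unclassifiable")
  multi <- sum(!is.na(z) & z > threshold) >= 2L
  comp <- !is.na(composite) && composite > threshold
  if (comp && multi) "both"
  else if (comp) "composite_only"
  else if (multi) "multi_test_only"
  else "none"
}

# config with every stochastic nuisance switched off except what a test uses
quiet_config <- function(...) {
  zero <- stats::setNames(rep(0, 7), params)
  defaults <- list(missing_rate_item = 0, followup_rate = 1,
                   prevalence_preCI = 0, prevalence_POCD = 0,
                   intertest_corr = 0, learning_effect = zero, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
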