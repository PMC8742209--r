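#' Rule-threshold configuration
#'
#' Every numeric threshold used by any decision rule in the engine lives in a
#' single configuration object so that deployments can replace the defaults
#' without touching code. The defaults encode the published rule constants:
#' the 7-check-in clinical-status window and Table-style transition counts
#' (4, 5, 5, 5), the 4-check-in target window, the severe sleep bounds
#' (<= 4 h; >= min(12, goal upper limit + 4) h), the 3-of-7 medication
#' reach-out, the 2-hourly / max-3 notification cadence, the DSM-IV/CMF
#' episode windows (10/14, 7, 7, 4 consecutive days) and symptom counts, and
#' the CMF non-episode 7- and 56-day windows.
#'
#' Thresholds that the source protocol leaves to supplementary material
#' (weekly PHQ-8/ASRM reach-out thresholds, adherence-flag bounds, popup
#' suppression) carry documented defaults and are equally overridable.
#'
#' @param ... named overrides of any default threshold.
#' @return An object of class `livewell_rules`: a named list of thresholds.
#' @examples
#' cfg <- rule_config(phq8_episode_threshold = 12)
#' cfg$dn1_count
#' @export
rule_config <- function(...) {
  defaults <- list(
    # LiveWell 4-state machine (last-7-check-in window)
    status_window          = 7L,   # check-ins in the clinical-status window
    dn1_count              = 4L,   # well -> prodromal:      count(|WR| >= 2) >= 4
    dn2_count              = 5L,   # prodromal/recov -> well: count(|WR| <= 1) >= 5
    dn3_count              = 5L,   # prodromal/recov -> unwell: count(|WR| >= 3) >= 5
    dn4_count              = 5L,   # unwell -> recovering:   count(|WR| <= 2) >= 5
    wr_early_warning       = 2L,   # |WR| band: early warning / residual symptoms
    wr_worsening           = 3L,   # |WR| band: episode-level symptoms
    wr_crisis              = 4L,   # |WR| band: crisis
    # daily-review target rules (last-4-check-in window)
    target_window          = 4L,
    target_trigger_count   = 2L,   # problem days of 4 that trigger a target category
    severe_sleep_trigger   = 1L,   # severe sleep classes trigger at 1 day
    sleep_severe_low       = 4,    # hours: <= 4 h is severe short sleep
    sleep_severe_high_cap  = 12,   # hours: >= 12 h is severe long sleep ...
    sleep_goal_offset      = 4,    # ... or >= goal upper limit + 4 h, whichever less
    risk_lookback_days     = 14L,  # tier-2 history window for moderate/high risk
    # daily reach-out rules (last-7-check-in window)
    medication_reachout    = 3L,   # medication "all" on <= 3 of last 7 check-ins
    sleep_low_days         = 2L,   # sleep <= 4 h on >= 2 of last 7 check-ins
    sleep_dev_below        = 3,    # 7-day mean >= 3 h below goal midpoint
    sleep_dev_above        = 4,    # 7-day mean >= 4 h above goal midpoint
    popup_suppression_days = 3L,   # same non-crisis trigger silent after firing
    # weekly reach-out (new-onset crossing)
    phq8_episode_threshold = 10L,
    asrm_episode_threshold = 6L,
    # check-in adherence flags
    daily_adherence_min    = 4L,   # flag when < 4 completed of last 7 calendar days
    weekly_cadence_days    = 7L,
    weekly_overdue_days    = 3L,   # flag when >= 3 days past the weekly due date
    # notifications
    notify_interval_hours  = 2,
    notify_max             = 3L,
    # DSM-IV/CMF episode entry (Table 1 constants)
    depression_symptoms    = 5L,   # moderate depression symptoms
    depression_days        = 10L,  # qualifying days ...
    depression_window      = 14L,  # ... within 14 consecutive days
    mania_symptoms_elevated  = 3L, # moderate mania symptoms if mood elevated
    mania_symptoms_irritable = 4L, # if mood only irritable
    mania_days             = 7L,
    mixed_days             = 7L,
    mixed_depression_count = 3L,   # concurrent depressive symptom count ...
    mixed_depression_days  = 5L,   # ... on >= 5 of 7 consecutive days
    mixed_depression_window = 7L,
    hypomania_days         = 4L,
    # CMF non-episode statuses (Table 2 constants)
    cmf_window_days        = 7L,   # consecutive-day evaluation window
    recovery_days          = 56L,  # recovering -> recovery when run > 56 days
    symptom_count_max      = 2L,   # low-symptom bound ("symptom count <= 2")
    prodromal_new_symptoms = 2L,   # new moderate+ symptoms while in recovery
    episode_exit_days      = 7L    # entry criteria absent this long ends an episode
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown rule threshold(s): ", paste(unknown, collapse = ", "))
    defaults[names(over)] <- over
  }
  num <- vapply(defaults, function(v) is.numeric(v) && length(v) == 1L && v > 0, TRUE)
  if (!all(num)) stop("all rule thresholds must be positive scalars")
  structure(defaults, class = "livewell_rules")
}

#' @export
print.livewell_rules <- function(x, ...) {
  cat("LiveWell rule configuration (", length(x), " thresholds)\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a rule configuration as JSON
#'
#' Round-trips [rule_config()] objects through a flat JSON object; unknown
#' keys are rejected so stale config files fail loudly.
#'
#' @param config a `livewell_rules` object.
#' @param path file path.
#' @return `read_rule_config()` returns a `livewell_rules` object.
#' @export
write_rule_config <- function(config, path) {
  stopifnot(inherits(config, "livewell_rules"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_config
#' @export
read_rule_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(rule_config, raw)
}
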