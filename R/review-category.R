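#' The 26 daily-review content categories
#'
#' The daily review delivers exactly one of 26 content categories per
#' completed check-in, grouped in 3 tiers: tier 3 -- crisis (wellness rating
#' +4 or -4); tier 2 -- 15 clinical-status/wellness categories (continuing or
#' improving while unwell, prodromal, or recovering; worsening symptoms,
#' |WR| = 3, while not unwell; early warning signs, |WR| = 2, while well);
#' tier 1 -- 9 target and risk categories (medication, four sleep classes,
#' bedtime/risetime windows, and the default low / moderate-high risk
#' categories). The exact category names are a documented reconstruction (the
#' deployed table lives in supplementary material); they are config-replaceable
#' through the content corpus.
#'
#' @return Data frame with columns `category` and `tier` (26 rows).
#' @export
daily_review_categories <- function() {
  tier3 <- c("severe_up", "severe_down")
  tier2 <- c(
    paste0(rep(c("unwell", "prodromal", "recovering"), each = 3),
           c("_continuing_up", "_continuing_down", "_improving")),
    "prodromal_worsening", "recovering_worsening",
    "well_worsening_up", "well_worsening_down",
    "well_early_warning_up", "well_early_warning_down")
  tier1 <- c("medication", "sleep_less_severe", "sleep_more_severe",
             "sleep_less", "sleep_more", "bedtime_window", "risetime_window",
             "low_risk", "moderate_high_risk")
  data.frame(category = c(tier3, tier2, tier1),
             tier = rep(c(3L, 2L, 1L), c(length(tier3), length(tier2),
                                         length(tier1))))
}

#' Classify a night's sleep duration
#'
#' Five classes against the personalized sleep goal range: `less_severe`
#' (<= 4 hours), `more_severe` (>= 12 hours or >= goal upper limit + 4 hours,
#' whichever is less), `less` (< goal lower limit), `more` (> goal upper
#' limit), else `in_range`. The severe classes dominate the plain ones.
#'
#' @param sleep_hours sleep duration in hours, `[0, 24]` (vectorized).
#' @param profile a [user_profile()] supplying the goal bounds.
#' @param config a [rule_config()] supplying the severe bounds.
#' @return character vector of classes.
#' @examples
#' classify_sleep(c(4, 5.5, 7, 9, 12), user_profile())
#' @export
classify_sleep <- function(sleep_hours, profile = user_profile(),
                           config = rule_config()) {
  if (any(sleep_hours < 0 | sleep_hours > 24))
    stop("sleep_hours must lie in [0, 24]")
  severe_high <- min(config$sleep_severe_high_cap,
                     profile$sleep_goal_high + config$sleep_goal_offset)
  ifelse(sleep_hours <= config$sleep_severe_low, "less_severe",
  ifelse(sleep_hours >= severe_high, "more_severe",
  ifelse(sleep_hours < profile$sleep_goal_low, "less",
  ifelse(sleep_hours > profile$sleep_goal_high, "more", "in_range"))))
}

#' Goal-achievement feedback for the daily-review bar graphs
#'
#' Percent of the last (up to) 7 daily check-ins meeting each target goal:
#' medication (took all prescribed medications), sleep duration (within the
#' personalized goal range), and routine (bedtime/risetime inside the
#' personalized 1.5-hour windows, modular around midnight). Percentages are
#' rounded to the nearest integer, so 3 of 7 medication days reads 43%.
#'
#' @param checkins data frame of the last <= 7 daily check-ins.
#' @param profile a [user_profile()].
#' @return Named numeric vector of percentages in `[0, 100]`: `medication`,
#'   `sleep`, `bedtime`, `risetime`.
#' @export
goal_feedback <- function(checkins, profile = user_profile()) {
  if (is.null(checkins) || nrow(checkins) == 0L)
    stop("goal feedback requires at least one check-in")
  if (nrow(checkins) > 7L)
    checkins <- checkins[order(as.Date(checkins$date)), , drop = FALSE]
  checkins <- utils::tail(checkins[order(as.Date(checkins$date)), , drop = FALSE], 7L)
  pct <- function(met) round(100 * mean(met))
  c(medication = pct(checkins$medication == "all"),
    sleep = pct(checkins$sleep_hours >= profile$sleep_goal_low &
                  checkins$sleep_hours <= profile$sleep_goal_high),
    bedtime = pct(in_clock_window(checkins$bedtime,
                                  profile$bedtime_window_start,
                                  profile$window_width_hours)),
    risetime = pct(in_clock_window(checkins$risetime,
                                   profile$risetime_window_start,
                                   profile$window_width_hours)))
}

#' Select the daily-review content category
#'
#' The hierarchical (if-then/elseif-then) decision table run after every
#' completed daily check-in. Clinical status and wellness rating dominate:
#'
#' 1. `|WR| = 4` selects the crisis categories (tier 3, severe up/down).
#' 2. Clinical-status/wellness categories (tier 2): while unwell, continuing
#'    (`|WR| >= 3`, signed) or improving; while prodromal or recovering,
#'    worsening (`|WR| = 3`), continuing (`|WR| = 2`, signed) or improving
#'    (`|WR| <= 1`); while well, worsening (`|WR| = 3`, signed) or early
#'    warning signs (`|WR| = 2`, signed).
#' 3. Target categories (tier 1) over the last 4 check-ins: medication not
#'    fully taken on >= 2 of 4; severe short/long sleep on >= 1 of 4; short/
#'    long sleep on >= 2 of 4; bedtime or risetime outside the personalized
#'    window on >= 2 of 4 -- in the priority order medication > sleep >
#'    routine, severe sleep before plain sleep.
#' 4. Otherwise the default risk categories: `moderate_high_risk` when a
#'    tier-2/3 category fired within the configured look-back, else
#'    `low_risk`.
#'
#' @param status the user's current LiveWell clinical status (after the
#'   post-check-in status update), a state name or `livewell_status` record.
#' @param today the validated check-in that triggered the review (one row).
#' @param window4 data frame of the last <= 4 check-ins including today.
#' @param profile a [user_profile()].
#' @param config a [rule_config()].
#' @param recent_tier2 logical: did a tier-2 or tier-3 category fire within
#'   the last `config$risk_lookback_days` days?
#' @return A list of class `livewell_decision`: `category`, `tier`,
#'   `direction` (`"up"`, `"down"`, `"none"`), and `evidence` (the tailoring
#'   variable values that triggered the category).
#' @examples
#' ci <- daily_checkin("2021-03-01", "all", 7, "23:00", "07:00", 2)
#' select_category("well", ci, ci)
#' @export
select_category <- function(status, today, window4 = today,
                            profile = user_profile(), config = rule_config(),
                            recent_tier2 = FALSE) {
  if (inherits(status, "livewell_status")) status <- status$status
  status <- match.arg(status, livewell_states())
  wr <- as.integer(today$wellness)
  dir <- if (wr > 0) "up" else if (wr < 0) "down" else "none"
  sgn <- if (wr >= 0) "up" else "down"
  decision <- function(category, tier, direction, evidence) {
    structure(list(category = category, tier = tier, direction = direction,
                   evidence = evidence), class = "livewell_decision")
  }
  # tier 3: crisis
  if (abs(wr) >= config$wr_crisis)
    return(decision(paste0("severe_", sgn), 3L, sgn, list(wellness = wr)))
  # tier 2: clinical status and wellness rating
  ev <- list(status = status, wellness = wr)
  if (status == "unwell") {
    if (abs(wr) >= config$wr_worsening)
      return(decision(paste0("unwell_continuing_", sgn), 2L, sgn, ev))
    return(decision("unwell_improving", 2L, "none", ev))
  }
  if (status %in% c("prodromal", "recovering")) {
    if (abs(wr) >= config$wr_worsening)
      return(decision(paste0(status, "_worsening"), 2L, dir, ev))
    if (abs(wr) >= config$wr_early_warning)
      return(decision(paste0(status, "_continuing_", sgn), 2L, sgn, ev))
    return(decision(paste0(status, "_improving"), 2L, "none", ev))
  }
  # status == well
  if (abs(wr) >= config$wr_worsening)
    return(decision(paste0("well_worsening_", sgn), 2L, sgn, ev))
  if (abs(wr) >= config$wr_early_warning)
    return(decision(paste0("well_early_warning_", sgn), 2L, sgn, ev))
  # tier 1: targets over the last 4 check-ins
  w4 <- utils::tail(window4[order(as.Date(window4$date)), , drop = FALSE],
                    config$target_window)
  med_miss <- sum(w4$medication != "all")
  if (med_miss >= config$target_trigger_count)
    return(decision("medication", 1L, "none",
                    list(medication_missed = med_miss,
                         window = nrow(w4))))
  cls <- classify_sleep(w4$sleep_hours, profile, config)
  for (sc in c("less_severe", "more_severe")) {
    n <- sum(cls == sc)
    if (n >= config$severe_sleep_trigger)
      return(decision(paste0("sleep_", sc), 1L, "none",
                      list(sleep_days = n, sleep_hours = w4$sleep_hours[cls == sc])))
  }
  for (sc in c("less", "more")) {
    n <- sum(cls == sc)
    if (n >= config$target_trigger_count)
      return(decision(paste0("sleep_", sc), 1L, "none",
                      list(sleep_days = n, sleep_hours = w4$sleep_hours[cls == sc])))
  }
  bed_out <- sum(!in_clock_window(w4$bedtime, profile$bedtime_window_start,
                                  profile$window_width_hours))
  if (bed_out >= config$target_trigger_count)
    return(decision("bedtime_window", 1L, "none", list(bedtime_out = bed_out)))
  rise_out <- sum(!in_clock_window(w4$risetime, profile$risetime_window_start,
                                   profile$window_width_hours))
  if (rise_out >= config$target_trigger_count)
    return(decision("risetime_window", 1L, "none", list(risetime_out = rise_out)))
  # default risk categories
  if (isTRUE(recent_tier2))
    return(decision("moderate_high_risk", 1L, "none",
                    list(recent_tier2 = TRUE)))
  decision("low_risk", 1L, "none", list(wellness = wr))
}

#' @export
print.livewell_decision <- function(x, ...) {
  cat("Daily review category:", x$category,
      sprintf("(tier %d, direction %s)\n", x$tier, x$direction))
  invisible(x)
}
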