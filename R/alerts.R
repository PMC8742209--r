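#' Alert events
#'
#' Structured events emitted by the reach-out and adherence rules:
#' `user_popup` (in-app pop-up asking the user to call their psychiatrist,
#' with a call button -- `callto` always carries the psychiatrist's phone),
#' `provider_email` and `coach_email` (alert e-mails, emitted as events; the
#' transport is an integrator concern), and `coach_flag` (flagged rows in the
#' daily coach report).
#'
#' @param kind one of `"user_popup"`, `"provider_email"`, `"coach_email"`,
#'   `"coach_flag"`.
#' @param trigger rule identifier (e.g. `"crisis"`, `"medication"`).
#' @param date event date.
#' @param payload named list summarizing the triggering evidence.
#' @param callto phone number (required for `user_popup`).
#' @param user_id user the event concerns.
#' @return A list of class `livewell_alert`.
#' @export
alert_event <- function(kind, trigger, date, payload = list(), callto = NULL,
                        user_id = "user") {
  kind <- match.arg(kind, c("user_popup", "provider_email", "coach_email",
                            "coach_flag"))
  if (kind == "user_popup" && (is.null(callto) || !nzchar(callto)))
    stop("user_popup alerts must carry the psychiatrist's phone number")
  structure(list(kind = kind, trigger = trigger, date = as.Date(date),
                 payload = payload, callto = callto,
                 user_id = as.character(user_id)),
            class = "livewell_alert")
}

#' @export
print.livewell_alert <- function(x, ...) {
  cat(format(x$date), x$kind, "trigger:", x$trigger,
      if (!is.null(x$callto)) paste("call:", x$callto) else "", "\n")
  invisible(x)
}

#' Daily clinical reach-out rules
#'
#' Run after category selection on every completed check-in. A hierarchical
#' decision table selects at most one user pop-up per day (highest-priority
#' trigger), plus the accompanying e-mail events:
#'
#' 1. crisis wellness rating (+4/-4): pop-up + provider and coach e-mails;
#' 2. transition to the unwell or prodromal state: pop-up + e-mails;
#' 3. worsening symptoms (`|WR| = 3`) while not unwell: pop-up;
#' 4. medication taken in full on <= 3 of the last 7 check-ins: pop-up +
#'    coach e-mail;
#' 5. sleep <= 4 hours on >= 2 of the last 7 check-ins, or 7-check-in mean
#'    sleep >= 3 hours below / >= 4 hours above the personalized goal
#'    midpoint: pop-up + coach e-mail.
#'
#' Non-crisis triggers are suppressed for `config$popup_suppression_days`
#' days after they last fired (crisis always fires).
#'
#' @param decision the day's `livewell_decision` from [select_category()].
#' @param status_before,status_after LiveWell state names around the day's
#'   status update.
#' @param window7 data frame of the last <= 7 check-ins including today.
#' @param profile a [user_profile()].
#' @param config a [rule_config()].
#' @param date the check-in date.
#' @param last_fired named list mapping trigger id to the date it last fired
#'   (for popup suppression); maintained by the caller across days.
#' @return List of `livewell_alert` events (possibly empty).
#' @export
evaluate_daily_reachout <- function(decision, status_before, status_after,
                                    window7, profile = user_profile(),
                                    config = rule_config(),
                                    date = Sys.Date(), last_fired = list()) {
  date <- as.Date(date)
  w7 <- utils::tail(window7[order(as.Date(window7$date)), , drop = FALSE], 7L)
  today <- w7[nrow(w7), , drop = FALSE]
  wr <- as.integer(today$wellness)
  suppressed <- function(trigger) {
    prev <- last_fired[[trigger]]
    !is.null(prev) && as.numeric(date - as.Date(prev)) < config$popup_suppression_days
  }
  popup <- function(trigger, payload) {
    alert_event("user_popup", trigger, date, payload,
                callto = profile$psychiatrist_phone, user_id = profile$user_id)
  }
  emails <- function(trigger, payload, provider = TRUE) {
    ev <- list(alert_event("coach_email", trigger, date, payload,
                           user_id = profile$user_id))
    if (provider)
      ev <- c(ev, list(alert_event("provider_email", trigger, date, payload,
                                   user_id = profile$user_id)))
    ev
  }
  # 1. crisis -- never suppressed
  if (abs(wr) >= config$wr_crisis) {
    payload <- list(wellness = wr)
    return(c(list(popup("crisis", payload)), emails("crisis", payload)))
  }
  # 2. transition to unwell or prodromal
  if (!identical(status_before, status_after) &&
      status_after %in% c("unwell", "prodromal")) {
    trigger <- paste0("transition_", status_after)
    payload <- list(from = status_before, to = status_after)
    if (!suppressed(trigger))
      return(c(list(popup(trigger, payload)), emails(trigger, payload)))
  }
  # 3. worsening symptoms while not unwell
  if (abs(wr) >= config$wr_worsening && status_after != "unwell" &&
      !suppressed("worsening"))
    return(list(popup("worsening", list(wellness = wr, status = status_after))))
  # 4. medication adherence
  med_all <- sum(w7$medication == "all")
  if (nrow(w7) >= 7L && med_all <= config$medication_reachout &&
      !suppressed("medication")) {
    payload <- list(medication_all_days = med_all, window = nrow(w7))
    return(c(list(popup("medication", payload)),
             emails("medication", payload, provider = FALSE)))
  }
  # 5. sleep duration
  low_days <- sum(w7$sleep_hours <= config$sleep_severe_low)
  mid <- (profile$sleep_goal_low + profile$sleep_goal_high) / 2
  dev <- mean(w7$sleep_hours) - mid
  sleep_hit <-
    if (low_days >= config$sleep_low_days) "sleep_severe_low"
    else if (nrow(w7) >= 7L && dev <= -config$sleep_dev_below) "sleep_below_usual"
    else if (nrow(w7) >= 7L && dev >= config$sleep_dev_above) "sleep_above_usual"
    else NULL
  if (!is.null(sleep_hit) && !suppressed(sleep_hit)) {
    payload <- list(low_days = low_days, mean_sleep = mean(w7$sleep_hours),
                    goal_midpoint = mid)
    return(c(list(popup(sleep_hit, payload)),
             emails(sleep_hit, payload, provider = FALSE)))
  }
  list()
}

#' Weekly check-in reach-out rules
#'
#' Fires a clinical reach-out when a weekly PHQ-8 or ASRM total crosses from
#' below its episode threshold to at or above it (new-onset semantics: a
#' score that stays above threshold week after week fires only on the first
#' crossing). Thresholds default to the published instrument cutoffs (PHQ-8
#' >= 10 depressive, ASRM >= 6 manic) and are config-overridable.
#'
#' @param weekly one-row data frame with `date`, `phq8_total`, `asrm_total`
#'   (see [weekly_checkin()]).
#' @param previous the previous weekly check-in row, or `NULL` for the first.
#' @param profile a [user_profile()].
#' @param config a [rule_config()].
#' @return List of `livewell_alert` events (possibly empty).
#' @export
evaluate_weekly_reachout <- function(weekly, previous = NULL,
                                     profile = user_profile(),
                                     config = rule_config()) {
  crossing <- function(now, before, threshold) {
    now >= threshold && (is.null(before) || before < threshold)
  }
  out <- list()
  reach <- function(trigger, payload) {
    c(list(alert_event("user_popup", trigger, weekly$date, payload,
                       callto = profile$psychiatrist_phone,
                       user_id = profile$user_id)),
      list(alert_event("coach_email", trigger, weekly$date, payload,
                       user_id = profile$user_id)),
      list(alert_event("provider_email", trigger, weekly$date, payload,
                       user_id = profile$user_id)))
  }
  if (crossing(weekly$phq8_total, previous$phq8_total,
               config$phq8_episode_threshold))
    out <- c(out, reach("phq8_new_onset",
                        list(phq8_total = weekly$phq8_total,
                             threshold = config$phq8_episode_threshold)))
  if (crossing(weekly$asrm_total, previous$asrm_total,
               config$asrm_episode_threshold))
    out <- c(out, reach("asrm_new_onset",
                        list(asrm_total = weekly$asrm_total,
                             threshold = config$asrm_episode_threshold)))
  out
}

#' Check-in adherence flags for the coach report
#'
#' Flags users whose check-in adherence has dropped: fewer than 4 completed
#' daily check-ins over the last 7 calendar days, or a weekly check-in at
#' least 3 days past due (due 7 days after the last completed weekly
#' check-in; anchored at the first daily check-in when no weekly exists yet).
#'
#' @param checkin_dates dates of completed daily check-ins.
#' @param weekly_dates dates of completed weekly check-ins.
#' @param today evaluation date.
#' @param profile a [user_profile()].
#' @param config a [rule_config()].
#' @return List of `coach_flag` `livewell_alert` events (possibly empty).
#' @export
adherence_flags <- function(checkin_dates, weekly_dates, today,
                            profile = user_profile(), config = rule_config()) {
  today <- as.Date(today)
  checkin_dates <- sort(as.Date(checkin_dates))
  weekly_dates <- sort(as.Date(weekly_dates))
  out <- list()
  recent <- sum(checkin_dates > today - 7 & checkin_dates <= today)
  if (recent < config$daily_adherence_min)
    out <- c(out, list(alert_event(
      "coach_flag", "daily_adherence", today,
      list(completed_last7 = recent, required = config$daily_adherence_min),
      user_id = profile$user_id)))
  anchor <- if (length(weekly_dates)) max(weekly_dates)
            else if (length(checkin_dates)) min(checkin_dates) else NULL
  if (!is.null(anchor)) {
    overdue <- as.numeric(today - anchor) - config$weekly_cadence_days
    if (overdue >= config$weekly_overdue_days)
      out <- c(out, list(alert_event(
        "coach_flag", "weekly_overdue", today,
        list(days_since_last_weekly = as.numeric(today - anchor),
             overdue_days = overdue), user_id = profile$user_id)))
  }
  out
}

#' Daily check-in reminder schedule
#'
#' Users receive their first check-in reminder at their designated time, then
#' every 2 hours until they check in or have received 3 reminders. Returns
#' the reminder times actually delivered given an (optional) check-in time.
#'
#' @param notify_time designated first notification time (`"HH:MM"`).
#' @param checkin_time clock time the user checked in, or `NULL` if they
#'   never did that day.
#' @param config a [rule_config()].
#' @return Character vector of `"HH:MM"` reminder times (length 0..3).
#' @examples
#' notification_schedule("09:00")            # no check-in: 3 reminders
#' notification_schedule("09:00", "09:30")   # checked in after the first
#' @export
notification_schedule <- function(notify_time, checkin_time = NULL,
                                  config = rule_config()) {
  start <- parse_clock(notify_time)
  times <- start + round(config$notify_interval_hours * 60) *
    (seq_len(config$notify_max) - 1L)
  times <- times[times <= 1439L]
  if (!is.null(checkin_time)) times <- times[times < parse_clock(checkin_time)]
  format_clock(times)
}

#' Daily coach report
#'
#' One row per user: last-7-day check-in adherence, current clinical status,
#' the day's alert triggers, and whether an adherence rule flagged the user.
#' Flagged rows sort first.
#'
#' @param states named list mapping user id to current LiveWell state name.
#' @param alerts list of the day's `livewell_alert` events (all users).
#' @param adherence named numeric vector: completed daily check-ins over the
#'   last 7 calendar days, per user.
#' @param date report date.
#' @return Data frame of class `livewell_coach_report`, flagged rows first.
#' @export
build_coach_report <- function(states, alerts = list(), adherence = NULL,
                               date = Sys.Date()) {
  users <- names(states)
  by_user <- function(uid) {
    ua <- Filter(function(a) identical(a$user_id, uid), alerts)
    trig <- vapply(ua, function(a) paste0(a$kind, ":", a$trigger), "")
    flagged <- any(vapply(ua, function(a) a$kind == "coach_flag", TRUE))
    adh <- if (!is.null(adherence) && uid %in% names(adherence))
      round(100 * adherence[[uid]] / 7) else NA_real_
    data.frame(user_id = uid, date = as.Date(date),
               adherence_pct = adh, status = states[[uid]],
               alerts = paste(trig, collapse = ";"),
               flagged = flagged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(users, by_user))
  out <- out[order(!out$flagged, out$user_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("livewell_coach_report", class(out))
  out
}
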