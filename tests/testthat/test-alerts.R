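profile <- user_profile(psychiatrist_phone = "555-0100")

reachout <- function(wellness = rep(0, 7), medication = "all", sleep = 7,
                     status_before = "well", status_after = "well",
                     last_fired = list(), config = rule_config()) {
  w7 <- make_checkins(wellness, medication = medication, sleep_hours = sleep)
  today <- w7[nrow(w7), , drop = FALSE]
  decision <- select_category(status_after, today, utils::tail(w7, 4), profile,
                              config)
  evaluate_daily_reachout(decision, status_before, status_after, w7, profile,
                          config, date = today$date, last_fired = last_fired)
}

kinds <- function(alerts) sort(vapply(alerts, `[[`, "", "kind"))

test_that("crisis ratings trigger a pop-up with call button plus both e-mails", {
  ev <- reachout(wellness = c(rep(0, 6), 4))
  expect_identical(kinds(ev), c("coach_email", "provider_email", "user_popup"))
  popup <- ev[[which(vapply(ev, `[[`, "", "kind") == "user_popup")]]
  expect_identical(popup$trigger, "crisis")
  expect_identical(popup$callto, "555-0100")
})

test_that("transitions to unwell or prodromal alert user, provider, and coach", {
  ev <- reachout(wellness = c(0, 0, 0, 2, 2, 2, 2), status_before = "well",
                 status_after = "prodromal")
  expect_identical(kinds(ev), c("coach_email", "provider_email", "user_popup"))
  expect_identical(ev[[1]]$trigger, "transition_prodromal")
})

test_that("worsening symptoms while not unwell trigger a pop-up only", {
  ev <- reachout(wellness = c(rep(0, 6), 3), status_after = "well")
  expect_identical(kinds(ev), "user_popup")
  expect_identical(ev[[1]]$trigger, "worsening")
  # but not when already unwell (continuing, not worsening)
  ev <- reachout(wellness = c(rep(3, 7)), status_before = "unwell",
                 status_after = "unwell")
  expect_identical(length(ev), 0L)
})

test_that("medication and sleep reach-outs fire on the survey-derived thresholds", {
  ev <- reachout(medication = c("all", "all", "all", "some", "none", "some",
                                "none"))
  expect_identical(ev[[1]]$trigger, "medication")
  expect_identical(kinds(ev), c("coach_email", "user_popup"))
  expect_identical(ev[[1]]$payload$medication_all_days, 3L)
  # 4 of 7 adherent days: no reach-out
  ev <- reachout(medication = c("all", "all", "all", "all", "none", "some",
                                "none"))
  expect_identical(length(ev), 0L)
  # two nights at <= 4 h
  ev <- reachout(sleep = c(7, 7, 7, 7, 7, 3.5, 3))
  expect_identical(ev[[1]]$trigger, "sleep_severe_low")
  # 7-day mean >= 4 h above the goal midpoint (7 h for the default profile)
  ev <- reachout(sleep = rep(11.5, 7))
  expect_identical(ev[[1]]$trigger, "sleep_above_usual")
  ev <- reachout(sleep = rep(3.9, 7))   # also < 4 h twice -> severe wins
  expect_identical(ev[[1]]$trigger, "sleep_severe_low")
  ev <- reachout(sleep = c(6, 6, 6, 7, 7, 7, 7))
  expect_identical(length(ev), 0L)
})

test_that("no events fire when all goals are met", {
  expect_identical(length(reachout()), 0L)
})

test_that("at most one pop-up per day and suppression silences repeat triggers", {
  # crisis outranks a concurrent medication problem
  ev <- reachout(wellness = c(rep(0, 6), -4), medication = "none")
  popups <- Filter(function(a) a$kind == "user_popup", ev)
  expect_identical(length(popups), 1L)
  expect_identical(popups[[1]]$trigger, "crisis")
  # a medication pop-up that fired yesterday is suppressed for 3 days
  today <- make_checkins(rep(0, 7))$date[7]
  ev <- reachout(medication = "none",
                 last_fired = list(medication = today - 1))
  expect_identical(length(ev), 0L)
  ev <- reachout(medication = "none",
                 last_fired = list(medication = today - 3))
  expect_identical(ev[[1]]$trigger, "medication")
  # crisis is exempt from suppression
  ev <- reachout(wellness = c(rep(0, 6), 4),
                 last_fired = list(crisis = today - 1))
  expect_identical(ev[[1]]$trigger, "crisis")
})

test_that("weekly reach-outs use new-onset crossing semantics", {
  wk <- function(phq, asrm = 0, date = "2021-03-07") {
    data.frame(date = as.Date(date), phq8_total = phq, asrm_total = asrm)
  }
  ev <- evaluate_weekly_reachout(wk(14), wk(8), profile)
  expect_identical(ev[[1]]$trigger, "phq8_new_onset")
  expect_identical(kinds(ev), c("coach_email", "provider_email", "user_popup"))
  # constant above-threshold series does not re-fire
  expect_identical(length(evaluate_weekly_reachout(wk(14), wk(14), profile)), 0L)
  # below threshold: nothing
  expect_identical(length(evaluate_weekly_reachout(wk(0, asrm = 3),
                                                   wk(0, asrm = 2), profile)),
                   0L)
  # first-ever weekly check-in above threshold counts as new onset
  ev <- evaluate_weekly_reachout(wk(0, asrm = 8), NULL, profile)
  expect_identical(ev[[1]]$trigger, "asrm_new_onset")
})

test_that("adherence flags follow the daily and weekly thresholds", {
  today <- as.Date("2021-03-21")
  full <- today - 0:6
  expect_identical(length(adherence_flags(full, today - 3, today, profile)), 0L)
  three <- today - c(0, 2, 4)
  fl <- adherence_flags(three, today - 3, today, profile)
  expect_identical(fl[[1]]$kind, "coach_flag")
  expect_identical(fl[[1]]$trigger, "daily_adherence")
  expect_identical(fl[[1]]$payload$completed_last7, 3L)
  # weekly check-in 10 days ago: 3 days past the 7-day cadence
  fl <- adherence_flags(full, today - 10, today, profile)
  expect_identical(fl[[1]]$trigger, "weekly_overdue")
  expect_identical(length(adherence_flags(full, today - 9, today, profile)), 0L)
})

test_that("the reminder schedule is 2-hourly, at most 3, truncated at check-in", {
  expect_identical(notification_schedule("09:00"), c("09:00", "11:00", "13:00"))
  expect_identical(notification_schedule("09:00", "09:30"), "09:00")
  expect_identical(notification_schedule("09:00", "08:00"), character(0))
  expect_identical(notification_schedule("21:30"), c("21:30", "23:30"))
  for (h in seq(0, 21, by = 3)) {
    sched <- parse_clock(notification_schedule(format_clock(h * 60)))
    expect_lte(length(sched), 3L)
    if (length(sched) > 1L) expect_true(all(diff(sched) == 120L))
  }
})

test_that("pop-ups always carry a phone number", {
  expect_error(alert_event("user_popup", "crisis", Sys.Date()), "phone")
  ok <- alert_event("user_popup", "crisis", Sys.Date(), callto = "555-0100")
  expect_identical(ok$callto, "555-0100")
})

test_that("the coach report sorts flagged users first", {
  states <- list(u1 = "well", u2 = "prodromal", u3 = "well")
  alerts <- list(
    alert_event("coach_flag", "daily_adherence", "2021-03-21", user_id = "u2"),
    alert_event("user_popup", "medication", "2021-03-21", callto = "555",
                user_id = "u3"))
  rep <- build_coach_report(states, alerts,
                            c(u1 = 7, u2 = 2, u3 = 7), "2021-03-21")
  expect_identical(rep$user_id, c("u2", "u1", "u3"))
  expect_identical(rep$flagged, c(TRUE, FALSE, FALSE))
  expect_identical(rep$adherence_pct[rep$user_id == "u2"], 29)
  expect_match(rep$alerts[rep$user_id == "u3"], "user_popup:medication")
  solo <- build_coach_report(list(u9 = "well"), list(), c(u9 = 7))
  expect_identical(nrow(solo), 1L)
  expect_false(solo$flagged)
})
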