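#' Read and write engine input/output files
#'
#' Plain-text interchange formats: `checkins.csv` (one row per daily
#' check-in: `user_id,date,medication,sleep_hours,bedtime,risetime,wellness`),
#' `weekly.csv` (`user_id,date,phq8_1..8,asrm_1..5`), `symptoms.csv`
#' (per-day symptom severities for the DSM-IV/CMF machine), `profile.json`,
#' `rules.json`, and `corpus.json`. Readers validate on load, so schema
#' violations fail before any engine step runs.
#'
#' @param path file path.
#' @return the parsed, validated object.
#' @name livewell_io
NULL

#' @rdname livewell_io
#' @export
read_checkins <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_checkins(df)
}

#' @rdname livewell_io
#' @param checkins validated check-in data frame.
#' @export
write_checkins <- function(checkins, path) {
  utils::write.csv(checkins, path, row.names = FALSE)
  invisible(path)
}

#' @rdname livewell_io
#' @export
read_weekly <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  item_cols <- c(paste0("phq8_", 1:8), paste0("asrm_", 1:5))
  missing <- setdiff(c("date", item_cols), names(df))
  if (length(missing))
    stop("weekly check-in file missing column(s): ",
         paste(missing, collapse = ", "))
  totals <- lapply(seq_len(nrow(df)), function(i)
    score_weekly(unlist(df[i, paste0("phq8_", 1:8)]),
                 unlist(df[i, paste0("asrm_", 1:5)])))
  df$phq8_total <- vapply(totals, `[[`, 0, "phq8_total")
  df$asrm_total <- vapply(totals, `[[`, 0, "asrm_total")
  df$date <- as.Date(df$date)
  df[order(df$date), , drop = FALSE]
}

#' @rdname livewell_io
#' @param weekly weekly check-in data frame.
#' @export
write_weekly <- function(weekly, path) {
  drop <- intersect(c("phq8_total", "asrm_total"), names(weekly))
  utils::write.csv(weekly[, setdiff(names(weekly), drop)], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname livewell_io
#' @export
read_corpus <- function(path) {
  corpus <- jsonlite::read_json(path, simplifyVector = TRUE)
  corpus <- as.data.frame(corpus, stringsAsFactors = FALSE)
  if (!"next_id" %in% names(corpus)) corpus$next_id <- NA_character_
  if (!"position" %in% names(corpus)) corpus$position <- NA_integer_
  for (col in c("page_id", "category", "role", "next_id", "target",
                "determinant"))
    corpus[[col]] <- as.character(corpus[[col]])
  if ("choices" %in% names(corpus))
    corpus$choices <- as.character(corpus$choices)
  for (col in c("position", "variant", "tier"))
    corpus[[col]] <- as.integer(corpus[[col]])
  validate_corpus(corpus)
  corpus
}

#' @rdname livewell_io
#' @param corpus validated corpus data frame.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  jsonlite::write_json(corpus, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Convert a symptom table to symptom-day records
#'
#' Expects columns `date`, `dep_1..dep_9`, `man_1..man_7`, `mood_depressed`,
#' `mood_elevated`, `mood_irritable`, `impairment`, `hospitalized`,
#' `psychosis` (missing flag columns default to `FALSE`/`"none"`).
#'
#' @param df symptom data frame.
#' @return list of [symptom_day()] records, date-sorted.
#' @export
as_symptom_days <- function(df) {
  df <- df[order(as.Date(df$date)), , drop = FALSE]
  dep_cols <- grep("^dep_", names(df), value = TRUE)
  man_cols <- grep("^man_", names(df), value = TRUE)
  get <- function(col, i, default) {
    if (col %in% names(df)) df[[col]][i] else default
  }
  lapply(seq_len(nrow(df)), function(i) {
    symptom_day(
      date = df$date[i],
      depression = as.numeric(df[i, dep_cols]),
      mania = as.numeric(df[i, man_cols]),
      mood_depressed = isTRUE(as.logical(get("mood_depressed", i, FALSE))),
      mood_elevated = isTRUE(as.logical(get("mood_elevated", i, FALSE))),
      mood_irritable = isTRUE(as.logical(get("mood_irritable", i, FALSE))),
      impairment = as.character(get("impairment", i, "none")),
      hospitalized = isTRUE(as.logical(get("hospitalized", i, FALSE))),
      psychosis = isTRUE(as.logical(get("psychosis", i, FALSE))))
  })
}

#' @rdname livewell_io
#' @export
read_symptoms <- function(path) {
  as_symptom_days(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname livewell_io
#' @param days list of [symptom_day()] records.
#' @export
write_symptoms <- function(days, path) {
  rows <- lapply(days, function(d) {
    row <- data.frame(date = as.character(d$date))
    for (j in seq_along(d$depression)) row[[paste0("dep_", j)]] <- d$depression[j]
    for (j in seq_along(d$mania)) row[[paste0("man_", j)]] <- d$mania[j]
    row$mood_depressed <- d$mood_depressed
    row$mood_elevated <- d$mood_elevated
    row$mood_irritable <- d$mood_irritable
    row$impairment <- d$impairment
    row$hospitalized <- d$hospitalized
    row$psychosis <- d$psychosis
    row
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Serialize alert events to JSON lines
#'
#' One JSON object per line (an outbox; delivery is an integrator concern).
#'
#' @param alerts list of `livewell_alert` events.
#' @param path output file.
#' @export
write_alerts <- function(alerts, path) {
  lines <- vapply(alerts, function(a) {
    a$date <- as.character(a$date)
    jsonlite::toJSON(unclass(a), auto_unbox = TRUE, digits = NA, null = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_alerts
#' @export
read_alerts <- function(path) {
  lapply(readLines(path), function(line) {
    a <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    alert_event(a$kind, a$trigger, a$date, as.list(a$payload), a$callto,
                a$user_id)
  })
}

md5_of <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(object, auto_unbox = TRUE, digits = NA,
                              force = TRUE, na = "null"), f)
  unname(tools::md5sum(f))
}

#' Run the full engine over a date range
#'
#' Chronological replay for one user: for every completed daily check-in (in
#' date order) the engine updates the clinical status, selects the
#' daily-review content category, assembles the randomized review pages,
#' and evaluates the daily reach-out rules; on weekly check-in dates it
#' evaluates the weekly reach-out rules; every day it evaluates the
#' adherence flags. No adaptive content is produced on days without a
#' completed check-in. The run is reproducible: the same inputs and seed
#' give identical outputs, attested by the run manifest's digests.
#'
#' @param checkins validated daily check-in data frame.
#' @param weekly weekly check-in data frame (may be `NULL`).
#' @param profile a [user_profile()].
#' @param corpus a content corpus (default [generate_corpus()]).
#' @param config a [rule_config()].
#' @param seed integer seed driving all review-page randomization.
#' @return A list of class `livewell_run`:
#'   `status` (per-check-in status timeline), `decisions` (per-check-in
#'   category decisions), `reviews` (named list of assembled page
#'   sequences), `alerts` (list of `livewell_alert` events), `report`
#'   (final-day coach report), `manifest` (config/input digests, seed,
#'   engine version, per-day event counts).
#' @examples
#' spec <- trajectory_spec("stable_well", length_days = 14, noise = 0)
#' run <- run_range(generate_trajectory(spec))
#' run$decisions$category
#' @export
run_range <- function(checkins, weekly = NULL, profile = user_profile(),
                      corpus = generate_corpus(), config = rule_config(),
                      seed = 1L) {
  if (nrow(checkins) == 0L) {
    empty <- data.frame()
    return(structure(list(status = empty, decisions = empty,
                          reviews = list(), alerts = list(), report = empty,
                          manifest = list(seed = seed, n_days = 0L)),
                     class = "livewell_run"))
  }
  checkins <- checkins[order(as.Date(checkins$date)), , drop = FALSE]
  dates <- as.Date(checkins$date)
  current <- clinical_status_record(profile$initial_status, dates[1] - 1)
  alerts <- list()
  last_fired <- list()
  tier2_dates <- as.Date(character())
  decisions <- NULL
  reviews <- list()
  status_rows <- NULL
  weekly_sorted <- if (!is.null(weekly) && nrow(weekly))
    weekly[order(as.Date(weekly$date)), , drop = FALSE] else NULL
  prev_weekly <- NULL; weekly_idx <- 1L
  for (i in seq_len(nrow(checkins))) {
    today <- checkins[i, , drop = FALSE]
    date <- dates[i]
    win7 <- checkins[dates <= date, , drop = FALSE]
    win7 <- utils::tail(win7, config$status_window)
    before <- current$status
    nxt <- update_status(current, win7$wellness, config, date = date)
    fired <- !identical(nxt$status, current$status)
    current <- nxt
    status_rows <- rbind(status_rows, data.frame(
      date = date, wellness = today$wellness, status_before = before,
      status = current$status,
      triggering_rule = if (fired) as.integer(current$triggering_rule)
                        else NA_integer_))
    recent2 <- any(tier2_dates > date - config$risk_lookback_days)
    win4 <- utils::tail(win7, config$target_window)
    decision <- select_category(current$status, today, win4, profile, config,
                                recent_tier2 = recent2)
    if (decision$tier >= 2L) tier2_dates <- c(tier2_dates, date)
    decisions <- rbind(decisions, data.frame(
      date = date, category = decision$category, tier = decision$tier,
      direction = decision$direction))
    feedback <- goal_feedback(win7, profile)
    reviews[[as.character(date)]] <-
      assemble_review(decision, corpus, feedback, seed = seed + i)
    day_alerts <- evaluate_daily_reachout(decision, before, current$status,
                                          win7, profile, config, date,
                                          last_fired)
    for (a in day_alerts)
      if (a$kind == "user_popup") last_fired[[a$trigger]] <- date
    # weekly check-ins due on or before this date
    while (!is.null(weekly_sorted) && weekly_idx <= nrow(weekly_sorted) &&
           as.Date(weekly_sorted$date[weekly_idx]) <= date) {
      wk <- weekly_sorted[weekly_idx, , drop = FALSE]
      day_alerts <- c(day_alerts,
                      evaluate_weekly_reachout(wk, prev_weekly, profile,
                                               config))
      prev_weekly <- wk
      weekly_idx <- weekly_idx + 1L
    }
    weekly_dates <- if (is.null(weekly_sorted)) as.Date(character())
                    else as.Date(weekly_sorted$date[seq_len(weekly_idx - 1L)])
    # adherence is only assessable once a full 7-day window has elapsed
    if (date - dates[1] >= 6)
      day_alerts <- c(day_alerts,
                      adherence_flags(dates[dates <= date], weekly_dates, date,
                                      profile, config))
    alerts <- c(alerts, day_alerts)
  }
  final_date <- dates[length(dates)]
  adherence <- stats::setNames(sum(dates > final_date - 7), profile$user_id)
  final_alerts <- Filter(function(a) a$date == final_date, alerts)
  report <- build_coach_report(
    stats::setNames(list(current$status), profile$user_id),
    final_alerts, adherence, date = final_date)
  alert_days <- vapply(alerts, function(a) as.character(a$date), "")
  manifest <- list(
    engine_version = as.character(utils::packageVersion("livewell")),
    seed = seed,
    config_md5 = md5_of(unclass(config)),
    checkins_md5 = md5_of(lapply(checkins, as.character)),
    weekly_md5 = if (is.null(weekly_sorted)) NA_character_
                 else md5_of(lapply(weekly_sorted, as.character)),
    profile_md5 = md5_of(unclass(profile)),
    n_days = nrow(checkins),
    n_alerts = length(alerts),
    alerts_per_day = if (length(alert_days)) table(alert_days) else NULL)
  structure(list(status = status_rows, decisions = decisions,
                 reviews = reviews, alerts = alerts, report = report,
                 manifest = manifest),
            class = "livewell_run")
}

#' @export
print.livewell_run <- function(x, ...) {
  cat("LiveWell engine run:", x$manifest$n_days, "check-in days,",
      length(x$alerts), "alert events\n")
  if (nrow(x$status)) {
    cat("  final status:", x$status$status[nrow(x$status)], "\n")
    cat("  categories delivered:",
        length(unique(x$decisions$category)), "distinct\n")
  }
  invisible(x)
}
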