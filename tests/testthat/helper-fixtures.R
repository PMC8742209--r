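# shared fixtures and independent oracles, built in code at test time

# a block of daily check-ins with given wellness ratings (newest last)
make_checkins <- function(wellness, medication = "all", sleep_hours = 7,
                          bedtime = "23:00", risetime = "07:00",
                          start = as.Date("2021-03-01")) {
  n <- length(wellness)
  data.frame(date = start + seq_len(n) - 1L,
             medication = rep_len(medication, n),
             sleep_hours = rep_len(sleep_hours, n),
             bedtime = rep_len(bedtime, n),
             risetime = rep_len(risetime, n),
             wellness = as.integer(wellness), stringsAsFactors = FALSE)
}

# independent table-driven evaluator of the four-state transition rules,
# written directly from the published rule table (first matching row wins)
oracle_livewell <- function(status, ratings) {
  a <- abs(ratings)
  rules <- list(
    list(from = "well",       to = "prodromal", count = sum(a >= 2), min = 4),
    list(from = "prodromal",  to = "well",      count = sum(a <= 1), min = 5),
    list(from = "recovering", to = "well",      count = sum(a <= 1), min = 5),
    list(from = "prodromal",  to = "unwell",    count = sum(a >= 3), min = 5),
    list(from = "recovering", to = "unwell",    count = sum(a >= 3), min = 5),
    list(from = "unwell",     to = "recovering", count = sum(a <= 2), min = 5))
  for (r in rules) if (status == r$from && r$count >= r$min) return(r$to)
  status
}

# shorthand symptom-day builders
dep_day <- function(date, k = 5, impairment = "moderate", gate = TRUE, ...) {
  symptom_day(date, depression = c(rep(1, k), rep(0, 9 - k)),
              mood_depressed = gate, impairment = impairment, ...)
}
man_day <- function(date, k = 3, impairment = "moderate", elevated = TRUE,
                    irritable = FALSE, ...) {
  symptom_day(date, mania = c(rep(1, k), rep(0, 7 - k)),
              mood_elevated = elevated, mood_irritable = irritable,
              impairment = impairment, ...)
}
low_day_fixture <- function(date, count = 1) {
  symptom_day(date, depression = c(rep(1, count), rep(0, 9 - count)))
}
zero_day_fixture <- function(date) symptom_day(date)

# independent brute-force scan for depressive episode entry: does any
# 14-calendar-day window ending on the last observed day contain >= 10
# qualifying days? (qualifying = >= 5 moderate depression symptoms with
# depressed-mood gate and >= moderate impairment)
oracle_depression_entry <- function(days) {
  qual <- vapply(days, function(d) {
    d$mood_depressed && sum(d$depression >= 1) >= 5 &&
      match(d$impairment, c("none", "mild", "moderate", "marked", "severe")) >= 3
  }, TRUE)
  dates <- as.Date(vapply(days, function(d) as.character(d$date), ""))
  end <- dates[length(dates)]
  sum(qual[dates >= end - 13 & dates <= end]) >= 10
}

# fully independent episode-entry evaluator: expands the stream onto a
# calendar grid, recomputes day flags inline, and scans runs/windows with
# vector arithmetic rather than the package's recursion
oracle_episode_entry <- function(days) {
  dates <- as.Date(vapply(days, function(d) as.character(d$date), ""))
  grid <- seq(min(dates), max(dates), by = "day")
  at <- match(grid, dates)
  imp <- function(d) match(d$impairment,
                           c("none", "mild", "moderate", "marked", "severe"))
  flag <- function(f) {
    v <- rep(FALSE, length(grid))
    v[!is.na(at)] <- vapply(days[at[!is.na(at)]], f, TRUE)
    v
  }
  man_sym <- flag(function(d) {
    k <- sum(d$mania >= 1)
    (d$mood_elevated && k >= 3) || (d$mood_irritable && !d$mood_elevated && k >= 4)
  })
  sev <- flag(function(d) imp(d) >= 3 || d$hospitalized || d$psychosis)
  modimp <- flag(function(d) imp(d) >= 3)
  hosp <- flag(function(d) d$hospitalized)
  nohosp_psy <- flag(function(d) !d$hospitalized && !d$psychosis)
  dep3 <- flag(function(d) sum(d$depression >= 1) >= 3)
  depq <- flag(function(d) d$mood_depressed && sum(d$depression >= 1) >= 5 &&
                 imp(d) >= 3)
  n <- length(grid)
  trail <- function(v) { r <- 0L; i <- n; while (i >= 1 && v[i]) { r <- r + 1L; i <- i - 1L }; r }
  last <- function(v, w) sum(v[max(1, n - w + 1):n])
  if (trail(man_sym & modimp) >= 7 && last(dep3, 7) >= 5)
    return("mixed")
  if (trail(man_sym & sev) >= 7 || (man_sym[n] && sev[n] && hosp[n]))
    return("mania")
  if (last(depq, 14) >= 10) return("depression")
  if (trail(man_sym & !modimp & nohosp_psy) >= 4) return("hypomania")
  NULL
}
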