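#' The nine DSM-IV/CMF clinical states
#'
#' The assessor-side state machine distinguishes four episode states
#' (depression, mania, hypomania, mixed) and five non-episode states
#' (continued symptomatic, prodromal, recovering, symptomatic recovery,
#' asymptomatic recovery). "Recovery" is an umbrella condition covering the
#' symptomatic/asymptomatic recovery states (and prodromal, which is entered
#' only from recovery); it is reached from `recovering` after more than 56
#' consecutive low-symptom days.
#'
#' @return character vector of the nine state names.
#' @export
dsmcmf_states <- function() {
  c("depression", "mania", "hypomania", "mixed",
    "continued_symptomatic", "prodromal", "recovering",
    "symptomatic_recovery", "asymptomatic_recovery")
}

dsmcmf_episodes <- function() c("depression", "mania", "hypomania", "mixed")
dsmcmf_recovery_umbrella <- function() {
  c("symptomatic_recovery", "asymptomatic_recovery")
}

#' Admissible PSR values per DSM-IV/CMF status
#'
#' Psychiatric status ratings: 1 no symptoms, 1.5 mild, 2 residual/prodromal,
#' 3 moderate, 4 marked, 5 episode, 6 severe episode.
#'
#' @param status a DSM-IV/CMF state name.
#' @return numeric vector of PSR values admissible for that status.
#' @export
psr_range <- function(status) {
  switch(match.arg(status, dsmcmf_states()),
         depression = , mania = , mixed = c(5, 6),
         hypomania = 3,
         continued_symptomatic = c(3, 4),
         prodromal = c(2, 3, 4),
         recovering = c(1, 1.5, 2),
         symptomatic_recovery = 2,
         asymptomatic_recovery = c(1, 1.5))
}

#' DSM-IV/CMF status record
#'
#' @param status one of [dsmcmf_states()].
#' @param psr psychiatric status rating consistent with `status`.
#' @param effective_date date the status took effect.
#' @param triggering_rule decision number 1..10, or `"initial"`.
#' @param baseline_symptoms logical vector marking which symptoms were at
#'   moderate+ severity when the recovery umbrella was entered; used by the
#'   "new symptoms" clause of the prodromal rule.
#' @return A list of class `livewell_dsmcmf_status`.
#' @export
dsmcmf_status_record <- function(status, psr = NULL,
                                 effective_date = Sys.Date(),
                                 triggering_rule = "initial",
                                 baseline_symptoms = NULL) {
  status <- match.arg(status, dsmcmf_states())
  if (is.null(psr)) psr <- min(psr_range(status))
  if (!psr %in% psr_range(status))
    stop("PSR ", psr, " not admissible for status ", status)
  structure(list(status = status, psr = psr,
                 effective_date = as.Date(effective_date),
                 triggering_rule = as.character(triggering_rule),
                 baseline_symptoms = baseline_symptoms),
            class = "livewell_dsmcmf_status")
}

#' @export
print.livewell_dsmcmf_status <- function(x, ...) {
  cat("DSM-IV/CMF status:", x$status, "(PSR", paste0(x$psr, ")"),
      "since", format(x$effective_date),
      "(rule", paste0(x$triggering_rule, ")"), "\n")
  invisible(x)
}

# ---- per-day predicates ----------------------------------------------------

# mania symptom criteria: >= 3 moderate mania symptoms with elevated/expansive
# mood, or >= 4 with irritable mood only (gate itself at moderate+)
mania_symptoms_met <- function(day, config) {
  cnt <- symptom_count(day$mania)
  (day$mood_elevated && cnt >= config$mania_symptoms_elevated) ||
    (day$mood_irritable && !day$mood_elevated &&
       cnt >= config$mania_symptoms_irritable)
}

impaired_at_least <- function(day, level) {
  impairment_rank(day$impairment) >= impairment_rank(level)
}

# a day qualifying toward a manic episode (DN5): symptoms + severity context
mania_day <- function(day, config) {
  mania_symptoms_met(day, config) &&
    (impaired_at_least(day, "moderate") || day$hospitalized || day$psychosis)
}

# a day qualifying toward a hypomanic episode (DN4)
hypomania_day <- function(day, config) {
  mania_symptoms_met(day, config) &&
    !impaired_at_least(day, "moderate") && !day$hospitalized && !day$psychosis
}

# a day qualifying toward a depressive episode (DN7)
depression_day <- function(day, config) {
  day$mood_depressed &&
    symptom_count(day$depression) >= config$depression_symptoms &&
    impaired_at_least(day, "moderate")
}

# a day qualifying toward a mixed episode (DN6): mania criteria at >= moderate
# impairment (concurrent depressive symptoms handled over the 7-day window)
mixed_day <- function(day, config) {
  mania_symptoms_met(day, config) && impaired_at_least(day, "moderate")
}

episode_day <- function(day, status, config) {
  switch(status,
         mania = mania_day(day, config),
         mixed = mixed_day(day, config),
         depression = depression_day(day, config),
         hypomania = hypomania_day(day, config))
}

# ---- window arithmetic -----------------------------------------------------

# length of the run of consecutive calendar days ending at index t for which
# pred is TRUE; a date gap (unobserved day) breaks the run
trailing_run <- function(days, pred, t = length(days)) {
  run <- 0L
  i <- t
  while (i >= 1L && pred(days[[i]])) {
    run <- run + 1L
    if (i > 1L && days[[i]]$date - days[[i - 1L]]$date != 1) break
    i <- i - 1L
  }
  run
}

# number of observed days satisfying pred within the `width` calendar days
# ending at days[[t]]$date
days_in_window <- function(days, pred, width, t = length(days)) {
  end <- days[[t]]$date
  start <- end - width + 1
  n <- 0L
  for (i in seq_len(t)) {
    if (days[[i]]$date >= start && days[[i]]$date <= end && pred(days[[i]]))
      n <- n + 1L
  }
  n
}

# ---- episode entry (Table 1) -----------------------------------------------

#' Check DSM-IV/CMF episode entry
#'
#' Scans the episode entry rules against the end of a date-ordered symptom
#' stream. Mixed is checked before mania because a mixed presentation also
#' satisfies the mania criteria; after that the scan runs in severity order:
#'
#' * DN6 mixed: the mania criteria at moderate+ impairment for >= 7
#'   consecutive days with concurrent depressive symptoms (symptom count
#'   >= 3) on >= 5 of the last 7 days.
#' * DN5 mania: qualifying mania days (>= 3 moderate mania symptoms if mood
#'   elevated / >= 4 if only irritable; moderate+ impairment, hospitalization,
#'   or psychosis) on >= 7 consecutive days -- or hospitalization on a
#'   qualifying day.
#' * DN7 depression: >= 5 moderate depression symptoms with depressed-mood
#'   gate and moderate+ impairment on >= 10 of the last 14 consecutive days.
#' * DN4 hypomania: the mania symptom criteria at sub-moderate impairment,
#'   no hospitalization, no psychosis, >= 4 consecutive days.
#'
#' @param days list of [symptom_day()] records, dates strictly increasing.
#' @param config a [rule_config()].
#' @return `NULL` when no rule fires, else a list with `status`,
#'   `decision_number`, and `psr` (5, or 6 when the evaluation day shows
#'   hospitalization, psychosis, or severe impairment; hypomania is PSR 3).
#' @export
check_episode_entry <- function(days, config = rule_config()) {
  if (!length(days)) stop("empty symptom stream")
  t <- length(days)
  today <- days[[t]]
  episode_psr <- function() {
    if (today$hospitalized || today$psychosis ||
        impaired_at_least(today, "severe")) 6 else 5
  }
  # DN6 mixed -- checked before plain mania: a mixed presentation also
  # satisfies the mania criteria, so the more specific rule must win
  if (trailing_run(days, function(d) mixed_day(d, config)) >= config$mixed_days &&
      days_in_window(days,
                     function(d) symptom_count(d$depression) >=
                       config$mixed_depression_count,
                     config$mixed_depression_window) >=
        config$mixed_depression_days)
    return(list(status = "mixed", decision_number = 6L, psr = episode_psr()))
  # DN5 mania
  if (trailing_run(days, function(d) mania_day(d, config)) >= config$mania_days ||
      (mania_day(today, config) && today$hospitalized))
    return(list(status = "mania", decision_number = 5L, psr = episode_psr()))
  # DN7 depression
  if (days_in_window(days, function(d) depression_day(d, config),
                     config$depression_window) >= config$depression_days)
    return(list(status = "depression", decision_number = 7L,
                psr = episode_psr()))
  # DN4 hypomania
  if (trailing_run(days, function(d) hypomania_day(d, config)) >=
      config$hypomania_days)
    return(list(status = "hypomania", decision_number = 4L, psr = 3))
  NULL
}

# ---- non-episode statuses (Table 2) ----------------------------------------

high_day <- function(day, config) {
  symptom_count(day) > config$symptom_count_max ||
    impaired_at_least(day, "moderate")
}
low_day <- function(day, config) {
  symptom_count(day) <= config$symptom_count_max &&
    !impaired_at_least(day, "moderate")
}
symptomatic_low_day <- function(day, config) {
  cnt <- symptom_count(day)
  cnt > 0L && cnt <= config$symptom_count_max &&
    !impaired_at_least(day, "moderate")
}
zero_day <- function(day, config) {
  symptom_count(day) == 0L && !impaired_at_least(day, "moderate")
}

moderate_plus_symptoms <- function(day) {
  c(day$depression, day$mania) >= 1
}

# "new" clause of the prodromal rule: >= 2 symptoms at moderate+ severity that
# were not moderate+ when the recovery umbrella was entered
new_symptoms_day <- function(day, baseline, config) {
  if (is.null(baseline)) baseline <- rep(FALSE, length(moderate_plus_symptoms(day)))
  now <- moderate_plus_symptoms(day)
  if (length(baseline) != length(now)) return(FALSE)
  sum(now & !baseline) >= config$prodromal_new_symptoms
}

nonepisode_psr <- function(status, today, config) {
  cnt <- symptom_count(today)
  sev_max <- max(c(today$depression, today$mania, 0))
  switch(status,
    continued_symptomatic =
      if (sev_max >= 1.5 || impaired_at_least(today, "marked")) 4 else 3,
    prodromal =
      if (impaired_at_least(today, "marked") || cnt > 4) 4
      else if (cnt > config$symptom_count_max ||
               impaired_at_least(today, "moderate")) 3 else 2,
    recovering = if (cnt >= 1) 2 else if (sev_max > 0) 1.5 else 1,
    symptomatic_recovery = 2,
    asymptomatic_recovery = if (sev_max > 0) 1.5 else 1)
}

#' Check CMF non-episode status rules
#'
#' Applies the non-episode decision rules to the end of a symptom stream,
#' given the current (non-episode or just-exited-episode) status. Rules are
#' scanned in the order DN8, DN1, DN9, DN10, DN3, DN2, gated by from-state:
#'
#' * DN8 continued symptomatic (from an exited episode or recovering):
#'   symptom count > 2 or moderate+ impairment on >= 7 consecutive days.
#' * DN1 prodromal (from symptomatic/asymptomatic recovery): symptom count
#'   > 2, or >= 2 new moderate+ symptoms relative to recovery entry, or
#'   moderate+ impairment, on >= 7 consecutive days.
#' * DN9 recovering (from an exited episode or continued symptomatic):
#'   symptom count <= 2 and sub-moderate impairment on >= 7 and <= 56
#'   consecutive days.
#' * DN10 recovery (from recovering): the same low-symptom condition on > 56
#'   consecutive days; the destination is classified as asymptomatic recovery
#'   when the last 7 days were symptom-free, else symptomatic recovery.
#' * DN3 symptomatic recovery (from prodromal only -- not from recovering):
#'   symptom count in 1..2 and sub-moderate impairment, >= 7 consecutive days.
#' * DN2 asymptomatic recovery (from prodromal or symptomatic recovery --
#'   not from recovering): symptom count 0 and sub-moderate impairment,
#'   >= 7 consecutive days.
#'
#' @param days list of [symptom_day()] records, dates strictly increasing.
#' @param current_status the current state name, or `"episode_exit"` for a
#'   just-exited episode.
#' @param config a [rule_config()].
#' @param baseline_symptoms logical vector of moderate+ symptoms at recovery
#'   entry (for the "new symptoms" clause); `NULL` means none.
#' @return `NULL` when no rule fires, else a list with `status`,
#'   `decision_number`, and `psr`.
#' @export
check_nonepisode_status <- function(days, current_status,
                                    config = rule_config(),
                                    baseline_symptoms = NULL) {
  if (!length(days)) stop("empty symptom stream")
  t <- length(days)
  today <- days[[t]]
  w <- config$cmf_window_days
  from_exit <- identical(current_status, "episode_exit")
  res <- function(status, dn) {
    list(status = status, decision_number = dn,
         psr = nonepisode_psr(status, today, config))
  }
  high_run <- trailing_run(days, function(d) high_day(d, config))
  low_run <- trailing_run(days, function(d) low_day(d, config))
  # DN8: continued symptomatic, from non-recovery states
  if ((from_exit || current_status == "recovering") && high_run >= w)
    return(res("continued_symptomatic", 8L))
  # DN1: prodromal, from the recovery umbrella
  if (current_status %in% dsmcmf_recovery_umbrella()) {
    new_run <- trailing_run(days, function(d)
      high_day(d, config) || new_symptoms_day(d, baseline_symptoms, config))
    if (new_run >= w) return(res("prodromal", 1L))
  }
  # DN9: recovering, from exited episode or continued symptomatic
  if ((from_exit || current_status == "continued_symptomatic") &&
      low_run >= w && low_run <= config$recovery_days)
    return(res("recovering", 9L))
  # DN10: recovery, from recovering only
  if (identical(current_status, "recovering") && low_run > config$recovery_days) {
    zero_run <- trailing_run(days, function(d) zero_day(d, config))
    status <- if (zero_run >= w) "asymptomatic_recovery" else "symptomatic_recovery"
    return(list(status = status, decision_number = 10L,
                psr = nonepisode_psr(status, today, config)))
  }
  # DN3: symptomatic recovery, from prodromal (note: never from recovering)
  if (identical(current_status, "prodromal") &&
      trailing_run(days, function(d) symptomatic_low_day(d, config)) >= w)
    return(res("symptomatic_recovery", 3L))
  # DN2: asymptomatic recovery, from prodromal or symptomatic recovery
  if (current_status %in% c("prodromal", "symptomatic_recovery") &&
      trailing_run(days, function(d) zero_day(d, config)) >= w)
    return(res("asymptomatic_recovery", 2L))
  NULL
}

# ---- full machine ----------------------------------------------------------

#' Update the DSM-IV/CMF status from a symptom stream
#'
#' Runs one evaluation of the nine-state machine at the end of a symptom
#' stream: episode entry rules take precedence; a current episode persists
#' until its entry-day criteria have been absent for
#' `config$episode_exit_days` consecutive days, after which the non-episode
#' rules are evaluated.
#'
#' @param days list of [symptom_day()] records, dates strictly increasing.
#' @param current a `livewell_dsmcmf_status` record (or state name).
#' @param config a [rule_config()].
#' @return The updated `livewell_dsmcmf_status` record (the input record when
#'   no rule fires).
#' @export
update_dsmcmf <- function(days, current, config = rule_config()) {
  if (!length(days)) stop("empty symptom stream")
  if (is.character(current))
    current <- dsmcmf_status_record(current, effective_date = days[[1]]$date - 1)
  dates <- vapply(days, function(d) as.numeric(d$date), 0)
  if (length(dates) > 1L && any(diff(dates) <= 0))
    stop("symptom stream dates must be strictly increasing")
  t <- length(days)
  today <- days[[t]]
  hit <- check_episode_entry(days, config)
  if (!is.null(hit) && hit$status != current$status) {
    return(dsmcmf_status_record(hit$status, hit$psr, today$date,
                                hit$decision_number))
  }
  if (current$status %in% dsmcmf_episodes()) {
    # episode persists until entry-day criteria absent >= episode_exit_days
    calm <- trailing_run(days, function(d) !episode_day(d, current$status, config))
    if (calm < config$episode_exit_days || !is.null(hit)) return(current)
    from <- "episode_exit"
  } else {
    from <- current$status
  }
  hit <- check_nonepisode_status(days, from, config, current$baseline_symptoms)
  if (is.null(hit) || hit$status == current$status) return(current)
  baseline <- current$baseline_symptoms
  if (hit$status %in% dsmcmf_recovery_umbrella() &&
      !current$status %in% c(dsmcmf_recovery_umbrella(), "prodromal"))
    baseline <- moderate_plus_symptoms(today)  # entering recovery: fix baseline
  dsmcmf_status_record(hit$status, hit$psr, today$date, hit$decision_number,
                       baseline_symptoms = baseline)
}

#' Replay a symptom stream through the DSM-IV/CMF machine
#'
#' Evaluates [update_dsmcmf()] once per day, in date order, and returns the
#' per-date status and PSR timeline.
#'
#' @param days list of [symptom_day()] records (or a data frame as read by
#'   [read_symptoms()]).
#' @param initial_status starting state name (default asymptomatic recovery).
#' @param config a [rule_config()].
#' @return Data frame with one row per day: `date`, `status`, `psr`,
#'   `triggering_rule` (`NA` on days with no transition).
#' @export
dsmcmf_timeline <- function(days, initial_status = "asymptomatic_recovery",
                            config = rule_config()) {
  if (is.data.frame(days)) days <- as_symptom_days(days)
  n <- length(days)
  if (!n) return(data.frame(date = as.Date(character()), status = character(),
                            psr = numeric(), triggering_rule = integer()))
  current <- dsmcmf_status_record(initial_status,
                                  effective_date = days[[1]]$date - 1)
  out <- data.frame(date = as.Date(vapply(days, function(d) as.character(d$date), "")),
                    status = character(n), psr = numeric(n),
                    triggering_rule = rep(NA_integer_, n))
  for (i in seq_len(n)) {
    nxt <- update_dsmcmf(days[seq_len(i)], current, config)
    if (!identical(nxt$status, current$status)) {
      out$triggering_rule[i] <- as.integer(nxt$triggering_rule)
      current <- nxt
    }
    out$status[i] <- current$status
    out$psr[i] <- current$psr
  }
  out
}
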