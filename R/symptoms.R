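#' Impairment levels
#'
#' Functional impairment is rated on a five-level ordinal scale. Helpers map
#' the labels to integer ranks for threshold comparisons.
#'
#' @return character vector of the five levels, least to most impaired.
#' @export
impairment_levels <- function() c("none", "mild", "moderate", "marked", "severe")

impairment_rank <- function(x) {
  r <- match(x, impairment_levels())
  if (anyNA(r)) stop("unknown impairment level: ", paste(x[is.na(r)], collapse = ", "))
  r - 1L  # none = 0 .. severe = 4
}

#' Symptom severity scale
#'
#' Clinical monitoring form (CMF) symptom severities take one of five values:
#' none = 0, mild = 0.5, moderate = 1, marked = 1.5, severe = 2.
#'
#' @return the five admissible severity values.
#' @export
severity_scale <- function() c(0, 0.5, 1, 1.5, 2)

check_severities <- function(x, what = "severity") {
  if (length(x) && !all(x %in% severity_scale()))
    stop(what, " values must be on the CMF scale {0, 0.5, 1, 1.5, 2}")
  as.numeric(x)
}

#' One day of assessor-side symptom data
#'
#' A symptom day records per-symptom CMF severities for depression and mania
#' symptom sets, the episode entry mood gates (depressed mood / loss of
#' interest; elevated or expansive mood; irritable mood -- each at moderate
#' severity or worse), the day's overall impairment level, and hospitalization
#' / psychosis flags.
#'
#' @param date calendar date.
#' @param depression numeric vector of depression symptom severities (the
#'   DSM-IV depression criteria set; default 9 symptoms, all zero).
#' @param mania numeric vector of mania symptom severities (default 7).
#' @param mood_depressed,mood_elevated,mood_irritable episode-entry mood
#'   gates at moderate severity or worse.
#' @param impairment one of [impairment_levels()].
#' @param hospitalized,psychosis logical flags.
#' @return A list of class `livewell_symptom_day`.
#' @export
symptom_day <- function(date,
                        depression = numeric(9), mania = numeric(7),
                        mood_depressed = FALSE, mood_elevated = FALSE,
                        mood_irritable = FALSE,
                        impairment = "none",
                        hospitalized = FALSE, psychosis = FALSE) {
  impairment <- match.arg(impairment, impairment_levels())
  structure(list(
    date = as.Date(date),
    depression = check_severities(depression, "depression severity"),
    mania = check_severities(mania, "mania severity"),
    mood_depressed = isTRUE(mood_depressed),
    mood_elevated = isTRUE(mood_elevated),
    mood_irritable = isTRUE(mood_irritable),
    impairment = impairment,
    hospitalized = isTRUE(hospitalized),
    psychosis = isTRUE(psychosis)
  ), class = "livewell_symptom_day")
}

#' CMF symptom count
#'
#' A symptom contributes to the count only at moderate severity or worse
#' (severity >= 1); milder severities contribute zero. The count is therefore
#' the number of symptoms at moderate, marked, or severe level.
#'
#' @param severities numeric severities on [severity_scale()], or a
#'   `livewell_symptom_day` (counted over both symptom sets).
#' @return integer symptom count.
#' @examples
#' symptom_count(c(0, 0, 0.5, 0.5)) # 0: sub-moderate severities don't count
#' symptom_count(c(1, 1.5, 2))      # 3
#' @export
symptom_count <- function(severities) {
  if (inherits(severities, "livewell_symptom_day"))
    severities <- c(severities$depression, severities$mania)
  severities <- check_severities(severities)
  sum(severities >= 1)
}
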