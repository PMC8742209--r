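#' Daily check-in records
#'
#' A daily check-in is the user's once-per-day self-report: psychiatric
#' medication adherence (`all`, `some`, `none`), sleep duration in hours,
#' routine (bedtime and risetime clock times), and a signed 9-point wellness
#' rating. Wellness anchors: 0 balanced, -1/+1 daily hassles/uplifts, -2/+2
#' early warning or residual symptoms, -3/+3 episode-level symptoms, -4/+4
#' crisis.
#'
#' @param date calendar date (`Date` or ISO-8601 string).
#' @param medication one of `"all"`, `"some"`, `"none"`.
#' @param sleep_hours sleep duration in hours, in `[0, 24]`.
#' @param bedtime,risetime clock times (`"HH:MM"`).
#' @param wellness integer wellness rating in `-4..+4`.
#' @return A one-row data frame of class `livewell_checkin`.
#' @seealso [validate_checkin()] for validating raw records against a user's
#'   existing check-in history.
#' @export
daily_checkin <- function(date, medication, sleep_hours, bedtime, risetime,
                          wellness) {
  validate_checkin(list(date = date, medication = medication,
                        sleep_hours = sleep_hours, bedtime = bedtime,
                        risetime = risetime, wellness = wellness))
}

#' Validate a raw daily check-in record
#'
#' Rejects out-of-range wellness ratings (the scale has exactly 9 admissible
#' integer values, -4..+4), sleep durations outside `[0, 24]` hours, unknown
#' medication levels, unparseable clock times, and duplicate check-ins for a
#' calendar date already present in `existing_dates` (the app allows only one
#' check-in per day).
#'
#' @param raw a named list or one-row data frame with fields `date`,
#'   `medication`, `sleep_hours`, `bedtime`, `risetime`, `wellness`.
#' @param existing_dates dates of this user's already-accepted check-ins.
#' @return The validated one-row `livewell_checkin` data frame, or an error.
#' @examples
#' validate_checkin(list(date = "2021-03-01", medication = "all",
#'                       sleep_hours = 7, bedtime = "23:00",
#'                       risetime = "07:00", wellness = 2))
#' @export
validate_checkin <- function(raw, existing_dates = NULL) {
  need <- c("date", "medication", "sleep_hours", "bedtime", "risetime",
            "wellness")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("check-in missing field(s): ", paste(missing, collapse = ", "))
  date <- as.Date(raw$date)
  if (length(date) != 1L || is.na(date)) stop("invalid check-in date")
  if (!is.null(existing_dates) && date %in% as.Date(existing_dates))
    stop("duplicate check-in: a check-in for ", format(date),
         " already exists (only 1 check-in per day)")
  medication <- as.character(raw$medication)
  if (!medication %in% c("all", "some", "none"))
    stop("medication must be one of all/some/none, got: ", medication)
  sleep_hours <- as.numeric(raw$sleep_hours)
  if (is.na(sleep_hours) || sleep_hours < 0 || sleep_hours > 24)
    stop("sleep_hours must lie in [0, 24], got: ", raw$sleep_hours)
  wellness <- suppressWarnings(as.numeric(raw$wellness))
  if (is.na(wellness) || wellness != round(wellness) ||
      wellness < -4 || wellness > 4)
    stop("wellness rating must be an integer in -4..+4, got: ", raw$wellness)
  bed <- format_clock(parse_clock(raw$bedtime))
  rise <- format_clock(parse_clock(raw$risetime))
  out <- data.frame(date = date, medication = medication,
                    sleep_hours = sleep_hours, bedtime = bed,
                    risetime = rise, wellness = as.integer(wellness),
                    stringsAsFactors = FALSE)
  class(out) <- c("livewell_checkin", class(out))
  out
}

#' Validate a table of daily check-ins
#'
#' Runs [validate_checkin()] row by row in date order, enforcing the
#' one-check-in-per-day rule across the table.
#'
#' @param df data frame with the check-in columns (and optionally `user_id`).
#' @return the validated data frame, date-sorted, with `Date` dates.
#' @export
validate_checkins <- function(df) {
  if (nrow(df) == 0L) {
    df$date <- as.Date(df$date)
    return(df)
  }
  df <- df[order(as.Date(df$date)), , drop = FALSE]
  split_by <- if ("user_id" %in% names(df)) df$user_id else rep(1L, nrow(df))
  parts <- lapply(split(df, split_by), function(d) {
    seen <- as.Date(character())
    for (i in seq_len(nrow(d))) {
      validate_checkin(d[i, , drop = FALSE], existing_dates = seen)
      seen <- c(seen, as.Date(d$date[i]))
    }
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out$date <- as.Date(out$date)
  key <- if ("user_id" %in% names(out)) order(out$user_id, out$date) else order(out$date)
  out[key, , drop = FALSE]
}

#' Weekly check-in scoring (PHQ-8 and ASRM)
#'
#' The weekly check-in administers the 8-item Patient Health Questionnaire
#' (items scored 0--3, total 0--24) and the 5-item Altman Self-Rating Mania
#' scale (items 0--4, total 0--20). Totals are plain item sums.
#'
#' @param date calendar date of the weekly check-in.
#' @param phq8_items integer vector of 8 PHQ-8 item scores, each 0..3.
#' @param asrm_items integer vector of 5 ASRM item scores, each 0..4.
#' @return `weekly_checkin()`: a one-row data frame with item columns plus
#'   `phq8_total` and `asrm_total`. `score_weekly()`: a named list with the
#'   two totals.
#' @examples
#' score_weekly(phq8_items = c(1, 2, 0, 3, 1, 0, 2, 1),
#'              asrm_items = c(0, 1, 0, 0, 0))
#' @export
weekly_checkin <- function(date, phq8_items, asrm_items) {
  totals <- score_weekly(phq8_items, asrm_items)
  out <- data.frame(date = as.Date(date), t(phq8_items), t(asrm_items),
                    phq8_total = totals$phq8_total,
                    asrm_total = totals$asrm_total)
  names(out)[2:14] <- c(paste0("phq8_", 1:8), paste0("asrm_", 1:5))
  class(out) <- c("livewell_weekly", class(out))
  out
}

#' @rdname weekly_checkin
#' @export
score_weekly <- function(phq8_items, asrm_items) {
  phq8_items <- as.integer(phq8_items)
  asrm_items <- as.integer(asrm_items)
  if (length(phq8_items) != 8L || anyNA(phq8_items))
    stop("PHQ-8 requires exactly 8 item scores")
  if (any(phq8_items < 0L | phq8_items > 3L))
    stop("PHQ-8 item scores must lie in 0..3")
  if (length(asrm_items) != 5L || anyNA(asrm_items))
    stop("ASRM requires exactly 5 item scores")
  if (any(asrm_items < 0L | asrm_items > 4L))
    stop("ASRM item scores must lie in 0..4")
  list(phq8_total = sum(phq8_items), asrm_total = sum(asrm_items))
}
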