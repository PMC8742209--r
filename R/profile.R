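#' User profile
#'
#' Personalization set up with the coach at intake: the sleep-duration goal
#' range, the 1.5-hour bedtime and risetime windows, the preferred first
#' notification time, the coach-assigned initial clinical status, and
#' provider contact details used by reach-out alerts.
#'
#' @param user_id opaque user identifier.
#' @param sleep_goal_low,sleep_goal_high personalized sleep goal bounds, hours.
#' @param bedtime_window_start,risetime_window_start window starts (`"HH:MM"`).
#' @param window_width_hours width of both routine windows, hours.
#' @param notify_time preferred first daily notification time (`"HH:MM"`).
#' @param initial_status coach-set initial clinical status, one of
#'   `"well"`, `"prodromal"`, `"unwell"`, `"recovering"`.
#' @param psychiatrist_phone phone number placed on reach-out pop-ups.
#' @param coach_email,provider_emails alert e-mail recipients.
#' @return A list of class `livewell_profile`.
#' @export
user_profile <- function(user_id = "user",
                         sleep_goal_low = 6, sleep_goal_high = 8,
                         bedtime_window_start = "22:30",
                         risetime_window_start = "07:00",
                         window_width_hours = 1.5,
                         notify_time = "09:00",
                         initial_status = "well",
                         psychiatrist_phone = "000-000-0000",
                         coach_email = "coach@example.org",
                         provider_emails = character()) {
  if (!is.numeric(sleep_goal_low) || !is.numeric(sleep_goal_high) ||
      sleep_goal_low >= sleep_goal_high)
    stop("sleep goal bounds must satisfy sleep_goal_low < sleep_goal_high")
  if (!is.numeric(window_width_hours) || window_width_hours <= 0)
    stop("window_width_hours must be positive")
  initial_status <- match.arg(initial_status, livewell_states())
  parse_clock(bedtime_window_start); parse_clock(risetime_window_start)
  parse_clock(notify_time)
  structure(list(
    user_id = as.character(user_id),
    sleep_goal_low = sleep_goal_low, sleep_goal_high = sleep_goal_high,
    bedtime_window_start = bedtime_window_start,
    risetime_window_start = risetime_window_start,
    window_width_hours = window_width_hours,
    notify_time = notify_time,
    initial_status = initial_status,
    psychiatrist_phone = as.character(psychiatrist_phone),
    coach_email = as.character(coach_email),
    provider_emails = as.character(provider_emails)
  ), class = "livewell_profile")
}

#' @export
print.livewell_profile <- function(x, ...) {
  cat("LiveWell user profile:", x$user_id, "\n")
  cat("  sleep goal ", x$sleep_goal_low, "-", x$sleep_goal_high, " h; bedtime ",
      x$bedtime_window_start, "+", x$window_width_hours, "h; risetime ",
      x$risetime_window_start, "+", x$window_width_hours, "h\n", sep = "")
  cat("  initial status:", x$initial_status,
      "| notify:", x$notify_time, "\n")
  invisible(x)
}

#' Read or write a user profile as JSON
#' @param profile a `livewell_profile`.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "livewell_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$provider_emails <- as.character(raw$provider_emails)
  do.call(user_profile, raw)
}
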