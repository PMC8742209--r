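#' Clock-time helpers
#'
#' Clock times are stored as character `"HH:MM"` strings at the interface and
#' converted to minutes since midnight internally. Windows (e.g. a
#' personalized bedtime window) are treated as modular intervals on the
#' 24-hour circle so that windows spanning midnight (22:30--00:00) work.
#'
#' @param x character vector of `"HH:MM"` (or `"HH:MM:SS"`) clock times.
#' @return `parse_clock()` returns integer minutes since midnight in
#'   `[0, 1439]`; `format_clock()` the inverse.
#' @examples
#' parse_clock("23:30")
#' format_clock(90)
#' in_clock_window("23:00", "22:30", 1.5)
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) {
    m <- as.integer(round(x))
  } else {
    parts <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(?::[0-9]{2})?$", x))
    bad <- vapply(parts, length, 1L) == 0L | is.na(x)
    if (any(bad)) stop("unparseable clock time: ", paste(x[bad], collapse = ", "))
    m <- vapply(parts, function(p) as.integer(p[2]) * 60L + as.integer(p[3]), 1L)
  }
  if (any(m < 0L | m > 1439L)) stop("clock time out of range [00:00, 23:59]")
  m
}

#' @rdname parse_clock
#' @param minutes integer minutes since midnight.
#' @export
format_clock <- function(minutes) {
  minutes <- as.integer(minutes) %% 1440L
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

#' @rdname parse_clock
#' @param time clock time to test (string or minutes).
#' @param window_start start of the window (string or minutes).
#' @param width_hours window width in hours (default 1.5).
#' @return `in_clock_window()` returns a logical: is `time` inside the
#'   modular interval `[window_start, window_start + width_hours]`?
#' @export
in_clock_window <- function(time, window_start, width_hours = 1.5) {
  t <- parse_clock(time)
  s <- parse_clock(window_start)
  w <- as.integer(round(width_hours * 60))
  offset <- (t - s) %% 1440L
  offset >= 0L & offset <= w
}
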