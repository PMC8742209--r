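#' The four LiveWell clinical states
#'
#' The app-side state machine tracks four clinical states: `well`,
#' `prodromal`, `unwell`, and `recovering`. It is a deliberately simplified
#' view of the nine-state DSM-IV/CMF machine (see [update_dsmcmf()]),
#' assessable from daily wellness ratings alone.
#'
#' @return character vector of the four state names.
#' @export
livewell_states <- function() c("well", "prodromal", "unwell", "recovering")

#' Clinical status record
#'
#' @param status one of [livewell_states()].
#' @param effective_date date the status took effect.
#' @param triggering_rule decision number 1..4 that set it, or `"initial"`.
#' @return A list of class `livewell_status`.
#' @export
clinical_status_record <- function(status, effective_date = Sys.Date(),
                                   triggering_rule = "initial") {
  status <- match.arg(status, livewell_states())
  structure(list(status = status, effective_date = as.Date(effective_date),
                 triggering_rule = as.character(triggering_rule)),
            class = "livewell_status")
}

#' @export
print.livewell_status <- function(x, ...) {
  cat("Clinical status:", x$status, "since", format(x$effective_date),
      "(rule", paste0(x$triggering_rule, ")"), "\n")
  invisible(x)
}

#' Wellness-rating counts over the assessment window
#'
#' The clinical-status window holds the wellness ratings of the user's last
#' (up to) 7 completed daily check-ins -- count-based, not calendar-based, so
#' missed days shrink nothing; the window simply reaches further back. The
#' four counts feed the four transition rules.
#'
#' @param ratings integer vector of wellness ratings (newest last), length
#'   0..7, values in -4..+4.
#' @return Named integer vector: `n_ge2`, `n_ge3` (check-ins with
#'   `|WR| >= 2`, `>= 3`) and `n_le1`, `n_le2` (`|WR| <= 1`, `<= 2`).
#' @examples
#' wellness_counts(c(2, -2, 2, 2, 0, 0, 1))
#' @export
wellness_counts <- function(ratings) {
  if (length(ratings) > 7L)
    stop("the clinical-status window holds at most 7 check-ins")
  if (length(ratings) && (anyNA(ratings) || any(abs(ratings) > 4) ||
                          any(ratings != round(ratings))))
    stop("wellness ratings must be integers in -4..+4")
  a <- abs(as.integer(ratings))
  c(n_ge2 = sum(a >= 2L), n_ge3 = sum(a >= 3L),
    n_le1 = sum(a <= 1L), n_le2 = sum(a <= 2L))
}

#' Update the LiveWell clinical status after a daily check-in
#'
#' Applies the four transition rules to the current status and the wellness
#' ratings of the last (up to) 7 check-ins, in decision-number order, at most
#' one transition per check-in:
#'
#' * DN1: well -> prodromal when `count(|WR| >= 2) >= 4`
#' * DN2: prodromal or recovering -> well when `count(|WR| <= 1) >= 5`
#' * DN3: prodromal or recovering -> unwell when `count(|WR| >= 3) >= 5`
#' * DN4: unwell -> recovering when `count(|WR| <= 2) >= 5`
#'
#' Otherwise the status is unchanged. Counts are absolute (never pro-rated
#' for short windows), so with fewer than 4 ratings no rule can fire. Crisis
#' ratings (+/-4) count toward both the `>= 2` and `>= 3` criteria.
#'
#' @param current a `livewell_status` record (or a status string).
#' @param ratings wellness ratings of the last <= 7 check-ins, newest last.
#' @param config a [rule_config()].
#' @param date date of the triggering check-in, stamped on a new record.
#' @return A `livewell_status` record; `triggering_rule` is the decision
#'   number that fired, or the current record unchanged when none fired.
#' @examples
#' rec <- clinical_status_record("well", "2021-03-01")
#' update_status(rec, c(2, 2, -2, 2, 0, 0, 1), date = "2021-03-08")
#' @export
update_status <- function(current, ratings, config = rule_config(),
                          date = Sys.Date()) {
  if (is.character(current)) current <- clinical_status_record(current, date)
  status <- match.arg(current$status, livewell_states())
  n <- wellness_counts(ratings)
  to <- NULL; rule <- NULL
  if (status == "well" && n[["n_ge2"]] >= config$dn1_count) {
    to <- "prodromal"; rule <- 1L
  } else if (status %in% c("prodromal", "recovering") &&
             n[["n_le1"]] >= config$dn2_count) {
    to <- "well"; rule <- 2L
  } else if (status %in% c("prodromal", "recovering") &&
             n[["n_ge3"]] >= config$dn3_count) {
    to <- "unwell"; rule <- 3L
  } else if (status == "unwell" && n[["n_le2"]] >= config$dn4_count) {
    to <- "recovering"; rule <- 4L
  }
  if (is.null(to)) return(current)
  clinical_status_record(to, effective_date = as.Date(date),
                         triggering_rule = rule)
}

#' Replay daily check-ins through the clinical-status machine
#'
#' Runs [update_status()] once per completed check-in, in date order, using a
#' sliding window of the last 7 check-in wellness ratings, and returns the
#' per-date status timeline.
#'
#' @param checkins data frame of validated daily check-ins (see
#'   [validate_checkins()]).
#' @param profile a [user_profile()]; supplies the coach-set initial status.
#' @param config a [rule_config()].
#' @return Data frame with one row per check-in: `date`, `wellness`,
#'   `status_before`, `status`, `triggering_rule` (`NA` when no rule fired).
#' @export
status_timeline <- function(checkins, profile = user_profile(),
                            config = rule_config()) {
  checkins <- checkins[order(as.Date(checkins$date)), , drop = FALSE]
  n <- nrow(checkins)
  current <- clinical_status_record(profile$initial_status,
                                    if (n) as.Date(checkins$date[1]) - 1 else Sys.Date())
  out <- data.frame(date = as.Date(checkins$date),
                    wellness = as.integer(checkins$wellness),
                    status_before = character(n), status = character(n),
                    triggering_rule = rep(NA_integer_, n))
  for (i in seq_len(n)) {
    win <- checkins$wellness[max(1L, i - config$status_window + 1L):i]
    out$status_before[i] <- current$status
    nxt <- update_status(current, win, config, date = checkins$date[i])
    if (!identical(nxt$status, current$status)) {
      out$triggering_rule[i] <- as.integer(nxt$triggering_rule)
      current <- nxt
    }
    out$status[i] <- current$status
  }
  out
}
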