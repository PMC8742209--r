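#' Trajectory specification for the check-in simulator
#'
#' Defines a synthetic user trajectory with a controllable clinical arc so
#' that every rule path of the engine can be exercised without patient data.
#' Scenarios:
#'
#' * `stable_well` -- wellness stays in the balanced band (-1..+1).
#' * `prodromal_onset` -- balanced until `onset_day`, then sustained early
#'   warning ratings (|WR| = 2).
#' * `episode_and_recovery` -- a full arc: a one-day worsening spike, early
#'   warning ramp, episode-level ratings with a one-day crisis peak, then
#'   stepwise improvement back to balanced; drives the status machine around
#'   well -> prodromal -> unwell -> recovering -> well.
#' * `nonadherent_medication` -- balanced wellness but medication taken in
#'   full only intermittently.
#' * `sleep_disruption` -- balanced wellness with phased sleep/routine
#'   problems (severe short, short, severe long, long sleep; late bedtime;
#'   late risetime).
#' * `missed_checkins` -- balanced wellness, low completion rate.
#'
#' @param scenario one of the six scenario names.
#' @param length_days trajectory length in days (default 112, the 16-week
#'   active phase).
#' @param seed integer seed; the same spec always generates the same data.
#' @param noise probability that a day's wellness rating deviates by +/-1
#'   from the scenario path (truncated at +/-4).
#' @param adherence_rate probability a day's check-in is completed; missing
#'   days are dropped, not imputed. Default 1, or 0.5 for `missed_checkins`.
#' @param direction `"up"` (manic side, positive ratings) or `"down"`
#'   (depressive side) for scenarios with a symptomatic arc.
#' @param onset_day first symptomatic day for `prodromal_onset`.
#' @return A list of class `livewell_trajectory_spec`.
#' @export
trajectory_spec <- function(scenario = c("stable_well", "prodromal_onset",
                                         "episode_and_recovery",
                                         "nonadherent_medication",
                                         "sleep_disruption",
                                         "missed_checkins"),
                            length_days = 112L, seed = 1L, noise = 0.1,
                            adherence_rate = NULL,
                            direction = c("up", "down"), onset_day = 10L) {
  scenario <- match.arg(scenario)
  direction <- match.arg(direction)
  if (length_days < 1L) stop("length_days must be at least 1")
  if (noise < 0 || noise > 1) stop("noise must be a probability")
  if (is.null(adherence_rate))
    adherence_rate <- if (scenario == "missed_checkins") 0.5 else 1
  if (adherence_rate < 0 || adherence_rate > 1)
    stop("adherence_rate must be a probability")
  structure(list(scenario = scenario, length_days = as.integer(length_days),
                 seed = as.integer(seed), noise = noise,
                 adherence_rate = adherence_rate, direction = direction,
                 onset_day = as.integer(onset_day)),
            class = "livewell_trajectory_spec")
}

# scenario wellness-rating path (before noise), on the |WR| scale; the sign
# is applied afterwards for "up"/"down" arcs
scenario_wr_path <- function(spec) {
  n <- spec$length_days
  base <- rep(0L, n)
  stretch <- function(x, len) x[pmin(seq_len(len), length(x))]
  if (spec$scenario == "prodromal_onset" && n >= spec$onset_day) {
    base[spec$onset_day:n] <- 2L
  } else if (spec$scenario == "episode_and_recovery") {
    arc <- c(0, 0, 0, 0, 0,      # 1-5   balanced, status well
             3, 0,               # 6-7   worsening spike while well
             2, 2, 2,            # 8-10  early warning; DN1 fires day 10
             1,                  # 11    improving while prodromal
             3, 3, 3, 3, 3,      # 12-16 worsening; DN3 fires day 16
             4,                  # 17    crisis peak while unwell
             3, 3, 3,            # 18-20 continuing unwell
             2, 2, 2, 2, 2,      # 21-25 improving; DN4 fires day 25
             3,                  # 26    worsening while recovering
             2, 2,               # 27-28 continuing recovering
             1, 0, 0, 0, 0)      # 29-33 improving; DN2 fires day 33
    base <- stretch(c(arc, rep(0, max(0, n - length(arc)))), n)
  }
  as.integer(base) * if (spec$direction == "down") -1L else 1L
}

#' Generate a synthetic daily check-in trajectory
#'
#' Deterministic under the spec's seed. Scenario structure is carried by the
#' wellness-rating path, the medication pattern, or the sleep/routine fields;
#' all remaining fields stay at goal-compatible values so that only the
#' scenario's intended rules fire.
#'
#' @param spec a [trajectory_spec()].
#' @param profile a [user_profile()].
#' @param start_date date of the first day.
#' @return Data frame of validated daily check-ins (completed days only).
#' @examples
#' spec <- trajectory_spec("prodromal_onset", length_days = 21, noise = 0)
#' generate_trajectory(spec)$wellness
#' @export
generate_trajectory <- function(spec, profile = user_profile(),
                                start_date = as.Date("2021-01-01")) {
  rng <- local_rng(spec$seed)
  n <- spec$length_days
  wr <- scenario_wr_path(spec)
  mid <- (profile$sleep_goal_low + profile$sleep_goal_high) / 2
  bed0 <- parse_clock(profile$bedtime_window_start)
  rise0 <- parse_clock(profile$risetime_window_start)
  halfwin <- round(profile$window_width_hours * 60 / 2)
  medication <- rep("all", n)
  sleep <- rep(mid, n)
  bed <- rep(bed0 + halfwin, n)
  rise <- rep(rise0 + halfwin, n)
  for (i in seq_len(n)) {
    if (rng() < spec$noise) {
      wr[i] <- wr[i] + if (rng() < 0.5) 1L else -1L
      wr[i] <- max(-4L, min(4L, wr[i]))
    }
    sleep[i] <- round(sleep[i] + (rng() - 0.5) * 0.5, 1)
  }
  if (spec$scenario == "nonadherent_medication") {
    medication <- vapply(seq_len(n), function(i) {
      u <- rng()
      if (u < 0.3) "all" else if (u < 0.65) "some" else "none"
    }, "")
  }
  if (spec$scenario == "sleep_disruption") {
    phase <- findInterval(seq_len(n), c(1, 11, 21, 31, 41, 51, 61))
    sleep <- c(3.5, 5, 12.5, 9.5, mid, mid, mid)[phase]
    bed[phase == 5] <- (bed0 + 210) %% 1440   # ~3.5 h past window start
    rise[phase == 6] <- (rise0 + 240) %% 1440 # ~4 h past window start
  }
  keep <- vapply(seq_len(n), function(i)
    spec$adherence_rate >= 1 || rng() < spec$adherence_rate, TRUE)
  out <- data.frame(
    user_id = profile$user_id,
    date = start_date + seq_len(n) - 1L,
    medication = medication,
    sleep_hours = pmin(24, pmax(0, sleep)),
    bedtime = format_clock(bed),
    risetime = format_clock(rise),
    wellness = wr, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  validate_checkins(out)
}

# distribute `total` over n items capped at max_item (greedy)
items_for_total <- function(total, n_items, max_item) {
  items <- integer(n_items)
  for (i in seq_len(n_items)) {
    items[i] <- min(max_item, total)
    total <- total - items[i]
  }
  if (total > 0) stop("total exceeds scale maximum")
  items
}

#' Generate weekly check-ins matching a trajectory
#'
#' One weekly check-in every 7 days. For `episode_and_recovery` the relevant
#' scale total (PHQ-8 for a depressive arc, ASRM for a manic arc) crosses its
#' episode threshold during the unwell phase and returns below afterwards;
#' all other scenarios stay sub-threshold. For `missed_checkins`, weekly
#' check-ins after the first are skipped (exercising the overdue flag).
#'
#' @param spec a [trajectory_spec()].
#' @param profile a [user_profile()].
#' @param start_date date of the first trajectory day.
#' @param config a [rule_config()] supplying the episode thresholds.
#' @return Data frame of weekly check-ins (see [weekly_checkin()]).
#' @export
generate_weekly <- function(spec, profile = user_profile(),
                            start_date = as.Date("2021-01-01"),
                            config = rule_config()) {
  dates <- start_date + seq(7L, spec$length_days, by = 7L) - 1L
  if (spec$scenario == "missed_checkins" && length(dates) > 1L)
    dates <- dates[1]
  wr <- scenario_wr_path(spec)
  rows <- lapply(dates, function(d) {
    day <- as.integer(d - start_date) + 1L
    level <- abs(wr[min(day, length(wr))])
    if (spec$direction == "down" || spec$scenario != "episode_and_recovery") {
      phq <- if (level >= 3) config$phq8_episode_threshold + 4 else 2 * level
      asrm <- min(level, 4)
      weekly_checkin(d, items_for_total(phq, 8, 3),
                     items_for_total(asrm, 5, 4))
    } else {
      asrm <- if (level >= 3) config$asrm_episode_threshold + 2 else level
      weekly_checkin(d, items_for_total(min(2 * level, 6), 8, 3),
                     items_for_total(asrm, 5, 4))
    }
  })
  out <- do.call(rbind, rows)
  out$user_id <- profile$user_id
  out[, c("user_id", setdiff(names(out), "user_id"))]
}

#' Generate a synthetic DSM-IV/CMF symptom stream
#'
#' Seeded scenario streams for the nine-state machine. Across the shipped
#' scenario set every decision rule DN1--DN10 fires at least once:
#'
#' * `depression` -- 10 of 14 qualifying depressive days (DN7), then
#'   remission into recovering (DN9).
#' * `mania` -- 7 qualifying manic days (DN5), then lingering sub-episode
#'   symptoms (DN8) and remission (DN9).
#' * `hypomania` -- 4 qualifying days at sub-moderate impairment (DN4).
#' * `mixed` -- manic days with concurrent depressive symptoms (DN6).
#' * `recovery_course` -- from asymptomatic recovery: symptom return
#'   (DN1), partial remission (DN3), full remission (DN2).
#' * `long_recovery` -- from recovering: 57 low-symptom days (DN10).
#' * `null` -- symptom-free; no rule ever fires.
#'
#' @param scenario one of the scenario names above.
#' @param seed integer seed (severity jitter on sub-threshold symptoms).
#' @param start_date date of the first day.
#' @return List of [symptom_day()] records with attribute `initial_status`
#'   (the state the stream is meant to start from).
#' @export
generate_symptom_stream <- function(scenario = c("depression", "mania",
                                                 "hypomania", "mixed",
                                                 "recovery_course",
                                                 "long_recovery", "null"),
                                    seed = 1L,
                                    start_date = as.Date("2021-01-01")) {
  scenario <- match.arg(scenario)
  rng <- local_rng(seed)
  dep <- function(k) c(rep(1, k), rep(0, 9 - k))
  man <- function(k) c(rep(1, k), rep(0, 7 - k))
  mild <- function(n, k) {                       # k mild (0.5) severities
    x <- numeric(n); if (k > 0) x[seq_len(k)] <- 0.5; x
  }
  times <- function(n, ...) rep(list(list(...)), n)
  days <- switch(scenario,
    depression = c(
      lapply(1:4, function(i) list(depression = mild(9, round(rng() * 2)))),
      times(10, depression = dep(5), mood_depressed = TRUE,
            impairment = "moderate"),
      times(17, depression = mild(9, 1))),
    mania = c(
      times(3),
      times(7, mania = man(3), mood_elevated = TRUE, impairment = "moderate"),
      times(7, depression = dep(3)),             # sub-episode, count > 2
      times(8, depression = c(1, rep(0, 8)))),
    hypomania = c(
      times(2),
      times(4, mania = man(3), mood_elevated = TRUE, impairment = "mild"),
      times(8)),
    mixed = c(
      times(2),
      times(7, mania = man(3), depression = dep(3), mood_elevated = TRUE,
            mood_depressed = TRUE, impairment = "moderate")),
    recovery_course = c(
      times(7, depression = dep(3)),             # DN1 -> prodromal
      times(7, depression = dep(1)),             # DN3 -> symptomatic recovery
      times(8)),                                 # DN2 -> asymptomatic recovery
    long_recovery =
      times(58, depression = c(1, rep(0, 8))),   # DN10 fires on day 57
    null = times(10))
  initial <- switch(scenario,
                    recovery_course = "asymptomatic_recovery",
                    long_recovery = "recovering",
                    "asymptomatic_recovery")
  out <- lapply(seq_along(days), function(i) {
    args <- days[[i]]
    args$date <- start_date + i - 1L
    do.call(symptom_day, args)
  })
  attr(out, "initial_status") <- initial
  out
}

# corpus tier of each daily-review category: tier 3 covers episode and
# crisis content, tier 2 warning-sign and prodromal/recovering content,
# tier 1 the target and risk categories
category_corpus_tier <- function(category) {
  ifelse(grepl("^severe_|^unwell_", category), 3L,
         ifelse(grepl("^prodromal_|^recovering_|^well_", category), 2L, 1L))
}

corpus_target_pool <- list(
  `1` = c("sleep", "medication", "signs_symptoms", "support", "routine"),
  `2` = c("signs_symptoms", "support"),
  `3` = "signs_symptoms")
corpus_determinant_pool <- list(
  `1` = c("attitudes", "knowledge", "support", "evaluation", "planning"),
  `2` = c("evaluation", "skills", "knowledge", "adjustment", "practice"),
  `3` = c("evaluation", "skills", "adjustment", "knowledge", "support"))

#' Generate a labeled placeholder content corpus
#'
#' Two modes. With `pages_per_category`, every daily-review category receives
#' a full page set: crisis categories one single page; all others a first and
#' a last page plus middle pages (one chained unique pair when four or more
#' pages are requested), and the low-risk category carries the choice-option
#' pages. With `tier_shares` and `n_pages`, a fixture corpus whose per-tier
#' page counts match the requested shares exactly (largest-remainder
#' apportionment) for verifying [corpus_stats()]; categories are filled as
#' the tier budget allows.
#'
#' @param pages_per_category pages per non-crisis category (>= 2).
#' @param tier_shares numeric length-3 vector of tier page shares, summing
#'   to 1.
#' @param n_pages total page count for share mode.
#' @param seed integer seed for target/determinant label assignment.
#' @param categories category table (default [daily_review_categories()]).
#' @return A validated content corpus data frame (see [validate_corpus()]).
#' @examples
#' stats <- corpus_stats(generate_corpus(tier_shares = c(0.71, 0.22, 0.07),
#'                                       n_pages = 100))
#' stats$tier_shares
#' @export
generate_corpus <- function(pages_per_category = 4L, tier_shares = NULL,
                            n_pages = NULL, seed = 1L,
                            categories = daily_review_categories()) {
  rng <- local_rng(seed)
  cats <- categories$category
  tiers <- category_corpus_tier(cats)
  crisis <- grepl("^severe_", cats)
  budget <- if (is.null(tier_shares)) {
    ifelse(crisis, 1L, as.integer(pages_per_category))
  } else {
    if (length(tier_shares) != 3L || abs(sum(tier_shares) - 1) > 1e-8)
      stop("tier_shares must be 3 shares summing to 1")
    if (is.null(n_pages)) stop("share mode requires n_pages")
    exact <- tier_shares * n_pages
    per_tier <- floor(exact)
    rem <- n_pages - sum(per_tier)
    if (rem > 0) {
      ord <- order(exact - per_tier, decreasing = TRUE)
      per_tier[ord[seq_len(rem)]] <- per_tier[ord[seq_len(rem)]] + 1L
    }
    b <- integer(length(cats))
    for (tt in 1:3) {
      idx <- which(tiers == tt)
      left <- per_tier[tt]
      # crisis pages first (1 each), then first+last pairs, then middles
      for (i in idx[crisis[idx]]) if (left >= 1L) { b[i] <- 1L; left <- left - 1L }
      for (i in idx[!crisis[idx]]) if (left >= 2L) { b[i] <- 2L; left <- left - 2L }
      open <- idx[!crisis[idx] & b[idx] >= 2L]
      while (left > 0L && length(open)) {
        for (i in open) {
          if (left == 0L) break
          b[i] <- b[i] + 1L; left <- left - 1L
        }
      }
      if (left > 0L)
        stop("infeasible page counts: tier ", tt, " budget of ", per_tier[tt],
             " pages cannot host its categories")
    }
    b
  }
  if (any(!crisis & budget > 0 & budget < 2L))
    stop("non-crisis categories need at least 2 pages (first + last)")
  rows <- list()
  for (k in seq_along(cats)) {
    m <- budget[k]
    if (m == 0L) next
    cat <- cats[k]; tt <- tiers[k]
    pick_label <- function(pool) pool[floor(rng() * length(pool)) + 1L]
    tpool <- corpus_target_pool[[as.character(tt)]]
    dpool <- corpus_determinant_pool[[as.character(tt)]]
    mk <- function(role, position, variant, next_id = NA_character_,
                   choices = NA_character_) {
      data.frame(page_id = paste0(cat, "_", role, "_",
                                  if (is.na(position)) variant
                                  else paste0("p", position, "v", variant)),
                 category = cat, role = role, position = position,
                 variant = variant, next_id = next_id,
                 target = pick_label(tpool), determinant = pick_label(dpool),
                 tier = tt, choices = choices, stringsAsFactors = FALSE)
    }
    if (crisis[k]) { rows[[length(rows) + 1L]] <- mk("crisis", NA, 1L); next }
    pages <- list(mk("first", NA_integer_, 1L), mk("last", NA_integer_, 1L))
    extra <- m - 2L
    if (cat == "low_risk" && extra >= 2L) {
      pages <- c(pages,
                 list(mk("middle", 2L, 1L,
                         choices = "awareness;lifestyle;coping;team"),
                      mk("middle", 3L, 1L,
                         choices = "sleep;medication;attend;routine;tranquil;social")))
      extra <- extra - 2L
    } else if (extra >= 2L) {
      # one chained unique pair: the page-2 variant links to a unique page 3
      p3 <- mk("middle", 3L, 1L)
      p2 <- mk("middle", 2L, 1L, next_id = p3$page_id)
      pages <- c(pages, list(p2, p3))
      extra <- extra - 2L
    }
    v <- 2L; pos <- 2L
    while (extra > 0L) {  # remaining pages become extra variants
      role <- if (extra %% 3L == 0L) "first" else if (extra %% 3L == 1L) "last"
              else "middle"
      pages <- c(pages, list(mk(role, if (role == "middle") pos else NA_integer_, v)))
      v <- v + 1L
      extra <- extra - 1L
    }
    rows <- c(rows, pages)
  }
  corpus <- do.call(rbind, rows)
  rownames(corpus) <- NULL
  validate_corpus(corpus)
  corpus
}

#' Generate a synthetic user profile
#'
#' Draws personalized goals within realistic adult ranges: a 7.5--9-hour-wide
#' sleep goal band centred near 7.5 h, bedtime window starting 22:00--23:30,
#' risetime window 06:00--08:00.
#'
#' @param user_id identifier for the profile.
#' @param seed integer seed.
#' @return A [user_profile()].
#' @export
generate_profile <- function(user_id = "sim-user", seed = 1L) {
  rng <- local_rng(seed)
  low <- round(6 + rng() * 1.5, 1)
  user_profile(
    user_id = user_id,
    sleep_goal_low = low, sleep_goal_high = low + 2,
    bedtime_window_start = format_clock(22 * 60 + floor(rng() * 90)),
    risetime_window_start = format_clock(6 * 60 + floor(rng() * 120)),
    notify_time = "09:00",
    initial_status = "well",
    psychiatrist_phone = "555-0100",
    coach_email = "coach@example.org",
    provider_emails = "psychiatrist@example.org")
}
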