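profile68 <- user_profile(sleep_goal_low = 6, sleep_goal_high = 8)

test_that("sleep classification applies the severe bounds and goal range", {
  expect_identical(classify_sleep(4, profile68), "less_severe")
  expect_identical(classify_sleep(4.25, profile68), "less")
  expect_identical(classify_sleep(7, profile68), "in_range")
  expect_identical(classify_sleep(12, profile68), "more_severe")
  expect_identical(classify_sleep(11.75, profile68), "more")
  # goal_high + 4 undercuts the 12-hour cap
  p7 <- user_profile(sleep_goal_low = 5, sleep_goal_high = 7)
  expect_identical(classify_sleep(11.5, p7), "more_severe")
  expect_identical(classify_sleep(10.9, p7), "more")
  # severe labels dominate the plain ones
  expect_identical(classify_sleep(3, profile68), "less_severe")
  expect_error(classify_sleep(25, profile68), "\\[0, 24\\]")
})

test_that("goal feedback reports rounded percent of last-7-day goal attainment", {
  ci <- make_checkins(rep(0, 7))
  ci$medication <- c("all", "all", "all", "some", "none", "some", "some")
  fb <- goal_feedback(ci, profile68)
  expect_identical(unname(fb["medication"]), 43)   # 3 of 7 days
  expect_identical(unname(fb["sleep"]), 100)
  ci$medication <- "all"
  expect_identical(unname(goal_feedback(ci, profile68)["medication"]), 100)
  # bedtime 23:00 sits in the 22:30-24:00 window
  ci$bedtime <- "23:00"
  expect_identical(unname(goal_feedback(ci, profile68)["bedtime"]), 100)
  ci$bedtime <- "02:00"
  expect_identical(unname(goal_feedback(ci, profile68)["bedtime"]), 0)
  expect_error(goal_feedback(ci[0, ], profile68), "at least one")
})

test_that("category selection follows the tier hierarchy", {
  ci <- function(wellness, medication = "all", sleep = 7) {
    x <- make_checkins(wellness, medication = medication, sleep_hours = sleep)
    x[nrow(x), , drop = FALSE]
  }
  # crisis ratings always select a tier-3 category, one page, regardless of status
  for (status in livewell_states()) {
    d <- select_category(status, ci(-4), profile = profile68)
    expect_identical(d$category, "severe_down")
    expect_identical(d$tier, 3L)
  }
  expect_identical(select_category("well", ci(4), profile = profile68)$category,
                   "severe_up")
  # early warning while well
  d <- select_category("well", ci(2), profile = profile68)
  expect_identical(d$category, "well_early_warning_up")
  expect_identical(d$tier, 2L)
  # worsening while not unwell
  expect_identical(select_category("well", ci(-3), profile = profile68)$category,
                   "well_worsening_down")
  expect_identical(select_category("prodromal", ci(3), profile = profile68)$category,
                   "prodromal_worsening")
  expect_identical(select_category("recovering", ci(-3), profile = profile68)$category,
                   "recovering_worsening")
  # continuing / improving in the symptomatic states
  expect_identical(select_category("unwell", ci(3), profile = profile68)$category,
                   "unwell_continuing_up")
  expect_identical(select_category("unwell", ci(1), profile = profile68)$category,
                   "unwell_improving")
  expect_identical(select_category("prodromal", ci(-2), profile = profile68)$category,
                   "prodromal_continuing_down")
  expect_identical(select_category("recovering", ci(0), profile = profile68)$category,
                   "recovering_improving")
  # default when balanced and goals met
  d <- select_category("well", ci(0), profile = profile68)
  expect_identical(d$category, "low_risk")
  expect_identical(d$tier, 1L)
  expect_identical(select_category("well", ci(0), profile = profile68,
                                   recent_tier2 = TRUE)$category,
                   "moderate_high_risk")
})

test_that("target categories trigger on counts over the last 4 check-ins", {
  w4 <- function(medication = "all", sleep = 7, bedtime = "23:00",
                 risetime = "07:00") {
    make_checkins(rep(0, 4), medication = medication, sleep_hours = sleep,
                  bedtime = bedtime, risetime = risetime)
  }
  pick <- function(w) {
    select_category("well", w[4, , drop = FALSE], w, profile68)
  }
  # medication problems on 2 of 4 check-ins
  d <- pick(w4(medication = c("all", "some", "all", "none")))
  expect_identical(d$category, "medication")
  expect_identical(d$evidence$medication_missed, 2L)
  expect_identical(pick(w4(medication = c("all", "some", "all", "all")))$category,
                   "low_risk")
  # a single severe sleep day suffices; plain sleep problems need 2
  expect_identical(pick(w4(sleep = c(7, 7, 7, 3.5)))$category, "sleep_less_severe")
  expect_identical(pick(w4(sleep = c(7, 7, 12.5, 7)))$category, "sleep_more_severe")
  expect_identical(pick(w4(sleep = c(5, 7, 5, 7)))$category, "sleep_less")
  expect_identical(pick(w4(sleep = c(9, 7, 9, 7)))$category, "sleep_more")
  expect_identical(pick(w4(sleep = c(5, 7, 7, 7)))$category, "low_risk")
  # routine windows; medication outranks sleep outranks routine
  expect_identical(pick(w4(bedtime = c("23:00", "02:00", "02:00", "23:00")))$category,
                   "bedtime_window")
  expect_identical(pick(w4(risetime = c("11:00", "11:00", "07:30", "07:30")))$category,
                   "risetime_window")
  both <- w4(medication = c("some", "none", "all", "all"),
             sleep = c(3, 3, 3, 3), bedtime = "02:00")
  expect_identical(pick(both)$category, "medication")
  sleep_routine <- w4(sleep = c(5, 5, 7, 7), bedtime = "02:00")
  expect_identical(pick(sleep_routine)$category, "sleep_less")
})

test_that("selection is total and closed over the tailoring-variable cross-product", {
  cats <- daily_review_categories()$category
  seen <- character()
  sleep_by_class <- c(less_severe = 3, less = 5, in_range = 7, more = 9,
                      more_severe = 12.5)
  med_patterns <- expand.grid(rep(list(c("all", "some")), 4),
                              stringsAsFactors = FALSE)
  for (status in livewell_states()) {
    for (wr in -4:4) {
      for (p in seq_len(nrow(med_patterns))) {
        for (sl in sleep_by_class) {
          w <- make_checkins(c(0, 0, 0, wr),
                             medication = unlist(med_patterns[p, ]),
                             sleep_hours = sl)
          d <- select_category(status, w[4, , drop = FALSE], w, profile68)
          expect_true(d$category %in% cats)
          seen <- union(seen, d$category)
        }
      }
    }
  }
  # everything except the history-dependent default and the routine
  # categories (routine was held at goal in this cross-product) is reached
  expect_setequal(setdiff(cats, seen),
                  c("moderate_high_risk", "bedtime_window", "risetime_window"))
})

test_that("tier-2/3 selections are immune to medication and sleep problems", {
  w_bad <- make_checkins(c(0, 0, 0, 3), medication = "none", sleep_hours = 3)
  w_good <- make_checkins(c(0, 0, 0, 3))
  for (status in livewell_states()) {
    expect_identical(
      select_category(status, w_bad[4, , drop = FALSE], w_bad, profile68)$category,
      select_category(status, w_good[4, , drop = FALSE], w_good, profile68)$category)
  }
  w_bad$wellness[4] <- -4L
  d <- select_category("well", w_bad[4, , drop = FALSE], w_bad, profile68)
  expect_identical(d$category, "severe_down")
})

test_that("review assembly honors page-count, crisis, chaining, and seed contracts", {
  corpus <- generate_corpus(pages_per_category = 5)
  fb <- c(medication = 100, sleep = 100, bedtime = 100, risetime = 100)
  ci <- make_checkins(0)
  crisis <- select_category("well", transform(ci, wellness = 4L), ci, profile68)
  pages <- assemble_review(crisis, corpus, fb, seed = 3)
  expect_identical(nrow(pages), 1L)
  expect_false(any(pages$bar_graphs))
  low <- select_category("well", ci, ci, profile68)
  for (s in 1:10) {
    pages <- assemble_review(low, corpus, fb, seed = s)
    expect_gte(nrow(pages), 3L)
    expect_lte(nrow(pages), 6L)
    expect_identical(pages$role[1], "first")
    expect_identical(pages$role[nrow(pages)], "last")
    expect_true(pages$bar_graphs[1])
    expect_identical(sum(pages$bar_graphs), 1L)
  }
  expect_identical(assemble_review(low, corpus, fb, seed = 11),
                   assemble_review(low, corpus, fb, seed = 11))
  # a chained unique page is always followed by its linked successor
  med <- structure(list(category = "medication", tier = 1L, direction = "none",
                        evidence = list()), class = "livewell_decision")
  for (s in 1:10) {
    pages <- assemble_review(med, corpus, fb, seed = s)
    i <- which(!is.na(pages$next_id))
    for (j in i[i < nrow(pages)])
      expect_identical(pages$page_id[j + 1L], pages$next_id[j])
  }
  # low-risk choice pages carry the 6 lifestyle options
  pages <- assemble_review(low, corpus, fb, seed = 2)
  p3 <- pages$choices[!is.na(pages$choices) & pages$position == 3]
  expect_identical(strsplit(p3, ";")[[1]],
                   c("sleep", "medication", "attend", "routine", "tranquil",
                     "social"))
  expect_error(assemble_review(med, corpus[corpus$category != "medication", ],
                               fb), "missing from corpus")
})

test_that("corpus statistics recover label shares exactly", {
  one_tier <- generate_corpus(pages_per_category = 2,
                              categories = data.frame(
                                category = c("low_risk", "medication"),
                                tier = 1L))
  expect_identical(unname(corpus_stats(one_tier)$tier_shares), c(100, 0, 0))
  fixture <- generate_corpus(tier_shares = c(0.71, 0.22, 0.07), n_pages = 100)
  expect_identical(nrow(fixture), 100L)
  expect_identical(unname(corpus_stats(fixture)$tier_shares), c(71, 22, 7))
  # hand-built 3:1 target split
  hand <- data.frame(page_id = paste0("p", 1:8),
                     category = "low_risk",
                     role = c("first", rep("middle", 6), "last"),
                     position = c(NA, rep(2:4, 2), NA),
                     variant = c(1, 1, 1, 1, 2, 2, 2, 1),
                     next_id = NA_character_,
                     target = rep(c("sleep", "sleep", "sleep", "medication"), 2),
                     determinant = "knowledge", tier = 1L,
                     stringsAsFactors = FALSE)
  st <- corpus_stats(hand)
  expect_identical(unname(st$targets$tier1), c(75, 25))
  expect_identical(names(st$targets$tier1), c("sleep", "medication"))
  hand$target[1] <- NA
  expect_error(corpus_stats(hand), "unlabeled")
})
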