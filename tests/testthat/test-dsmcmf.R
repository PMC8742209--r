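dates_from <- function(n, start = "2021-01-01") as.Date(start) + seq_len(n) - 1

test_that("CMF symptom count ignores sub-moderate severities", {
  expect_identical(symptom_count(c(0, 0, 0.5, 0.5)), 0L)
  expect_identical(symptom_count(c(1, 1.5, 2)), 3L)
  expect_identical(symptom_count(numeric(9)), 0L)
  expect_identical(symptom_count(symptom_day("2021-01-01",
                                             depression = c(1, 0.5, rep(0, 7)),
                                             mania = c(2, rep(0, 6)))), 2L)
  expect_error(symptom_count(c(0.75)), "CMF scale")
})

test_that("depressive episode entry needs 10 qualifying days of 14", {
  stream <- function(q) {
    # q qualifying days at the end of a 14-day stream
    d <- dates_from(14)
    c(lapply(d[seq_len(14 - q)], zero_day_fixture),
      lapply(d[seq(14 - q + 1, length.out = q)], dep_day))
  }
  expect_null(check_episode_entry(stream(9)))
  hit <- check_episode_entry(stream(10))
  expect_identical(hit$status, "depression")
  expect_identical(hit$decision_number, 7L)
  expect_identical(hit$psr, 5)
  # oracle agreement on the constructed streams
  expect_false(oracle_depression_entry(stream(9)))
  expect_true(oracle_depression_entry(stream(10)))
})

test_that("manic, hypomanic, and mixed entries follow their day and count rules", {
  d <- dates_from(10)
  # hypomania: 4 consecutive qualifying days, sub-moderate impairment, PSR 3
  hypo <- lapply(d[1:4], man_day, impairment = "mild")
  hit <- check_episode_entry(hypo)
  expect_identical(hit$status, "hypomania")
  expect_identical(hit$decision_number, 4L)
  expect_identical(hit$psr, 3)
  expect_null(check_episode_entry(hypo[1:3]))
  # mania: 7 consecutive days at moderate impairment
  mania <- lapply(d[1:7], man_day)
  hit <- check_episode_entry(mania)
  expect_identical(hit$status, "mania")
  expect_identical(hit$decision_number, 5L)
  expect_identical(hit$psr, 5)
  expect_null(check_episode_entry(mania[1:6]))
  # hospitalization short-circuits the 7-day requirement
  hosp <- list(man_day(d[1], hospitalized = TRUE))
  hit <- check_episode_entry(hosp)
  expect_identical(hit$status, "mania")
  expect_identical(hit$psr, 6)
  # irritable-only mood requires 4 mania symptoms, not 3
  irr3 <- lapply(d[1:7], man_day, elevated = FALSE, irritable = TRUE)
  expect_null(check_episode_entry(irr3))
  irr4 <- lapply(d[1:7], man_day, k = 4, elevated = FALSE, irritable = TRUE)
  expect_identical(check_episode_entry(irr4)$status, "mania")
  # concurrent depressive symptoms turn mania into a mixed episode
  mixed <- lapply(d[1:7], function(dd)
    symptom_day(dd, mania = c(1, 1, 1, rep(0, 4)),
                depression = c(1, 1, 1, rep(0, 6)),
                mood_elevated = TRUE, mood_depressed = TRUE,
                impairment = "moderate"))
  hit <- check_episode_entry(mixed)
  expect_identical(hit$status, "mixed")
  expect_identical(hit$decision_number, 6L)
})

test_that("a calendar gap breaks a consecutive-day run", {
  d <- c(dates_from(3), dates_from(4, "2021-01-05"))  # gap after day 3
  days <- lapply(d, man_day)
  expect_null(check_episode_entry(days))              # longest run is 4 < 7
  expect_identical(check_episode_entry(lapply(dates_from(7), man_day))$status,
                   "mania")
})

test_that("non-episode rules respect windows, from-state gates, and note f", {
  low56 <- lapply(dates_from(56), low_day_fixture)
  low57 <- lapply(dates_from(57), low_day_fixture)
  # recovering holds through 56 qualifying days; day 57 reaches recovery
  expect_null(check_nonepisode_status(low56, "recovering"))
  hit <- check_nonepisode_status(low57, "recovering")
  expect_identical(hit$decision_number, 10L)
  expect_identical(hit$status, "symptomatic_recovery")
  expect_identical(hit$psr, 2)
  zero57 <- lapply(dates_from(57), zero_day_fixture)
  expect_identical(check_nonepisode_status(zero57, "recovering")$status,
                   "asymptomatic_recovery")
  # note f: symptomatic/asymptomatic recovery are never entered from
  # recovering through the 7-day rules
  low7 <- lapply(dates_from(7), low_day_fixture)
  expect_null(check_nonepisode_status(low7, "recovering"))
  expect_identical(check_nonepisode_status(low7, "prodromal")$decision_number,
                   3L)
  zero7 <- lapply(dates_from(7), zero_day_fixture)
  expect_identical(
    check_nonepisode_status(zero7, "symptomatic_recovery")$decision_number, 2L)
  # prodromal from recovery: symptom count > 2 for 7 days
  high7 <- lapply(dates_from(7), function(dd)
    symptom_day(dd, depression = c(1, 1, 1, rep(0, 6))))
  hit <- check_nonepisode_status(high7, "asymptomatic_recovery")
  expect_identical(hit$status, "prodromal")
  expect_identical(hit$decision_number, 1L)
  expect_null(check_nonepisode_status(high7[1:6], "asymptomatic_recovery"))
  # prodromal also fires on two new moderate symptoms while in recovery
  new2 <- lapply(dates_from(7), function(dd)
    symptom_day(dd, depression = c(1, 1, rep(0, 7))))  # count 2, not > 2
  expect_null(check_nonepisode_status(new2, "asymptomatic_recovery",
                                      baseline_symptoms = rep(TRUE, 16)))
  hit <- check_nonepisode_status(new2, "asymptomatic_recovery",
                                 baseline_symptoms = rep(FALSE, 16))
  expect_identical(hit$status, "prodromal")
  # moderate impairment: continued symptomatic from non-recovery states,
  # prodromal from the recovery umbrella
  high_imp <- lapply(dates_from(7), function(dd)
    symptom_day(dd, impairment = "moderate"))
  expect_identical(
    check_nonepisode_status(high_imp, "episode_exit")$decision_number, 8L)
  expect_identical(
    check_nonepisode_status(high_imp, "asymptomatic_recovery",
                            baseline_symptoms = rep(TRUE, 16))$decision_number,
    1L)
})

test_that("episodes persist until entry criteria are absent for 7 days", {
  d <- dates_from(20)
  days <- c(lapply(d[1:7], man_day), lapply(d[8:20], zero_day_fixture))
  current <- update_dsmcmf(days[1:7], "asymptomatic_recovery")
  expect_identical(current$status, "mania")
  for (t in 8:13) {
    current <- update_dsmcmf(days[1:t], current)
    expect_identical(current$status, "mania")  # < 7 calm days
  }
  current <- update_dsmcmf(days[1:14], current)
  expect_identical(current$status, "recovering")
  expect_identical(current$triggering_rule, "9")
})

test_that("every emitted PSR lies in the admissible set for its status", {
  for (sc in c("depression", "mania", "hypomania", "mixed", "recovery_course",
               "long_recovery", "null")) {
    days <- generate_symptom_stream(sc)
    tl <- dsmcmf_timeline(days, attr(days, "initial_status"))
    for (i in seq_len(nrow(tl)))
      expect_true(tl$psr[i] %in% psr_range(tl$status[i]),
                  info = paste(sc, tl$date[i], tl$status[i], tl$psr[i]))
  }
})

test_that("episode entry agrees with the brute-force window scan on random streams", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(14:60, 1)
    days <- lapply(dates_from(n), function(dd) {
      if (runif(1) < 0.55) dep_day(dd, k = sample(4:6, 1),
                                   impairment = sample(c("mild", "moderate"), 1),
                                   gate = runif(1) < 0.9)
      else zero_day_fixture(dd)
    })
    hit <- check_episode_entry(days)
    expect_identical(!is.null(hit) && hit$status == "depression",
                     oracle_depression_entry(days),
                     info = paste("rep", rep))
  }
})

test_that("adding a qualifying day never retracts a fired episode entry", {
  days <- lapply(dates_from(10), dep_day)
  base <- c(lapply(dates_from(4, "2020-12-28"), zero_day_fixture), days)
  expect_identical(check_episode_entry(base)$status, "depression")
  extended <- c(base, list(dep_day(as.Date("2021-01-11"))))
  expect_identical(check_episode_entry(extended)$status, "depression")
})
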