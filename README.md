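# livewell

`livewell` is an R implementation of the rule-based expert system behind a
smartphone self-management intervention for bipolar disorder. It is aimed at
digital-mental-health researchers and engineers who need a replicable,
inspectable reference for just-in-time adaptive intervention logic: every
decision rule is explicit, every threshold lives in an overridable
configuration object, and a seeded simulator exercises every rule path
without any patient data.

## What it implements

Users complete a **daily check-in** — medication adherence (all/some/none),
sleep duration, bedtime/risetime, and a signed 9-point wellness rating
(WR ∈ −4..+4; 0 balanced, ±2 early warning signs, ±3 episode-level
symptoms, ±4 crisis) — and a **weekly check-in** (PHQ-8 and ASRM). On each
completed check-in the engine:

1. **Updates clinical status** with a four-state machine over the last 7
   check-ins: well → prodromal when count(|WR| ≥ 2) ≥ 4; prodromal or
   recovering → well when count(|WR| ≤ 1) ≥ 5; prodromal or recovering →
   unwell when count(|WR| ≥ 3) ≥ 5; unwell → recovering when
   count(|WR| ≤ 2) ≥ 5.
2. **Selects one of 26 content categories** through a hierarchical decision
   table (crisis, then status/wellness categories, then medication, sleep,
   and routine targets over the last 4 check-ins, then default risk
   categories) and assembles the randomized 3–6-page daily review with
   goal-attainment bar-graph data.
3. **Evaluates reach-out rules**: at most one pop-up per day (crisis;
   transition to unwell/prodromal; worsening while not unwell; medication
   taken in full on ≤ 3 of 7 days; sleep ≤ 4 h on ≥ 2 of 7 days or a 7-day
   mean far from the personal goal), plus provider/coach e-mail events,
   check-in adherence flags, and the daily coach report. Reminders run every
   2 h from the user's chosen time, at most 3.

A separate nine-state **DSM-IV/CMF machine** classifies episode entries
(depression ≥ 5 moderate symptoms on ≥ 10 of 14 days; mania ≥ 3/≥ 4 moderate
symptoms on ≥ 7 days; mixed; hypomania ≥ 4 days) and non-episode statuses
(continued symptomatic, prodromal, recovering, symptomatic/asymptomatic
recovery; recovery after > 56 low-symptom days) with psychiatric status
ratings, from assessor-style symptom-severity streams.

See `vignettes/livewell-methods.Rmd` for the full rule semantics and the
design decisions taken where the source protocol left choices open.

## Worked example

Simulate a 45-day episode-and-recovery arc and replay it through the engine:

```r
library(livewell)
spec     <- trajectory_spec("episode_and_recovery", length_days = 45, noise = 0)
checkins <- generate_trajectory(spec)
run      <- run_range(checkins, generate_weekly(spec), seed = 1)

run$status[!is.na(run$status$triggering_rule), ]
#>          date wellness status_before     status triggering_rule
#> 10 2021-01-10        2          well  prodromal               1
#> 16 2021-01-16        3     prodromal     unwell               3
#> 25 2021-01-25        2        unwell recovering               4
#> 33 2021-02-02        0    recovering       well               2
```

The status machine walks the full published path — prodromal on the 4th
early-warning rating (rule 1), unwell on the 5th episode-level rating
(rule 3), recovering once 5 of 7 ratings fall back to |WR| ≤ 2 (rule 4),
and well again after sustained balanced ratings (rule 2). The reach-out
pop-ups track the same arc:

```r
data.frame(trigger = sapply(Filter(function(a) a$kind == "user_popup",
                                   run$alerts), `[[`, "trigger"))
#>                trigger
#> 1            worsening
#> 2 transition_prodromal
#> 3            worsening
#> 4       asrm_new_onset
#> 5            worsening
#> 6    transition_unwell
#> 7               crisis
#> 8            worsening
```

Each pop-up event carries the psychiatrist's phone number; crisis and
transition events also emit provider and coach e-mail events. The weekly
ASRM total crosses its episode threshold once during the unwell phase
(`asrm_new_onset`) and, by new-onset semantics, does not re-fire while it
stays elevated. Per-day category decisions, the assembled review pages, the
final coach report, and a reproducibility manifest are in `run$decisions`,
`run$reviews`, `run$report`, and `run$manifest`.

## Command line

A thin CLI over the same functions ships in `inst/cli/livewell.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "livewell.R", package = "livewell"))')
Rscript $CLI simulate --scenario episode_and_recovery --seed 3 --days 40 --out sim
Rscript $CLI status   --checkins sim/checkins.csv --profile sim/profile.json --out status.csv
Rscript $CLI run-range --checkins sim/checkins.csv --weekly sim/weekly.csv \
        --profile sim/profile.json --seed 3 --out run
```

Subcommands: `simulate`, `status`, `dsmcmf`, `review`, `run-range`,
`corpus-stats`; `--rules rules.json` overrides any default threshold.

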