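---
title: "Decision rules and state machines in livewell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision rules and state machines in livewell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livewell)
```

## The problem

Bipolar disorder runs a relapsing course: episodes of depression, mania,
hypomania, and mixed states alternate with inter-episode periods that carry
substantial residual symptoms and relapse risk. Adjunctive psychotherapies
reduce relapse mainly by supporting a handful of self-management targets --
taking medication as prescribed, keeping an adequate sleep duration, holding
a regular routine, and noticing early warning signs. `livewell` implements
the rule-based expert system of a smartphone self-management intervention
built on exactly those targets: a *daily check-in* (medication adherence,
sleep hours, bedtime/risetime, and a signed 9-point wellness rating) feeds
an inference engine that classifies clinical status, selects one of 26
feedback content categories per day, and triggers clinical reach-outs and
coach alerts. The engine is fully rule-driven so that the intervention is
replicable; every numeric threshold is held in a [rule_config()] object and
can be overridden without touching code.

## The wellness rating and the four-state status machine

The wellness rating (WR) is a signed integer in −4..+4, anchored per user
with a coach: 0 balanced, ±1 ordinary hassles/uplifts, ±2 early warning or
residual symptoms, ±3 episode-level symptoms, ±4 crisis. Positive ratings
point toward the manic pole, negative toward the depressive pole; the status
rules use the absolute value, so the machine is symmetric under sign change
(a property the tests assert exhaustively).

The app-side state machine has four states -- *well*, *prodromal*, *unwell*,
*recovering* -- and four transition rules evaluated after every completed
check-in over the user's last (up to) 7 check-ins:

| # | from | to | criterion |
|---|------|----|-----------|
| 1 | well | prodromal | count(\|WR\| ≥ 2) ≥ 4 |
| 2 | prodromal, recovering | well | count(\|WR\| ≤ 1) ≥ 5 |
| 3 | prodromal, recovering | unwell | count(\|WR\| ≥ 3) ≥ 5 |
| 4 | unwell | recovering | count(\|WR\| ≤ 2) ≥ 5 |

Three deliberate readings are baked in. The window is **count-based, not
calendar-based**: it holds the last 7 *completed* check-ins, so missed days
stretch the window back in time rather than shrinking it. Counts are
compared to the absolute thresholds even when fewer than 7 check-ins exist,
which makes the machine conservative early on (with fewer than 4 ratings no
rule can fire at all). Rules are scanned in decision-number order with at
most one transition per check-in; because 5 + 5 > 7, rules 2 and 3 can never
both be satisfied by one window, so the scan order only matters for the
(well-defined) rule-1-first case.

```{r}
update_status("well", c(2, 2, -2, 2, 0, 0, 1), date = "2021-03-08")
```

## The nine-state DSM-IV/CMF machine

The assessor-side machine distinguishes nine statuses from daily
symptom-severity data (severities on the clinical monitoring form scale
none = 0, mild = 0.5, moderate = 1, marked = 1.5, severe = 2; a *symptom
count* is the number of symptoms at moderate or worse). Episode entries:
depression (≥ 5 moderate depression symptoms, depressed-mood gate, moderate+
impairment, on ≥ 10 of 14 consecutive days), mania (≥ 3 moderate mania
symptoms with elevated mood or ≥ 4 with irritable mood only; moderate+
impairment, hospitalization, or psychosis; ≥ 7 consecutive days or
hospitalization), mixed (the mania criteria with depressive symptom count
≥ 3 on ≥ 5 of 7 consecutive days), and hypomania (the mania symptom criteria
at sub-moderate impairment for ≥ 4 consecutive days, PSR 3). Non-episode
statuses (continued symptomatic, prodromal, recovering, symptomatic and
asymptomatic recovery) use 7-day windows, except that *recovering* becomes
*recovery* only after more than 56 consecutive low-symptom days.

Where the published rule tables leave room, the package commits to the
following and exposes each choice in the configuration:

* **Episode exit.** The tables define entries, not exits. An episode ends
  when its entry-day criteria have been absent for 7 consecutive days
  (`episode_exit_days`), matching the 7-day evaluation window the
  non-episode rules already use.
* **Rule precedence.** Episode rules dominate non-episode rules. Within
  episodes, *mixed is checked before mania*: a mixed presentation satisfies
  the mania criteria by construction, so a severity-first order would make
  the mixed rule unreachable. After mixed, the scan runs mania, depression,
  hypomania.
* **From-state gates.** The non-episode table's "recovery" column is read as
  a from-state gate: prodromal is entered only from the recovery states;
  continued-symptomatic and recovering only from exited episodes or from
  each other. The symptomatic/asymptomatic recovery rows carry the table's
  own footnote ("from prodromal or symptomatic recovery only and not from
  recovering") literally, so the only exit from *recovering* downward is the
  56-day recovery rule, which classifies its destination as asymptomatic
  recovery when the trailing week was symptom-free and symptomatic recovery
  otherwise. A literal consequence is that asymptomatic recovery cannot
  step sideways to symptomatic recovery without passing through prodromal;
  we keep the literal reading and note it as a limitation.
* **"New symptoms".** The prodromal rule also fires on two new moderate+
  symptoms relative to a baseline frozen when the recovery umbrella was
  entered (`prodromal_new_symptoms`).
* **PSR.** Within an episode the psychiatric status rating is 6 when the
  evaluation day shows hospitalization, psychosis, or severe impairment,
  else 5. Non-episode PSRs are derived from the day's symptom count and
  impairment within each status's admissible set (see `psr_range()`).
* **Calendar gaps.** Consecutive-day conditions are broken by unobserved
  days: a gap never counts toward a run. The 10-of-14 and 5-of-7 windows are
  calendar windows over observed days.

The relationship between the four-state app machine and this nine-state
machine is deliberately *not* modelled: no mapping from wellness ratings to
DSM/CMF states is implied, and none has been established empirically.

## The daily review: 26 categories in 3 tiers

After the status update, a hierarchical if-then/elseif-then table selects
exactly one content category (none on days without a completed check-in):

1. **Crisis (tier 3).** \|WR\| = 4 selects `severe_up`/`severe_down`; the
   review is a single page, without goal bar graphs, asking the user to take
   immediate action.
2. **Status/wellness (tier 2), 15 categories.** While unwell: continuing
   (\|WR\| ≥ 3, split by sign) or improving. While prodromal or recovering:
   worsening (\|WR\| = 3), continuing (\|WR\| = 2, split by sign), or
   improving (\|WR\| ≤ 1). While well: worsening (\|WR\| = 3) or early
   warning signs (\|WR\| = 2), both split by sign.
3. **Targets (tier 1) over the last 4 check-ins.** Medication not fully
   taken on ≥ 2 of 4; severe short sleep (≤ 4 h) or severe long sleep
   (≥ min(12 h, goal upper limit + 4 h)) on ≥ 1 of 4; short/long sleep
   (outside the personalized goal range) on ≥ 2 of 4; bedtime or risetime
   outside its personalized 1.5-hour window on ≥ 2 of 4 -- in the priority
   order medication > sleep > routine, severe before plain.
4. **Default risk.** `moderate_high_risk` when a tier-2/3 category fired in
   the last 14 days (`risk_lookback_days`), else `low_risk`.

The exact category names and the 15/9 split live in supplementary material
of the source protocol that is not publicly reproduced, so the enumeration
here is a documented reconstruction, chosen as the only partition consistent
with every count and category name in the main text. One count was genuinely
open: the status/wellness enumeration that the text sizes at 15 enumerates
naturally to 14 (9 continuing/improving + 3 worsening + 2 early-warning).
We close the gap by splitting *worsening while well* by sign -- in the well
state there is no prior direction context, exactly as for early warning --
giving 9 + 4 + 2 = 15. The corpus is config-replaceable, so a deployment
holding the original tables can substitute them without code changes.

Reviews are assembled as 3--6 pages: a first page with category feedback and
bar-graph data (percent of the last 7 days meeting each target goal, rounded
to integers -- 3 of 7 medication days reads 43%), middle pages sampled
uniformly among position variants except where a chained unique page forces
its successor, and a reiterating last page. Sampling avoids immediately
repeating the previously shown first/last variant and is deterministic under
a seed.

```{r}
ci <- daily_checkin("2021-03-01", "all", 7, "23:00", "07:00", 0)
select_category("well", ci, ci)
```

## Reach-outs, flags, and notifications

At most one clinical reach-out pop-up fires per day, from a hierarchy:
crisis rating (plus provider and coach e-mails); transition to unwell or
prodromal (plus e-mails); worsening symptoms while not unwell; medication
taken in full on ≤ 3 of the last 7 check-ins (the survey-derived "3 of 7
days, 43% adherence" rule; plus coach e-mail); sleep ≤ 4 h on ≥ 2 of the
last 7, or a 7-day mean ≥ 3 h below / ≥ 4 h above the personalized goal
midpoint (plus coach e-mail). The goal midpoint stands in for the survey's
undefined "usual" sleep. Every pop-up carries the psychiatrist's phone
number. Non-crisis triggers are suppressed for 3 days after firing
(`popup_suppression_days`) to avoid daily nagging; crisis is never
suppressed. Weekly check-ins (PHQ-8, ASRM) trigger reach-outs on *new onset*
only -- a total crossing from below its episode threshold (defaults 10 and
6, the published instrument cutoffs; the protocol itself cites but does not
print them) to at or above it. Adherence flags for the coach report fire on
fewer than 4 completed daily check-ins in the last 7 calendar days (after a
one-week warm-up at the start of a run) or a weekly check-in ≥ 3 days past
its 7-day cadence. Check-in reminders run from the user's chosen time every
2 hours, at most 3, truncated at check-in.

## What the simulator does and does not emulate

The simulator exists to exercise rule paths, not to model psychopathology.
Scenario trajectories are piecewise-deterministic wellness arcs (plus
optional ±1 rating noise, truncated at ±4, and Bernoulli check-in
completion with dropped -- never imputed -- rows) shaped so that, jointly,
the six check-in scenarios in both polarities drive all four status rules,
all 26 categories, and every alert kind, and the seven symptom-stream
scenarios drive all ten DSM/CMF rules; an integration test asserts exactly
this. Default length is 112 days, the 16-week active phase of the
intervention. The generated weekly item scores are constructed sums, not
psychometrically calibrated item responses; real data would show
autocorrelated ratings, missingness correlated with symptom severity, and
disagreement between self-report and assessor ratings, none of which is
emulated. Passing tests therefore certify the *rules*, not clinical
validity on real users. The placeholder content corpus is labelled but
textless; share-mode generation apportions tier page counts by largest
remainder so that requested shares are recovered exactly.

## Numerical and degenerate-input choices

Clock times are minutes since midnight; routine windows are modular
intervals on the 24-hour circle, so a 23:30 bedtime window wraps past
midnight. Boundaries are inclusive where the source phrases them so ("≤ 4
hours", "≥ 4 of 7"). Dates are ISO-8601 calendar dates with no timezone
arithmetic; one check-in per user per date is enforced at validation. Empty
inputs are defined: an empty rating window yields zero counts and no
transition; an empty check-in table yields an empty, error-free engine run;
goal feedback requires at least one check-in. All randomization flows
through seeded generators that save and restore the caller's RNG state.

Test problem sizes were chosen to make the heavy properties exact rather
than sampled where feasible: the four-state machine is compared against an
independently written rule-table oracle on all 5^7 = 78,125 length-7 rating
windows per starting state (using sign symmetry to halve the alphabet), and
episode entry is compared against an independent calendar-grid scanner on
randomized streams of up to 60 days.

## Known limitations

* The 26-category enumeration and several alerting thresholds are
  reconstructions of unpublished supplementary tables; all are
  config-replaceable.
* The literal from-state gates leave no direct asymptomatic → symptomatic
  recovery transition (it routes through prodromal).
* No concordance between the app's four-state output and the DSM/CMF
  nine-state output is claimed or testable here.
* Low/moderate/high risk are collapsed to two default categories
  (`low_risk`, `moderate_high_risk`) distinguished by recent tier-2/3
  history; the source does not state how the three levels are separated.
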