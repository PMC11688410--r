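---
title: "cageRT: models and methods for IntelliCage reaction-time protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cageRT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cageRT)
```

## The scientific problem

The IntelliCage is an automated group-housing apparatus with four operant
corners. Each corner carries an RFID reader, two nose-poke ports with
motorised doors gating water bottles, lick sensors, LED cues and an air-puff
valve. Because water is the only programmed reward, a cohort of mice can be
run through a multi-week operant battery without handling. cageRT implements
a 34-day battery of this kind for comparing a transgenic Alzheimer's-model
genotype (`TG`, 3xTg-AD-like) against non-transgenic controls (`NonTg`),
together with the trial adjudication, dependent-variable extraction and
mixed-ANOVA statistics needed to analyse it - and a generative simulator
that produces event streams with the statistical structure the analysis
assumes, so that every inferential step can be validated against a known
ground truth.

## The protocol calendar

`build_default_protocol()` encodes the calendar: Free Adaptation (days 1-4,
doors open), Door Adaptation (5-6, doors open on corner entry), Nose Poke
Adaptation (7-8, doors open on a poke), Water Deprivation Adaptation (day 9,
first day of the restricted water window), Place Preference (10-12, water
only at each animal's assigned corner), Reversal (13-15, only at the
diagonally opposite corner), four reaction-time tasks (RT1 16-18: fixed 2 s
pre-cue with 7 s cue; RT2 19-21: variable 2/4/8 s pre-cue, 7 s cue; RT3
22-24: 3 s cue; RT4 25-28: 1 s cue), Place Avoidance (day 29: doors closed
everywhere, a poke at the assigned corner triggers an air puff), a
home-cage delay day (30) and Extinction (31-34, water at all corners, puff
removed).

From day 9 onward water is available only during a 3-h window of the dark
phase; the default window is 18:00-21:00 (clock anchored at lights-on
06:00), configurable on the protocol object because the source protocol
specifies only "three hours of the dark phase". On the avoidance day no
water is available at all.

Two conventions had to be fixed where the protocol leaves them open:

* **Day boundary.** Analysis days are 24-h periods anchored at protocol
  start (taken to be lights-on), not at midnight; an event belongs to the
  day its *visit* started, keeping each visit atomic.
* **Corner geometry.** Corners 1,2 are front and 3,4 back; diagonal
  opposition is 1<->4, 2<->3. `reversal_corner()` is an involution with no
  fixed point, which is all the analysis relies on.

### Corner assignment

Each animal's place-preference corner should be its *least visited* corner
during adaptation, but occupancies must stay balanced (at most a difference
of 1 between corners, and per-genotype where arithmetically possible) to
prevent crowding and imitation learning. `assign_corners()` uses a
deterministic greedy rule: animals are processed in genotype-alternating
id order and placed into the least-visited corner that still has capacity,
ties toward the lowest corner number, with a feasibility check that keeps
under-filled corners reachable. On the fully-contended test case (8 animals
all preferring one corner) the greedy solution attains the brute-force
optimum of total preference rank; the balance invariant is property-tested
on random rosters.

### Dropout rule

An animal that records no licks over two consecutive in-cage days is
rescued (rehydrated outside the cage and returned) the first time, and
removed from the experiment the second time. `detect_dropouts()` evaluates
the rule on whole protocol days, skipping the home-cage-delay day; removed
animals contribute metric rows only for days before removal.

## Trial model and adjudication

In the RT phases the first nose poke of a visit to the assigned corner
initiates a trial at `t_init`. A pre-cue delay `D` (drawn from the phase's
set) must elapse before the LED lights for the cue duration `C`. The first
post-initiation poke decides the outcome:

* offset `< D`: **premature** (impulsivity error),
* `D <= offset < D + C`: **correct** - the door opens if the water window
  is open at that moment,
* no poke before `D + C`: **abandoned** (attention/engagement error).

Boundary conventions: the cue window is half-open `[D, D+C)`, so a poke at
exactly `D` is correct (the LED is on). Pokes at offsets `>= D + C` are
ignored; the trial has already lapsed. One visit carries at most one trial:
after an error the animal must exit and re-enter, which is the only reading
consistent with "the first nose poke of a visit initiates a trial". The
water window gates *reward delivery*, not classification: a correct
response outside the window is scored correct but unrewarded
(`reward = FALSE`), since the LEDs and poke sensors operate continuously
while only the water is restricted.

`classify_trial()` is the scalar contract; `run_session()` is the
vectorised batch adjudicator, tested property-wise for equivalence with a
per-visit `adjudicate_visit()` loop and against a brute-force
interval-membership oracle on 10^5 fuzzed trials.

## The generative model

Each genotype is a stationary phenotype (`genotype_params()`):

| parameter | meaning | units | NonTg | TG |
|---|---|---|---|---|
| `visit_rate_dark` / `visit_rate_light` | corner-visit Poisson intensity | visits/h | 6 / 1.5 | 8 / 2 |
| `p_poke` | visit contains a nose poke | prob. | 0.70 | 0.75 |
| `lick_burst_mean` | licks per rewarded visit | licks | 30 | 34 |
| `h` | premature-poke hazard during the pre-cue | 1/s | 0.05 | 0.15 |
| `r` | cue-response rate after LED onset | 1/s | 0.5 | 0.3 |
| `p_visit_assigned` | visit targets the assigned corner | prob. | 0.40 | 0.40 |

Premature poking is a constant-hazard (Poisson) process during the delay
and the cue response is an exponential latency, the simplest model with the
observed qualitative structure; it yields the closed-form oracle

\[
p_{prem} = 1 - e^{-hD},\qquad
p_{corr} = e^{-hD}\,(1 - e^{-rC}),\qquad
p_{aband} = e^{-hD}\,e^{-rC},
\]

implemented in `expected_outcome_fractions()` and verified by Monte Carlo
(3 binomial SE at 10^5 trials per `(D, C)` cell) and by inverting the
premature fraction back to `h` (`estimate_hazard()`).

The published study reports no numeric visit rates, lick counts or hazard
parameters, so the scenario defaults above were chosen once as
field-realistic values reproducing the study's qualitative signature - TG
with more visits and initiated trials (higher water-seeking drive), but
fewer licks and a lower %Correct in the harder RT tasks (heightened
impulsivity `h`, impaired attention `r`) - and were not revisited
afterwards. With these values the RT4 %Correct means differ by roughly 18
percentage points between genotypes, a large effect in keeping with the
strong group separations the study reports for the hardest task.

Other simulator conventions worth knowing:

* **Hard-core thinning.** Visit arrivals are thinned to a minimum 60 s gap
  per animal (and visit spans capped below it), since a mouse cannot
  re-enter a corner instantly. This keeps start times final before any
  within-visit event is placed, which is what makes replay exact.
* **Circadian structure** is two-level (dark/light intensity) only.
* **Visit durations** are log-normal (median 10 s) and affect no dependent
  variable, only event layout.
* **Shared pre-cue stream.** Pre-cue delays come from a stateless
  counter-based stream keyed by `(seed, roster index, day, within-day trial
  index)` (`precue_draw_keyed()`), so replaying the simulated event tables
  through `run_session()` re-derives exactly the delays the simulator drew
  and reproduces the ground-truth trial table *identically*. Keying per day
  (rather than per cohort) makes day-subset simulations replayable too.

What the simulator does **not** model - and what a green test therefore
does not establish: learning or fatigue within and across days (all rates
are stationary), social interaction and crowding at corners, avoidance
learning after air puffs, sex or individual variability within genotype
(between-animal variance is purely sampling noise), and dropout behaviour.
Statistical-power figures computed on simulated cohorts transfer to real
cohorts only insofar as real between-animal variance is comparable.

## Dependent variables

`build_metric_table()` produces one row per (animal, day, variable):
adaptation counts (Total Visits, Total Licks, Visits with Nose Poke, Visits
with >= 1 Lick, Visits During Water Access), place-preference variables
(Assigned Visits, Assigned Visits with >= 1 Lick, and %Correct = assigned
visits with a lick over *all* visits x 100 - the denominator is total
visits, exactly as the protocol defines it), RT variables (initiated
Trials, %Abandoned, %Premature, %Correct, each overall and stratified by
pre-cue delay), and avoidance variables (assigned visits and assigned
visits with a poke, the working-memory error count). Percentages with a
zero denominator are `NA`, never 0: 0/0 is undefined and a 0 would bias
group means downward. Total Licks sums burst counts from the lick sensor;
per-lick timing is never needed by any dependent variable.

## Statistics

`mixed_anova()` implements the classical univariate split-plot
decomposition with genotype between subjects and day within:
`F_geno = MS_geno / MS_subj(geno)` on `(g-1, N-g)` df, and
`F_day`, `F_interaction` against `MS_day x subj(geno)` on
`(k-1, (k-1)(N-g))` df - with 10 + 14 subjects and 2 days this yields the
`F(1, 22)` reporting shape. Because day is fully crossed with subjects, the
within-stratum decomposition is orthogonal even with unequal group sizes,
and the implementation agrees with both a brute-force cell-means oracle and
`aov()` with an `Error(subject)` stratum to 1e-8 relative. Design choices:

* **Sphericity** is uncorrected (plain univariate df), matching the
  reporting shape of the source protocol; a Greenhouse-Geisser option was
  considered and deliberately left out of scope.
* **Missing days** trigger complete-case exclusion of the subject, with a
  warning naming the excluded animals; exposed via `excluded_subjects` so
  reduced df in reports are always explainable.
* **Degenerate inputs** (constant DV, a genotype with < 2 subjects, < 2
  days) are errors, not silent zeros.

`bonferroni_posthoc()` is gated on a significant genotype x day interaction
(p < 0.05); with a non-significant interaction it returns an empty table
carrying the reason. Two families are supported, matching how such designs
are reported: genotype contrasts within each day (unpaired pooled t,
family size m = k) and day-pair contrasts within each genotype (paired t,
m = g * C(k,2)); adjusted p = min(1, m * p_raw). Effects with
0.05 <= p < 0.10 are labelled trends in printed output and never gate post
hocs. `two_sample_ttest()` is the pooled-variance Student form (df =
n1 + n2 - 2), whose square equals the one-way ANOVA F.

Type-I error of the genotype main effect is calibrated by simulation under
a null scenario with identical genotype parameters (rejection rate within
3 binomial SE of 5% over 400 replicates), and power under the paper-like
scenario (RT4 %Correct genotype effect detected in at least 80% of 50
replicates); both checks run in the acceptance test suite.

## Data formats and numerical choices

Event data arrive as four tab-delimited tables (visits, pokes, licks,
roster) keyed by `visit_id`; `parse_event_export()` validates headers,
referential integrity and all type invariants (times inside visits,
non-overlapping visits per animal, corners 1-4). `write_store()` /
`read_store()` serialise the whole dataset into a single plain-text
sectioned file - the role a single-file relational database plays in the
original workflow - writing numerics with 17 significant digits so the
round trip is bit-exact. Timestamps are seconds since protocol start at
millisecond-or-better resolution (the hardware's clock resolution is not
documented; double precision comfortably covers it); no time-zone or DST
handling is attempted.

## Known limitations

* The engine assumes one trial per visit and ignores door-motor latency.
* Whether pre-cue draws in the real apparatus were i.i.d. or block-shuffled
  is unknown; i.i.d. uniform is assumed (and is what the keyed stream
  provides).
* The avoidance phase logs puffs but the simulator does not make animals
  avoid the corner afterwards, so extinction-phase dynamics are flat.
* Multi-cage experiments with staggered starts are out of scope.
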