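# endosched

Prediction-driven scheduling of gastrointestinal endoscopy waiting lists.

Endoscopy units conventionally book every elective procedure into a flat
30-minute slot, although realized procedure times range from a couple of
minutes to well over an hour. `endosched` is a toolkit for studying
adaptive alternatives: it predicts per-patient procedure durations from
routinely available characteristics, schedules a prioritized waiting list
with either a greedy heuristic or an exact day-level assignment model, and
evaluates the resulting schedules in simulation — throughput, lateness
against recommended due dates, and per-room-day overtime and earliness
against a daily operational time budget.

It is aimed at health-services operations researchers and endoscopy-unit
planners who want a reproducible desk-scale testbed rather than a
hospital-IT integration.

## The models

**Duration model.** Procedure duration is regressed on patient features
(sex, age band, BMI band, priority class, comorbidities, past failed
colonoscopy, procedure type, indication, endoscopist specialty) with a
pluggable regressor registry — linear, random forest, gradient-boosted
trees (the default), Gaussian process, multilayer perceptron. Features are
chosen by wrapper backward elimination: refit, drop the least-important
feature, score every visited set by k-fold cross-validated MAE, and keep
the best set of at most four features. A planned appointment is the
predicted duration plus a 15-minute buffer for consent, preparation and
room turnover (the fixed baseline books 30 minutes regardless).

**Assignment model.** Let binary x_{ped} indicate that patient p is seen
by endoscopist e on day d. The scheduler maximizes

    omega_1 * sum x_ped  -  omega_2 * sum_{d > d_p} (d - d_p)^2 x_ped

subject to eligibility (x_ped = 0 unless e is in E_p, the designated
endoscopist for nominative patients, otherwise every accepting compatible
provider), room-day capacity (sum_p delta_p x_ped <= delta_e^d), and at
most one appointment per patient. Here d_p is the priority-derived due
date, delta_p the planned appointment minutes, and delta_e^d the working
block of endoscopist e on day d. Weights satisfy
omega_1 > omega_2 * (max lateness)^2, so scheduling one more patient always
dominates any overdue penalty; the squared penalty spreads unavoidable
overdue days evenly across patients. The solver is an exact depth-first
branch and bound with a fractional-knapsack bound, symmetry reduction,
warm starting and node/time/gap limits; an exhaustive oracle verifies it on
small instances.

**Synthetic cohort.** Because real waiting-list extracts are rarely
shareable, a generator produces cohorts whose feature marginals match a
published unit's case mix and whose durations follow a truncated
log-normal (bounds 2–85 min) with covariate effects, calibrated so the
population mean and standard deviation are 16.2 and 9.85 minutes. Due
dates fall uniformly in [-7, 14] days around the horizon start.

## Worked example

```r
library(endosched)

# a 1000-patient synthetic waiting list and six room streams over 10 days
prov   <- generate_roster(roster_spec(n_endoscopists = 6, n_days = 10,
                                      daily_block_minutes = 390, seed = 2))
cohort <- generate_cohort(cohort_spec(n_patients = 1000, seed = 3),
                          roster = prov$roster)

# baseline: every patient in a flat 30-minute slot
baseline <- schedule_greedy(sort_waiting_list(cohort, "fixed"),
                            prov$roster, prov$calendar)
print(build_report(baseline, cohort, prov$calendar))
#> <metrics_report> policy = fixed30-greedy
#>   scheduled 780 (unscheduled 220); avg late 4.07 d; avg wait 153.26 d
#>   overtime 1586 min (26.43/day/room); earliness 425 min (7.09/day/room)

# full policy comparison (trains the duration model in-run)
tab <- run_experiment_throughput(throughput_config(replications = 1,
                                                   base_seed = 1))
print(tab)
#> <comparison_table> 3 policies x 1 replication(s)
#>              policy n_scheduled avg_late_days avg_overtime_day_room
#> 1    fixed30-greedy         780         3.921                25.022
#> 2 predictive-greedy         731         3.477                12.151
#> 3               mip         771         3.815                 7.288
#>   avg_earliness_day_room
#> 1                  5.103
#> 2                 17.508
#> 3                 11.526
```

Reading the numbers: the flat-slot baseline fills all 6 × 10 × 13 = 780
slots and leaves 220 patients waiting, but because the average realized
appointment (procedure + 15-minute buffer) is 31.2 minutes, those fully
booked days run about 25 minutes of overtime per room per day. The
adaptive policies book realistic appointment lengths: the greedy variant
fits fewer, longer appointments (731), while the assignment model repacks
the same predictions to recover most of the throughput (771) with the
least overtime and lateness spread more evenly across priority classes.

A command-line wrapper with `generate`, `train`, `schedule`, `exp1` and
`exp2` subcommands is installed at `inst/cli/endosched.R`.

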