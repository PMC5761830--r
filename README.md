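# tripcoord

Coordination of dual-foraging seabird pairs from binned colony attendance
records.

Small pelagic seabirds such as the dovekie (little auk, *Alle alle*)
provision their chick with a *dual foraging strategy*: short trips (ST,
mean ~2 h) that deliver food, alternating with long trips (LT, mean ~13 h)
that mainly restore the adult's own reserves. If the two parents schedule
their long trips independently, the chick faces long gaps between meals;
if they offset them, food arrives steadily. `tripcoord` implements, as a
tested and reusable pipeline, the full analysis needed to ask whether pairs
coordinate: from 10-minute presence/absence records at the colony to
study-level significance and chick-growth consequences. It is written for
behavioural ecologists working with attendance data from continuous
observation sessions of marked pairs.

## The method

* **Trip classification.** Each maximal absence run is a foraging trip.
  The ST/LT cut-off is the value minimising
  `var(log d | d < c) + var(log d | d ≥ c)` over all midpoints of
  consecutive distinct sorted log-durations — exact, because the objective
  is piecewise constant between data points.
* **Monte Carlo coordination test.** Per pair-session, each bird's series
  of *activity strings* (runs of CO/ST/LT windows) is shuffled: trip
  strings permuted uniformly among trip positions, CO strings among CO
  positions, without replacement, so exactly one CO string stays between
  consecutive trips and the series skeleton is preserved. The statistic is
  the number of windows with one bird on ST while the other is on LT;
  its null distribution comes from 10,000 shuffles. A second statistic,
  the coefficient of variation of inter-feeding intervals (feedings placed
  at each completed trip's end, both parents pooled), tests whether the
  chick is fed more evenly than chance.
* **p-values and combination.** Three tie-handling rules are reported per
  test (`p_paper` strict-tail, `p_mc` valid Monte Carlo, `p_mid` mid-p);
  sessions of the same pair are combined by Stouffer's Z-method
  (`Z = Σ z_i / √k`), with Fisher and logit alternatives, and study-level
  Z is reported both over all sessions and over per-pair combined values.
  The per-session **coordination level** is `(obs − exp)/exp` with `exp`
  the null mean.
* **Chick growth.** Eight growth indicators (day 14–16 mass, peak mass and
  day, fledging mass and day, mass recession, SGR1, SGR2), PCA on the
  Z-scaled indicators, and four linear mixed models (ML, pair as random
  intercept) relating coordination, feeding evenness and body condition.
* **Synthetic data.** A seedable generator reproduces the study's data
  structure (48-h sessions, bimodal log-normal trips, 49-min colony bouts,
  1–5 sessions per pair, chick mass trajectories) with a tunable
  coordination coupling `kappa`, so calibration, power and end-to-end
  checks run without any field data.

See `vignettes/coordinated-provisioning.Rmd` for the model assumptions,
parameter defaults and design choices.

## Worked example

```r
library(tripcoord)

corpus <- simulate_corpus(sim_params(seed = 42))   # 25 pairs, ~75 sessions
report <- run_full_pipeline(corpus, n_iter = 2000, seed = 42)
print(report)
```

```
<provisioning_report>
  ST/LT cut-off: 6.75 h; mean ST 1.89 h, mean LT 12.72 h
  71 included sessions from 25 pairs (0 excluded)
  ST-while-LT overlap: 38.6% +/- 15.2% of windows
  inter-feeding intervals: 127 +/- 106 min
  study-level st_lt_overlap: Z = 1.22, p = 0.111 (over 71 sessions)
  study-level interfeed_cv: Z = 2.97, p = 0.00149 (over 71 sessions)
  growth PCA: first two components 56% of variance
```

Reading the output: the variance-minimising cut-off lands at 6.75 h,
cleanly between the short-trip mean (1.89 h) and long-trip mean (12.72 h)
recovered from the pooled trips. On average 38.6% of each session's windows
have one parent on a short trip while the other is on a long one. At this
corpus's moderate default coupling (`kappa = 0.6`) the feeding-evenness
test detects coordination at the study level (intervals more even than
chance, Z = 2.97), while the overlap test stays below the significance
threshold — per-session effects of a moderate coupling are small, and
stronger coupling (`kappa = 0.8`–`0.9`) is needed before the overlap Z
clears it (the end-to-end acceptance test runs exactly that scenario).
`report$session_results`, `report$pair_combined`, `report$study_level` and
`report$growth` hold the per-session tests, combined p-values and model
fits; `lme4` singular-fit flags are carried in
`report$growth$models$table`.

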