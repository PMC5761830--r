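---
title: "Testing coordinated chick provisioning in dual-foraging seabirds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing coordinated chick provisioning in dual-foraging seabirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripcoord)
```

## The question and the data

Many pelagic seabirds provision their single chick with a *dual foraging
strategy*: short trips (ST, a couple of hours) that deliver food to the
chick, alternated with long trips (LT, half a day or more) that mainly serve
adult self-maintenance. If both parents happen to be on long trips at the
same time, the chick waits a long time between meals; if they offset their
long trips, food arrives steadily. `tripcoord` implements a complete
analysis of this coordination hypothesis from the simplest possible field
data: during continuous 48-h observation sessions, each marked bird's
presence or absence at the colony is noted once per 10-minute window.

Everything downstream derives from those binned records:

* an **activity timeline** per bird and session — every window labelled
  `CO` (at the colony), `ST`, `LT`, or `MASKED` (excluded);
* a **trip table** — each maximal absence run is one foraging trip;
* **feeding events** — a bird returning from a trip feeds the chick, so
  each completed trip contributes one feeding at its end window.

## Separating short from long trips

Trip durations are bimodal and approximately log-normal within mode. The
cut-off separating the two classes is the value minimising the sum of the
two within-class sample variances (denominator $n-1$) of
$\log(\text{duration})$. The objective is piecewise constant between
observed durations, so it is evaluated exactly at the midpoints of
consecutive distinct sorted log-durations; no grid resolution is involved.
Ties in the objective resolve to the smallest candidate. Each class must
keep at least `min_class_size = 2` trips (a variance needs two points), and
a duration exactly at the cut-off classifies as LT (the rule is "strictly
below is ST"). The cut-off is estimated once on durations pooled over birds,
sessions and years, then applied globally, because the separation between
foraging modes is a property of the foraging environment rather than of a
single session.

```{r cutoff-example}
set.seed(1)
d <- c(rlnorm(200, log(1.9), 0.5), rlnorm(100, log(12.8), 0.4))
estimate_cutoff(d)
```

## Exclusion rules

A fixed observation window inevitably clips some trips. A trip that touches
the session start or end has an unknowable true duration, so it is never
classified; its window span is set to `MASKED` in the bird's own timeline
*and in the partner's timeline over the same span*. Masking the partner's
concurrent records keeps the two series aligned, which the pair-level
overlap statistic requires. (An alternative reading — dropping the partner's
whole overlapping trips rather than the window span — is available as the
diagnostic switch `partner_masking = FALSE`, but it breaks the alignment and
is not used for inference.) Two further rules exclude whole pair-sessions:
a female that fed at most once in 48 h is taken to be deserting the brood
(normal at the end of chick rearing, but fatal to a test of biparental
provisioning), and sessions where a colour mark had faded are excluded as
unreliable. Exclusion is always a flag, never a deletion.

## The randomization test

The test statistic for coordination is the number of 10-minute windows in
which one pair member is on a short trip while the other is on a long trip.
The test statistic for feeding evenness is the coefficient of variation
(SD/mean) of the inter-feeding intervals, with both parents' feedings pooled
at the nest. Both are compared against a Monte Carlo null built by shuffling
each bird's *activity strings* — the maximal runs of consecutive windows
sharing one category.

A colony attendance series is strictly alternating: every trip ends at the
colony, so exactly one CO string separates consecutive trip strings. The
shuffle preserves that skeleton: trip strings are permuted uniformly among
the trip positions, CO strings uniformly among the CO positions, everything
sampled without replacement. Keeping the skeleton fixed — including whether
the series begins or ends with a CO string — is what makes the test exact:
under the null hypothesis that trip types and durations occur in a
sequentially independent order, the observed series is exchangeable with the
shuffled ones. We verified during development that looser schemes which also
randomise the boundary structure (for instance, scattering leftover CO
strings at random over the two series ends) produce a null whose trip
positions are *more* dispersed than any alternating process can generate;
the observed overlap then sits systematically above the null and the type-I
error rate roughly doubles or triples. The skeleton-preserving permutation
has no such bias, and its small-instance distribution is checked exactly
against full enumeration (`exact_null_small()`) in the test suite.

Masked spans are excised before string extraction: they split the session
into independent sub-series that are shuffled separately and re-placed in
their original slots, so shuffled trips never bleed across excluded spans.
Each iteration shuffles both birds independently, rebuilds the aligned
timelines, and recomputes the statistic; feeding events for the CV test are
re-derived from the shuffled trip ends exactly as for the observed series.
Two parents can return within one 10-minute window; coincident feedings
collapse to a single time point so intervals are always positive. The
default is 10,000 iterations per session, and separate tests are run for
every pair-session because each bird's own pool of trips and colony bouts
defines its null.

### Tie handling: three p-values

Both statistics are discrete, so the null distribution carries non-trivial
mass exactly at the observed value and the tie rule matters. Every
`randomization_result` therefore reports:

* `p_paper` — the proportion of null values *strictly* beyond the observed
  one (greater for overlap, lower for CV). This is the traditional
  strict-tail rule; with heavy ties it is anti-conservative.
* `p_mc` — $(\#\{\text{beyond or tied}\} + 1)/(n_{\text{iter}} + 1)$, the
  standard Monte Carlo p-value in which the observed arrangement counts as
  one of the draws. It is never anti-conservative under exchangeability and
  is bounded away from zero, so it is what the package combines across
  sessions.
* `p_mid` — the mid-p, counting half of the tie mass. Its rejection rate
  equals the nominal level under exchangeability, which makes it the
  reference for the package's calibration tests.

The **coordination level** for a session is
$(\text{obs} - \text{exp})/\text{exp}$, with "exp" the mean of the null
samples: the proportional excess of ST-while-LT overlap relative to chance.
The same construction applied to the interval CV gives a relative evenness
index (negative values = more even than chance).

## Combining sessions

Pairs were observed in up to five sessions, and session-level p-values from
the same pair are pseudoreplicates. They are combined per pair with the
Stouffer Z-method, $Z = \sum_i z_i / \sqrt{k}$ with
$z_i = \Phi^{-1}(1 - p_i)$, unweighted because no session is more
informative than another by design. Fisher's method and the logit method
(with the conventional $t_{5k+4}$ reference) are provided as alternatives
and agree in direction on well-powered data; note the logit method's $k=1$
identity is only approximate because its t reference is itself an
approximation. Monte Carlo p-values equal to 1 are clamped to
$n_{\text{iter}}/(n_{\text{iter}}+1)$ before transformation. Study-level
summaries are computed under both defensible aggregations — one Stouffer Z
over all included sessions, and one over the per-pair combined p-values —
and both are reported side by side.

## Chick growth

Eight standard growth indicators replace growth-curve fitting (the
indicators are the better-behaved summary for a species whose chicks show a
pre-fledging mass recession): raw mass on day 14–16, peak mass, fledging
mass (the last measurement), mass recession (peak − fledging), peak day,
fledge day, and two Specific Growth Rates, SGR1 (day 14–16 mass → peak) and
SGR2 (peak → fledging). The SGR formula is implemented in two conventions:
`paper_literal`, $(\ln m_2 - \ln m_1) / ((t_2 - t_1) \times 100)$, and the
textbook `percent_per_day`, $100 (\ln m_2 - \ln m_1)/(t_2 - t_1)$. They
differ by exactly $10^4$; because all growth variables are Z-scaled before
the PCA, the choice provably cannot change the PCA or the models, and the
convention is recorded in the output. Peak-mass ties resolve to the earliest
day. With nest checks every ~3 days the fledge day is interval-censored; it
is taken as the midpoint between the last day the chick was seen and the
first day it was missing (after day 21), or as the last measurement day plus
a configurable 1.5-day offset when no check data exist.

The indicators are strongly inter-correlated, so they are Z-transformed and
reduced by PCA (complete-case rows; zero-variance columns dropped with a
warning); the first two component scores serve as the body-condition
responses. Four linear mixed models (maximum likelihood, breeding pair as a
random intercept, fitted with `lme4`/`lmerTest`) then ask: (a) does
coordination change with chick age, (b) does higher coordination mean lower
relative interval CV, and (c, d) do coordination or interval CV predict body
condition, controlling for the number of feedings per session? The
denominator-df method for the F tests (Satterthwaite by default) is
configurable and reported, and singular fits are flagged rather than
silenced.

## The synthetic-data generator

`simulate_corpus()` generates data with the statistical structure the
analysis assumes, so every stage is testable without field data. Each bird
alternates colony bouts and foraging trips in continuous time, simulated
jointly for the pair from a 24-h lead-in so sessions begin mid-behaviour and
boundary-truncated trips arise naturally. Defaults mirror the study system:

* colony bouts: truncated log-normal on 10–80 min with mean 49 min (the
  log-normal shape within those constraints is a free choice; the `meanlog`
  is solved numerically so the *truncated* mean hits 49);
* trip durations: log-normal with arithmetic means 1.9 h (ST, log-SD 0.5)
  and 12.8 h (LT, log-SD 0.4), rounded to whole 10-min windows so generator
  and pipeline share one resolution;
* sessions: 48 h on a 10-min grid; 25 pairs with 1–5 sessions each
  (median 3, ≈79 pair-sessions); session-mean chick ages from ~9 to ~25
  days;
* trip-type choice: at each trip start the trip is long with probability
  $p_{LT}(1 - \kappa \cdot [\text{partner on LT}])$. The baseline
  $p_{LT} = 0.25$ puts the long-trip share of trips at one in four —
  roughly one completed LT plus several ST per bird per 48 h, a realistic
  dual-foraging budget in which LTs are rarer but dominate time at sea.
  $\kappa$ is the coordination coupling: $\kappa = 0$ gives independent
  birds (the calibration null), $\kappa = 1$ forbids starting an LT while
  the partner is on one. The package default $\kappa = 0.6$ represents the
  moderately coordinated regime the analysis is designed to detect;
* chick mass: a logistic rise to a peak near day 20 followed by a linear
  recession to fledging between days 23 and 30, sampled every 3 days from
  day 13/14 with Gaussian measurement noise (SD 3 g); `growth_effect_beta`
  optionally shifts peak mass down in proportion to the chick's mean
  interval CV, building in a true coordination–growth link for power
  checks. The generator's ground truth for "peak mass/day" is defined on
  the measurement grid, since a 3-day weighing cadence cannot see the
  continuous-time maximum.

A trip flush with a session boundary is emitted as observationally
truncated: the adjacent colony attendance falls outside the recorded
windows, so the pipeline cannot (and should not) distinguish it from a trip
that genuinely continued.

What the generator deliberately does **not** emulate: weather and
oceanographic forcing of trip durations, between-individual heterogeneity
in trip-duration distributions, serial dependence of trip types within a
bird (types are independent draws, matching the null the test assumes),
observation error in presence scoring, and partial-window colony visits
(durations are generated in whole windows; a real bird present for part of
a window is recorded as present). Passing calibration on these data
therefore shows the engine is exact for sequentially independent foragers;
it does not rule out miscalibration on data whose trip sequence is serially
dependent for reasons other than partner coordination.

## Numerical and scale choices

Test-suite simulations use 1,000 sessions at 1,000 iterations for size
checks and 500 sessions at 500 iterations per coupling level for power
checks; the end-to-end corpus runs 2,000 iterations per session, and the
acceptance script runs the full 10,000. These sizes put Monte Carlo error
well below the margins being asserted while keeping the whole suite fast on
one CPU. Degenerate sessions (a bird with no usable trips, or fewer than
three feedings for the CV test) are flagged and excluded from combination
rather than forced to a p-value. All randomness flows through R's seeded
RNG; a seed plus identical inputs reproduces every null sample bit for bit.

## Known limitations

* The 10-minute grid quantises everything; durations are only ever known to
  ±10 min, and two feedings inside one window are indistinguishable.
* The desertion rule (≤1 female feeding) and the truncation masking both
  discard information; with many masked spans a session's null can become
  very coarse, which the exact-enumeration oracle handles but real
  inference should treat with caution (the `p_mc` rule stays valid, merely
  conservative).
* The mixed-model stage is a thin contract over `lme4`: it reports, but
  does not remedy, singular fits on small corpora.
* Study-level aggregation over sessions vs over pairs is a genuine
  ambiguity; both numbers are always reported.
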