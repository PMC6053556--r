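---
title: "Monitoring a cryptic calling bird with acoustic recorders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring a cryptic calling bird with acoustic recorders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boomr)
```

## The monitoring problem

Male Australasian bitterns advertise with sequences of low-frequency
"booms". Because the birds are visually cryptic and their wetlands are
large and hard to access, population monitoring rests on *call-counts*:
fixed-duration (15-min) watches at stations several hundred metres apart
during which every call sequence is logged. A field observer additionally
judges, call by call, how many distinct birds are calling. Autonomous
recorders (single-channel "mono" units and two-microphone "stereo" units,
each processed either visually on spectrograms or audibly in real time)
promise the same call-count index at far lower cost — provided their counts
can be calibrated against observer counts, and provided the loss of the
observer's individual-discrimination ability is understood and priced.

`boomr` packages that whole chain: a synthetic survey generator, the two
rule-based individual estimators, the device-versus-observer calibration
statistics, the itemized cost model, and a permutation-based power tool.

## The synthetic survey model

No field data ship with the package (the original records sit in agency
archives), so all statistical behaviour is exercised on simulated campaigns
whose structure mirrors a real paired deployment.

**Birds.** `simulate_population()` places `n_birds` agents at bearings
uniform on a configurable arc (default the full 360°; a recorder on a
straight wetland edge would use 180°) and distances uniform on 100–1000 m.
Each bird has a Gamma-distributed expected call rate (default mean 3
sequences per 15-min session, shape 4 — modest between-bird heterogeneity)
and a characteristic booms-per-sequence count drawn once per bird from a
shifted Poisson `1 + Poisson(boom_mean - 1)` (default mean 3).

**Why stereotyped boom counts?** Field observers use boom count as an
*individual* cue: the criterion "consistently had a different number of
booms" is only informative if a given male repeats roughly the same
sequence length. We therefore make the per-bird count fixed within a
session by default; `boom_jitter_p` reintroduces per-call variation for
stress-testing. Making boom counts i.i.d. per call instead would
contradict the field criterion and lets a single bird masquerade as two,
violating the minimum-count interpretation of the estimator.

**Emission and detection.** Per session each bird emits
`Poisson(call_rate)` sequences at uniform times in the 15-min window. Every
emitted sequence is then detected independently on each requested channel
(OBS, MONO, STEREO) with the channel's probability from
`detection_spec()` — a scalar or a declining function of distance. Detected
copies carry:

* a bearing jittered by a wrapped normal (`bearing_noise_sd`, default 5° —
  chosen so the observer criteria's 10° threshold can be stressed from
  both sides);
* a volume class derived from physics: received level
  `loudness / (distance/100)²` is cut at `volume_cuts` (default 0.04 and
  0.25, i.e. roughly beyond 500 m → `low`, 200–500 m → `med`, closer →
  `high`), optionally misclassified to an *adjacent* class with probability
  `volume_misclass_p` (a listener may confuse `med` with `low` or `high`,
  never `low` with `high`);
* the bird's boom count;
* for STEREO, a left/right ear from the true geometry via
  `stereo_channel_of()`: bearings strictly in the half-plane left of the
  recorder heading map to `left`, everything else — including bearings
  exactly on the heading axis — to `right` (a documented, tested
  tie-break).

**Campaigns.** `simulate_campaign()` reproduces the paired-deployment
bookkeeping: 43 sessions with all three channels, 80 with observer + mono,
14 with observer + stereo (137 total), cycled over 40 stations. The number
of birds audible per session is `Poisson(2.5)`: with that default a
session with more than six callers occurs roughly once or twice per
137-session campaign, matching field experience that more-than-six counts
are rare but real. Session call-count distributions at any particular
wetland are not publicly documented, so these defaults are illustrative of
a moderately dense population rather than calibrated to one site; they were
fixed once, before any calibration experiment, and the package's tests do
not depend on their precise values except where stated.

**What the simulator does not emulate**: temporal and weather-driven
variation in calling rate within and between nights, bird movement within
a session (bearings are fixed per bird), observer-specific biases and
fatigue, correlated detection failures (wind gusts masking all channels at
once), and any acoustic-propagation detail beyond inverse-square loudness.
Passing tests therefore demonstrate the *algorithms* behave as specified,
not that any particular wetland will show slope 0.9 or six callers.

## Counting individuals

### Field-observer criteria

`assign_observer()` streams calls in time order against a growing set of
candidate birds (clusters). A call founds a new bird only if **no** cluster
accepts it; a cluster accepts when all three cues are compatible:

1. **Bearing**: circular difference to the cluster's reference bearing (the
   running circular mean of member bearings) at most
   `bearing_threshold_deg` (default 10°). A literal reading of the field
   rule — new bird if >10° from *any* previous call — would split almost
   every pair of calls; the cluster reading below matches the rule's
   intent of separating birds, not calls.
2. **Volume**: the call's class already seen in the cluster; or — the *soft
   start*, on by default and switchable off — the cluster has a single
   member, the class is adjacent, and the bearing difference is within half
   the threshold. The soft start prevents a borderline `low`/`med` judgment
   on a bird's second call from spuriously doubling it.
3. **Booms**: the call is rejected only on *consistent* evidence — the
   cluster must already hold at least two calls and the call's boom count
   match none seen there. One observation is never "consistent".

If several clusters accept, the nearest by bearing wins (ties to the lowest
cluster id). Calls sharing a timestamp are processed in a canonical order
(bearing, then volume, then booms) so that input order cannot change the
result. Where uncertainty exists the call merges, so the estimate is a
*minimum* number of individuals: on zero-noise simulations the estimate
never exceeds the true number of callers (a tested property).

### Stereo-audible criteria

`assign_stereo_audible()` implements what a listener can do with two ears
and no bearings: a call is a new bird iff its (volume class, ear)
combination is new. With three volume classes and two ears the estimator
can never report more than `distinguishable_capacity(3, 2) = 6` birds —
the ceiling binds exactly when callers are numerous and the estimator
saturates, which is why crowded sites undercount on stereo recordings.

## Calibration statistics

Counts from 15-min sessions are small, skewed and tie-rich, so association
is measured by Spearman's rank correlation with averaged ranks
(`spearman_cor()`, delegating to `stats::cor.test(..., method =
"spearman", exact = FALSE)`): the p-value uses the t approximation
`t = ρ√((n−2)/(1−ρ²))` on `df = n − 2`, standard for n > 10. Fisher's
transformation `z = atanh ρ` is reported alongside. Degenerate pairings
(a margin with zero variance, e.g. every session single-bird) yield a
flagged undefined ρ rather than an arbitrary number.

The device-versus-observer slope is fit through the origin
(`through_origin_fit()`, via `lm(y ~ 0 + x)`): zero observer calls should
predict zero device calls, and the slope then estimates the per-call
detection ratio — a property the tests verify by simulation (a mono channel
detecting 67% of calls calibrates to slope 0.67 ± Monte-Carlo error). The
slope SE uses residual df `n − 1` and the CI the matching t quantile
(a normal multiplier is available by explicit argument). Reference CIs
computed from the original field data cannot be reproduced without those
data; no test pretends otherwise.

`calibration_table()` assembles one row per option. In simulated campaigns
the visual/audible distinction is carried by the detection probability
assigned to the device channel, so both processing options of one device
map to the same channel unless the user simulates them separately with
different `p_detect`.

## The cost model

`line_item_costs()` itemizes, per option and year: purchase (year 1 only),
sound-file processing or field counting, deployment, travel wages to/from
and around the site, programming (for observers: pre-occasion briefings),
and vehicle running. Defaults (`default_options()`, `cost_rates()`,
`monitoring_design()`; also shipped as
`inst/extdata/cost_defaults.yaml`) encode the published reference schedule
for a 40-station × 6-night × 2-year bittern programme at NZ$25/hr wages
and NZ$0.77/km mileage, and the engine reproduces that schedule cell for
cell — the acceptance tests assert all 85 display cells.

Numerical conventions worth stating:

* **Rounding**: all accumulation is unrounded; display rounds half *away
  from zero* (112.5 → 113, 37.5 → 38). Totals are rounded after summation,
  which is why the observer option's displayed year total (25,821, from
  25,821.47) is one dollar below the sum of its displayed line items
  (25,822). `percent_saving()` compares unrounded cumulative costs and
  rounds the percentage for display: 73% for mono-visual versus observers,
  46% for stereo versus observers.
* **Calibration-to-schedule choices**: the reference schedule is not fully
  derivable from its own stated assumptions, and where the two conflict we
  reproduce the schedule and expose the knob. Mono options charge one
  return trip as wages but two as vehicle kilometres
  (`wage_trips_per_year = 1`, `vehicle_trips_per_year = 2`); stereo
  deployment accrues once per year with the per-occasion servicing burden
  carried by per-occasion programming; the stereo year-two vehicle figure
  uses an override of $554 (the computed value would be $600.60); observer
  deployment accrues once per year. All four are plain
  `option_assumptions()` parameters a user can change.
* Observer field-counting time follows the design's count duration
  (15 min → 0.25 hr per session), so shortening counts propagates into the
  observer option's costs automatically.

`value_matrix()` records the qualitative side: every option indexes
call-rate easily; only stereo-audible processing can estimate numbers
(with work, and capped at six); only observers engage the public.

## Power for the stations × occasions design

`estimate_power()` asks: under the survey model, how often would a
two-sample comparison of session counts detect a proportional change in
calling rate? Each replicate draws two campaigns of
`n_stations × n_occasions` session totals — using
`simulate_session_counts()`, the exact Poisson-thinning marginal of the
full session simulator (a tested equivalence), since only totals enter the
test — and applies `permutation_mean_diff_test()`: a two-sided permutation
test on the difference in means with the observed statistic included in
the reference set, so p ≥ 1/(n_perm + 1) and the test is exactly valid
(slightly conservative under ties). A permutation test was chosen over a
parametric model because session counts are over-dispersed, tie-rich and
non-normal, and because it keeps the power tool assumption-free beyond
exchangeability. Exhaustive enumeration is available for tiny groups.

The default problem sizes — 500 Monte-Carlo replicates of 240-session
campaigns with 199 permutations per test — put the Monte-Carlo SE of a
power estimate near 0.02 while keeping a full run in the tens of seconds;
the unit tests use smaller grids of the same machinery. Under the default
baseline (3 detected sequences per session) the 40 × 6 design has power
well below 0.8 for a ±10% change; the variance structure behind any
published power claim for a specific wetland (between-station and
between-night components) is not reconstructible from public sources, so
this module is a transparent re-derivation tool, not a reproduction of any
particular figure.

## Known limitations

* The observer-criteria estimator resolves genuinely ambiguous field
  judgments with fixed documented tie-breaks; real observers may differ,
  and drifting (moving) birds are handled only through the running
  circular-mean reference bearing.
* The stereo estimator inherits the six-bird ceiling and, like the field
  method, is sensitive to the subjective volume classification; between-
  processor variability is not modelled.
* Costs are unitless "NZ$-like" figures with no discounting, uncertainty,
  or exchange-rate handling; rankings, not absolute values, are the
  intended output.
* The simulator's defaults describe a plausible moderately-dense wetland,
  not a fitted model of any site.
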