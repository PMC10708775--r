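---
title: "Interval-consistency monitoring of wearable vitals: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-consistency monitoring of wearable vitals: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdvitals)
```

# The problem

Wearable vital-sign sensors in a dense crowd produce noisy streams: genuine
health deterioration shows up as *saturation* — the signal pinned outside
the clinical band for a sustained stretch — while motion artifacts and brief
sensor glitches show up as *fluctuation* — short spikes that immediately
revert. A surveillance system that alarms on every out-of-range reading
drowns in false alerts; one that smooths aggressively misses infections.
`crowdvitals` implements an interval-consistency pipeline that separates the
two regimes, checks fluctuating data over a *series* of intervals before
judging anyone abnormal, and couples the health decision to proximity
alerting and device-discharge estimation.

# The assessment model

Streams are cut into non-overlapping sensing intervals of `interval_length`
readings (default 10; a trailing fragment shorter than half an interval is
discarded, longer fragments are kept). Per interval:

* **SId** counts readings with every vital inside the clinical band minus
  readings with any vital outside. We read the population-level
  non-infected-minus-infected sum as a per-interval evidence score because
  the assessment is applied per person per interval; a single
  population-wide number could not drive personal recommendations.
* **PSId** is the person's healthy baseline: per-vital running means updated
  *only* from intervals the correlation stage judged normal, so it is always
  a convex combination of healthy window means. For comparability with SId
  it is scored as a virtual interval of `interval_length` readings pinned at
  the baseline means (`+interval_length` while those means stay clinical).
* **Δsf** `= (1/2π) · r² · (SId − PSId)²` with `r` the out/in reading-count
  ratio of the interval. The `1/2π` factor is kept literally; the inner
  summation is absorbed into the squared deviation because the per-index
  form is not well defined for a single interval.
* **X** counts *pinned* out-of-range readings: the reading is outside the
  band and every vital moved less than its noise floor since the previous
  reading (defaults 0.5 % SpO2, 2 bpm, 0.1 °C — roughly twice the default
  per-reading noise standard deviation, so honest noise rarely breaks a
  genuine plateau). The first reading has no predecessor and never counts.
* **Y** `= |(1/ε_id) · Σ(SId_i − PSId) · (Cint_min − In_Cint_max)² /
  max(Δsf − 1, ε)|` over the supplied windows. In the pipeline each
  interval's Y is the single-window evaluation with its own Δsf; the
  multi-window form is exposed for series-level use. One wearable per
  person, so the device count `ε_id` is 1.
* **Norm(SId)** `= X²·(Cint_min/In_Cint_max) − Y²`: saturation pushes the
  normalized score up, fluctuation down. The calibration bounds default to
  `Cint_min = 2`, `In_Cint_max = 5` — unitless interval-count bounds on
  consistent/inconsistent fluctuation; only their ratio (0.4) and difference
  (−3) enter the statistics, and the defaults keep `Norm(SId)` of a fully
  pinned interval (X = 9 at the default window length) an order of magnitude
  above the decision threshold.

The interval-series statistic chains the per-interval ratios
`Norm(SId)_i / SId_i` with the baseline-correlation closer
`(1 − PSId/(SId·X))²` as a root sum of squares; the printed radical chain we
implement admits other groupings, and this reading is the one that keeps the
statistic monotone in each squared term.

# Classification and correlation

The forest inputs are `M = SId, N = 0` for a person's first interval and
`M = Norm(SId), N = Y/X` afterwards, so `M + N` reproduces the interval
input exactly — an identity asserted continuously in the tests. The
probability forest (200 trees, class-balanced weights, fixed seed, single
thread for determinism) is trained on intervals overlapping ground-truth
events: artifact ⇒ fluctuation, sustained drift ⇒ saturation. Intervals with
no event are not training material, because the label set of the
classification result is exactly {saturation, fluctuation}; at predict time
every interval receives the fluctuation-class probability `∃O`. When a run
has fewer than two event classes a self-supervised fallback labels intervals
by the abrupt-change flag. For real data, that fallback is the documented
extension point.

The correlation stage smooths the label history with add-one counts,
`ρCint = (n_sat + 1)/(n + 2)` and `ρIn_Cint = (n_fluct + 1)/(n + 2)` — the
estimation rule is otherwise unspecified and the smoothing is the minimal
choice that keeps `σO = 1 − ρCint/ρIn_Cint` finite. The branch condition
`σO > Y/X` is re-evaluated each interval, with ties falling to the lower
branch. The two recursions deliberately live on different scales: the upper
branch subtracts the previous `Y/X` and probability ratio from
`Norm(SId)_i`, which grows large and **positive** under sustained
saturation; the lower branch subtracts `N·SId·X` and the previous
out/in-count ratio (our reading of the per-interval infected/non-infected
ratio — it is the only quantity of that name available at runtime) from
`SId_i`, which goes strongly **negative** under out-of-range evidence.

## The status decision

Because the branches have opposite polarity, a single one-sided cut cannot
serve both. `decide_status()` therefore takes the abnormal side as
`> +threshold` for upper-branch outputs and `< −threshold` for lower-branch
outputs (threshold 1.0: comfortably above the `≈ −ρ ratio` noise of healthy
upper-branch outputs and below the `≈ +SId` level of healthy lower-branch
ones), and requires the last `K = 2` consecutive outputs on the abnormal
side — the operational meaning of verifying consistency over a *series* of
intervals. No single-interval alarm is possible at `K = 2`.

False-rate mitigation applies the M-property `SId + σO·∃O_i` as the
corrected score wherever the `σO > Y/X` gate is open; the corrected score
lives on the SId scale, so those intervals are re-tagged to lower-branch
polarity. Closed-gate intervals are untouched — mitigation can never flip
them, an invariant the tests assert.

A person is judged infected when at least half of their assessed intervals
carry abnormal status — with ~20 intervals per run this tolerates early
intervals spent accumulating history.

# Discharge, distance and recommendations

The raw discharge value follows the stated form — per-device
abnormal/normal count ratio times the device count times
`|Cint_min − In_Cint_max|^(i−1)`, over the `(1 − σO)^(i−1)`-weighted device
sum — with the numerator base in absolute value, since a negative base would
alternate the sign of a probability with the interval index. The raw values
are then explicitly renormalized over the active device set so that
`Σ ρhwdc = 1` exactly; after that normalization the device-independent
factors cancel and the distribution reduces to the devices' count-ratio
shares, which we state openly rather than hide. The set over which the sum
runs is read as the active wearable devices (the alternative, summing over
intervals, is noted but not adopted). `ω = 0` (not operating) when a
device's share exceeds 0.5 or its battery is below 5 %.

Threshold-distance violations (default 2.0 m, the public-health distancing
convention; the method itself fixes no value) are detected per interval with
a uniform grid of threshold-sized cells compared to 3×3 neighbourhoods; the
grid output is *exactly* the brute-force all-pairs scan, an equivalence the
acceptance tests check on random crowds of 100–500 people. Only pairs with
at least one currently-abnormal member raise alerts. Recommendations are
coded identifiers (`isolate` when saturation dominates the interval,
`psid_with_sid` for the baseline-review path on an operating device,
`maintain_distance` for violation counterparts, `replace_device` when
`ω = 0`, which suppresses the health recommendation); no message text is
prescribed beyond the codes.

The iterative consistency check recomputes `σO` from the smoothed counts
and, while `σO > Y/X`, performs the μ fluctuation function and records the
re-checked interval as consistent — which raises `ρCint` and strictly lowers
`σO`, so the loop provably reaches `σO ≤ Y/X`; a cap of 100 iterations
guards degenerate states and sets a divergence flag instead of looping.

# What the simulator emulates — and what it does not

The generator draws healthy baselines uniformly from adult resting ranges
(SpO2 97–99 %, pulse 60–100 bpm, temperature 36.5–37.2 °C) and shifts
infected baselines by −6 SpO2 points, +20 bpm and +1.5 °C — deep enough into
the abnormal band that the separability assumption of the end-to-end
recovery checks holds by construction. Motion is a random waypoint walk at
0.5–1.5 m/s in a 50 × 50 m arena; artifacts are 1–3-reading sign-alternating
spikes at 2 per 100 readings; drifts last at least one full interval at 1
per run; readings drop out at 1 % and batteries decay linearly at 5×10⁻⁴
per reading. Blood pressure is deliberately absent from the default vital
set (the assessment discussion uses oxygen, pulse and temperature only);
the schema is extensible per vital.

Passing tests on this substrate show the pipeline's *mechanics* are right —
they do not show field performance: real wearables have autocorrelated
noise, posture- and perfusion-dependent artifacts, gradual onsets rather
than step shifts, and mobility far from a random waypoint walk. Infection
status is static within a run; there is no transmission model, and no
image-based crowd counting.

# Numerical choices

All divisions share one configurable guard `ε = 10⁻⁹`; every activation is
counted by call site (`guard_log()`), never silently absorbed. The
`Δsf − 1` denominator of Y is genuinely sign-indefinite and is the most
frequent guard site; fully pinned intervals also activate the out/in-count
guard. Degenerate inputs fail loudly: empty streams, empty windows, empty
device sets and single-class training sets are errors, not defaults.
Boundary ties resolve conservatively — abrupt-change detection uses strict
inequalities, and the branch condition's tie falls to the lower branch.
Seeds for every stage are derived from the master seed with a
Lehmer-style mixing of a per-stage salt, kept below 2³¹.

# Problem sizes

The shipped checks use 10,000 evaluation intervals (2,000 training) for the
symmetric-null fraction, 100–120 random inputs per statistic for the
oracle-equivalence suites, 50 random crowds of 100–500 people for the
grid/brute-force equivalence, and a 200-person, 200-step crowd for
end-to-end recovery — sizes at which every property is stable across seeds
while the whole suite runs in well under a minute on a single core.

# Known limitations

* The lower-branch recursion mixes the SId count scale with a probability
  ratio, and the upper branch subtracts a probability ratio from a
  normalized signal; both are retained as stated, and the branch-aware
  polarity of the status decision is the package's own resolution of the
  scale mismatch.
* After normalization the discharge distribution carries no information
  from `σO` or the calibration bounds (they cancel); the raw value is
  returned alongside for inspection.
* The fluctuation-rate metric reports the share of fluctuation-flagged
  intervals without an injected artifact; with event-trained forests most
  healthy no-event intervals fall into the fluctuation class by design, so
  the metric should be read as "re-check traffic", not as an error rate.
* The forest's self-supervised fallback (abrupt-change labels) is untested
  against real wearables and is the first thing to replace when moving off
  synthetic data.
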