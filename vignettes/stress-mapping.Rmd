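---
title: "Detecting and mapping moments of stress from wearable campaigns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and mapping moments of stress from wearable campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmapr)
```

## The measurement model

Skin conductance (GSR, in microsiemens) rises within seconds when the
sympathetic nervous system is aroused; peripheral vasoconstriction under
the same arousal produces a *delayed* drop in skin temperature (ST). A
"moment of stress" (MOS) is operationalized as the joint occurrence of
both signatures. Conductance is modelled as a slow *tonic* baseline — a
per-participant level drifting over minutes — with fast *phasic*
responses superimposed; only the phasic component is informative about
discrete stress events.

The pipeline has five stages, each exposed as ordinary functions:

1. **Ingestion** (`read_physio()`, `read_track()`, `read_diary()`): all
   sources are joined on absolute UTC time, which is the only key the
   heterogeneous devices share. GSR and ST are resampled by linear
   interpolation onto a common uniform grid (default 4 Hz, the native
   rate of the wristband sensors both channels come from; the rule's
   windows are defined in seconds and need a uniform grid).
2. **Filtering** (`preprocess_trace()`): a 0.5 Hz low-pass removes
   technical noise, then a 0.05 Hz high-pass removes the tonic baseline
   from GSR. ST receives the low-pass only, because the rule inspects ST
   extrema in absolute terms.
3. **Detection** (`detect_mos()`): the rule template below.
4. **Georeferencing** (`locate()`): time interpolation into the GPS
   track.
5. **Mapping** (`rasterize()`, `gi_star()`, `difference_map()`,
   `compare_campaigns()`): standardized rates on a metric grid, local
   hot/cold-spot statistics, sensor-vs-diary comparison, and pre-post
   campaign change.

## The detection rule

At candidate onset $t$ the rule fires iff all three clauses hold on the
filtered signals:

* **(a) sustained rise** — phasic GSR is non-decreasing over
  $[t,\,t+5\,\mathrm{s}]$, allowing per-step dips up to a tolerance
  (default 0.005 µS) that absorbs residual noise, with a strictly
  positive net change. This is deliberately stricter than "positive net
  change": a spike-and-recover shape does not count as five seconds of
  increase.
* **(b) slope** — the rise is steep enough:
  $\arctan\!\big(\tfrac{\Delta \mathrm{GSR}/\Delta t}{s}\big)\cdot
  \tfrac{180}{\pi} \ge 10^\circ$. An angle of a µS-versus-seconds line
  is meaningless without an axis scale, so the scale $s$ is an explicit
  parameter (default $s = 1\,$µS/s, i.e. 1 µS/s maps to 45°); the
  default makes the 10° criterion equivalent to a slope of
  $\tan 10^\circ \approx 0.176$ µS/s.
* **(c) delayed thermal response** — within
  $[t+3\,\mathrm{s},\,t+13\,\mathrm{s}]$ the smoothed ST contains a
  local maximum followed by a local minimum whose drop is at least
  `st_min_drop_degc` (default 0: any strict decrease).

A single physiological episode satisfies the sliding rule at many
adjacent onsets, so firings closer than 5 s (`merge_refractory_s`) are
merged, keeping the earliest onset and the steepest slope. Note that the
merged onset can precede the underlying ramp by up to half a rise
window: samples that are flat ahead of the ramp do not violate clause
(a), and clause (b) is already met once most of the ramp lies inside the
window. Detection-versus-truth matching tolerances should therefore not
be set below a few seconds.

Open parameters the rule statement leaves undefined — the length of the
ST search window after the 3 s lag (10 s), the minimum ST drop (0 °C),
and the consolidation of overlapping firings (5 s refractory) — are
declared defaults here, exposed in `mos_rule_config()`, not inferred
intent.

### Numerical conventions

* **Extrema with plateaus**: interior extrema are sign changes of the
  first difference with zero-runs skipped, so a plateau resolves to its
  earliest sample. At the search-window boundaries, a leading plateau
  followed by a decrease counts as a maximum at the window start, and a
  trailing decrease counts its end as a minimum. Without the boundary
  convention the canonical template (temperature flat, then falling
  shortly after the lag) would never fire, because the "maximum" of a
  flat-then-falling window is its edge.
* **Zero-phase filtering**: both filters are order-2 Butterworth designs
  applied forward–backward, so event timing is not biased by filter
  delay. The effective magnitude response is the square of the
  single-pass response; `filter_response()` evaluates it in closed form
  from the designed coefficients. Note that the designed *digital*
  filter, not the analog prototype, is the reference: at probe
  frequencies approaching Nyquist (e.g. 1 Hz at a 4 Hz rate) bilinear
  frequency warping makes the digital response visibly lower than the
  analog closed form $1/\sqrt{1+(f/f_c)^4}$, and measured attenuation
  matches the former, not the latter.
* **Edge handling**: series are extended by odd-symmetric reflection
  long enough for the zero-state startup transient to decay inside the
  padding (the pad length is derived from the slowest filter pole), so a
  constant input maps to a numerically exact constant and the high-pass
  rejects DC to machine precision.
* **Gaps**: source gaps ≤ 2 s are linearly interpolated and flagged;
  longer gaps split the trace into segments that are filtered and
  scanned independently, so the rule template never straddles unmeasured
  spans.

## Georeferencing and its confidence

Each detection (and each diary entry lacking coordinates) is located by
linear interpolation of longitude/latitude between the bracketing GPS
fixes. At walking speeds and 1 s fix intervals the straight-segment
assumption is benign; the residual GPS uncertainty is *surfaced* rather
than corrected, as a per-record confidence: `exact` (time coincides with
a fix), `interpolated` (bracketing fixes ≤ 10 s apart), `low` (wider
bracket, value still returned), `unlocatable` (outside the track span;
the record is kept). No map-matching to a street network is attempted.

## Grid, standardization, and the Gi* statistic

Counts alone mirror where people walked, not where stress concentrates,
so per-cell event counts are standardized by measurement density:
$x_j = n_{\mathrm{mos}}(j)/n_{\mathrm{meas}}(j)$, with cells holding
fewer than `min_support = 10` sensor samples excluded (rates from
near-empty cells are noise). The grid lives in an automatically selected
UTM zone (25 m cells by default, a city-block sub-scale; the origin is
snapped to a cell-size multiple so campaigns over the same area share
cell boundaries). Cell membership is half-open in both axes, making
edge-point assignment deterministic. The transverse-Mercator projection
is implemented with the Krüger series, accurate to well below a
millimetre inside a zone.

The local Getis–Ord statistic is computed per included cell $i$:

$$ z_i = \frac{\sum_j w_{ij} x_j - \bar{X} \sum_j w_{ij}}
  {S\,\sqrt{\frac{n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2}{n-1}}},
  \qquad S = \sqrt{\tfrac{1}{n}\sum_j x_j^2 - \bar{X}^2}. $$

Weights are binary, symmetric, self-inclusive (the "star"), from a fixed
distance band of twice the cell size between centroids — a conventional
choice; the neighborhood, grid resolution and significance thresholds
are all configuration decisions, as no canonical values exist for this
kind of campaign. Degenerate fields follow explicit conventions:
$S = 0$ (all rates equal) yields $z \equiv 0$, as does a cell whose
denominator vanishes because its band spans the whole study area.
Classification uses the standard two-sided normal thresholds
($|z| \ge 1.645, 1.96, 2.576$ for 90/95/99%). No multiple-testing
correction is applied by default, matching how such maps are usually
read as descriptive layers; `stats::p.adjust` can be applied to
`2 * pnorm(-abs(z))` downstream where inferential use is intended.

Diary fusion maps the four emotion qualities to a valence partition —
negative = {anger/disgust, sadness, fear}, positive = {happiness} — and
`difference_map()` compares min–max-normalized sensor and diary rate
fields (missing side treated as 0, constant fields normalizing to 0),
positive values marking cells where sensors see relatively more stress
than participants report.

Pre-post comparison reports $(\mathrm{post}-\mathrm{pre})/\mathrm{pre}
\times 100$ overall and per zone polygon; `exposure_rate` mode divides
counts by measurement-seconds first so unequal campaign sizes do not
masquerade as change. A zero pre-campaign statistic is an explicit
error, not an `Inf`.

## What the synthetic generator emulates — and what it does not

`generate_campaign()` produces every stream the pipeline ingests:
participants walk a route (default: a rectangular loop around a city
centre sized to the walk), pass stressor sites, and each passage plants
— with configurable probability — a stress response at a known,
annotated onset. The planted shapes are the *minimal* geometry
satisfying the rule: a linear GSR rise (default 1.5 µS over 5 s, a
16.7° slope clearing the 10° threshold with a wide margin even after
filtering losses of roughly a fifth of the net rise) followed by an
exponential decay (τ = 4 s), and an ST plateau, linear drop (0.3 °C
starting 3 s after onset) and recovery. White Gaussian noise (defaults
0.05 µS and 0.02 °C, the measurement-noise scale of wrist-worn sensors)
is added *before* filtering so the low-pass is exercised meaningfully.
Diary entries are emitted at stressor passages with probability 0.5,
negative-valenced, from the closed vocabularies.

For pre-post scenarios, `reduction_factor` thins the planted-event
*count* deterministically (`round(f * n)`, with a seeded choice of
which sites), so annotation rate ratios are exact by construction and
only sensor noise propagates into the recovered percent change.

Passing tests on this generator demonstrate internal consistency — the
detector recovers exactly what the template defines, the mapping is
count-conserving, seeded runs are byte-identical — not field validity.
Real electrodermal activity has variable SCR kinetics, motion artifacts,
electrode drift and non-Gaussian noise; real GPS has urban-canyon
multipath; real diaries are sparse and biased. None of these are
modelled, deliberately: the generator defines a ground truth, which real
data never supplies.

## Problem sizes and verification

The bundled tests and the acceptance script run entirely on generated
data, at sizes chosen to exercise every code path while staying
desk-scale: single-participant traces of 2000 s at 4 Hz with 50 planted
events for detector scoring (perfect recovery without noise; precision
and recall stay above 0.95 at the default noise); 200 random 8×8 grids
checking the vectorized Gi* against a literal double-loop oracle to
below 1e−9; 20 seed pairs for the planted 20% pre-post reduction
(recovered within ±3 percentage points on average; single seeds scatter
by ~2 pp because a handful of detection misses among 40–50 events moves
one campaign's count by 2–2.5%). The projection is validated against
geodesic distances from an independent geodesy library and meridian-arc
identities.

## Known limitations

* The rule is a fixed template; it does not adapt to per-participant
  response amplitudes, and the 10° criterion inherits the axis-scale
  convention discussed above.
* Interpolation in geographic coordinates and the absence of
  map-matching make individual event positions uncertain at the 5–15 m
  scale typical of consumer GPS; the confidence flag propagates, but is
  not used to weight the Gi* statistic.
* Diary entries enter the maps only through the valence partition;
  trigger categories and intensities are carried but not modelled.
* Percent-change comparisons assume comparable detection operating
  points between campaigns; if noise levels differ systematically
  between pre and post, rate changes confound with sensitivity changes.
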