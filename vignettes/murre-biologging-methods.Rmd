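---
title: "Processing geolocation-immersion-pressure logger data from diving seabirds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing geolocation-immersion-pressure logger data from diving seabirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`murrelog` implements the complete inference chain for combined
geolocation-immersion-pressure loggers of the kind deployed on Common
Murres (*Uria aalge*) at Northwest Atlantic colonies: daily positions
from light-derived twilights, activity and colony phenology from
temperature-gated wet/dry records, dive and dive-bout analytics from
8-s pressure records, parental-care stage delineation, kernel core
areas and sex overlap, and diet-tissue fractionation adjustment of
stable-isotope values. A seeded synthetic deployment generator with
full ground truth closes the loop: every stage of the chain is tested
by recovering what the generator put in.

## Solar geometry

All downstream modules share one solar model: declination and the
equation of time from the standard closed-form series in Julian
centuries (geometric mean solar longitude, mean anomaly, equation of
center, mean obliquity), giving geometric sun altitude without a
refraction term. The thresholds the pipeline uses (-3.44&deg;, -5&deg;)
already absorb apparent-horizon effects, so adding refraction would
double-count. Accuracy against an independent ephemeris is ~0.01&deg;,
far inside the 100-200 km positional error of threshold geolocation.
Diel phases are classified by altitude alone: day at or above 0&deg;,
night below -12&deg; (nautical), twilight between; the boundary
convention (0&deg; is day, -12&deg; is twilight) is fixed for
determinism. Twilight times are solved from the hour-angle equation
with two refinement passes evaluating the ephemeris at the event
itself; polar day/night return flags, never errors. All times are UTC
throughout; there is no local-time logic anywhere.

## Threshold geolocation and the sun-angle bias

Longitude comes from the twilight midpoint: local solar noon offset
from 12:00 UTC, corrected by the equation of time, at 15&deg; per hour.
Latitude comes from day length. For a threshold sun altitude $a_0$,
half-day hour angle $H$ and declination $\delta$,

$$\cos H = \frac{\sin a_0 - \sin\phi \sin\delta}{\cos\phi \cos\delta}.$$

Rather than inverting this closed form once, `estimate_latitude()`
solves for the latitude whose *forward-modelled* day length (via
`twilight_times()` at the same threshold) matches the observed
sunrise-to-sunset interval, by bisection on $\phi \in [-70, 70]$ to
1e-4&deg;. Day length is monotone in latitude away from the equinoxes,
so the root is unique, and the estimate/back-calculate round trip is an
identity to solver tolerance by construction. Within about a degree of
zero declination day length is uninformative and the solver raises a
typed degeneracy error instead of returning noise.

The loggers' onboard algorithm assumes a -3.44&deg; sun angle, but the
twilights it actually records correspond to about -5&deg;; the day
length it sees is therefore longer than its model expects, pushing
latitudes north before the autumn equinox (day length increases with
latitude when $\delta > 0$) and south in winter (the relation flips).
`recalculate_position()` undoes this: back-calculate the twilight pair
from the raw position at -3.44&deg;, then re-estimate latitude from
that day length at -5&deg;. Longitude, a pure timing quantity, is
unchanged to within rounding.

Track filtering removes, in date order: equinox-window dates (9 Sep -
9 Oct and 6 Mar - 6 Apr, endpoints inclusive, by calendar date),
positions outside an optional expected-range polygon (default: a
38-58&deg;N, 42-62&deg;W box), and fixes implying more than 500 km/day
relative to the previous *retained* fix (a greedy forward pass;
haversine distance, 6371 km mean radius). The reference-fix choice and
filter order are this package's own, since several orderings satisfy
the same description; the greedy pass makes filtering idempotent,
which the tests assert.

## Immersion activity and phenology

The immersion channel records a dry state every 60 s only while
ambient temperature is below 28&deg;C. Two consequences shape the
module. First, the channel contains *only* dry minutes; wet is the
complement. Second, leg-tucking — a swimming bird drawing its
instrumented leg into its plumage, dry but warmed toward body
temperature — is suppressed by the gate and never appears, so at-sea
dry events can be read as flight candidates without a temperature
test.

Dry events are maximal runs of consecutive records (`merge_gap_min`
defaults to 0: "uninterrupted" is read literally), with duration
(last - first) + 60 s. A calendar day is a colony-attendance day if it
intersects a dry event longer than 360 min, or a dry event longer than
60 min lying wholly in night at the colony (murres do not fly at
night); the two rules act as OR, with the qualifying event recorded in
an audit table. Departure is the last attendance day followed by at
least 14 days without attendance — the gap length is this package's
operationalisation of "the season ended", chosen long enough that
weather-driven absences of a few days never split the season — and
arrival is the first attendance day on or after 1 March.

## Dives, bouts and patch quality

Pressure is sampled every 8 s below 2 m, so surfacing appears as
absence: runs broken by gaps longer than 16 s are separate dives, kept
if maximum depth reaches 3 m, with duration (last - first) + 8 s and
the post-dive interval (PDI) measured to the next dive's start.
Bottom time follows the vertical-velocity rule: with
$v_i = (d_{i+1} - d_i)/\Delta t$, the bottom phase runs from the first
sample whose forward $|v| < 0.5$ m/s to the last sample whose backward
$|v| < 0.5$ m/s. Absolute value is deliberate — ascent velocities are
negative in this sign convention, and the bottom phase is the low-speed
span. Descent (ascent) rate is maximum depth over the time from dive
start to the first bottom sample (last bottom sample to dive end),
falling back to the maximum-depth sample when no bottom phase exists.
An independent brute-force velocity-scan oracle in the test suite
agrees exactly on 1000 random profiles.

Bouts are identified from the PDI distribution as a two-process
exponential mixture,

$$f(t) = p\,\lambda_f e^{-\lambda_f t} + (1-p)\,\lambda_s e^{-\lambda_s t},$$

fast = within-bout pauses, slow = between-bout gaps. The fit is
maximum likelihood with a deterministic multi-start (quantile-derived
initial values; no RNG, so results are reproducible without seeding)
over a parameterisation that enforces $0 < p < 1$ and
$\lambda_f > \lambda_s$. The bout-ending criterion is the weighted
density intersection,

$$t^{*} = \frac{\ln\!\big(p\lambda_f / ((1-p)\lambda_s)\big)}{\lambda_f - \lambda_s},$$

about 202 s at (p = 0.7, 0.02/s, 0.001/s). A fit is declared
single-process when the rate ratio collapses below 1.5, the weight
reaches a boundary, or the likelihood-ratio improvement over a single
exponential is below 12 (twice log-likelihood) — a margin chosen above
the null's occasional spurious-improvement tail while three orders of
magnitude below what genuine bout structure produces at the study's
sample sizes. PDIs above the criterion start new bouts; per-dive PDI
summaries exclude intervals over 25 min, while bout fitting uses all
intervals.

The index of patch quality scores bottom time against what a dive of
that depth should last: IPQ = bottom time / $\hat D(\text{depth})$,
with $\hat D$ a linear duration-on-depth fit to the same dataset
(depth and duration are nearly collinear in murres). The exact
published formulation this index descends from is not fully specified
in the methods literature we implement against, so the scoring
function is pluggable; the default satisfies the defining contract —
strictly increasing in bottom time at fixed depth — and is what the
tests pin down. Only dives in bouts of at least two dives are scored
(isolated dives carry surface pauses unrelated to foraging), and bouts
are summarised as mean IPQ.

## Stages and offspring independence

Bi-parental care (BPC) runs from deployment to colony departure for
males and to one week before departure for females, who keep
attending the colony after the male-chick pair leaves. Male-only care
(MOC) starts at departure; no parental care (NPC) is 1 November to
31 January, truncated by the log.

Offspring independence is read off the convergence of male daily dive
effort onto the female level: the first date after departure at which
the male's 5-day centred rolling mean stays at or below the pooled
female mean + 1 SD for 7 consecutive days. The rolling window, the
+1 SD margin and the 7-day persistence are this package's
operationalisation of a convergence the source material describes only
qualitatively; all three are arguments. A centred window keeps the
detection lag small (about +2 days, which dominates the method's bias).
The search is bounded at 31 October of the departure year: from
1 November winter effort rises for both sexes, so the female
male-only-care reference stops being a valid benchmark, and without
the bound a late-independence male could structurally never resolve.
Males whose effort never converges inside the searchable window are
returned unresolved, not guessed.

## Core areas and overlap

Positions are pooled by sex within stage, projected with a Lambert
azimuthal equal-area projection centred on the pooled centroid
(equal-area is what makes km&sup2; and overlap ratios defensible), and
smoothed with an isotropic Gaussian kernel onto a 50-km grid whose
cell edges are anchored to a shared origin so independently fitted
distributions overlay cell-for-cell. The bandwidth minimises the
closed-form least-squares cross-validation score over 30 log-spaced
candidates spanning 0.1-3 times the bivariate Silverman reference
bandwidth; a minimum on the candidate boundary (the classic degenerate
LSCV profile) falls back to the reference bandwidth with a warning.
The 50% core area is the smallest set of highest-density cells
reaching half the probability mass. Directional overlap is
HR(f,m) = A(f,m)/A(f) and its mirror image; because a single printed
overlap per stage is ambiguous between the two directions and their
mean, all three are always reported.

## Isotopes

Diet-tissue fractionation offsets (secondary coverts 3.7/1.9,
breast feathers 3.6/2.5, whole blood 2.63/0.37 permil for
&delta;&#8321;&#8325;N/&delta;&#8321;&#8323;C) are subtracted from raw
values — an exact affine shift, kept invertible by preserving the raw
columns. Tissues map to stages by their growth and turnover timing:
blood (~2-week turnover) to BPC, secondary coverts (grown over the
post-fledging moult) to MOC, late-winter breast feathers to NPC, the
last standing in for the whole winter because no live-sampled tissue
reflects early winter. Group summaries (mean, n-1 SD, n by sex and
stage) are emitted as tidy tables; inferential modelling is left to
the caller's statistics environment.

## The synthetic generator

`scenario_config()` fixes the study conditions; its defaults are the
conditions the pipeline was built around, not tuning knobs: colony at
47.27&deg;N 52.77&deg;W; male colony departure drawn around mid-August
with the female departing about 7 days later; offspring dependence
N(62.8, 8.9) days; daily effort targets of about 96 (independent
female) versus 174 min/day (single-parenting male) during male-only
care, with near-equal sex levels in the other stages; dive depths by
sex and stage (e.g. 35.5 m female vs 48.6 m male in MOC); PDI mixture
(0.7, 0.02/s, 0.001/s); twilight timing noise of 2 min SD — a typical
threshold-geolocation twilight error, stated here because the source
conditions do not quantify it.

What it emulates, per channel: *positions* — a bounded drift-plus-noise
daily walk (colony-bound in BPC, offshore in MOC, winter area in NPC)
whose twilights are observed at -5&deg; plus noise and then
misinterpreted by the onboard -3.44&deg; assumption, reproducing the
fall-north/winter-south bias; *immersion* — overnight colony
attendance bouts on every colony night, short daytime flights at sea,
temperature-suppressed leg-tucks present only in the truth schedule;
*pressure* — dives in mixture-structured bouts with bout-level
rich/poor patch-quality multipliers on a depth-dependent bottom-time
baseline, rendered at 8-s cadence below the 2-m threshold, with each
day's dives accumulated until the day's effort target is met (so
configured effort is rendered to within one dive).

Rendering choices that are placement, not statistics: sessions start
near dawn and rendered between-bout gaps are capped at 1800 s so a
day's diving stays inside its UTC day; PDIs are snapped to the 8-s
grid with a 24-s floor so consecutive dives remain separable. The
recovery checks that quantify mixture-parameter bias therefore sample
the mixture directly rather than through the renderer. A
daily-resolution channel (`simulate_daily_effort()`) draws accumulated
dive time per day without rendering profiles; cohort-scale stage
analyses use it, full rendering being reserved for dive-module closure
and effort calibration.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: light-curve shading and weather-driven
twilight outliers (noise is clean Gaussian), pressure-sensor drift,
behavioural states beyond the four modelled, individual heterogeneity
in effort targets, and any coupling between position and dive
behaviour. Recovery rates on synthetic data are upper bounds on
real-data performance.

## Problem sizes and reproducibility

The shipped checks run at the scales the method descriptions imply:
a 150-day track for geolocation closure; 50 replicates of 2000 PDIs
for bout-criterion recovery; 1000 random profiles against the
bottom-time oracle; 100 birds for phenology recovery (&plusmn;1 day,
&ge;95%); 50 males spanning true dependence 51-75 days (MAE &le; 3);
6 birds per sex over 30 days for effort calibration (ratio within 5%).
`scripts/acceptance.R --seed <int> --out <path>` recomputes all of
these from scratch through the installed package and writes them as
JSON; every random draw descends from the single `--seed`.

## Known limitations

Latitude is unavailable near equinoxes by physics, not implementation;
the pipeline flags rather than fills. The latitude solver's
hemisphere/root handling assumes regional (single-hemisphere) tracks.
The kernel estimator is a plain product-Gaussian KDE — no boundary
correction at coastlines and no Brownian-bridge use of the time index.
The independence estimator assumes a step-like effort drop; gradual
weaning inflates its lag. The IPQ baseline is refit per dataset, so
scores are comparable within, not across, datasets.
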