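# murrelog

Processing chain for combined geolocation-immersion-pressure loggers
deployed on diving seabirds, built around the annual cycle of Common
Murres (*Uria aalge*) at Northwest Atlantic colonies. The scientific
question this serves: how does parental care drive sex-specific
foraging in a monomorphic seabird whose male parent alone rears the
chick at sea after colony departure? Answering it from leg-mounted
loggers takes a chain of inferences, each of which this package
implements and tests:

- **Geolocation** — daily longitude from the twilight midpoint,
  latitude from day length via
  `cos H = (sin a0 − sin φ sin δ)/(cos φ cos δ)`; correction of the
  logger's onboard sun-angle bias (twilights back-calculated at the
  built-in −3.44°, latitudes re-estimated at the true −5°); track
  filtering (>500 km/day speed rule, equinox windows 9 Sep–9 Oct and
  6 Mar–6 Apr, range polygon).
- **Activity** — dry events from 60-s immersion records gated at
  28 °C; colony-attendance days (dry events > 360 min, or > 60 min
  wholly at night); colony departure/arrival phenology.
- **Dives** — dive detection (8-s sampling below 2 m, dives ≥ 3 m);
  bottom time by the 0.5 m s⁻¹ vertical-velocity rule; per-bird
  bout-ending criterion as the density intersection
  `t* = ln(p λf / ((1−p) λs)) / (λf − λs)` of a maximum-likelihood
  two-process exponential mixture of post-dive intervals; an index of
  patch quality (bottom time relative to the duration a dive of that
  depth should last) for within-bout dives; accumulated daily dive
  time; diel attribution (day ≥ 0°, twilight 0° to −12°, night < −12°).
- **Stages** — bi-parental care (deployment → departure; females
  −7 days), male-only care, winter (1 Nov – 31 Jan); offspring
  independence as the date a male's rolling daily effort converges
  onto the female mean + 1 SD for 7 consecutive days.
- **Home ranges** — LSCV-bandwidth Gaussian kernel utilization
  distributions on a 50-km equal-area grid; 50% core contours;
  directional overlap `HR(f,m) = A(f,m)/A(f)`.
- **Isotopes** — diet-tissue fractionation adjustment (blood
  2.63/0.37, secondary coverts 3.7/1.9, breast feathers 3.6/2.5 ‰ for
  δ¹⁵N/δ¹³C) and sex-by-stage summaries.
- **Synthetic deployments** — a seeded generator emitting every logger
  channel with full ground truth, so the whole chain is validated by
  recovery.

The methods vignette
(`vignettes/murre-biologging-methods.Rmd`) documents the models,
parameter choices and limitations; `analysis/01_simulate.R` …
`analysis/07_isotopes.R` walk the full workflow over a simulated
cohort, writing tables under `results/`.

## Worked example

Simulate a 6-bird cohort, run the full pipeline, and read the report:

```r
library(murrelog)
cfg <- scenario_config(seed = 42, n_females = 3, n_males = 3,
                       pressure_end = "2010-09-25", track_end = "2010-11-20")
dep <- simulate_deployment(cfg)
report <- run_pipeline(dep, pipeline_config(seed = 42))
report$phenology
report$dive_summary[, c("bird_id", "sex", "n_dives", "mean_depth_m",
                        "bec_s", "mean_bout_ipq")]
report$overlap
```

```
 bird_id sex departure_date arrival_date
     F01   F     2010-07-25   2011-05-17
     F02   F     2010-08-06   2011-05-11
     F03   F     2010-08-03   2011-05-13
     M01   M     2010-07-25   2011-05-13
     M02   M     2010-08-08   2011-05-20
     M03   M     2010-08-02   2011-05-11

 bird_id sex n_dives mean_depth_m    bec_s mean_bout_ipq
     F01   F    4353     35.87222 510.8931     0.4275150
     F02   F    3474     35.58156 479.1217     0.4338863
     F03   F    3722     35.55751 474.7949     0.4320831
     M01   M    5769     48.46770 386.5237     0.3794125
     M02   M    4481     48.78088 442.8709     0.3687465
     M03   M    4965     48.42871 404.6335     0.3752337

 stage n_f n_m area_f_km2 area_m_km2     hr_fm  hr_mf mean_overlap
   MOC   2   3      45000      40000 0.7222222 0.8125    0.7673611
```

Reading it: each bird's colony departure and spring arrival come from
its dry-event record; the dive table shows the configured sex contrast
during male-only care emerging from the raw pressure channel — males
dive deeper (≈48.5 m vs ≈35.7 m), carry their own bout-ending
criteria, and score *lower* patch quality (mean bout IPQ ≈0.37 vs
≈0.43) because bottom time does not keep pace with their deeper,
longer dives; the overlap row gives each sex's 50% kernel core area
(km²) and the directional and mean overlap of female and male core
areas during male-only care.

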