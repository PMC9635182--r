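---
title: "Winter biologging of diving seabirds: behaviour rules, energetics and thermal habitat states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winter biologging of diving seabirds: behaviour rules, energetics and thermal habitat states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wintermurre)
```

## The problem

Small diving seabirds such as thick-billed murres (*Uria lomvia*) overwinter
at sea in the Northwest Atlantic, where short days and near-freezing water
put them close to an energetic ceiling. Leg-mounted
temperature-depth-immersion loggers sampling every 10 s record enough to
reconstruct, for every bird-day: how long the bird flew, dove, rested and
swam; the sea surface temperature (SST) it experienced; its daily energy
expenditure; and — via a hidden Markov model on daily SST — which of the
region's thermal habitats (cold shelf water, warm basin water, warmer
North Atlantic water) it was using.

`wintermurre` implements that full chain as testable components, together
with a ground-truth simulator so every stage can be validated end to end
without access to any field data.

## Rule-based behaviour classification

All rules operate on maximal runs of samples; a "day" is the UTC calendar
day throughout (loggers record UTC and birds cross no fixed timezone
boundary at sea; using UTC keeps all birds comparable).

* **Dives** are maximal runs with depth ≥ 5 m. Duration is the sample count
  times the cadence — no sub-sample interpolation of the 5-m crossing, the
  simplest faithful reading of a 10-s sampled rule. A dive spanning
  midnight belongs to the date of its start.
* **Flight** is a dry run lasting ≥ 60 s whose maximum temperature stays
  below 7 °C (cold airstream on the exposed tag). A dry run whose maximum
  exceeds 7 °C is **rest** with the tagged leg tucked into the plumage,
  whatever its length. Because the two published rules use strict
  inequalities, a run whose maximum is exactly 7 °C is left in the
  swimming residual. Rest hours underestimate true resting because birds
  alternate the tucked leg; no correction is attempted.
* **Bird-detected SST** is the mean temperature over *at-surface* samples:
  wet, not diving, inside the day's in-dive temperature range (5th–95th
  percentiles, widened by 1 °C), and thermally stable — the temperature
  range within the centred 180-s window around the sample is below 0.5 °C.
  We evaluate the stability window as a centred rolling window at every
  sample (the stricter reading of "every 180-s period"), with window
  membership decided by timestamp so recording gaps shrink windows rather
  than borrow samples across them.
* **Budgets** are computed per sample and aggregated by day, so flight +
  dive + rest + swim always equals the day's recorded coverage exactly
  (24 h when gap-free). Recording gaps are excluded, never interpolated —
  interpolating a wet/dry flag would fabricate behaviour.
* **Dive timing** is classified into day (solar elevation > 0°), civil
  twilight (0 to −6°), nautical twilight (−6 to −12°) and night (< −12°),
  evaluated at the bird's mean daily position (average of dawn and dusk
  geolocation estimates, longitudes averaged on the circle). Each dive
  takes the class of its start instant. The published interval notation
  leaves boundary elevations ambiguous; we assign a boundary to the
  brighter class, a fixed rule that makes tests exact.

Solar elevation uses a standard low-precision (NOAA/Meeus class) geometric
algorithm, accurate to a few tenths of a degree over 1950–2050 — ample,
since twilight classes are degrees wide. No refraction correction is
applied; twilight definitions are geometric. Moon illumination is the
phase-angle illuminated fraction evaluated at 12:00 UTC on each date (a
single value per date is required and the evaluation instant is otherwise
unspecified; noon UTC is the middle of the data day).

## Energetics

Daily energy expenditure combines activity-specific costs:

$$\mathrm{DEE} = 508\,T_f + 3.64 \sum_d \left(1 - \frac{d}{e^{1.23}}\right)
  + (113 - 2.75\,\mathrm{SST})\,T_s + (72.2 - 2.75\,\mathrm{SST})\,T_r$$

with \(T_f, T_s, T_r\) in hours, each dive duration \(d\) in minutes and
SST in °C. The per-dive term is implemented exactly as printed even though
it turns negative for dives longer than \(e^{1.23} \approx 3.42\) min; the
count of such dives is attached to the result rather than silently
clipped, since the coefficient's published unit history is fragile and any
"fix" would be a different model. Days without an SST estimate get a
missing DEE (the equation requires SST; no imputation).

Apparent energy intake assumes energy balance over five days:
\(\mathrm{AEI} = (\mathrm{DEE}_5 / 0.73) / Td_5\), kJ per hour of diving,
where the subscript 5 denotes a 5-day moving average. We use a centred
window requiring at least 3 non-missing values: centred windows avoid
phase lag relative to the behaviour they smooth, and the minimum-count
rule retains days near track edges and isolated gaps.

## The habitat-state HMM

Daily SST per bird is modelled as a 3-state Gaussian hidden Markov model —
the smallest number of states giving non-overlapping distributions for
this region — with state-dependent means and SDs, a free initial
distribution shared across birds, and daily transition probabilities that
follow a multinomial logit in covariates (year, day of year, moon
illumination, daily NAO index):

$$\Pr(i \to j \mid x_t) = \frac{e^{\eta_{ij}(x_t)}}{1 + \sum_{j' \ne i} e^{\eta_{ij'}(x_t)}},
  \qquad \eta_{ij}(x_t) = \beta_{ij,0} + \beta_{ij}^\top x_t .$$

Fitting maximises the scaled forward log-likelihood directly by BFGS on
unconstrained transformations (log SDs, softmax initial distribution):
covariate-dependent transitions make the EM M-step non-closed-form, so
direct maximisation is the natural choice. Details that matter:

* **Missing SST days** stay in the series as missing emissions (density
  replaced by 1), contributing transition information without splitting
  tracks.
* **Covariates are z-scored internally** for optimizer conditioning; the
  likelihood is invariant to this affine change and coefficients are
  reported on both scales. The day-of-year covariate enters linearly.
* **Label order** is canonicalised by ascending fitted mean
  (Cold/Warm/Warmer), so permuting the initialisation recovers the same
  model.
* **Starting values** are means −1, 3, 8 °C with common SD 3 °C, logit
  intercepts −3 (off-diagonal daily probability ≈ 0.045), zero slopes,
  uniform initial distribution. The test suite verifies that perturbing
  the starting means by ±1 °C leaves the fitted state distributions
  unchanged.
* **Model selection** fits all \(2^4\) covariate subsets and takes the
  lowest AIC; among models within 2 AIC units the fewest-parameter model
  wins (the tie rule stated for the study's regression models; the HMM
  selection rule is otherwise unspecified).
* **Decoding** is by Viterbi under the inhomogeneous transition matrices,
  exact ties broken toward the colder state. **Model checking** simulates
  from the fitted model at the observed covariates and compares observed
  marginal quantiles and mean per-bird autocorrelations to simulated
  2.5–97.5% envelopes. Gridded SST cells are labelled with the state of
  highest emission density (ties to the colder state).

Forward likelihood and Viterbi are verified against exhaustive enumeration
over all \(3^T\) paths for short series, to 10⁻⁸.

## What the simulator emulates — and what it does not

The generator renders, for each bird, a 10-s multichannel stream from a
known daily habitat-state sequence, so that the *detectable consequences*
of each published rule are present by construction:

* Daily states follow the multinomial-logit transition model (the same
  construction the HMM fits). Default emission parameters are the fitted
  values of the winter analysis: −0.1 ± 1.2 °C (Cold), 3.1 ± 0.3 °C
  (Warm), 6.5 ± 2.4 °C (Warmer); default intercept transitions use the
  reported daily probabilities (Cold→Warm 0.033, Cold→Warmer 0.001,
  Warm→Cold 0.024, Warm→Warmer 0.003). The Warmer row is unreported; we
  use a slow exit (Warmer→Cold 0.008, Warmer→Warm 0.025) consistent with
  rare but multi-week Warmer-water bouts, and start the chain at the
  stationary distribution of the intercept matrix.
* Each day is tiled with flight, rest, dive and swim intervals. Flight and
  rest hours centre on the reported budgets (0.52/0.32 h flight per day in
  Cold/Warm water); dive hours sit in the reported 3–6 h/day band. Dive
  *counts* per light class follow the state's allocation probabilities
  (Cold 81/10/5/4%, Warm 62/12/12/14% day/civil/nautical/night; the Cold
  twilight split is our own, only the daylight and night shares being
  reported). Dives are placed at clock times whose solar elevation at the
  bird's position matches the scheduled class.
* Dives are symmetric trapezoids with 2 m/s vertical transit, maximum
  depth drawn per light class (deep by day, < 20 m at night, matching the
  reported attenuation of depth with light). Durations are truncated
  log-normal, median 1.5 min, maximum 4 min — within murre physiological
  range; the winter dive-duration distribution itself is unpublished, so
  these are stand-ins, not estimates. The transit speed is what lets a
  ≤ 4-min dive reach the reported daytime depths.
* The tag is wet except in flight and rest; wet temperature is true SST
  (one Gaussian draw per day from the state's emission) plus sensor noise
  (SD 0.05 °C, the resolution class of these tags — small enough that the
  180-s stability rule holds at the surface by construction); dry
  temperature is 2 °C in flight and 15 °C at rest, placed cleanly on
  either side of the 7 °C rule. A one-sample buffer separates scheduled
  intervals so dry runs and dives never merge, which is what makes the
  dive-count round trip exact.
* Positions are a fixed per-bird location on the Labrador Shelf/Basin
  (55–60°N, 48–55°W) with small daily jitter, emitted as synthetic
  dawn/dusk pairs so the position-averaging path is exercised. NAO is a
  stationary AR(1) with autocorrelation 0.8 — the real analysis uses the
  observed daily index; AR(1) reproduces its multi-day persistence only
  qualitatively. Moon illumination is computed for the real calendar.
* A day whose light-class allocation requests a class that never occurs at
  the simulated latitude (daylight dives in polar night) raises a
  schedule-infeasible error naming the bird and date.

Not emulated: a light channel usable for geolocation, sea ice, prey
fields, gradual SST drift within a state, tag temperature lag during
rapid transitions, or behavioural autocorrelation beyond the daily state.
Passing round-trip tests therefore demonstrates that the *rules and
estimators are implemented correctly and invert the generative model*,
not that the rules are unbiased on real oceans — e.g. real surface
intervals can fail the stability screen in strong SST fronts, and real
dry-cold runs shorter than 60 s (take-off attempts) are counted as swim
here exactly as in the published rules.

## Numerical choices and degenerate inputs

* Quantiles use the linear-interpolation definition (R type 7).
* The water-temperature range is computed from all in-dive samples,
  without depth restriction (unspecified in the source; the alternative
  would need a depth cut that is itself unspecified).
* The 7 °C flight/rest threshold is absolute, as printed, even where SST
  approaches 7 °C.
* Empty inputs return empty, typed results; days without dives have an
  undefined water range and hence missing SST; zero rolling dive time
  gives missing AEI rather than infinity.
* The optimizer floors emission SDs at 10⁻⁶ °C while probing, and
  non-finite likelihood evaluations are penalised rather than fatal.
* Exact density or probability ties break toward the lower (colder) state
  index everywhere, making decoded output deterministic.

## Scale of the validation experiments

The recovery experiments in the test suite and acceptance script use 54
birds × 90 days for the HMM refit (the study's scale) and 10 birds × 30
days per habitat for the logger-stream round trips; unit tests use
minutes-long streams where the rule forces the answer. At these sizes a
full run of everything completes in a few minutes on one core.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim_config = simulation_config(n_birds = 5, n_days = 30, rng_seed = 1),
  output_dir = "out"
)
res <- run_pipeline(cfg)
res$fit                      # fitted state means/SDs, logLik, AIC
head(res$summaries)          # bird-day budgets, SST, DEE, AEI, state
res$occupancy$by_bird        # days per habitat state per bird
```

## Known limitations

* Energetics coefficients are taken as printed; the per-dive term's sign
  behaviour for long dives is inherited, flagged, and deliberately not
  "corrected".
* The HMM assumes Gaussian emissions and first-order daily dynamics; real
  SST series are autocorrelated within states, which the model check is
  designed to expose.
* Light-class dive shares are allocated per dive (counts), matching how
  the shares are reported; per-time allocation would differ slightly
  because dive duration varies with depth and light.
* The simulator's within-day schedule is random given the state; it does
  not model bout structure, weather-driven behaviour within a day, or
  gradual habitat transitions.
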