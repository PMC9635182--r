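# wintermurre

Winter biologging analysis for diving seabirds: rule-based behaviour
classification of 10-s temperature–depth–immersion logger streams,
bird-detected sea surface temperature, activity-budget energetics, and a
covariate-transition Gaussian hidden Markov model that classifies
bird-days into thermal habitat states. A ground-truth simulator generates
complete multi-bird winter datasets so the whole pipeline is testable end
to end.

## Who it is for

Movement ecologists working with archival temperature-depth recorders
(TDRs) on wintering seabirds — murres and other alcids in particular —
who need to go from raw multichannel logger files to a model-ready
bird-day table: activity budgets, energetics, dive timing by light
category, and decoded habitat states.

## What it computes

**Behaviour rules** (applied to maximal runs of 10-s samples):

* dive = depth ≥ 5 m; flight = dry ≥ 60 s with max temperature < 7 °C;
  rest (leg-tuck) = dry with max temperature > 7 °C; the remainder swims.
* bird-detected SST = mean of wet, non-diving, thermally stable samples
  (range < 0.5 °C per centred 180-s window) lying within the day's
  in-dive 5th–95th temperature percentile range ± 1 °C.
* dive timing classified as day / civil twilight / nautical twilight /
  night by solar elevation (> 0°, to −6°, to −12°, below) at the bird's
  mean daily position.

**Energetics** (kJ, per bird-day):

    DEE = 508·T_f + 3.64·Σ(1 − d/e^1.23) + (113 − 2.75·SST)·T_s + (72.2 − 2.75·SST)·T_r
    AEI = (DEE_5 / 0.73) / Td_5

with T_f, T_s, T_r in hours, dive durations d in minutes, SST in °C, and
the subscript 5 a centred 5-day moving average.

**Habitat states**: daily SST per bird follows a 3-state Gaussian hidden
Markov model (Cold / Warm / Warmer) whose daily transition probabilities
are multinomial-logit functions of covariates (year, day of year, moon
illumination, NAO). Direct likelihood maximisation, AIC covariate
selection, Viterbi decoding, simulation-based model checking, and
assignment of gridded SST cells to the densest state.

## Worked example

Simulate five birds over thirty winter days, run the full pipeline, and
inspect the results:

```r
library(wintermurre)
cfg <- pipeline_config(
  sim_config = simulation_config(n_birds = 5, n_days = 30, rng_seed = 1),
  output_dir = "out"
)
res <- run_pipeline(cfg)
res$fit
#> Gaussian SST hidden Markov model (3 states)
#>   covariates on transitions: (none)
#>   Cold   mean  -0.26 degC  sd  1.29 degC
#>   Warm   mean   3.10 degC  sd  0.32 degC
#>   Warmer mean   6.37 degC  sd  2.22 degC
#>   logLik -199.17, 14 parameters, AIC 426.33, convergence 0
```

The fitted state means sit near the generating values (−0.1, 3.1 and
6.5 °C) even at this small scale; the Cold and Warmer states are harder to
pin down than Warm because their SDs are wide (1.2 and 2.4 °C vs 0.3 °C).
The bird-day table carries budgets, SST, energetics and the decoded state:

```r
head(res$summaries[, c("date", "sst_c", "t_fly_h", "t_dive_h", "dee_kj",
                       "aei_kj_per_h", "state")], 4)
#>         date   sst_c t_fly_h t_dive_h dee_kj aei_kj_per_h state
#> 1 2019-01-01 -0.8077  0.6806    3.681   2826        941.2     1
#> 2 2019-01-02 -0.3558  0.6000    3.883   2755        901.9     1
#> 3 2019-01-03  0.4914  0.5861    4.469   2688        880.7     1
#> 4 2019-01-04  2.0888  0.4361    4.431   2571        849.4     1
```

Bird 01 is in Cold water (state 1): around −1 to 2 °C at the surface,
roughly 4 h diving and 0.5–0.7 h flying per day, and a daily energy
expenditure near 2600–2800 kJ — flight and cold-water thermoregulation
are the expensive terms. `res$occupancy` summarises days per state per
bird and the proportion of birds in each state by date;
`export_model_table(res$summaries)` produces the normalised responses
(activity ÷ 24 h, light-class dive time ÷ total dive time, with the
+1-minute low-zero adjustment flagged) that downstream mixed models
consume.

`daily_summary.csv` and `hmm_params.json` are written to `output_dir`;
the same stages are available as subcommands (`simulate`, `classify`,
`pipeline`, `fit-hmm`, `decode`, `check`, `export`) through
`inst/cli/wintermurre.R`.

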