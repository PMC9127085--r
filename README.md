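# routewalk

Street-environment effects on pedestrian route choice.

When pedestrians walk short utilitarian trips (home to a first
destination), most follow the shortest-distance path or the path with the
least directional change — those choices are explained by distance and
network legibility alone. The informative trips are the ones that
*deviate*: something about the micro-level street environment (sidewalks,
greenery, street walls, shops, bins, benches) pulled the walker off the
obvious route. routewalk is for researchers in urban planning,
transportation and public health who want to quantify that pull from
observed routes and a per-edge walkability audit.

## What it does

* **Network model** — a planar street network (GeoJSON LineStrings +
  attribute CSV) with fifteen audited street-environment attributes per
  edge, and its angular *segment graph* (segments as nodes, links weighted
  by turn angle θ/90: straight = 0, right angle = 1, U-turn = 2).
* **Labeled alternatives** — per OD pair, the shortest-distance route and
  the least-directional-change route (direction-aware turn-cost search;
  deterministic tie-breaking), plus angular step-depth maps
  (`angular_step_depth()`).
* **Overlap decomposition** — overlap ratio (shared edge length / chosen
  route length), full-overlap classification, and extraction of deviated
  part-routes between divergence and reconvergence nodes.
* **Route-level environment** — length-weighted means for widths, D/H
  ratio, ordinal condition codes and facility proportions; sums for counts.
* **Conditional logit** — own likelihood/score/information Newton engine.
  With utility U_nj = β'x_nj + ε_nj, ε i.i.d. Gumbel,

  P(n chooses i) = exp(β'x_ni) / Σ_j exp(β'x_nj),

  maximised in β with SEs from the inverse observed information,
  z = β/SE, two-sided normal p.
* **Pipeline** — `run_pipeline()` excludes 100%-overlap trips and fits the
  four models {entire route, deviated part-route} × {shortest, least
  angular}, with CSV/JSON reports; `inst/scripts/routewalk` wraps it for
  the shell.
* **Synthetic simulator** — grid networks, audit-scale attributes, ~350 m
  trips and utility-maximising choices under known coefficients, so the
  whole pipeline is testable without field data.

## Worked example

Simulate a cohort of 219 pedestrians on an 8×8 jittered grid with known
preferences (greener routes attract, wider sidewalks here deter:
β = (green_spaces 1.0, sidewalk_width −0.5)), then run the full analysis:

```r
library(routewalk)

cfg <- synthetic_config(seed = 42)          # study-scale defaults
net <- generate_network(cfg)
od  <- sample_od_pairs(net, cfg)
cohort <- simulate_choices(net, od, cfg$beta_true, seed = 42)
report <- run_pipeline(net, cohort,
                       pipeline_config(attributes = names(cfg$beta_true)))
report
#> Route choice analysis report
#>   trips: 219, mean length 374.0 m
#>   full overlap vs shortest: 163/219 (74%)
#>   full overlap vs least_angular: 167/219 (76%)
#>   full overlap vs both: 111/219 (51%)
#>   model entire_shortest: n = 56, logLik = -30.620
#>   model part_shortest: n = 56, logLik = -29.632
#>   model entire_least_angular: n = 52, logLik = -35.897
#>   model part_least_angular: n = 52, logLik = -35.883
```

Most simulated walkers stick to an optimal route (74% fully overlap the
shortest path), so only the 56 deviating trips inform the chosen-vs-
shortest models — exactly the exclusion logic the method prescribes. The
entire-route model recovers the generating preferences:

```r
report$models$entire_shortest
#> Conditional logit fit: 56 choice sets, 2 attributes
#>          category      attribute       coef        se          z           p
#>  Roadway features sidewalk_width -0.6955613 0.8767545 -0.7933364 0.427581846
#>       Streetscape   green_spaces  2.8418373 0.9056678  3.1378363 0.001701999
#> Log-likelihood: -30.620 (null: -38.816); converged in 5 iterations
```

Green space attracts deviators (positive, z = 3.1); sidewalk width repels
(negative, not significant at this n). For unbiased coefficient recovery
use the estimation counterpart of the generation step,
`fit_clogit(cohort_choice_data(net, cohort))`, which keeps both labeled
alternatives in every choice set.

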