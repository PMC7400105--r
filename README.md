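# etdrift

Drift correction and long-term evaluation for electronic-tongue
(potentiometric sensor-array) experiments.

Electronic tongues fingerprint liquid samples with an array of partially
selective sensors (seven channels by default: ZZ, BA, BB, CA, GA, HA, JB).
Their readings drift between repeats and between weekly sessions —
temperature, cross-contamination by the sensor head and carryover on the
sensor membranes all contribute — which breaks the comparisons across weeks
that the instrument exists for. `etdrift` is for chemometricians and sensor
engineers who need to correct that drift and quantify how well a correction
worked.

## What it implements

Four corrections, each a fit/apply pair dispatched by `correct()`:

| method | idea |
|---|---|
| `additive_all` | subtract each (session, round) block's per-sensor mean over **all** samples: X' = X − X̄ |
| `additive_ref` | subtract the per-block mean of designated **reference classes** only |
| `linear_ref` | per sensor and session, regress base-session reference centroids on later-session ones (y = m·x + b, ≥ 2 references) and map the whole session |
| `cc` / `cc_modified` | estimate the drift direction p as the first PCA loading of pooled reference readings; remove the projection (classic), or subtract **twice** the drift score from later sessions only, reflecting them onto session 0 (modified) |

Evaluation follows the long-term protocol: a canonical LDA built on
session 0, stratified threefold cross-validation, projection of every later
session, per-(session, class) accuracies and confusion matrices, and
relative Euclidean centroid distances in the 3-dimensional discriminant
space (target-class displacement from its session-0 centroid, normalized by
the session-0 MSG–citric-acid centroid distance).

A synthetic generator (`simulate_experiment()`, `scenario()`) emulates a
6-session, 4-class (citric acid, NaCl, MSG, apple juice), 7-sensor
experiment with per-session additive/multiplicative drift, a linear
temperature response (50 units/°C), first-order memory carryover and
cross-contamination dilution with a pH track — so the whole pipeline runs
and is tested with no instrument and no download.

## Worked example

```r
library(etdrift)

exp <- simulate_experiment(scenario("baseline_drift", seed = 1))
ms  <- exp$measurements   # 432 observations: 6 sessions x 18 rounds x 4 classes

# raw data: the session-0 model decays as drift accumulates
raw <- threefold_cv(ms, target_class = "apple_juice",
                    norm_pair = c("MSG", "citric_acid"), label = "none")
class_accuracy(raw, "apple_juice")
#>         0         1         2         3         4         5
#> 100.00000 100.00000  66.66667   0.00000   0.00000   0.00000

# additive correction relative to the whole sample set
fix <- correct(ms, "additive_all")
rep <- threefold_cv(fix$corrected, target_class = "apple_juice",
                    norm_pair = c("MSG", "citric_acid"), label = "additive_all")
class_accuracy(rep, "apple_juice")
#>   0   1   2   3   4   5
#> 100 100 100 100 100 100

round(rbind(raw = raw$distances$mean, corrected = rep$distances$mean), 3)
#>           [,1]  [,2]  [,3]  [,4]  [,5]  [,6]
#> raw          0 0.427 0.907 1.388 1.839 2.244
#> corrected    0 0.010 0.009 0.033 0.022 0.017
```

Session 0 classifies perfectly on raw data; by week 3 the drifting
apple-juice cluster has moved ~1.4 normalized centroid distances away and
classification collapses to 0%. After the additive correction the class is
recovered at 100% in every session and the residual displacement is ~1–3%
of the MSG–citric-acid separation.

The same pipeline is available from the command line (exit codes: 0 ok,
2 usage error, 3 data error):

```sh
ET=$(Rscript -e 'cat(system.file("cli", "etdrift.R", package = "etdrift"))')
Rscript $ET simulate --scenario baseline_drift --seed 1 --out run
Rscript $ET correct  --in run/measurements.csv --method additive_all --out run/add
Rscript $ET compare  --in run/measurements.csv \
  --refs citric_acid,NaCl,MSG --ref citric_acid \
  --target apple_juice --norm-pair MSG,citric_acid --out run/cmp
```

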