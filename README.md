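# swnc — sensor-weighted network classification for wearable activity recognition

`swnc` is an R toolkit for studying how body-worn accelerometer activity
recognition degrades when sensors are disturbed at run time — rotated inside
a loose attachment, displaced, uncalibrated or failing — and how much of
that degradation a weighted decision-fusion ensemble can absorb. It is aimed
at researchers in wearable sensing / digital health who want a controlled,
fully reproducible benchmark of single-sensor versus multi-sensor
robustness.

## The model

For `M` sensor nodes and `N` activity classes, the **sensor-weighted network
classifier (SWNC)** stacks three levels:

1. **Base level** — `M x N` binary one-vs-rest classifiers `c_mn` (default:
   kNN with per-classifier grid-selected odd `k`, each on its own top-`L`
   features ranked by the one-vs-rest ROC criterion `|AUC - 0.5|`).
2. **Node level** — each classifier's held-out accuracy `R_mn` becomes a
   class weight `λ_mn = R_mn / Σ_k R_mk`. An accepting classifier votes 1
   for its class; a rejecting one votes 1 for every *other* class. The node
   output is `O_mq = Σ_n λ_mn y_nq`, decided by argmax.
3. **Network level** — node accuracies give node weights
   `μ_m = R_m / Σ_k R_k` and the fused output is `O_q = Σ_m μ_m O_mq`,
   again decided by argmax (ties to the lowest class index).

Disturbances are injected only into test data, in two parametric families:
**rotational noise** (an Euler rotation of the sensor frame, with per-axis
angles drawn uniformly from `[0, max]` degrees) and **additive noise**
(zero-mean white Gaussian, standard deviation in mG). A synthetic-data
module generates labeled multi-sensor biaxial datasets (gravity projection +
harmonic dynamics + noise floor, with per-subject variability) emulating a
classic 20-subject, 5-placement, 9-activity wearable study, and an
evaluation module produces accuracy-versus-noise curves with repeated
stratified 70/30 splits.

## Worked example

```r
library(swnc)

sc  <- default_scenario(subjects = 6, windows_per = 3, seed = 7)
set <- generate_dataset(sc$config, sc$profiles, sc$placements)
set
#> <signal_set> 5 sensors, 162 windows of 300 samples @ 50 Hz, 9 classes, 6 subjects

set.seed(1)
idx   <- stratified_split(set$label, 0.7)
model <- swnc_fit(subset_windows(set, idx$train))
model
#> <swnc> 5 nodes x 9 classes; encoding 'complement'
#>   node weights mu: 0.200 0.213 0.220 0.213 0.153

test <- subset_windows(set, idx$test)
accuracy(predict(model, test)$class, test$label)
#> [1] 0.978

# rotate the hip sensor by up to 90 degrees in the test data only
rotated <- disturb(test, disturbance_spec("rotational", 90, sensors = 1, seed = 2))
pred <- predict(model, rotated)
accuracy(pred$class, test$label)          # fused network
#> [1] 1
accuracy(pred$node_class[, 1], test$label) # the disturbed hip node alone
#> [1] 0.4
```

The fused network absorbs the disturbance that cripples the single rotated
sensor (0.40 alone versus 1.00 fused here): the four clean nodes outvote the
corrupted one, weighted by their clean-data reliability. `run_sweep()`
repeats this comparison over level grids, disturbed-sensor counts `S = 1..M`
and repeated random splits, returning mean ± sd accuracy curves and
fusion-versus-single comparison tables; see the methods vignette
(`vignettes/swnc-methods.Rmd`) for the full protocol, parameter meanings
and known limitations.

A command-line interface covering the same pipeline
(`simulate`, `corrupt`, `train`, `predict`, `sweep`, `report`) is installed
at `inst/cli/swnc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/swnc.R", package="swnc"))')" \
  simulate --seed 7 --subjects 6 --out signals.csv
```

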