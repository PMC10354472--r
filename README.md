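# nestwatch

Within-nest behavioural and thermal analysis of bumblebee colonies under
combined neonicotinoid and cold stress.

Bumblebee workers respond to nest cooling by clustering on the brood and
incubating it. Dietary imidacloprid (a neonicotinoid, at field-realistic
ppb doses) impairs locomotion specifically at low body temperature, and
the two stressors interact with colony size: small colonies cannot keep
their workers warm, so the pesticide's low-temperature impairment bites
hardest exactly where the thermoregulatory response is most needed.
nestwatch is the analysis side of experiments that measure this: it takes
tagged-bee trajectory tables, nest maps and probe-annotated thermal image
stacks, and produces behavioural metrics, spatial-centrality scores,
body-temperature-conditioned activity-transition estimates and
colony-growth models. A seeded synthetic colony generator with recorded
ground truth stands in for raw video, so every stage of the pipeline is
testable end to end on any machine.

## What it computes

* **I/O**: CSV trajectory tables, JSON nest maps, probe logs, census
  tables, and multipage 16-bit TIFF thermal stacks (own minimal codec; no
  external imaging library needed).
* **Thermal**: per-frame linear calibration (`T = gain*counts + offset`)
  against in-nest probes; smooth non-rigid (thin-plate spline)
  registration of tracking coordinates into thermal frames; disc-mean
  body and brood temperatures (20 px ≈ 6 mm radius).
* **Behaviour**: the eleven per-bee per-video metrics (element
  interaction rates, spatial correlation to nest-mates, contact rate,
  degree centrality, moving speed, distance-to-centre and four brood/pot
  distance summaries), activity thresholding from the bimodal speed
  distribution, contact networks, on/off-nest classification.
* **Centrality**: PCA (scaled/centred) of the metrics; PC1 oriented so
  higher = nearer the nest centre; Yeo-Johnson normalisation.
* **Markov**: active/inactive transition probabilities per 2 °C
  body-temperature bin with Wilson CIs; control-vs-imidacloprid contrast
  below/above 18 °C with bee-level bootstrap.
* **Models**: LMMs/GLMMs via lme4 (bee-in-colony and block random
  effects), AIC selection with a simplicity rule (ΔAIC > 4), Poisson
  productivity model with the cold x pesticide x log10(colony size)
  interaction and predictions at sizes 4 and 40.
* **Pipeline**: `run_pipeline()` drives simulate → thermal → metrics →
  centrality → markov → stats from one JSON config, seeded and
  manifest-hashed.

## Worked example

```r
library(nestwatch)

# a 4.5 h cold-exposure trial for a synthetic 8-worker colony
sim <- simulate_colony(sim_params(n_bees = 8, seed = 42))
length(sim$segments)      # 29 two-minute videos at 1.5 Hz

m <- compute_behaviour_table(sim$segments, sim$nest)
nrow(m)                   # 232 (bee, video) records
attr(m, "threshold")      # $threshold 6.49 px/frame, $method "kde_valley"

mod <- centrality_model(m)
mod                       # <pca_model (queenright_11): 11 vars,
                          #  PC1 65.7% variance, sign +1>
sc  <- score_centrality(m, mod)
tmap <- aggregate(t_air_c ~ video_id, sim$truth, mean)
sc$t_air <- tmap$t_air_c[match(sc$video_id, tmap$video_id)]
mean(sc$pc1_transformed[sc$t_air >= 23])   # -1.55  (warm: dispersed)
mean(sc$pc1_transformed[sc$t_air <= 12])   #  2.99  (cold: clustered)
```

The numbers mean: the pooled speed distribution is bimodal with a valley
at 6.5 px/frame separating stationary from walking bees; the first
principal component of the eleven metrics carries about two thirds of
their variance and, after orientation, reads as spatial centrality; and
mean centrality rises by ~4.5 transformed units between the warm
baseline (24 °C) and the depth of the cold exposure (10 °C) — the
thermoregulatory clustering response the analysis is built to quantify.

Transition estimates and the treatment contrast:

```r
imd <- simulate_colony(sim_params(n_bees = 8, seed = 42,
                                  imidacloprid = TRUE))
thr <- activity_threshold(pooled_speeds(sim))$threshold
ct  <- arm_contrast(sim_activity_sequences(sim, thr),
                    sim_activity_sequences(imd, thr))
round(ct$below, 3)   # diff 0.097, CI [0.083, 0.111]: the 0.1 offset
round(ct$above, 3)   # diff 0.000, CI [-0.013, 0.015]: nothing above 18 C
```

## Command line

```sh
Rscript inst/cli/nestwatch.R simulate --out data/ --seed 7 --n-bees 16
Rscript inst/cli/nestwatch.R validate data/
Rscript inst/cli/nestwatch.R metrics --detections data/detections.csv \
    --nest data/nest_map.json --out metrics.csv
Rscript inst/cli/nestwatch.R run --config pipeline.json --out report/
```

See the vignette (`vignettes/nestwatch-methods.Rmd`) for the models,
parameter defaults with units, the synthetic generator's assumptions,
and known limitations.
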