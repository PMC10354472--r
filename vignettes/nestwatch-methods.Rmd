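---
title: "nestwatch: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nestwatch: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Bumblebee colonies buffer their brood against cold by clustering on the
nest and incubating. Sublethal doses of the neonicotinoid imidacloprid
impair thermoregulatory behaviour, and the two stressors interact: the
damage is concentrated in small colonies, whose workers cool below the
temperature range where the pesticide's locomotor effects bite. nestwatch
implements the full desk-side analysis for experiments of this kind:
from tagged-bee trajectories and probe-calibrated thermal imagery to
per-bee behavioural metrics, a PCA-based *spatial centrality* score,
body-temperature-conditioned Markov activity transitions, and
mixed-effects models of behaviour and colony growth — together with a
seeded synthetic colony generator so that every stage is testable without
any raw video.

# The measurement pipeline

## Thermal calibration

Raw thermal frames are in sensor counts. Each frame is calibrated
independently against in-nest temperature probes with a two-parameter
linear model, `T = gain * counts + offset`, fitted by least squares over
the probes; probe count values are disc means (radius 3 px) at the
annotated probe pixel, and probe temperatures are interpolated linearly in
time from the probe log (entries roughly every 20 s) to the frame
timestamp. A two-parameter model is the simplest identifiable choice with
three probes and matches radiometric practice; whether the original
analysis fitted gain and offset or offset alone is not knowable from a
methods text, so the model form is a declared configuration decision. A
degenerate fit (identical probe counts) flags the frame uncalibrated
rather than guessing.

On noiseless, truly linear sensor data the calibration is exact to
machine precision for any gain and offset — this is a test, not a hope.
One practical geometry note: per-frame calibration is only
well-conditioned if the probes span a temperature range, so the synthetic
default places one probe in the warm nest centre and two in the cool
periphery, mirroring the two-inner/one-outer probe layout of the
experimental nests.

## Registration

The tracking and thermal cameras see the nest through different optics
and a non-planar nest surface, so tag coordinates are mapped into thermal
frames through a smooth non-rigid warp fitted to manually annotated
control-point pairs. nestwatch uses a thin-plate spline: the minimiser of
squared control-point error plus a bending-energy penalty (weight
`lambda`, default `1e-3`; control coordinates are normalised to unit
scale before solving so the penalty is resolution-independent). The
affine family is the null space of the penalty, so an exactly affine
geometry is reproduced exactly from four or more non-collinear pairs, and
`lambda -> 0` gives exact interpolation. A b-spline coefficient grid
would serve equally; the TPS form needs no grid-spacing choice and keeps
the affine-exactness property without tuning.

## Body and brood temperature

A bee's body temperature is the mean calibrated temperature over all
pixels whose centre lies within 20 thermal px (about 6 mm) of the
warped tag centroid, clipped at frame edges; a centre that maps off-frame
yields an invalid reading, not an error. Brood temperatures use the same
disc mean at the brood centroids.

# The behavioural metrics

Eleven metrics are computed per bee per video: brood and wax-pot
interaction rates (occupancy-weighted element counts per spatial bin),
mean spatial correlation to nest-mates (Pearson over flattened occupancy
grids), mean contact rate and degree centrality (contacts are centroid
pairs closer than 1 cm), moving speed (px/frame while above the activity
threshold), mean distance to the social nest centre (the mean position of
all bees in the video), and four brood/pot distance summaries (medians
over frames, of all-element distances and of per-frame closest-element
distances). Auxiliary outputs — activity fraction, mean distance to
nest-mates, speed in mm/s, on/off-nest class — are carried in the same
table but excluded from the headline PCA so its input dimensionality
stays at eleven.

Parameter choices with units and rationale:

* **Spatial bin size, 20 mm** (converted to px via the nest scale):
  about two body lengths; all occupancy-based metrics share one binning.
* **Contact threshold, 10 mm**: physical ("less than 1 cm between
  centroids"), converted per dataset.
* **Activity threshold**: the valley of a kernel-density estimate of the
  pooled frame-wise speed distribution between its two largest modes,
  pooled per colony per session — pooling stabilises the valley estimate.
  If the KDE is unimodal the boundary of a two-means split is used and
  flagged.
* **Detection gaps**: speeds bridge gaps of up to 3 frames
  (displacement divided by gap); longer gaps break the track. This
  avoids spurious speed spikes from re-acquired tags.
* **On/off-nest**: nearest-brood distance below 10 mm is on-nest, above
  20 mm off-nest, otherwise intermediate.

# Spatial centrality

The eleven metrics are centred, scaled to unit variance and
eigendecomposed; PC1 is the centrality score. Because the sign of a
principal component is arbitrary, PC1 is oriented so the
distance-to-centre loading is negative (higher score = closer to the
nest centre). Scores are then Yeo-Johnson transformed with the
maximum-likelihood lambda estimated on the pooled training scores — per
experiment, not per colony, to preserve cross-colony comparability.
Records with missing metrics are dropped from the fit and scored by mean
imputation with a flag. The microcolony variant uses the five-variable
set (mean distance to other bees, minimum brood distance, brood
interaction rate, distance to the social centre, number of unique
contacts).

# Markov activity analysis

Each frame is active or inactive by the speed threshold. Each
consecutive same-bee frame pair (gap of exactly one frame, both states
defined) is one Bernoulli trial conditioned on the first frame's state
and assigned to the temperature bin of the *first* frame's body
temperature — which frame's temperature conditions the transition is not
derivable from a methods text, so first-frame is the declared convention.
Default bins are 2 °C wide from 10 to 30 °C; estimates with fewer than 50
opportunities are suppressed; intervals are Wilson scores. The treatment
contrast is the difference in p(active→inactive), pooled over shared bins
with opportunity weighting, reported separately below and above the 18 °C
body-temperature threshold, with a bee-level bootstrap CI. Smoothing of
p(T) curves is deliberately a post-process on binned estimates (a
penalized spline can be applied downstream); the estimator itself stays
count-based and exactly testable.

# Mixed models and AIC selection

Behavioural responses are modelled with linear mixed models (bee nested
in colony, block, and where applicable caste and treatment day as random
effects) and colony productivity with a Poisson log-link GLMM (block
random intercept; species random slopes for colony size when several
species are present). Candidates are compared by maximum-likelihood AIC
with a simplicity preference: the simplest model within 4 AIC of the
minimum wins; a more complex model must improve AIC by more than 4.
Numerical optimisation is delegated to lme4 — the package's contract is
model structure, convergence and singularity reporting, and
reproducibility. Satterthwaite degrees of freedom require a backend this
deployment does not ship, so p-values use the normal approximation and
are flagged `df_method = "normal"`. The productivity analysis excludes
single-bee colonies and colonies above 40 bees at treatment, and reports
predictions with CIs at reference sizes 4 and 40 per treatment arm.

# The synthetic colony generator

The generator is first-class, tested code: it produces trajectories,
thermal stacks, probe logs and censuses with the statistical structure
the analysis assumes, plus ground truth for parameter recovery.

**Dynamics.** Bees carry a binary activity state. Per frame,
`p(active→inactive) = p_ai_base + p_ai_slope * max(0, 24 - T_body)`, plus
`delta_ai_imid` when the colony is imidacloprid-fed and `T_body < 18 °C`
— a piecewise-linear form with an additive offset below threshold, the
fewest-parameter shape consistent with the finding that the pesticide
acts predominantly below 18 °C. `p(inactive→active)` is constant. Active
bees take Gaussian steps (s.d. 25 tracking px per axis) plus a drift
toward the brood centre of mass of magnitude
`thermotaxis_gain * max(0, 24 - T_air)`; inactive bees show only small
tag jitter (1.5 px). Defaults (`p_ai_base = 0.07`, `p_ia_base = 0.05`,
`p_ai_slope = 0.015 / °C`, `delta_ai_imid = 0.1`) give warm-nest activity
around 0.4 and active/inactive bout lengths of order ten seconds at
1.5 Hz, in the range reported for within-nest workers.

**Body temperature** equals the local thermal field at the bee's
(warped) position: ambient air temperature plus Gaussian kernels at brood
items (amplitude 0.6 °C, s.d. 60 thermal px each) and at every bee
(0.3 °C, 25 px, own kernel included). There is no thermal inertia — body
temperature tracks location instantaneously. That is the simplest model
consistent with body temperature being location-driven; adding inertia
is a noted extension, and nothing downstream depends on its absence.

**Why colony size matters in the stated world.** Brood count scales with
worker number (worker:brood 2:1, as in the microcolony design), so large
colonies sit on a broad warm platform: at 80 workers the brood field
keeps the nest region above the 18 °C threshold even at a 10 °C ambient,
while a 4-worker nest with 2 brood warms it by barely 1 °C. The
imidacloprid activity penalty therefore engages across the whole arena
in small colonies but almost nowhere a large colony's workers actually
are — the emergent size-protection pattern.

**Baseline positions.** At baseline temperature most workers rest on the
nest (Gaussian spread around the brood that scales with brood area) and a
fraction (`off_nest_frac = 0.4`) sits off-nest, uniformly over the arena
— real colonies at ambient temperature always have off-nest workers, and
it is precisely the off-nest workers whose cold response the pesticide
impairs: a chilled imidacloprid-exposed bee off the nest freezes more,
drifts more slowly toward the cluster during the cooling ramp, and drags
the colony's centrality response down. With everyone starting on the
nest, both arms sit at the clustering equilibrium throughout and no
attenuation can emerge, because the movement model's stationary spatial
distribution depends only on the drift-to-diffusion ratio, which the
activity level scales out of. The off-nest fraction is therefore not a
free dial but the ingredient that makes the attenuation a transient,
cooling-phase phenomenon — which is also where the analysis quantifies
it (the centrality response is measured as the PC1-versus-air-temperature
slope over the active cooling phase).

**Cameras.** The true tracking-to-thermal geometry is affine (per-axis
scale ≈ 0.15, small offsets) plus a sinusoidal perturbation of 3 thermal
px amplitude and ~3500 px period — smooth, non-trivial, and recoverable
from 25 control points. The sensor model is
`counts = (T - offset) / gain + N(0, sd)` with gain 0.05 °C/count and
noise 1 count (50 mK, the sensitivity class of the thermal camera
modelled). Probe logs report disc-mean *true* temperature at the probe
annotations: the probes are trusted ground truth, as in internal
calibration against reference sensors.

**Census.** Total productivity is Poisson with log-linear predictor
`b0 + b_size*log10(size) + b_cold*cold + b_imid*imid + b_ci*cold*imid +
b_3way*cold*imid*log10(size) + block`. A pure three-way term cannot
produce a combined-stress deficit that is *largest in small colonies*
(either sign of `b_3way` makes the deficit grow or shrink monotonically
with `log10(size)` from zero), so the generator carries a negative
two-way `b_ci = -1.2` with a positive `b_3way = 0.75`: the combined arm
loses about half its productivity at size 4 and essentially nothing at
size 40, and the fitted three-way coefficient is positive — the pattern
and sign structure of the size-dependent interaction this package is
built to detect. Defaults put productivity in the tens, block effects at
s.d. 0.2 on the log scale.

**Determinism.** One integer seed drives R's Mersenne-Twister; the
compiled simulation loop draws through R's RNG with a fixed per-frame
draw order that does not depend on treatment arm, so matched seeds give
matched streams and `delta_ai_imid = 0` makes the arms bitwise
identical. All outputs are reproducible byte-for-byte under a fixed
seed.

# What the generator does not emulate

Detection dropouts and identity switches (every bee is seen every
frame); queen/worker behavioural differentiation; foraging trips;
physical heat conduction and thermal inertia; emissivity differences
between materials; colony-to-colony variation in nest architecture
beyond brood count. A green test against this generator establishes that
the estimators recover the structure they target at realistic noise
levels and scales — not that the biological effect sizes in any real
dataset will match the defaults.

# Numerical choices and degenerate inputs

* Calibration: probe-count spread below `1e-12` counts → frame flagged
  uncalibrated, no exception.
* Registration: duplicate or collinear control points are hard errors
  naming the problem; coordinates are normalised before the TPS solve to
  keep the bordered system well-conditioned.
* Occupancy bins: the arena is covered by `ceiling(extent / bin)` bins
  anchored at the arena origin; detections on the far boundary clamp
  into the last bin.
* Transition counting: only frame pairs with gap exactly 1 are Markov
  steps; a pair bridging a 2–3-frame gap defines speed (and hence state)
  but is a multi-step transition and is not counted.
* Yeo-Johnson lambda: golden-section maximum-likelihood search on
  [-3, 5]; the piecewise formula switches branch at lambda = 0 and 2
  with the usual log limits.
* AIC ties: exact ties (and all models within 4 AIC) resolve to the
  fewest fixed-effect parameters, then earliest candidate order.

# Known limitations

Per-frame calibration assumes the probes span a usable temperature
range; a nest in thermal equilibrium with its probes yields
ill-conditioned fits, which are flagged but not rescued. The Markov
estimator conditions on the first frame's temperature; at steep ramps
with coarse bins this blurs bin assignment by up to one frame of
temperature change. Mixed-model p-values are normal approximations; for
small random-effect group counts they are anti-conservative. The
pipeline's synthetic mode simulates one colony per arm rather than a
full multi-colony design; multi-colony experiments are driven from the
simulator and model stages directly, as in the acceptance suite.
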