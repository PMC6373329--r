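# refkin

Reference tissue kinetic modeling and short static-scan quantification for
dynamic brain PET.

## The problem

Tracers of the noradrenaline reuptake transporter (NET) need 90–120 min of
dynamic scanning plus kinetic modeling to yield regional non-displaceable
binding potentials (BP<sub>ND</sub>) — a heavy burden for movement-disorder
patients scanned off medication. A practical alternative is a single 30-min
static acquisition and the ratio estimate

BP = (C̄<sub>VOI</sub> − C̄<sub>ref</sub>) / C̄<sub>ref</sub>,

computed against a reference region devoid of specific binding (occipital
cortex). `refkin` implements both routes and the statistics that decide
whether, and from which start time, the static route is good enough:

* **framing** — frame schedules (`"6x30,3x60,2x120,22x300"`: 33 frames,
  120 min), frame binning, 30-min static windows aligned to frame
  boundaries;
* **kinetic models** — MRTM (three-coefficient multilinear fit yielding the
  reference efflux constant k₂′ = γ₁/γ₃), population-mean k₂′ transfer, and
  MRTM2 / basis-function SRTM2 for regional BP<sub>ND</sub>
  (BP<sub>ND</sub> = R₁k₂′/k₂ₐ − 1);
* **static quantification** — ratio BP per subject × region × window
  (30–60, 40–70, 50–80, 60–90 min), hemisphere pooling;
* **agreement statistics** — Spearman ρ, absolute-agreement ICC(A,1),
  pooled OLS regressions of static on model BP, and clinical covariate
  correlations with permutation p-values and Bonferroni adjustment;
* **synthetic cohort** — an SRTM2-consistent forward simulator with known
  ground truth (population k₂′ = 0.0322 ± 0.0105 min⁻¹, regional binding
  levels from near zero up to ~0.25, frame-duration-dependent noise), so
  the whole chain is testable without image data. A NIfTI label-map TAC
  extractor connects real 4D volumes to the same pipeline.

See `vignettes/reference-tissue-quantification.Rmd` for the models,
assumptions, and design choices.

## Worked example

Simulate a noiseless 10-subject cohort on the standard protocol, run the
full chain, and look at the pooled static-vs-SRTM2 regressions:

```r
library(refkin)
cfg <- pipeline_config(seed = 1, simulate = list(noise_alpha = 0))
res <- run_pipeline(cfg)
res$regressions[res$regressions$model == "SRTM2", ]
```

```
 window model slope intercept    r2         p stars n_points
  30-60 SRTM2 0.608  -0.01645 0.961  4.64e-71   ***      100
  40-70 SRTM2 0.701  -0.01296 0.979  1.89e-84   ***      100
  50-80 SRTM2 0.788  -0.00965 0.989  1.10e-98   ***      100
  60-90 SRTM2 0.868  -0.00651 0.995 3.48e-115   ***      100
```

The slope rises monotonically with the window start time and stays below 1:
early static windows underestimate binding because the tissue-to-reference
ratio has not yet reached its transient-equilibrium plateau, and the bias
shrinks as the window moves later. The same mechanism shows region-wise —
for the highest-binding region, the thalamus:

```r
subset(res$agreement, region == "thalamus" & model == "SRTM2")[,
  c("window", "mean_model", "mean_static", "rho", "icc")]
```

```
 window mean_model mean_static   rho   icc
  30-60      0.216       0.128 0.842 0.156
  40-70      0.216       0.149 0.842 0.264
  50-80      0.216       0.169 0.842 0.436
  60-90      0.216       0.187 0.927 0.674
```

The static thalamic BP climbs from 0.13 (30–60 min window) towards the
model value 0.22 as the window starts later, and rank correlation and
absolute-agreement ICC improve along with it. (Between-subject spread here
comes only from the simulated k₂′ and binding jitter; measurement noise is
off in this example.)

`res$clinical` holds the Spearman correlations of thalamic BP with age,
disease duration, Hoehn–Yahr stage, UPDRS-III and LEDD; with the default
generator the binding is independent of the covariates by construction and
the Bonferroni-adjusted p-values are non-significant.

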