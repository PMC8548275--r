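# rachis

Hydraulic analysis of germ cell volume homeostasis in a syncytial gonad.

## What this package is for

In the adult *C. elegans* germline, cells share cytoplasm with a central
channel (the *rachis*) through openings called rachis bridges. Along the
gonad axis (x = 0 at the distal tip, x = 1 at the proximal turn) germ cells
first grow collectively (~100 → ~150 fl) and then split into growers and
shrinkers (~65 to ~1,200 fl); the shrinking cells die. `rachis` implements
the quantitative analysis by which this behaviour can be understood as a
**hydraulic instability** — the tissue-scale cousin of the two-balloon
instability, in which the larger of two coupled elastic compartments
inflates at the expense of the smaller:

* **Volumetrics** — find the transition position x\* where per-cell volume
  distributions stop being unimodal: a weighted two-segment (slope-break)
  fit of the SD-vs-mean relation, a Hartigan dip-test scan, and a
  Gaussian-mixture ΔBIC scan (`bin_volumes`, `detect_transition_slope`,
  `dip_test`, `gmm_bimodality`, `detect_transition_bimodality`).
* **Flux inference** — particle image velocimetry (`piv_displacement`),
  axisymmetric integration of the rachis flux Q<sub>r</sub>(x)
  (`flux_from_field`), cell volume flux Q<sub>c</sub>(x)
  (`cell_volume_flux`), and the steady-state balances
  ∂<sub>x</sub>Q<sub>r</sub> = J and ∂<sub>x</sub>(Q<sub>c</sub>+Q<sub>r</sub>) = S
  for the germ-cell-to-rachis current J and the material uptake S
  (`infer_J`, `infer_S`).
* **Two-phase hydraulic model** — a 1D steady-state closure with exchange
  law J = α(P<sub>c</sub> − P<sub>r</sub>), solved as a linear
  boundary-value problem and fitted to observed fluxes
  (`solve_steady_state`, `fit_parameters`, `predict_J`).
* **Doublet instability** — the two-balloon equation for the relative
  volume difference ν = (V₂ − V₁)/(V₁ + V₂), with effective potential W(ν),
  analytic linear stability, trajectories with absorbing boundaries at
  ν = ±1, and the bifurcation diagram along the gonad (`dnu_dt`,
  `effective_potential`, `linear_growth_rate`, `integrate_doublet`,
  `bifurcation_along_gonad`).
* **Synthetic data** — a seeded generator (`synthetic_config`,
  `generate_dataset`) that emulates cell tables, velocity fields, advected
  speckle image pairs and apoptosis/mitosis event streams with the
  statistical structure the analysis assumes, used as ground truth by the
  entire test suite.

All fluxes are in fl/min (1 fl = 1 µm³); x is the fraction of gonad length.
See the methods vignette (`vignettes/hydraulic-instability.Rmd`) for the
models, their assumptions, and every numerical choice.

## Worked example

```r
library(rachis)
cfg <- synthetic_config(seed = 1)   # 18 gonads x 292 cells, planted x* = 0.65
res <- run_pipeline(pipeline_config(cfg), out_dir = "gonad_run")

res$transition_slope
#> transition (slope_break): x* = 0.650  [0.637, 0.662]
#>   sd-vs-mean slopes: distal 0.137, proximal 0.964

str(res$consistency)
#> $ x_transition    : num 0.65    # volume-distribution transition
#> $ x_transition_dip: num 0.7     # dip-scan variant
#> $ x_j_zero        : num 0.568   # inferred cell->rachis current inverts
#> $ x_s_zero        : num 0.658   # inferred material uptake changes sign
#> $ x_bifurcation   : num 0.653   # doublet symmetric state loses stability
```

Reading this: the volume transition sits at 65 % of gonad length with a
±1.2 % bootstrap CI, the SD-vs-mean slope jumps seven-fold across it, the
inferred uptake S changes sign at ~66 %, the current J inverts at ~57 %,
and the doublet model predicts loss of stability of equal-volume pairs at
~65 % — the three landmarks agree within 0.1 of gonad length, which is the
central consistency statement this pipeline reproduces on synthetic data.
`gonad_run/` receives `cells.csv`, `profile.csv`, `transition.json`,
`fit.json`, `bifurcation.csv` and a provenance manifest (seed + config
hash embedded in every file).

A command-line driver with the same stages ships in `inst/cli/gonad.R`:

```sh
Rscript inst/cli/gonad.R simulate --out data/ --seed 1
Rscript inst/cli/gonad.R volumes --cells data/cells.csv --method slope
Rscript inst/cli/gonad.R stats flucs --k-treated 10 --n-treated 19 \
    --k-control 3 --n-control 21
# treated 52.6%, control 14.3%, Fisher p = 0.01711
```

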