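---
title: "Hydraulics of germ cell volume homeostasis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulics of germ cell volume homeostasis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rachis)
```

## The problem

The adult *C. elegans* gonad arm is a syncytium: germ cells line a tube of
radius $R$ and stay connected, through openings called rachis bridges, to a
shared cytoplasmic channel (the rachis). As cells move from the distal tip
($x = 0$, fraction of gonad length) to the proximal turn ($x = 1$), they
first grow collectively from roughly 100 fl to roughly 150 fl; closer to the
turn the volume distribution splits, with cells ranging from tens of
femtolitres to more than a thousand, and the small cells are removed by
physiological apoptosis. This package implements, end to end, the
quantitative machinery needed to analyse that behaviour as a problem of
tissue hydraulics:

1. **Volumetrics** — locate the axial position $x^\*$ where per-cell volume
   distributions switch from unimodal to bimodal.
2. **Flux inference** — measure the rachis flux $Q_r(x)$ from mid-plane
   velocity fields and the cell volume flux $Q_c(x)$ from cell tables, then
   use the steady-state balances
   $$\partial_x Q_r = J, \qquad \partial_x (Q_c + Q_r) = S$$
   to infer the germ-cell-to-rachis current $J(x)$ and the material uptake
   from the surrounding tissue $S(x)$.
3. **A 1D two-phase model** — close the balances with
   $J = \alpha\,(P_c - P_r)$, a Poiseuille-like rachis and a Darcy-like cell
   phase, solve the boundary-value problem, and fit $(\alpha, \kappa_r,
   \gamma_c)$ to observed fluxes.
4. **The doublet (two-balloon) instability** — the dynamics of the relative
   volume difference $\nu = (V_2 - V_1)/(V_1 + V_2)$ of two coupled cells,
   its effective potential $W(\nu)$, linear stability, and the bifurcation
   along the gonad.

Fluxes are reported in fl/min ($1\,\mathrm{fl} = 1\,\mu m^3$), velocities in
$\mu$m/s for image-derived fields and $\mu$m/min for cell motion, and $x$ is
always the fraction of gonad length.

## The synthetic world

No raw data are deposited for this system, so the package states a
self-consistent synthetic world (`synthetic_config()`) and treats it as the
ground truth for every test. Its defaults are the reported conditions:

* 18 gonad arms with 292 scored cells each (about 5,300 cells);
* distal mean volume 100 fl growing to 150 fl at the transition;
* a planted transition at $x^\* = 0.65$, beyond which volumes follow a
  two-component mixture whose modes separate linearly towards 65 fl and
  1,200 fl (the printed extremes, also enforced as a hard envelope via
  truncated sampling);
* apoptosis at 5 % per cell-hour restricted to 70–90 % of gonad length
  (the reported 4–6 % per hour and zone);
* a smooth uptake profile $S(x)$ with a positive half-sine lobe on
  $[0, x^\*]$ and a negative lobe on $[x^\*, 1]$, changing sign exactly once.

The volume noise model is lognormal with SD proportional to the mean
(coefficient of variation 0.15), which reproduces the linear SD-vs-mean
relation of homogeneous growth; the distributional family itself is a
choice of this package, not a reported fact. The small mode's mixture
weight declines linearly from 0.5 to 0.4 towards the turn when apoptosis is
active (removal of small cells), and stays at 0.5 in the
apoptosis-deficient variant (`apoptosis = FALSE`).

The hydraulic truth is produced by the package's own steady-state model:
given $S(x)$, the default parameters $\alpha = 10$, $\kappa_r = 1$,
$\gamma_c = 6\times 10^5$ (arbitrary pressure units) and the cell-volume
density implied by the mean-volume curve, `generate_truth()` yields
$Q_r, Q_c, J, P_c, P_r$ and the cell speed $v_c = Q_c L / \rho_V$. These
parameters were calibrated once, before any test was frozen, so that the
solution reproduces the printed geometry: $Q_r$ rises, peaks near 60 % of
gonad length at about 550 fl/min (a mean mid-plane speed of roughly
0.2 µm/s across a 4 µm lumen), and falls to zero at the turn; $J$ is
positive distally and negative proximally.

Velocity fields are Poiseuille profiles across the lumen whose
axisymmetric integral matches the truth $Q_r$ exactly (centreline speed
$2 Q_r / \pi a^2$), plus Gaussian noise of 0.05 µm/s; image pairs advect a
blurred speckle texture by the field (backward warp, bilinear
interpolation), leaving the texture outside the lumen static.

What a green test does **not** establish: the generator makes no attempt at
realistic nuclei or membranes, at 3D geometry, at out-of-plane flow, at
gonad-to-gonad geometric variability, or at the real spatial correlations
of cytoplasmic turbulence. Green tests certify that the estimators recover
the stated world; transfer to microscope data depends on segmentation and
PIV quality outside this package's scope.

## Numerical and statistical choices

**Dip statistic.** The environment provides no dip-test implementation, so
the classical greatest-convex-minorant / least-concave-majorant algorithm
is implemented in C++. During development it was fuzzed against the
canonical reference implementation on 3,000 random datasets (sizes 2–200,
heavy ties, point masses) with zero mismatches; eight reference values are
frozen in the tests. One deliberate convention difference: constant data
return dip 0 (and p = 1) rather than the minimal attainable $1/(2n)$. The
test's null distribution is bootstrapped from the uniform distribution
(1,000 draws), seeded deterministically per sample size and cached.

**Slope-break detector.** The SD-vs-mean relation is fitted with a
continuous two-segment (hinge) model, the hinge placed at a candidate bin's
mean and chosen by exhaustive search over bins $3 \dots n-2$. The fit is
inverse-variance weighted using
$\mathrm{Var}(\widehat{sd}) \approx sd^2 / (2(n-1))$: proximal bins have
SDs twenty times larger than distal ones, and unweighted least squares lets
their sampling noise drown the distal corner entirely. The detected
transition is reported at the **proximal edge** of the hinge bin — the
hinge bin is the last bin of the distal regime, so its centre is biased by
half a bin. The same edge convention is used by the bimodality scans
(first persistently bimodal bin, one isolated exception tolerated). The
bootstrap CI resamples gonads (via per-gonad sufficient statistics), and is
floored at one bin width, mirroring the reporting convention of a
transition known to $\pm$1.5 bins of 40.

**Bimodality criteria.** The dip criterion flags a bin at p < 0.05; the
Gaussian-mixture criterion flags $\Delta\mathrm{BIC} =
\mathrm{BIC}_1 - \mathrm{BIC}_2 > 0$ on log-volumes, fitted by a
deterministic quantile-initialized EM with a variance floor. Both are
stand-ins: the underlying study mentions two unimodality methods without
naming them. The dip criterion is conservative near the transition, where
the first post-transition bin mixes barely-separated modes: at the default
planted $x^\* = 0.65$ all of 50 seeds recover within $\pm 0.05$; at a
planted 0.5 about one seed in six flags one bin late ($+0.075$). The
measured behaviour is what the tests assert.

**Flux derivatives.** $J$ and $S$ are Savitzky–Golay derivatives (order 2,
window one tenth of the grid, polynomial edge handling). The returned
smoothed flux is defined as the exact cumulative-trapezoid antiderivative
of the returned derivative, so the discrete identity
`cumtrapz(x, J) + Qr_smooth[1] == Qr_smooth` holds to machine precision.
The proximal-most 5 % of stations is flagged low-confidence (centreline
estimation fails near the highly curved turn in real data). For
apoptosis-deficient-like inputs the analysis conventionally starts at
$x = 0.16$, where steady fields first become reliable.

**Two-phase closure and its gauge.** The closure (uniform $\alpha$,
constant $\kappa_r$, friction $\gamma_c$ acting on the cell phase of
density $\rho_V(x)$) is the minimal one reproducing the qualitative
claims; the original study's full model is in supplementary material that
this package deliberately does not mirror. Two consequences are documented
rather than hidden:

* The parameter triple has an exact scale invariance
  $(\alpha, \kappa_r, 1/\gamma_c) \to c\,(\alpha, \kappa_r, 1/\gamma_c)$
  with $P \to P/c$; fluxes are unchanged. `fit_parameters()` therefore
  gauge-fixes the fitted point by rescaling along this direction until
  $\gamma_c$ equals its initial value. Self-generated data are recovered
  essentially exactly.
* In this closure the pressure-difference inversion (equivalently the $Q_r$
  peak and the zero of $J$ — all three coincide exactly, by construction of
  the conservative staggered scheme) falls slightly **distal** of the
  uptake zero: at the uptake zero $S = 0$, so $J = -\partial_x Q_c$ there,
  and the cell flux is still rising. The reported observation places the
  inversion slightly proximal; reproducing that fine structure evidently
  requires closure details (e.g. position-dependent bridge conductivity)
  beyond the minimal model. The offset is small (about 0.05 of gonad
  length at the defaults) and the tests assert the robust part — inversion
  within 0.075 of the uptake zero.

The discretization is finite-volume staggered (pressures on nodes, fluxes
on faces) with boundary conditions $Q_r(0) = Q_c(0) = Q_r(1) = 0$ and gauge
$P_r(1) = 0$; conservation residuals are at machine precision and the
scheme converges at second order.

**Doublet model.** The basal-area asymmetry uses
$\lambda(\nu) = ((1+\nu)^p - (1-\nu)^p)/((1+\nu)^p + (1-\nu)^p)$ with
$p = 2/3$ (area $\propto V^{2/3}$), configurable because only the
dependence on $\nu$ is reported. The balloon law is the linear
$\Delta P = T\nu/R$ with no further nonlinearity. $|\nu| = 1$ is an
absorbing boundary ("coarsened": the small cell has lost its cytoplasm);
boundary states are classified stable when the flow points outward.
Integration is adaptive Cash–Karp RK4(5). The effective potential is
$W(\nu) = -\int_0^\nu \dot\nu\,d\nu'$ by adaptive quadrature; the
"normalized" variant rescales to $\max|W| = 1$ — the figure convention it
imitates normalizes at $\nu = 0$, where $W$ as defined here is exactly 0,
so a shape normalization is the only meaningful reading.

For the sweep along the gonad, the doublet inherits $S(x)$ (scaled by the
axial fraction of one doublet, default 0.05) and $P_c - P_r$ from the model
solution. The remaining constants are set a priori: $A_c$ from the gonad
cross-section, $\alpha_0$ as the per-doublet share of the tissue
conductivity, and the tension scale $T/R$ at 10 % of the solution's peak
$|P_c - P_r|$ — tension is a perturbative destabilizer, so the bifurcation
tracks the point where the hydraulic stabilizers vanish, landing near the
transition (about 0.63–0.65 at the defaults).

**Small statistics.** Treated-vs-control outcome proportions use a
two-sided Fisher exact test (small counts; the original significance test
is unnamed) with percentages rounded to one decimal; the tests verify the
p-value against a hypergeometric enumeration oracle. Event-rate profiles
carry exact Poisson intervals ($\chi^2$ form), cumulative apoptosis uses
$100(1-(1-p_a)^h)\%$, interface curvature the circular-arc sagitta
formula, and z-stack volumes a Riemann sum over plane areas.

**Formats.** Tables and profiles are CSV (dot decimal, 6 significant
digits, `#` provenance comments with package version, seed and
configuration hash); parameters are JSON (the environment has no YAML
package, so configuration files are JSON as well). Image frames and
velocity-field channels use a minimal single-strip uncompressed TIFF
(float32/uint16/uint8), verified against an independent TIFF library
during development — it is intentionally not a general TIFF reader.

## Worked example

```{r example, eval = FALSE}
library(rachis)
cfg <- synthetic_config(seed = 1)
res <- run_pipeline(pipeline_config(cfg), out_dir = "gonad_run")
res$consistency
#> $x_transition     0.650   # slope-break transition
#> $x_transition_dip 0.700   # dip-scan transition
#> $x_j_zero         0.568   # inferred J sign change
#> $x_s_zero         0.658   # inferred uptake zero
#> $x_bifurcation    0.653   # doublet symmetric state loses stability
```

The three landmarks — volume-distribution transition, current inversion and
doublet bifurcation — agree within 0.1 of gonad length, which is the
package-level restatement of the study's central consistency claim at desk
scale.

## Known limitations

* The two-phase closure is a reconstruction; its parameters are effective
  and only identified up to the documented gauge.
* The dip scan inherits the dip test's conservatism at marginal mode
  separation (about one bin of lag worst-case at the defaults).
* PIV is plain ZNCC block matching with parabolic sub-pixel refinement; no
  window deformation, no multi-pass, no outlier replacement beyond
  nearest-valid filling.
* The synthetic gonad is a straight tube; the curved turn region, where the
  centreline method fails on real data, is represented only by the
  low-confidence flag.
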