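---
title: "Bilateral distance and direction coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral distance and direction coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereosmell)
```

This vignette documents the model underlying `stereosmell`, the default
parameter values and where they come from, what the synthetic generators
do and do not capture, and the numerical and design decisions a user
should know about before trusting the outputs.

## 1. The forward model

A fly faces the $+y$ axis with its antennae at $(\pm s/2, 0)$,
$s = 0.3$ mm (`antenna_sep`). A pheromone source at distance $d$ from an
antenna drives that antenna's sensory response through a four-parameter
logistic in distance:

$$R(d) = \mathrm{base} + \frac{\mathrm{top} - \mathrm{base}}
{1 + \exp\!\big((d - \mathrm{ED50})/\mathrm{slope}\big)}.$$

`ED50` is the half-maximal distance and `slope` the distance scale of the
fall-off; responses *decrease* with distance, hence the $+$ sign in the
exponent. Dynamics are first order: traces relax toward the
instantaneous steady state with time constant `tau_rise` (0.3 s) and are
initialized at the steady state of the first sample, so constant-position
scripts are exactly at steady state from the first frame. Gaussian trial
noise of SD `noise_sd` (0.05) is added to simulated observations.

The second-order (PN) stage combines the two antennae linearly with
contralateral inhibition and half-wave rectification:

$$P_L = \max\!\big(0,\; w_\mathrm{ipsi} R_L +
(w_\mathrm{contra} - g_\mathrm{inhib}) R_R\big),$$

and symmetrically for $P_R$. In the linear (unrectified) regime the
bilateral difference is

$$P_L - P_R = (w_\mathrm{ipsi} - w_\mathrm{contra} + g_\mathrm{inhib})
\,(R_L - R_R),$$

so the circuit amplifies the left–right contrast exactly when
$w_\mathrm{ipsi} - w_\mathrm{contra} + g_\mathrm{inhib} > 1$, i.e.
$g_\mathrm{inhib} > w_\mathrm{contra}$. Setting `g_inhib = 0` (an
inhibition block) collapses the amplification; this is tested across the
whole default stimulus lattice.

### Default parameters

| parameter | default | rationale |
|---|---|---|
| `top`, `base` | 1, 0 | responses normalized to the per-ROI maximum |
| `ed50` | 2.4 mm | second-order neuron preset (`lpn`) |
| `slope` | 0.5 mm | typical fall-off scale for the presets |
| `w_ipsi` | 1 | reference ipsilateral drive |
| `w_contra` | 0.69 | contralateral/ipsilateral ORN synapse-count ratio (3,580 / 5,184) |
| `g_inhib` | 0.9 | strong inhibition from the bilateral interneuron; must exceed `w_contra` for contrast amplification |
| `tau_rise` | 0.3 s | calcium-indicator rise scale |
| `noise_sd` | 0.05 | trial-to-trial variability used throughout the recovery suite |

Presets `forward_model_preset("orn" / "lpn" / "lvpn")` set
(ED50, slope) to (2.2, 0.6), (2.4, 0.3) and (1.5, 0.8) mm. Imaging runs
at `fs = 7.2` Hz; distance sessions use the ten standard distances
5, 3.5, 3, 2.5, 2, 1.5, 1, 0.75, 0.5, 0.25 mm, and approach scripts
support speeds 1.41, 4.30 and 8.04 mm/s.

**These defaults are study conditions, not knobs**: tests and the
acceptance script run at the defaults, and tolerances were chosen from
the statistics of the estimators (see §5), not adjusted to outcomes.

## 2. The stimulation lattice and the spatial code

`build_hex_lattice()` enumerates the 16 hexagonal-lattice positions
within 2 mm of the head (rings at 1, $\sqrt 3$ and 2 mm), spanning 11
distinct angles in 30° steps with no stimulus directly behind
(±180° absent). `angular_tuning()` builds an 11-point tuning profile on
the middle ($\sqrt 3$ mm) ring: 6 angles are measured there directly; the
5 angles present only on the inner/outer rings are interpolated onto the
middle ring with weights $w_1 = 2 - \sqrt 3$ (inner) and
$w_2 = \sqrt 3 - 1$ (outer), the linear-in-distance weights for
$1 \le \sqrt 3 \le 2$.

`fit_decoder()` regresses stimulus coordinates on the bilateral
difference and sum, $(\hat x, \hat y) \sim (R-L,\; R+L)$, and
`evaluate_decoder()` cross-validates it (`loo_fly`, `loo_position`, or
in-sample). Angle errors are wrapped to $(-180°, 180°]$.

### Why exact decoding needs the linear code

With logistic distance tuning, the response *sum* at fixed ring distance
is an even function of $\sin(\text{angle})$ and carries no cosine term,
and two rings share angles with different responses but identical
targets — a 3-coefficient linear decoder is provably not exact on the
logistic forward model (empirically, cosine $R^2 \approx 0.02$).
Exactness statements ("decoding is exact, sine/cosine $R^2 = 1$")
are therefore *in-model* statements, and
`generate_lattice_session(code = "linear")` provides the in-model data
generator: an affine bilateral code $L = c_0 + c_1 x - c_2 y$,
$R = c_0 + c_1 x + c_2 y$ with $(c_0, c_1, c_2) = (0.5, 0.10, 0.12)$,
constants fixed in advance so responses stay positive over the lattice.
On that code, leave-one-fly-out errors are at machine precision and the
decoder coefficients invert the code analytically
($x = (L + R - 2c_0)/2c_1$, $y = (R - L)/2c_2$).

One subtlety: the sine/cosine regressions reach $R^2 = 1$ only on the
`angular_tuning()` profile (all points on one ring), not on raw
mixed-ring trials, because $R - L \propto d \sin\theta$ varies across
rings ($R^2 \approx 0.93$ raw). The analysis workflow therefore always
regresses on the angular-tuning profile.

## 3. Generators: scope and limits

All generators are *statistical stand-ins*, adequate for validating the
analysis code, not for simulating physics:

- **Distance/lattice sessions** draw i.i.d. Gaussian noise around the
  deterministic steady state; there is no plume dynamics, adaptation, or
  fly-to-fly parameter variability.
- **Approach presentations** (`script_presentation`) move the source on
  straight-line scripts at the standard speeds; traces follow first-order
  kinetics only.
- **Arena trajectories** (`generate_osp_trajectories`) are biased random
  walks with wall reflection in an 8 mm-radius arena; `attraction_bias`
  tilts steps toward the stimulus fly. They produce realistic occupancy
  statistics but not courtship microstructure.
- **Turn scenarios** (`generate_turn_scenario`) script piecewise-constant
  orientation with linear ramps — ground truth for detector recall, not
  naturalistic locomotion.
- **Toy connectomes** split planted type-to-type synapse counts evenly
  across cell pairs (remainder to the first pairs); they preserve totals
  and side labels, nothing morphological.

## 4. Analysis rules

- **dF/F0** baseline is the mean over $[t_\mathrm{start}+1\,\mathrm s,\;
  t_\mathrm{onset})$. Half-rise time interpolates linearly between
  samples; a trace already at/above half-peak at onset returns 0; a trace
  with no positive excursion is an error.
- **Turn detection** gates on angular speed ≥ 60°/s sustained,
  orientation toward the target, a proximity gate measured
  antennae-to-abdomen (< 5 mm; note a 7 mm *centroid* separation can
  still pass after subtracting the body offsets), and merges events
  closer than the refractory window.
- **Partner selection** includes a downstream type with > 50 synapses,
  excludes with ≤ 10, and otherwise includes iff the input percentage
  exceeds the line through (10 synapses, 4%) and (50, 0.5%), i.e.
  $4 - 0.0875\,(s - 10)$, strictly.
- **Input selectivity** considers partners with > 0.5% of inputs or > 10
  synapses; a cell is *multimodal* if sensory input exceeds 25% of
  olfactory input, *glomerulus-selective* if one glomerulus supplies
  > 50% of olfactory input, *mixed-olfactory* otherwise, and
  *unclassifiable* with no olfactory input.
- **Treadmill trials** classify responses from forward/lateral/rotational
  ball velocities (thresholds 0.75 and 0.25 mm/s at 50 Hz) and integrate
  the curved path for lateral displacement; group differences use an
  exact permutation test when the group sizes allow full enumeration, a
  seeded Monte-Carlo approximation with the $(1 + \#)/(B + 1)$ estimator
  otherwise.
- **Statistical dispatch** (`stat_dispatch`) picks t/Wilcoxon (or their
  paired versions), Kruskal–Wallis or Friedman from Shapiro and variance
  gates, with Benjamini–Hochberg-corrected pairwise follow-ups.
- **Circular statistics** (median, common-median test) are hand-written
  to the published definitions because no circular-statistics package is
  available; both are validated against brute-force oracles and the test
  holds its nominal type-I error (5.9% measured at the 5% level).

## 5. Numerical choices

- **Logistic fits** use `stats::nls` with the `SSfpl` self-start and
  `nls.control(scaleOffset = 1)` so exact (zero-residual) data converge;
  `minpack.lm::nlsLM` is the fallback. The residual SE is
  $\sqrt{\mathrm{RSS}/(n-4)}$. An ED50 outside the sampled distance range
  triggers a warning rather than an error.
- **Low-pass smoothing** uses a zero-phase Butterworth
  (`signal::filtfilt`), which assumes zero initial conditions; traces are
  demeaned before filtering and the mean restored, otherwise a constant
  trace comes back distorted at the edges.
- **Exact-fit $R^2$** is computed directly as $1 - \mathrm{RSS} /
  \mathrm{TSS}$ rather than via `summary.lm`, which warns on
  "essentially perfect" fits.
- **Cross-correlation lags** (`crosscorr_lag`) use `stats::ccf` with the
  convention that positive lags mean the neural signal follows the
  stimulus; by default the trace is inverted because responses grow as
  distance shrinks. The lag of a slowly varying (highly autocorrelated)
  stimulus is weakly identified — an estimator property, so validation
  uses white-noise stimuli.
- **Pipeline reproducibility**: `run_pipeline()` hashes the recursively
  key-sorted YAML of the config *excluding* `out_dir`, so the same
  analysis written to different directories produces byte-identical
  reports; unknown config keys are errors, and declared inputs are
  schema-validated (row and column of every violation reported) before
  any stage runs. All randomness flows from the single `seed` entry.

## 6. Design decisions

- The package keeps a *module* layout (generators, preprocessing, tuning,
  spatial code, behavior, connectome, pipeline) rather than a
  single-model shape, but applies the classic S3 modelling idiom where it
  fits: `fit_sigmoid()` returns a `sigmoid_fit` with `print`, `coef`,
  `predict` and `summary` methods, and `fit_decoder()` a
  `bilateral_decoder` with `print`, `coef` and `predict`.
- Settling-time checks use holds of at least $16\tau$
  ($e^{-16} < 10^{-6}$); after only $10\tau$ a first-order kernel is
  still $4.5\times10^{-5}$ away from the step, so "within $10^{-6}$ after
  $10\tau$" is unattainable and the package documents $16\tau$ instead.
- The opposite-sex-preference score is a single-assay occupancy contrast
  (percentage of time near the stimulus fly, rim-excluded), comparable
  across conditions by the permutation machinery rather than baked-in
  test choices.
- The adaptation index is offset response / peak (1 = no adaptation),
  chosen so "less adaptation" is monotone increasing.

```{r example}
fit <- fit_sigmoid(build_distance_tuning(
  generate_distance_session(forward_model_params(), seed = 42)))
coef(fit)
```
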