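---
title: "Methods: an age-dependent analytical CSF and its grid-search estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an age-dependent analytical CSF and its grid-search estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agecsf)
```

## The model and its assumptions

`agecsf` implements a physiological contrast sensitivity function (CSF)
in the signal-to-noise tradition: a sinusoidal grating of spatial
frequency $u$ (cpd) is detected when its modulation exceeds $k$ times
the modulation of the observer's internal noise. The internal noise has
a photon component $\Phi_{opt}$ (filtered by the lateral-inhibition MTF
$M_{lat}$) and a neural component $\Phi_{neu}$, and the stimulus itself
is low-passed by the optical MTF $M_{opt}$ before detection. Working
through the noise propagation gives

$$\mathrm{CSF}(u) = \frac{M_{opt}(u)}{k}
  \sqrt{\frac{XYT}{2\left(\Phi_{opt} + \Phi_{neu}/M_{lat}^2(u)\right)}},$$

with $X, Y$ the angular field size (deg) and $T = \min(T_e, T_o)$ the
effective integration time (s). The age extension makes every
component an explicit function of observer age $A$ (years):

* the pupil diameter $d(A)$ (Watson's age correction of the unified
  luminance–field-size formula), which feeds both the retinal
  illuminance $E$ (troland, Stiles–Crawford-corrected) and the
  aberration part of the optical blur
  $\sigma_{opt} = \sqrt{\sigma_0^2 + (C_{ab} d)^2}$;
* fitted analytical age curves for the four free parameters: the
  intrinsic blur $\sigma_0(A)$ (0.42 at age 17 rising towards 0.68),
  the quantum efficiency $\eta(A)$ (0.042 falling towards 0.019), and
  piecewise-constant $k(A)$ (3 below/at age 50, 4 above) and
  $u_{opt}(A)$ (35 cpd, then 30 cpd);
* retinal cell-density models: foveal cone density declining linearly
  with age, ganglion density anchored at $3 N_c(A, 0)$ with a
  two-lobe Lorentzian eccentricity profile, which scales the neural
  noise and the lateral-inhibition drop-off frequency off-fovea.

Assumptions inherited from this modelling tradition: photopic
adaptation (all fitted data lie between 12.5 and 300 cd/m²), foveal or
near-foveal square test fields, detection (not identification)
thresholds, and an age domain of 17–90 years — below 17 the fitted age
curves involve fractional powers of negative numbers and are undefined,
so the package raises a domain error rather than extrapolating.

## Parameters and constants

| name | meaning | units | default |
|------|---------|-------|---------|
| `k` | detection signal-to-noise ratio | — | age curve (3 or 4) |
| `u_opt` | optical cut-off frequency | cpd | age curve (35 or 30) |
| `sigma0` | intrinsic optical SD | — | age curve (0.42–0.68) |
| `eta` | quantum efficiency | fraction | age curve (0.019–0.042) |
| `Cab` | aberration coefficient | per mm | 0.08 |
| `p` | photon conversion factor | photons s⁻¹ deg⁻² Td⁻¹ | 1.285×10⁶ |
| `phi0` | foveal neural noise | s deg² | 3×10⁻⁸ |
| `u0` | foveal inhibition drop-off | cpd | 7 |
| `Te` | eye integration time | s | 0.1 |
| `gain` | global sensitivity gain | — | 1 |

All constants live in a single `csf_constants()` block and can be
overridden programmatically or from a YAML file. On the scale of `p`:
the photopic photon-conversion factor is conventionally quoted with a
fractional mantissa (1.285), but the troland-to-photon-flux conversion
is of order $10^6$; using the bare mantissa would make photon noise ten
orders of magnitude larger than the neural noise ($3\times10^{-8}$
s deg²) and drive sensitivities to zero. The default is therefore
$1.285\times10^6$, which makes the two noise sources commensurate and
yields photopic sensitivities of order $10^2$–$10^3$.

## Choices where the formulation was open

Several pieces of the model circulate in slightly different renderings;
the package fixes them as follows and exposes switches where the
alternative is defensible.

* **Squared lateral-inhibition term.** The noise-propagation algebra
  ($\Phi_n = \Phi_{opt} M_{lat}^2 + \Phi_{neu}$, threshold filtered by
  $M_{opt} M_{lat}$) forces $\Phi_{neu}/M_{lat}^2$ in the denominator.
  The spatiotemporal variant is treated analogously, with
  `squared_neural_term = FALSE` available for the literal unsquared
  reading.
* **Prefactor.** The same algebra yields
  $M_{opt}/k \cdot \sqrt{XYT/(2(\cdot))}$; an alternative convention
  differing by $\sqrt 2$ exists, so a global `gain` constant (default
  1) makes either scale reachable. The absolute sensitivity scale is
  not validated by data in any case (see Limitations).
* **Inhibition cut-off off-fovea.** The drop-off frequency is
  $u_{inh}(A,e) = u_0 \cdot r \cdot b(e)^{-1/2}$ with $r$ the ganglion
  density ratio $N_g(A,e)/N_g(A,0)$ and $b(e)$ a fixed eccentricity
  bracket whose weights (0.85, 0.13, 0.02) sum to exactly 1 at the
  fovea. The linear-ratio reading is the default because substituting
  $r = b$ recovers the classical $u_0\, b^{1/2}$ form exactly;
  `inhibition_ratio = "sqrt"` gives the square-root reading.
* **Age-50 boundary.** The piecewise $k, u_{opt}$ step lies between the
  fitted groups whose means straddle 50–55 years; age 50 itself is
  assigned to the young branch ($A \le 50 \Rightarrow k = 3$).
* **Slow flicker.** $k^*(w)$ involves $(w - 0.5)^{2.497}$; below 0.5 Hz
  it is clamped at its limit value 1.0835 (static or quasi-static
  stimuli).
* **Temporal filters.** The temporal optical and inhibition MTFs
  $H_1, H_2$ have no published closed form in this model family; they
  are pluggable callables (identity by default, which reduces the
  spatiotemporal model to the spatial one divided by $k^*(w)$).

## The fitting engine

`grid_fit()` reproduces the original estimation protocol: a
deterministic search over a finite grid, $\eta \in [0.005, 0.150]$
step $10^{-4}$, $\sigma_0 \in [0.01, 2.00]$ step 0.01,
$u_{opt} \in [1, 100]$ step 2.5, $k \in [0.5, 20]$ step 0.25 —
about $9\times10^8$ combinations. Two exact reformulations make this
tractable:

1. the prediction factorises as
   $\hat s(u) = g\, A(u;\sigma_0,u_{opt})\, B(u;\eta)/k$, so the sum of
   squared errors is quadratic in $1/k$ with coefficients
   $\sum A^2B^2$ and $\sum A B s^{obs}$ that are matrix products over a
   $(\sigma_0 \times u_{opt})$-by-$\eta$ grid slab;
2. the default `"staged"` strategy searches $\sigma_0$, $u_{opt}$ and
   $k$ **in full** (those axes are short) and stages only the long
   $\eta$ axis: a stride-⌈n/150⌉ scan locates the basin, then the
   surrounding window (±2 strides) is re-searched at full resolution,
   expanding whenever the optimum lands on a window edge.

Staging only $\eta$ is deliberate: the optical MTF depends on
$(\sigma_0, u_{opt})$ **only through the ratio**
$\sigma_{opt}/u_{opt}$, so the error surface carries an exact ridge in
that plane and any coarsening there can strand the search on the ridge
away from an on-grid optimum. Ties are broken by the lexicographically
smallest $(\eta, \sigma_0, u_{opt}, k)$, and the `"exhaustive"`
strategy (identical code path without staging) is available behind an
explicit flag; on thinned grids, and on a full-grid noisy fixture we
checked, both strategies return the identical argmin. The reported
RMSE is recomputed through the forward model at the returned optimum,
independently of the factorised search.

## Identifiability — what a fit can and cannot recover

The ridge above is not a numerical nuisance but a structural property:
$\sigma_0$ and $u_{opt}$ are **jointly unidentifiable** from CSF data,
at any noise level, because only $\sigma_{opt}/u_{opt}$ enters the
model. Noise-free data generated from an on-grid parameter set are
recovered *exactly* (the true point is the unique zero-residual grid
point), but under realistic 5% multiplicative noise the fitted
$(\sigma_0, u_{opt})$ slide along the ridge while their blur ratio is
recovered to a few percent. Likewise $\eta$ is only weakly identified
at photopic luminances, where neural noise dominates photon noise over
most of the frequency range, and it trades off against $k$; $k$ itself
is well recovered (its grid is coarse relative to its leverage). The
package's tests therefore pin recovery of the identifiable quantities
— $k$, the blur ratio, and the residual RMSE relative to the curve
scale — rather than per-parameter equality for $\sigma_0$, $u_{opt}$
and $\eta$. Users interpreting fitted parameter values (including
published per-group estimates obtained with this protocol) should keep
this degeneracy in mind.

A related wrinkle: a handful of the published per-group estimates
($k = 3.77$ or $4.10$, $u_{opt} = 27, 30, 34, 35, 45$) do not lie on
the stated search grid ($k$ step 0.25 from 0.5; $u_{opt}$ step 2.5
from 1). The package keeps the stated ranges and samplings; only the
$\eta$ granularity ($10^{-4}$, consistent with every printed
four-decimal $\eta$) is treated as pinned by the estimates table.

## The synthetic-data generator

`synthesize_dataset()` emulates the kind of photopic CSF table the
model is fitted to: a default frequency ladder of
{0.5, 1, 2, 4, 8, 16, 22} cpd spanning the ranges of the reference
experiments, group ages 17–77 years, luminances 12.5–300 cd/m² (the
packaged examples use 100 cd/m², 5.5° binocular — one reference
condition), and sensitivities equal to the forward model times a
multiplicative lognormal multiplier with mean 1 and a default
coefficient of variation of 5% — psychophysical thresholds are
ratio-scale, and multiplicative noise keeps synthetic sensitivities
positive. Draws are seeded and restore the caller's RNG state.

What it does **not** emulate: between-observer variability within an
age group (it draws one noisy curve, not a panel of observers),
frequency-correlated measurement error (staircase procedures share
state across frequencies), lapses/guessing asymmetries, or optical
pathologies. Passing recovery tests on these synthetic tables
therefore demonstrates correctness of the estimation machinery under
the model's own noise assumptions — not that real per-observer CSF
data would constrain the parameters equally well.

## Numerical choices

* $\mathrm{CSF}(0) = 0$ exactly: $M_{lat}(0) = 0$ makes the neural term
  infinite; the IEEE semantics ($1/0 = \infty$, $x/\infty = 0$) give
  the correct limit without special-casing.
* $\eta(A)$ is numerically flat at its 0.042 limit just above age 17
  (the inner exponential underflows); tests assert strict monotonicity
  away from the boundary only. $k^*(w)$ similarly saturates at its
  4.188 asymptote above ~20 Hz.
* Age extrapolations of the pupil model that would produce a
  non-positive diameter raise an error instead of clamping — a clamped
  pupil would silently corrupt the illuminance and noise chain.
* Grid axes are built as `from + step * (0:n)` with a floored `n`, so
  no axis overruns its stated range (the $u_{opt}$ axis tops out at
  98.5 cpd).
* Grid ties are broken lexicographically; staged and exhaustive
  searches share one evaluation path so their tie behaviour is
  identical.
* JSON serialisation uses 17 significant digits so parameter sets and
  comparison reports round-trip doubles without loss; the CSV writer
  does the same.

## Problem sizes used by the test suite

The packaged checks run at desk scale: oracle-equivalence sweeps use
200 random (age, frequency, condition) tuples; recovery experiments
use one synthetic 7-frequency curve per fit, 20 seeded replicates for
the noisy-recovery characterisation, and staged-vs-exhaustive
equivalence on grids thinned tenfold per axis (the full-grid
exhaustive search, ~13 s, was run during development to validate the
staged optimiser and is exercised in tests only on thinned grids).

## Known limitations

* Photopic only: no rod pathway, dark-adaptation kinetics or
  mesopic/scotopic extension — the age-dependent data needed to fit
  one are lacking.
* The absolute sensitivity scale is validated only by order of
  magnitude and shape properties (band-pass, peak position, age
  ordering); no published full worked value exists to anchor it, which
  is why the `gain` constant is exposed.
* The published RMSE comparisons against the three reference
  experiments are not reproduced here: those experiments' data points
  are not available in machine-readable form. The comparison machinery
  is validated on synthetic data instead.
* $H_1, H_2$ temporal filters are user-supplied; with the identity
  defaults the spatiotemporal prediction is exact only up to the
  $k^*(w)$ attenuation.
* Eccentricity handling scales the neural quantities but keeps the
  optical chain foveal; wide-field predictions ($e \gtrsim 30°$)
  should be treated as qualitative.
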