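---
title: "Methods: TG-43 characterization of a miniature X-ray tube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TG-43 characterization of a miniature X-ray tube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electronic brachytherapy replaces radionuclide sources (Ir-192, Co-60) with
a miniature kilovoltage X-ray tube. Before such a source can be used
clinically its dose distribution must be characterized in the AAPM TG-43
formalism, which factorizes the dose rate around the source as

$$\dot D(r, \theta) \;=\; \Lambda \cdot
  \frac{G(r,\theta)}{G(r_0,\theta_0)} \cdot g(r) \cdot F(r,\theta),$$

with the reference point at $r_0 = 1$ cm on the transverse plane
($\theta_0 = 90^\circ$). For a carbon-nanotube cold-cathode tube the source
is well approximated as a point, so the geometry function is
$G_P(r) = 1/r^2$ throughout; `mxt43` deliberately does not offer the
line-source variant. Because the tube's output is controlled by its
emission current rather than contained activity, the dose-rate constant
$\Lambda$ is carried per unit current (cGy h^-1^ uA^-1^); the classical
division by air-kerma strength $S_K$ is available as an explicit separate
mode of `dose_rate_constant()`, with the unit harmonization (1 Gy cm^2^
min^-1^ = 6000 cGy cm^2^ h^-1^) documented rather than implied.

The experimental geometry this package models measures in an ABS plastic
phantom with radiochromic film placed in a plane 1 cm *below* the source
axis (to avoid the film's directional response at glancing incidence), and
converts the ABS-measured parameters to water through a distance-dependent
conversion function derived from paired depth-dose curves. Every stage of
that chain is implemented and testable here against a synthetic dose
kernel that stands in for Monte Carlo transport.

## The synthetic dose kernel

`generate_dose_grid()` evaluates, at every voxel centre,

$$D(r,\theta,\phi) = K\, r^{-2}\, c_m\, A_m(r)\, f(\theta)\,
  (1 + \varepsilon\, h(\phi))\, (1 + \text{noise}),$$

with

* **attenuation** $A_m(r) = w\,e^{-\mu_\text{fast} r} +
  (1-w)\,e^{-\mu_\text{slow} r}$ per medium, a two-component spectral
  mixture: the soft part of a kilovoltage spectrum is absorbed within the
  first centimetres while the hardened remainder decays slowly. A
  single-exponent form (even with a quadratic hardening term in the
  exponent) cannot reproduce both the steep initial fall-off and the slow
  tail of the packaged radial-dose tables; the mixture reproduces the water
  table within 0.039 at every tabulated radius. $A_m(0) = 1$ by
  construction.
* **medium scale** $c_m$, a dimensionless absorption factor letting the
  water/ABS dose ratio exceed 1 near the source.
* **polar profile** $f(\theta) = 1 + \sum_k a_k \cos^k\theta$, normalized to
  1 on the transverse plane by construction. The default is a cubic with
  $f(0^\circ) = 1.16$ (forward bremsstrahlung enhancement) and
  $f(180^\circ) = 0.85$; the backward value is a design choice (no backward
  data exist to calibrate against) representing modest attenuation by the
  tube body while keeping the profile positive everywhere. An unconstrained
  least-squares cubic would dip negative behind the source, which is why
  the constrained fit is used.
* **azimuthal ripple** $h(\phi) = \sin(2\phi + \phi_0)$ with amplitude
  $\varepsilon = 0.03$ by default, i.e. a 6% peak-to-trough azimuthal
  variation with its maximum ratio near 150 degrees, matching the scale
  and location of the reported azimuthal dependence.
* **noise**: multiplicative Gaussian with relative SD 0.007 by default,
  seeded and reproducible. This is a free parameter of the stand-in, not a
  Monte Carlo tally error model; the per-voxel relative-error maps of a
  real MC engine are out of scope.

### Calibration of the defaults

The default coefficients in `default_kernel_params()` are frozen results of
a one-time least-squares calibration: the two attenuation mixtures were fit
jointly to the packaged water and ABS radial-dose tables *and* to the two
conversion-factor endpoints (water/ABS ratio 1.23 at 1 cm, 0.85 at 5 cm);
the polar coefficients were fit to the packaged per-angle anisotropy means
under the two endpoint constraints above. These defaults are the study
conditions assumed by the acceptance tests and are not tuning knobs.

### What the generator does and does not emulate

It reproduces inverse-square falloff, medium-dependent beam hardening (so
the water/ABS ratio falls from above 1 to below 1 with distance),
forward-peaked polar anisotropy, a small azimuthal ripple, and seeded
multiplicative scoring noise on a 1 mm voxel lattice bounded by the
30 x 30 x 20 cm^3 phantom. It does **not** transport photons or electrons:
there is no scatter tail beyond what the mixture absorbs, no spectral
scoring, no heterogeneity (the film slice is not modelled as a material),
and the noise is spatially white rather than correlated as real tally noise
is. Passing tests therefore demonstrate that the *analysis chain* recovers
known ground truth under realistic structure — not that the kernel is a
substitute for transport physics on real data.

## Extraction choices

* **Interpolation.** Trilinear everywhere, voxel centres defining sample
  positions — but applied to the geometry-reduced field $D \cdot r^2$, with
  the $1/r^2$ restored analytically at the sample point
  (`dose_at(..., geometry_corrected = TRUE)`, the default). Interpolating
  the raw dose on a 1 mm lattice is biased high by about 1% at the 1 cm
  reference point because $1/r^2$ is strongly convex there; that bias
  propagates into every normalized parameter. Removing the geometry factor
  before interpolating — the standard practice for TG-43 dose tables —
  reduces it below 0.1%. The transverse reference dose at $r_0$ is
  interpolated log-log so a pure inverse-square profile interpolates
  exactly.
* **Ring and bin averaging.** $g(r)$ uses the azimuthally averaged
  transverse dose (2.5 degree steps); $F(r,\theta)$ averages a 2-degree
  polar bin azimuthally (5 degree steps), mirroring voxel-ring averaging;
  at $\theta = 0$ the ring degenerates to the on-axis point. Film-plane
  pixels are binned to polar lattice cells of half-width 0.05 cm and
  1 degree, with each pixel referred to the node radius through $1/r^2$;
  at the reference point specifically, the film plane is tangent to the
  $r_0$ sphere (every pixel sits at $r > r_0$), so the reference film
  reading is the pixel directly below the source rather than a cell
  average.
* **Normalization is exact.** $g(r_0) = 1$, $F(r,\theta_0) = 1$ and the
  azimuthal ratio at $\phi = 0$ are set identically to 1, not merely to
  within floating-point error. Converted $g$-tables are renormalized at
  $r_0$ automatically.
* **Masking, not filling.** Anisotropy rows without a valid transverse
  reference are masked with a warning; film samples outside the
  measurability region ($\theta < 20^\circ$ or $r\sin\theta < d$) carry
  `valid = FALSE`; comparisons intersect validity masks. Argmax ties break
  toward smaller $r$, then smaller angle; statistics use the sample SD
  (n - 1).

## Film dosimetry model

netOD follows the standard background-subtracted log-ratio convention
(`log10((unexposed - background) / (exposed - background))`), red channel
by default, since the source geometry prints no formula. Calibration fits
dose as a third-order polynomial in netOD (at least four distinct levels),
refuses non-monotone fits, and stores the residual SD; conversion flags
out-of-range netOD (no silent extrapolation) and saturated pixels. The
film's energy dependence at kilovoltage qualities is *not* corrected
pixelwise; it enters only as the dominant 11% Type B budget component, as
in the experimental protocol being modelled. Film scans are 16-bit RGB
TIFF at 75 dpi (0.3387 mm pitch); the in-plane axis along the tube is `u`,
lateral is `v`, a configurable convention since the physical orientation is
not dictated by the formalism.

## Material conversion

`derive_cf()` forms $CF(r) = D_\text{water}(r) / D_\text{ABS}(r)$ on the
shared radii (interpolating monotone-cubically in log dose when lattices
differ). The default fit form keeps the pointwise ratios with monotone
cubic interpolation between them — the source procedure fits "a
distance-dependent conversion function" without stating a form, and the
pointwise form adds no shape assumptions; a low-order polynomial is
available as an option. The stored uncertainty is the water-normalized
RMSE of the converted ABS curve against the direct water curve. Note that
the pointwise form reproduces its own derivation radii exactly (RMSE 0 in
a noise-free world); a meaningful residual arises only for the polynomial
form or when curves are interpolated across lattices — which is why the
packaged experimental budget keeps its literature CF component rather than
substituting the run's own residual.

## Uncertainty budget

Components are carried in percent, typed A (statistical) or B
(systematic), combined in quadrature within type, and totalled as
$\sqrt{A^2 + B^2}$. Two per-region estimators support the Monte-Carlo-side
budget: a dose-weighted mean relative error, and a geometric
(voxel-alignment) term $(max - min)/(2\,\overline{D}\,\sqrt 3)$ over the
voxels of a 1 mm transverse ring — a uniform-distribution approximation
that grows near the source where the gradient across the region steepens.
The packaged budget reproduces the published component set; its strict
quadrature total is 12.02%, and the regression report deliberately flags
the published 12.06% total as non-reproducible from the printed
components.

## Packaged reference tables

The published radial-dose, anisotropy, azimuthal and budget tables ship as
CSV fixtures, checksummed at load. Transcription preserved the source's
internal inconsistencies (two summary SDs and the budget total do not
recompute from the printed cells; the abstract's radial-dose values match
no table column); `regression_report()` recomputes every quoted statistic
from the cells and reports these three as designed failures, so they are
visible rather than silently "fixed". The anisotropy table's ambiguous
short-row alignment was resolved by the film-reach rule
$r\sin\theta \ge 1$ cm, which also places the quoted ratio extrema (1.26
and 0.84) exactly where the text locates them.

## Problem sizes and determinism

The default pipeline simulates two 105^3^ grids at 1 mm voxels (a 10.5 cm
cube centred on the source — large enough for every tabulated radius and
angle, truncating the full phantom, whose outer regions contribute nothing
to the tabulated parameters), extracts the 22 tabulated radii and
10-degree polar grid, and runs the film chain at the 75 dpi pitch; unit
tests use coarser, smaller grids of the same family. All randomness flows
from a single integer seed; two runs with the same seed produce
byte-identical report bundles (no timestamps in outputs; RNG state is
saved and restored around generation).

## Known limitations

* The kernel family is smooth and separable; it cannot represent scatter
  build-up bumps, spectral scoring, or heterogeneity effects, so
  calibration agreement with the packaged tables is bounded (~0.04 in g)
  by the family, not by noise.
* The film chain models a stabilized, orientation-fixed scan; multichannel
  correction, lateral scanner response and batch dependence are out of
  scope.
* The conversion function accepts any curve pair but ships calibrated only
  for the water/ABS pair.
* $S_K$ is an adopted input constant; nothing here re-derives free-air
  kerma, and the link between the per-current and classical $\Lambda$
  conventions is intentionally left to the user's choice of mode.
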