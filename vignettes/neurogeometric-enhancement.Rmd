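---
title: "A Gabor-induced sub-Riemannian geometry for image enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Gabor-induced sub-Riemannian geometry for image enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogabor)
```

## The model

Simple cells in the primary visual cortex (V1) respond to localized,
oriented, band-pass patterns, and neighbouring cells differ systematically
in preferred orientation, spatial frequency and phase. `neurogabor` models
the receptive profile of such a cell as an extended complex Gabor function
and takes that single modelling choice as the generator of everything else
in the package: the feature space, its geometry, the connectivity model, and
an image-enhancement flow.

A profile is parameterized by a *feature point*
$(q_1, q_2, \theta, \omega, \phi)$ on the five-dimensional manifold
$\mathcal{M} = \mathbb{R}^2 \times S^1 \times \mathbb{R}^+ \times S^1$:
retinal position, orientation, spatial frequency (radians/pixel) and phase.
Every profile is a rototranslated, frequency-modulated, phase-shifted copy
of the mother profile

$$\Psi_0(x, y, s) = e^{-i(\omega y - s)}\, e^{-(x^2 + y^2)/\sigma^2},$$

with the plane-wave vector $r = (-\omega \sin\theta, \omega \cos\theta)$
after rotation. The temporal rate multiplying the phase coordinate is fixed
to 1: the model is static. `sigma = 1` is the unit-width profile of the
analytic development; all experiments in this package use `sigma = 2`
pixels.

**Lifting.** Correlating an image against the filter bank at phase 0
produces a complex coefficient field $O(q_1, q_2, \theta, \omega)$ — the
simple-cell output responses, or the *lift* of the image into
$\mathcal{M}$. Two structural facts keep this tractable:

* the phase axis is analytically redundant: the coefficient at phase $\phi$
  is exactly $e^{-i\phi}$ times the phase-0 coefficient, so a 4D array plus
  a unit factor carries the full 5D information (`materialize_phase()`);
* because the bank spans *all* frequencies rather than one, the transform
  admits an exact inverse: an adjoint sum with conjugate filters and
  quadrature weights, then a Fourier-domain normalization (below).

**Contact geometry.** The wave content of the profile couples the spatial
and phase differentials through the 1-form
$\Theta = -\omega \sin\theta\, dx + \omega \cos\theta\, dy - ds$, whose
kernel is spanned by the horizontal frame

$$X_1 = \cos\theta\,\partial_x + \sin\theta\,\partial_y, \quad
  X_2 = \partial_\theta, \quad
  X_3 = -\sin\theta\,\partial_x + \cos\theta\,\partial_y +
        \omega\,\partial_s, \quad
  X_4 = \partial_\omega.$$

The only nonzero brackets are $[X_1, X_2]$, $[X_2, X_3]$ and $[X_3, X_4]$;
adding $[X_1, X_2]$ to the frame spans the full tangent space at every
point (the Hörmander condition), so any two feature points are connected by
horizontal paths. Constant-coefficient horizontal integral curves — circular
arcs in space when the orientation turns, with linear frequency drift and
quadratic phase — are the package's model of V1 association fields
(`closed_form_curve()`, `curve_fan()`).

A note on the volume form: the standard fully antisymmetrized evaluation of
$\Theta \wedge d\Theta \wedge d\Theta$ on the coordinate basis gives
$-2\omega$ (`volume_form_coefficient()`). The factor $-2$ is the
combinatorial constant of this convention; the substantive property is that
the density is proportional to $\omega$ and never vanishes, which is what
makes $\Theta$ a contact form. Tests assert the exact value $-2\omega$.

**Group law.** Each fixed-frequency layer carries a Lie group of rigid
motions extended by phase. The natural law composes the spatial part of the
right factor through the rotation of the *left* factor; a variant that
rotates by the *sum* of both angles is retained behind
`group_multiply(..., as_printed = TRUE)` for comparison, but it fails the
identity axiom ($e \cdot h \neq h$) and is not used anywhere. The package
default is the axiom-satisfying law, verified on thousands of random
triples.

## The enhancement flow

The induced metric on a layer is $g = I + w w^T$ with
$w_i = \sqrt{c_i}\, X_i u$ — identity where the lifted image is flat,
stretched along the horizontal gradient where it is not. Its algebra is
closed-form: $\det g = 1 + |w|^2$ and
$g^{-1} = I - w w^T / (1 + |w|^2)$ (rank-one identities, used throughout
and cross-checked against dense linear algebra in the tests).

Enhancement evolves each frequency channel of the lifted image by the
Laplace–Beltrami flow $\partial_t u = L u$ with

$$L u = \frac{1}{\sqrt{\det g}} \sum_{i,j}
        Y_i\!\left(\sqrt{\det g}\; g^{ij}\, Y_j u\right),
  \qquad Y_i = \sqrt{c_i}\, X_i,$$

in the *reduced* setting $c_3 = c_4 = 0$: diffusion acts along the
orientation-aligned spatial direction ($X_1$) and the orientation axis
($X_2$) only. Reasons: direct $X_3$ diffusion blurs across object
boundaries (the commutator $[X_1, X_2]$ already provides the needed
transversal coupling), phase diffusion is a no-op up to a constant factor,
and dropping $X_4$ keeps frequency channels independent, so each channel is
a three-dimensional rototranslation-layer flow instead of one
five-dimensional problem. The metric weights enter through the weighted
frame $Y_i$, which makes the small-amplitude limit of $L$ exactly the
weighted horizontal Laplacian $c_1 X_1 X_1 + c_2 X_2 X_2$. The $c_3, c_4$
hooks remain in `flow_config()` because reversing the roles of
$(c_1, c_2)$ and $(c_3, c_4)$ is the natural starting point for inpainting
rather than enhancement; no inpainting algorithm is shipped.

Real and imaginary parts of each channel evolve as independent scalar
flows, each inducing its own metric (`metric_source = "channel"`, the
default). The complex coupling is not uniquely determined by the model;
`metric_source = "modulus"` shares the modulus-induced metric between both
parts, and `"identity"` freezes the metric for linear horizontal diffusion.

## Discretization

* **Spatial derivatives.** $X_1$ needs samples at
  $q \pm (\cos\theta_k, \sin\theta_k)$, which are off-grid for most
  orientations; they are obtained by cubic B-spline interpolation
  (`interp_order = 3`, with exact prefiltering via a direct tridiagonal
  solve) or bilinear interpolation (`interp_order = 1`, whose nonnegative
  stencils give a discrete maximum principle). Because the offset is
  uniform over a slice, interpolation is a cached linear map — one small
  matrix per axis per orientation.
* **Angular derivatives.** Periodic central differences with spacing
  $2\pi/K$.
* **Divergence form.** $L$ is realized in two passes of the first-order
  central differences: derivatives, then fluxes
  $F_i = \sqrt{\det g}\, g^{ij} Y_j u$, then derivatives of the fluxes.
  The composition of two central first differences is a *wider* stencil
  than the direct second difference used by
  `sub_riemannian_laplacian()`; the two agree exactly on spatially
  quadratic, orientation-constant fields, which is how the
  small-amplitude-limit test is posed (on the deep interior of a 48-pixel
  grid, margin 16, where boundary effects of the spline prefilter — which
  decay geometrically at rate $2 - \sqrt3 \approx 0.27$ per pixel — are
  below $10^{-6}$).
* **Boundaries.** Reflective in $x, y$ (edge-mirrored, matching diffusion
  semantics on photographs), periodic in $\theta$. A fully periodic mode
  exists for spectral tests.
* **Time stepping.** Explicit Euler, $u \leftarrow u + \Delta t\, L u$,
  with the metric recomputed every iteration by default
  (`metric_period`). The Gershgorin bound on the admissible step is

  $$\Delta t \le \frac{4 s_\theta^2 r}
    {1 + 2\sqrt2\, s_\theta \sqrt r + 3 s_\theta^2 r - |1 - s_\theta^2 r|},
    \qquad s_\theta = \frac{2\pi}{K},\; r = \frac{c_1}{c_2},$$

  which evaluates to $0.87$ at the reference configuration ($K = 16$,
  $c_1 = 1$, $c_2 = 0.0625$); the operational step $0.1$ sits well inside
  it. `flow_state()` and `enhance()` refuse a step above the bound. The
  bound localizes eigenvalues of the *frozen-coefficient* update; it is not
  a discrete maximum principle. For the bilinear stencils the
  max-principle threshold is the stricter $1/(2(c_1 + c_2/s_\theta^2))
  \approx 0.36$ at the reference configuration, so the monotonicity test
  runs at $0.3\times$ the Gershgorin bound and the energy-decay test at the
  operational $\Delta t = 0.1$, both below that threshold.

**Normalization of the inverse transform.** The continuum inverse carries a
reproducing constant that depends on the bank; the package absorbs it by
dividing the adjoint in the Fourier domain by the bank's weighted coverage
$\sum_c w_c |\hat\Psi_c|^2$, floored at $10^{-3}$ of its maximum
(Wiener-style). This equalizes non-uniform frequency sampling and makes the
periodic-boundary round trip exact wherever the coverage clears the floor.
A consequence worth stating plainly: with scale-2 filters the coverage of
the shipped banks never falls below about $2\%$ of its maximum anywhere on
a 64-pixel Fourier grid, even with only 4 orientation samples, so the
normalized round trip is nearly independent of the orientation count $K$.
What *does* degrade with small $K$ is the coverage itself — its minimum
over the represented frequency annulus drops markedly from $K = 16$ to
$K = 8$ (`spectral_coverage()`), which is the quantity the package tests
for the sampling-quality claim. An unnormalized adjoint inverse would
translate those coverage ripples directly into reconstruction artifacts;
the normalized inverse deliberately does not.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `sigma` | pixels | 2 | Gaussian envelope scale of all filters |
| `trunc_factor` | — | 6 | half-width of filter support in units of `sigma` (24 px total at scale 2; the 256-pixel preset uses 12, i.e. 48 px) |
| `K` | — | 16 | orientation samples on $[0, 2\pi)$ |
| `omegas` | rad/pixel | 0.25–2.25 | frequency grid; non-uniform grids get trapezoidal quadrature |
| `c1, c2` | — | 1, $\beta^2$ | diffusion weights; $\beta = K/N$ matches angular and spatial units ("space homogeneity") |
| `dt` | — | 0.1 | explicit Euler step, checked against the bound |
| `iterations` | — | 15 | diffusion time $T = \mathrm{iterations} \times \Delta t$ |

## Synthetic data

All test inputs are generated in code: oriented gratings
$0.5 + 0.5\,c\,\cos(\omega_0(-x\sin\theta_0 + y\cos\theta_0) + \mathrm{ph})$,
composites of several gratings with total contrast capped at 1, and
additive white Gaussian noise applied without clipping (the flow theory is
linear in intensity; clipping happens only at image export). Two presets
are pre-registered:

* `noisy-gratings-64` — the enhancement test scene: two gratings
  ($\theta = 0, \omega = 0.75$ and $\theta = \pi/3, \omega = 1.5$,
  contrast 0.5 each) with $\sigma_n = 0.1$ noise, seed 42;
* `bandlimited-64` — five noise-free gratings with integer wave vectors
  (exactly periodic on the 64-grid) spanning the covered band, for
  transform round-trip studies.

What these fixtures emulate: oriented multi-frequency structure plus white
noise, the regime the diffusion model addresses. What they do not emulate:
natural-image statistics (broadband $1/f$ spectra, occlusions, textures),
so a passing enhancement test demonstrates correct mechanics of the flow,
not photographic image quality. Problem sizes in the shipped tests —
$64 \times 64$ images, $K \in \{8, 16, 32\}$, up to 29 frequencies, 15
iterations — are the package's chosen study conditions; the enhancement and
multifrequency comparisons each run in well under a minute per
configuration on one core.

## Numerical and design choices, in brief

* The forward lift carries no conjugate; the conjugate filters belong to
  the inverse. Both are computed as FFT products; the direct-sum definition
  is retained in the test suite as an oracle.
* The frequency quadrature on non-uniform grids is trapezoidal; the phase
  integral contributes a constant ($2\pi$) because the integrand is a unit
  factor.
* Branches of the closed-form curves switch at $|c_2| = 10^{-10}$; the
  two branches already agree to $10^{-5}$ at $|c_2| = 10^{-8}$.
* Curves are truncated where $\omega \le 0$: positive frequency is a
  manifold constraint, not a numerical convenience.
* Frozen metric plus bilinear interpolation plus $\Delta t$ under the
  monotonicity threshold yields a convex-combination update, hence the
  max-principle test; cubic splines trade that guarantee for accuracy.
* Divergence detection: any non-finite value after an Euler step raises an
  error naming the iteration.

## Known limitations

* The enhancement flow processes each frequency layer independently
  ($c_4 = 0$); cross-frequency coupling is representational (shared
  reconstruction), not dynamical.
* The reflective-boundary round trip has a systematic $\sim 2$–$3\%$ L2
  error on 64-pixel gratings scenes, dominated by the mismatch between
  reflect-padding of coefficients and the true lift of a padded image.
* No sub-Riemannian distance computation, geodesics, or inpainting
  algorithm; the rotation-by-sum group variant is exposed for inspection
  only.
* Filter support is configurable (`trunc_factor`) rather than fixed,
  because the two natural choices (24 px and 48 px at scale 2) serve
  different image sizes; presets encode both.
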