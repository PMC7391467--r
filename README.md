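# neurogabor

Gabor lifting, sub-Riemannian geometry and Laplace–Beltrami image
enhancement — a working implementation of a neurogeometric model of the
primary visual cortex (V1) whose simple cells are selective for
orientation, spatial frequency and phase.

The package is for researchers in computational neuroscience and
biological image analysis who want the full chain from receptive-profile
model to image-processing algorithm in one place:

1. **Receptive profiles.** Each simple cell is an extended complex Gabor
   function: a rototranslated, frequency-modulated, phase-shifted copy of
   the mother profile Ψ₀(x, y, s) = e^{−i(ωy − s)} e^{−(x²+y²)/σ²}, with
   wave vector r = (−ω sin θ, ω cos θ).
2. **Lifting.** Correlating an image against the filter bank maps it to a
   complex coefficient field on the feature manifold
   ℳ = ℝ² × S¹ × ℝ⁺ × S¹ (position, orientation θ, frequency ω, phase φ);
   because *all* frequencies are represented, the transform has an exact
   inverse (adjoint with conjugate filters plus Fourier-domain coverage
   normalization).
3. **Geometry.** The profile's wave content induces the contact form
   Θ = −ω sin θ dx + ω cos θ dy − ds; its kernel is spanned by the
   horizontal frame X₁ = cos θ ∂x + sin θ ∂y, X₂ = ∂θ,
   X₃ = −sin θ ∂x + cos θ ∂y + ω ∂s, X₄ = ∂ω, which is bracket-generating
   (Hörmander). Constant-coefficient horizontal integral curves model the
   association fields of contour integration.
4. **Enhancement.** Each frequency channel evolves by the Laplace–Beltrami
   flow ∂ₜu = Lu of the induced metric g = I + (Yu)(Yu)ᵀ,
   Yᵢ = √cᵢ Xᵢ (reduced weights c₁ = 1, c₂ = β², β = K/N, c₃ = c₄ = 0),
   discretized by explicit Euler with B-spline-interpolated central
   differences and a Gershgorin time-step bound

   Δt ≤ 4s²r / (1 + 2√2·s√r + 3s²r − |1 − s²r|),  s = 2π/K, r = c₁/c₂,

   which evaluates to **0.87** for the reference configuration (K = 16,
   c₁/c₂ = 16) — so the operational step Δt = 0.1 is safely admissible.

Everything is testable offline: seeded synthetic gratings, composites and
Gaussian noise stand in for experimental imagery.

## Worked example

```r
library(neurogabor)

# stability bound for the reference configuration
max_timestep(K = 16, c1 = 1, c2 = 0.0625)
#> [1] 0.8674528

# seeded noisy-grating scene, 64 x 64
fx <- fixture_preset("noisy-gratings-64")
psnr(fx$noisy, fx$clean)
#> [1] 19.96556

# lift through the 16-orientation, 14-frequency bank and diffuse
# (15 explicit Euler steps, dt = 0.1, c1 = 1, c2 = 0.0625)
pr <- preset("enhance-64")
bank <- build_bank(pr$bank)
enhanced <- enhance(fx$noisy, bank, pr$flow)
psnr(enhanced, fx$clean)
#> [1] 20.39633

head(attr(enhanced, "diagnostics"), 3)
#>   iteration  energy  max_abs
#> 1         1 6418179 9.086578
#> 2         2 6382055 9.085932
#> 3         3 6347540 9.085299
```

The flow removes noise energy monotonically (the `energy` column) and
raises the PSNR against the clean scene by ~0.4 dB in 15 iterations; a
single-frequency flow from the same grid always does worse (see the
acceptance suite). The reconstruction warning about sub-floor spectral
coverage refers to the uncovered high-frequency corners of the Fourier
grid, which carry only noise here.

Association-field curves come from the same geometry:

```r
fan <- curve_fan(feature_point(0, 0, 0, omega = 1),
                 curve_coefficients(c1 = 1), vary = "c2",
                 values = c(-1, -0.5, 0.5, 1))
round(as.data.frame(fan[[4]])[c(1, 51, 101), ], 3)
#>       t    q1    q2 theta omega phi
#> 1   0.0 0.000 0.000   0.0     1   0
#> 51  0.5 0.479 0.122   0.5     1   0
#> 101 1.0 0.841 0.460   1.0     1   0
```

i.e. a circular arc of radius |c₁/c₂| = 1 whose orientation advances
linearly — one member of the fan in which ±c₂ trace mirror-image arcs.

A thin command-line wrapper ships in `inst/cli/neurogabor.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/neurogabor.R", package="neurogabor"))')" \
  stability-bound --K 16 --c1 1 --c2 0.0625
# 0.87
```

with subcommands `enhance`, `coverage`, `curves`, `stability-bound`, YAML
configs, and a JSON run manifest recording the resolved parameters and
per-iteration diagnostics.

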