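---
title: "Designing multipigment tissue phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multipigment tissue phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phantomkit` computes pigment recipes for solid tissue-simulating optical
phantoms. This vignette documents the models it implements, the
assumptions behind them, the numerical choices that matter, and what the
synthetic data used in the test suite does and does not establish.

## The data model

Everything is a `spectrum`: a real-valued curve on a regular, inclusive
wavelength grid. The working grid is 370–950 nm at 1 nm (581 samples),
the range over which pigments are characterized; all fits resample their
inputs onto the basis grid first, and extrapolation outside a measured
range is an error rather than a guess. Units are declared per spectrum
(mm⁻¹ for optical coefficients, dimensionless in [0, 1] for reflectance)
and never converted silently.

A `pigment_basis` holds per-unit-concentration absorption and reduced
scattering spectra for a named set of pigments, tagged by optical role
(yellow, magenta, miscellaneous, white, black). Concentration is mass
fraction — mg pigment per g total phantom mass — and mixing is assumed
exactly linear in concentration: characterized pigments are normalized to
their mass fraction, and no saturation model is applied. A `recipe` is a
nonnegative concentration vector over basis names.

## Recipe design from optical properties

**Two-step broadband fit.** Tissue absorption varies over two to three
orders of magnitude between the blue and the NIR, so an unweighted
least-squares fit would spend all of its freedom on the blue peak. Step
one therefore solves a weighted NNLS over the non-white pigments,

μa-objective: Σλ [w(λ) μa(λ) − w(λ) C_abs(λ) x]², w(λ) = max μa / μa(λ),

which makes every wavelength count equally on a relative scale. Target
values below 10⁻⁶ mm⁻¹ are clamped before the division so weights stay
finite. Step two subtracts the scattering that the fitted absorbers
already contribute (colored pigments scatter measurably) from the target
μs′, clamps negative residuals to zero per wavelength, and solves a plain
NNLS over the white pigments. Both solves use the Lawson–Hanson active-set
algorithm (`pracma::lsqnonneg`), which terminates at exact KKT conditions;
recovered concentrations on noiseless representable targets are exact to
rounding (the test suite asserts ≤ 10⁻⁶ relative).

One structural consequence of the two-step split: all absorption is
attributed to non-white pigments. TiO2- and ZnO-like whites absorb below
~410/380 nm, so a recipe containing them is *not* an exact fixed point of
the two-step method — that UV absorption surfaces as blue-end residual,
the same limitation seen in physical phantoms. The joint band fit below
has no such split and can represent absorbing whites exactly.

**Band-weighted joint fit.** Many applications only need properties
matched at discrete bands. A single NNLS over all pigments minimizes
Σλ [w_a(λ)(μa − C_abs q)² + w_s(λ)(μs′ − C_scat q)²] with strong weights
inside the requested bands and weight 1 outside. When per-band weights
are not given they default to K / (in-band maximum of the target
property) with K = 1000, which puts bands of very different magnitude on
a comparable footing; the weights are exposed because band prioritization
is application-specific. An empty band set degenerates to the uniform
joint fit.

**Composite-spectrum utilities.** Measured absorption built from two
sample thicknesses is merged with `sigmoid_blend`: the thin-sample curve
is used up to 560 nm, the thick-sample curve from 620 nm, and a logistic
ramp centred at 590 nm with 10 nm scale bridges the gap (weights < 1%
outside the transition, and the pure spectra are used exactly outside
[560, 620]). Scattering curves are constrained to the Mie–Rayleigh
power law μs′(λ) = a[f (λ/λ₀)⁻⁴ + (1−f)(λ/λ₀)⁻ᵇ] with λ₀ = 500 nm,
a ≥ 0, f ∈ [0, 1], b ∈ [0, 4]; `power_law_fit` is a bounded
Levenberg–Marquardt solve with a 9-point multistart over (f, b) because
the surface has a ridge where Rayleigh fraction trades off against large
Mie powers.

## The white Monte Carlo reflectance model

Diffuse reflectance depends on refractive index as well as on (μa, μs′),
and epoxy (n = 1.56) is far from tissue; matching measured reflectance
directly therefore requires a transport model. The forward model is a
*white* Monte Carlo: a single scattering-only random walk ensemble in a
semi-infinite half-space at unit scattering coefficient, pencil beam at
normal incidence, Henyey–Greenstein phase function with g = 0.8
(fixed globally, which is what makes one reference run valid across
wavelengths under similarity scaling μs = μs′/(1−g)). At each surface
encounter the photon weight splits deterministically: the Fresnel
transmitted fraction escapes and is recorded as (cumulative dimensionless
pathlength, weight); the reflected fraction continues. Specular
reflection of the incident beam is excluded from the diffuse tally. Any
(μa, μs′) query is then

R_d = (1/N) Σᵢ wᵢ exp(−μa Lᵢ), Lᵢ = pathᵢ/μs.

Total diffuse detection over all exit angles mirrors an integrating
sphere; there is no aperture model, no layered media and no transmission
tally (phantoms are assumed optically thick).

Numerical choices:

- **Termination and tail capture.** Walks are terminated at a cumulative
  pathlength of 10⁵ mean free paths or when the weight falls below 10⁻⁶.
  In a non-absorbing half-space every photon eventually escapes, so
  discarding residual weight would bias R_d low by ~1% at μa → 0 for a
  mismatched boundary (first-return times are heavy-tailed). The residual
  weight is instead tallied as escaping at the termination pathlength:
  energy is then conserved exactly at μa = 0, and the upward bias at
  μa > 0 is bounded by w_res · exp(−μa·cap/μs) — about 10⁻⁹ relative at
  μa = 10⁻³ mm⁻¹.
- **Determinism.** The walk uses R's RNG under an explicit seed stored in
  the configuration and in every cache file; identical (seed, config)
  reproduce the ensemble bit for bit.
- **Validation.** The estimator is checked three ways in the test suite:
  energy conservation at zero absorption; agreement within 2% with an
  independently coded diffusion-approximation closed form (extrapolated
  boundary, image source) at transport albedo ≥ 0.99 for a matched
  boundary; and agreement with a direct absorption-sampling Monte Carlo
  (steps at μt, albedo weighting per collision) within Monte Carlo noise
  on random property pairs.
- **Compression.** For iterative fitting the ensemble is aggregated into
  4096 log-spaced pathlength bins carrying (weight sum, weight-averaged
  path). Total weight — hence R_d at μa = 0 — is preserved exactly, and
  reflectance at μa > 0 is reproduced to ~10⁻³ relative; fits and their
  targets use the same compressed ensemble so the inner objective is
  exact.
- Default photon budgets: 10⁵ for characterization-quality runs, smaller
  ensembles (5×10³–2×10⁴) in tests where only consistency, not variance,
  is at stake.

## Reflectance inversion and its degeneracy

`fit_reflectance` minimizes Σλ [R(λ) − wMC(C_abs q, C_scat q, n)]² over
q ≥ 0 with a fixed ensemble (common random numbers), so the objective is
deterministic and smooth, using Levenberg–Marquardt with box projection
and an *analytic* Jacobian: R_d depends on q only through
k(λ) = μa(1−g)/μs′, and dR_d/dk = −(1/N) Σ wᵢ pathᵢ e^{−k·pathᵢ} comes
from the same ensemble at negligible cost.

A semi-infinite homogeneous medium has no intrinsic length scale, so its
reflectance depends on (μa, μs′) only through the ratio k per wavelength.
Scaling an entire recipe by a constant changes nothing in the predicted
spectrum: *the inverse problem is underdetermined by exactly one global
scale factor*. The fit therefore accepts an optional scattering anchor —
the μs′ the phantom should have at a reference wavelength (500 nm by
default), entering as one extra weighted residual. Without it the fit
still matches the spectrum but reports in its diagnostics that the
concentration scale was set by the starting point.

Initialization exploits the same structure: each target value is
inverted for k(λ) through the ensemble (R_d is strictly decreasing in k,
a bracketed 1-D root), after which the recipe must satisfy the *linear*
homogeneous system (C_abs − K C_scat/(1−g)) q = 0 plus the anchor row —
one NNLS. On targets the basis can represent, this start is already the
solution to rounding; on real targets it lands close and the LM polish
minimizes the true reflectance-space objective. A diffusion-theory
inversion against a generic skin-like scattering prior is retained as a
fallback initializer, with uniform small concentrations behind that.
Convergence: relative objective decrease below 10⁻¹⁰ or 200 iterations;
non-convergence is flagged in the result, not thrown. The inner loop
runs on a 5 nm wavelength subsample; reported predictions and metrics
are on the full grid.

## The skin model and three-band inversion

The computational skin absorption model is the linear chromophore
combination μa = StO2·B·H·μa_HbO2 + (1−StO2)·B·H·μa_Hb + W·μa_water +
F·μa_fat + M·μa_mel on a 470–950 nm grid, with defaults W = 0.5,
F = 0.02, M = 2.55×10⁻⁴ (pale skin) and blood hemoglobin concentration
H = 2.3 mmol/L; B = 4.78% then corresponds to 110 μM total hemoglobin
(B·H). Hemoglobin spectra are per-molar; water, fat and melanin are
pure-substance coefficients scaled by volume fraction.

Inversion uses band-averaged absorption at 540–560, 625–645 and
820–840 nm (inclusive arithmetic means at 1 nm): after subtracting the
assumed water and fat terms, the system is linear in
(u₁, u₂, u₃) = (StO2·B·H, (1−StO2)·B·H, M) and solved directly;
StO2 = u₁/(u₁+u₂) (which cancels H, so the saturation estimate is
invariant to the assumed hemoglobin concentration), B = (u₁+u₂)/H,
M = u₃. Negative components are clamped to zero and flagged; a condition
number above 10¹² or non-positive total hemoglobin is an error. On
noiseless model spectra the round trip is exact to machine precision —
the basis of the acceptance checks — and the classic failure mode is
reproduced qualitatively: because M is small, absolute errors of
+0.01/+0.005 mm⁻¹ in the red/NIR bands move the melanosome estimate by
a factor of ~2–3 while barely moving StO2.

The packaged chromophore table
(`inst/extdata/chromophores_synthetic.csv`) is generated by
`synthetic_chromophores()`: smooth parametric stand-ins with
literature-like shapes and magnitudes (bimodal oxyhemoglobin at 542/577
nm, deoxyhemoglobin 555 nm band and 760 nm shoulder, ~1.2×10⁴ mm⁻¹·M⁻¹
at the visible peaks; water and fat NIR features; power-law melanin).
They are synthetic: users with a preferred literature compilation load
it through `read_chromophores` in the same CSV dialect, and nothing in
the inversion depends on which tabulation is used.

## The synthetic pigment basis

`generate_synthetic_basis` emulates the qualitative structure of a
characterized 20-pigment artist set: 6 yellows (single broad Gaussians,
peaks 400–460 nm, σ 25–40 nm), 6 magentas (bimodal, 500–600 nm,
σ 12–20 nm — narrower than the yellows, as measured pigments are — one
with an extra ~625 nm peak), 3 miscellaneous absorbers (one ~500 nm
peak, two red/NIR absorbers out to 750 nm), 2 blacks (one spectrally
flat, one monotone-decreasing like India ink), 3 whites (Mie–Rayleigh
scattering with distinct amplitude/fraction/power orderings and UV
absorption edges at 410 nm, 380 nm and none). All colored pigments carry
small power-law scattering. Randomized peak positions and magnitudes are
drawn under the given seed, so every basis is reproducible, and the
category-wise spectra are numerically full-rank, which is what makes the
NNLS recovery tests identifiable.

What passing tests on this basis shows: the optimization machinery is
correct (exact recovery, monotone nested-basis behaviour, KKT
optimality). What it does not show: that any particular physical pigment
set can reach a given tissue target — real pigment availability, batch
variation, and measurement noise are outside the generator's scope, and
no inter-batch variability or aging model is included.

## Problem sizes and limitations

The test suite runs the property fits on a 5 nm grid (117 samples) and
the acceptance checks on the full 1 nm grid; Monte Carlo ensembles are
10⁵ photons for the physics checks and 5×10³–2×10⁴ for fitting round
trips, sizes at which the whole suite completes in about a minute while
leaving every assertion tolerance-driven rather than noise-driven.

Known limitations: no layered media or finite-thickness transmission in
the transport model; no aperture/NA model for detection; no uncertainty
propagation from pigment characterization error; recipes are not rounded
to pipettable amounts; published similarity tables for physical phantoms
(which require the measured spectra of those phantoms) are out of scope —
the package reproduces the arithmetic and the noiseless round trips, not
the wet-lab measurements.
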