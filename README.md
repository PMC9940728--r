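# phantomkit

Design tools for **multipigment tissue-simulating optical phantoms**.

Solid epoxy phantoms doped with artist pigments can emulate the
wavelength-dependent absorption (μa) and reduced scattering (μs′) of real
tissue across 370–950 nm — something the traditional single-absorber /
single-scatterer (India ink + TiO2) recipe cannot do. Given a library of
per-concentration pigment optical-property spectra, `phantomkit` computes
the nonnegative pigment recipe whose mixture best matches a target
specified in any of three ways:

1. **Optical-property spectra** — target μa(λ) and μs′(λ), via weighted
   nonnegative least squares (NNLS):
   - a two-step broadband fit: absorbing pigments are fit to μa with a
     magnitude-equalizing weight w(λ) = max μa / μa(λ), then white pigments
     are fit to the residual scattering after subtracting what the
     absorbers already scatter;
   - a single joint band-weighted fit for phantoms that only need to match
     at discrete wavelength bands.
2. **A diffuse-reflectance spectrum** — via a white Monte Carlo (wMC)
   photon-transport model: one scattering-only reference walk ensemble per
   (refractive index, anisotropy) pair is reweighted by exp(−μa·L) to
   predict Rd for any optical-property pair, and a bound-constrained
   nonlinear least-squares loop iterates the recipe until the predicted
   spectrum matches the target.
3. **A chromophore composition** — a computational skin model
   μa(λ) = StO2·B·H·μa_HbO2 + (1−StO2)·B·H·μa_Hb + W·μa_water + F·μa_fat
   + M·μa_mel, with a three-band inversion recovering the hemoglobin
   oxygen saturation StO2, blood volume fraction B and melanosome volume
   fraction M from measured band absorption.

Fit quality is reported with the field's two standard similarity metrics:
mean absolute error (MAE; log10-scale for absorption) and the spectral
angle mapper (SAM), the magnitude-invariant angle between two spectra.

The package ships a seeded synthetic 20-pigment basis generator (6 yellows,
6 magentas, 3 miscellaneous absorbers, 2 blacks, 3 whites) emulating the
qualitative spectra of characterized artist pigments, so the entire
pipeline is runnable and testable without proprietary characterization
data; measured bases load from the same CSV dialect.

## Worked example

Fit a 20-pigment recipe to a hemoglobin-like tissue target:

```r
library(phantomkit)

basis <- generate_synthetic_basis(seed = 1)       # 370-950 nm, 1 nm grid
lam <- wavelengths(basis$grid)
mua <- spectrum(1.2 * exp(-0.5 * ((lam - 542) / 15)^2) +
                1.0 * exp(-0.5 * ((lam - 577) / 12)^2) +
                2.5 * exp(-0.5 * ((lam - 420) / 20)^2) +
                0.02 + 0.04 * pmax(lam - 700, 0) / 250, basis$grid)
musp <- power_law_eval(power_law_params(a = 1.2, f_ray = 0.2, b_mie = 1.2),
                       basis$grid)
target <- tissue_target(mua, musp, label = "hemoglobin-like")

fit_broadband(basis, target)
#> <fit_result>
#> <recipe> basis 'synthetic_seed1'
#>   yellow02     0.303683 mg/g
#>   magenta02    0.46831 mg/g
#>   black_flat   0.0523456 mg/g
#>   white_tio2   0.249905 mg/g
#>   white_zno    0.562484 mg/g
#>   residuals: abs 798.9, scat 0.02703
#>   absorption: MAE 0.2244 (log10 0.2388), SAM 35.3 deg
#>   scattering: MAE 0.00587, SAM 0.386 deg
```

The recipe is in mass-fraction units (mg pigment per g phantom). The
scattering curve is matched almost perfectly (SAM 0.4°); the absorption
shape is matched as well as this pigment set allows (the yellow pigments
are broader than the hemoglobin blue peak). A traditional TiO2 + India-ink
phantom fit to the same target gives log10-MAE 0.501 and SAM 61.4° for
absorption versus 0.239 / 35.3° here — the multipigment basis roughly
halves both.

Chromophore-composition phantoms and their verification:

```r
ch <- synthetic_chromophores()
p <- skin_params(StO2 = 0.30, B = 0.0478)          # W = 0.5, F = 0.02
total_hemoglobin(p) * 1e6                          # 109.9 uM
invert_sto2(skin_mua(p, ch), oximetry_bands(), ch)
#> <inversion_result> StO2 30.00%, blood 4.780%, melanosome 0.0255%
```

A command-line interface wraps the same functions (see `exec/phantomkit`):

```sh
phantomkit basis gen --seed 1 --out mybasis
phantomkit fit broadband --basis mybasis --mua mua.csv --musp musp.csv --out recipe.yaml
phantomkit fit reflectance --basis mybasis --target R.csv --n 1.56 --photons 1e5 --seed 7 --out recipe.yaml
phantomkit skin make --sto2 0.30 --blood 0.0478 --out mua.csv
phantomkit skin invert --mua mua.csv
phantomkit compare fitted.csv target.csv
```

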