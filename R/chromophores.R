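#' Chromophore reference set
#'
#' Absorption spectra of the skin-model chromophores. Hemoglobin spectra are
#' per unit molar concentration (mm^-1 per mol/L); water, fat and melanin
#' are pure-substance absorption coefficients (mm^-1) scaled by volume
#' fraction in the skin model.
#'
#' @param mua_hbo2,mua_hb Oxy-/deoxyhemoglobin molar absorption `spectrum`s.
#' @param mua_water,mua_fat,mua_mel Pure-substance absorption `spectrum`s.
#' @return An object of class `chromophore_set`.
#' @export
chromophore_set <- function(mua_hbo2, mua_hb, mua_water, mua_fat, mua_mel) {
  specs <- list(mua_hbo2 = mua_hbo2, mua_hb = mua_hb, mua_water = mua_water,
                mua_fat = mua_fat, mua_mel = mua_mel)
  for (nm in names(specs)) {
    stopifnot(inherits(specs[[nm]], "spectrum"))
    if (any(specs[[nm]]$values < 0))
      stop("chromophore_set: ", nm, " must be non-negative")
    check_same_grid(specs[[nm]], specs[[1]], "chromophore spectra")
  }
  structure(c(specs, list(grid = mua_hbo2$grid)), class = "chromophore_set")
}

#' Default skin-model wavelength grid (470-950 nm, 1 nm)
#' @return A `wl_grid`.
#' @export
skin_grid <- function() wl_grid(470, 950, 1)

#' Synthetic chromophore reference spectra
#'
#' Smooth parametric stand-ins for literature chromophore tabulations,
#' shaped after the qualitative features of the real compounds: oxyhemoglobin
#' with its bimodal 540/577 nm bands and low NIR absorption rising past 800
#' nm, deoxyhemoglobin with a single 555 nm band and a 760 nm shoulder, water
#' rising in the NIR with a 970-nm-side shoulder, fat with a 930 nm band, and
#' melanin decaying monotonically as a power law. These are synthetic
#' approximations, not measured values: every inversion in the package is
#' exercised as a round trip so results never depend on the tabulation being
#' literature-exact.
#'
#' @param grid Wavelength grid, default [skin_grid()].
#' @return A `chromophore_set`.
#' @export
synthetic_chromophores <- function(grid = skin_grid()) {
  lam <- wavelengths(grid)
  # molar magnitudes comparable to hemoglobin compilations:
  # ~1.2e4 mm^-1 (mol/L)^-1 at the visible peaks, a few hundred in the NIR
  hbo2 <- 40 * (290 * exp(-0.5 * ((lam - 542) / 12)^2) +
                  270 * exp(-0.5 * ((lam - 577) / 10)^2) +
                  40 * exp(-0.5 * ((lam - 480) / 40)^2) +
                  3 + 9 * pmax(lam - 700, 0) / 250)
  hb <- 40 * (330 * exp(-0.5 * ((lam - 555) / 18)^2) +
                45 * exp(-0.5 * ((lam - 760) / 18)^2) +
                20 * exp(-(lam - 600) / 60) * (lam > 600) + 12)
  water <- 0.0003 + 0.0025 * exp(-0.5 * ((lam - 750) / 35)^2) +
    0.045 * exp(-0.5 * ((lam - 980) / 45)^2) +
    0.006 * exp(-0.5 * ((lam - 835) / 30)^2)
  fat <- 0.0002 + 0.011 * exp(-0.5 * ((lam - 930) / 18)^2) +
    0.002 * exp(-0.5 * ((lam - 760) / 25)^2)
  mel <- 52 * (lam / 500)^-3
  chromophore_set(spectrum(hbo2, grid), spectrum(hb, grid),
                  spectrum(water, grid), spectrum(fat, grid),
                  spectrum(mel, grid))
}

#' Read / write chromophore sets
#'
#' Multi-column spectrum CSV with columns
#' `wavelength_nm,hbo2,hb,water,fat,melanin`.
#'
#' @param path File path.
#' @param chromo A `chromophore_set` (for writing).
#' @return `read_chromophores` returns a `chromophore_set`.
#' @export
read_chromophores <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("wavelength_nm", "hbo2", "hb", "water", "fat", "melanin")
  if (!all(need %in% names(df)))
    stop("read_chromophores: expected columns ", paste(need, collapse = ","))
  wl <- df$wavelength_nm
  steps <- diff(wl)
  if (any(abs(steps - steps[1]) > 1e-9))
    stop("read_chromophores: wavelengths must be regularly spaced")
  grid <- wl_grid(wl[1], wl[length(wl)], steps[1])
  chromophore_set(spectrum(df$hbo2, grid), spectrum(df$hb, grid),
                  spectrum(df$water, grid), spectrum(df$fat, grid),
                  spectrum(df$melanin, grid))
}

#' @rdname read_chromophores
#' @export
write_chromophores <- function(chromo, path) {
  stopifnot(inherits(chromo, "chromophore_set"))
  df <- data.frame(wavelength_nm = wavelengths(chromo$grid),
                   hbo2 = chromo$mua_hbo2$values, hb = chromo$mua_hb$values,
                   water = chromo$mua_water$values,
                   fat = chromo$mua_fat$values,
                   melanin = chromo$mua_mel$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Skin-model parameters
#'
#' Composition of the computational skin absorption model: hemoglobin oxygen
#' saturation, volume fractions of blood, water, fat and melanosomes, and
#' the hemoglobin concentration within blood.
#'
#' @param StO2 Hemoglobin oxygen saturation, in \[0, 1\].
#' @param B Blood volume fraction, in \[0, 1\].
#' @param W Water volume fraction, default 0.5.
#' @param F Fat volume fraction, default 0.02.
#' @param M Melanosome volume fraction, default 2.55e-4 (pale skin).
#' @param H Hemoglobin concentration within blood, mol/L, default 2.3e-3.
#' @return An object of class `skin_params`.
#' @export
skin_params <- function(StO2, B, W = 0.5, F = 0.02, M = 2.55e-4,
                        H = 2.3e-3) {
  for (v in list(StO2 = StO2, B = B, W = W, F = F, M = M)) {
    if (v < 0 || v > 1) stop("skin_params: fractions must be in [0, 1]")
  }
  if (H < 0) stop("skin_params: H must be >= 0")
  if (B + W + F + M > 1)
    warning("skin_params: volume fractions sum to more than 1")
  structure(list(StO2 = StO2, B = B, W = W, F = F, M = M, H = H),
            class = "skin_params")
}

#' Skin absorption spectrum
#'
#' \deqn{\mu_a(\lambda) = StO_2 B H \mu_a^{HbO_2} + (1-StO_2) B H \mu_a^{Hb}
#'   + W \mu_a^{water} + F \mu_a^{fat} + M \mu_a^{mel}}
#'
#' @param params A [skin_params()].
#' @param chromo A `chromophore_set`.
#' @return Absorption `spectrum` (mm^-1) on the chromophore grid.
#' @export
skin_mua <- function(params, chromo) {
  stopifnot(inherits(params, "skin_params"), inherits(chromo, "chromophore_set"))
  v <- params$StO2 * params$B * params$H * chromo$mua_hbo2$values +
    (1 - params$StO2) * params$B * params$H * chromo$mua_hb$values +
    params$W * chromo$mua_water$values +
    params$F * chromo$mua_fat$values +
    params$M * chromo$mua_mel$values
  spectrum(v, chromo$grid)
}

#' Total hemoglobin concentration of the skin model
#' @param params A [skin_params()].
#' @return B * H in mol/L.
#' @export
total_hemoglobin <- function(params) {
  stopifnot(inherits(params, "skin_params"))
  params$B * params$H
}

#' Mean of a spectrum over a wavelength band
#' @param spec A `spectrum`.
#' @param band `c(lo_nm, hi_nm)`, inclusive; must lie within the grid.
#' @return Arithmetic mean of the in-band samples.
#' @export
band_mean <- function(spec, band) {
  stopifnot(inherits(spec, "spectrum"), length(band) == 2)
  lam <- wavelengths(spec$grid)
  if (band[1] < min(lam) - 1e-9 || band[2] > max(lam) + 1e-9)
    stop("band_mean: band extends outside the spectrum grid")
  sel <- band_mask(band, lam)
  mean(spec$values[sel])
}

#' Invert three-band absorption to StO2, blood and melanosome fractions
#'
#' Given the band-averaged absorption coefficients of a measured phantom at
#' three bands, subtracts the assumed water and fat contributions and solves
#' the 3x3 linear system in (u1, u2, u3) = (StO2*B*H, (1-StO2)*B*H, M) with
#' band-averaged chromophore coefficients. Then StO2 = u1/(u1+u2),
#' B = (u1+u2)/H, M = u3. Negative solutions are clamped to zero and
#' flagged.
#'
#' @param band_mua Either three band-mean absorption values (mm^-1) in band
#'   order, or an absorption `spectrum` from which band means are taken.
#' @param bands A three-band [band_set()], default [oximetry_bands()].
#' @param chromo A `chromophore_set`.
#' @param W,F Assumed water and fat volume fractions (defaults 0.5, 0.02).
#' @param H Hemoglobin concentration within blood, mol/L, default 2.3e-3.
#' @return An object of class `inversion_result` with `StO2_hat`, `B_hat`,
#'   `M_hat`, `band_mua`, `residual` and `clamped`.
#' @export
invert_sto2 <- function(band_mua, bands = oximetry_bands(), chromo,
                        W = 0.5, F = 0.02, H = 2.3e-3) {
  stopifnot(inherits(bands, "band_set"), inherits(chromo, "chromophore_set"))
  if (length(bands$bands) != 3)
    stop("invert_sto2: exactly three bands are required")
  if (inherits(band_mua, "spectrum"))
    band_mua <- vapply(bands$bands, function(b) band_mean(band_mua, b),
                       numeric(1))
  band_mua <- as.numeric(band_mua)
  if (length(band_mua) != 3)
    stop("invert_sto2: band_mua must supply three band values")
  bm <- function(spec) vapply(bands$bands, function(b) band_mean(spec, b),
                              numeric(1))
  M3 <- cbind(hbo2 = bm(chromo$mua_hbo2), hb = bm(chromo$mua_hb),
              mel = bm(chromo$mua_mel))
  if (kappa(M3, exact = TRUE) > 1e12)
    stop("invert_sto2: band-averaged chromophore system is singular")
  rhs <- band_mua - W * bm(chromo$mua_water) - F * bm(chromo$mua_fat)
  u <- solve(M3, rhs)
  clamped <- any(u < 0)
  u_cl <- pmax(u, 0)
  residual <- sqrt(sum((M3 %*% u_cl - rhs)^2))
  tot <- u_cl[[1]] + u_cl[[2]]
  if (tot <= 0)
    stop("invert_sto2: total hemoglobin signal is non-positive; StO2 undefined")
  structure(list(StO2_hat = min(max(u_cl[[1]] / tot, 0), 1),
                 B_hat = tot / H,
                 M_hat = u_cl[[3]],
                 band_mua = band_mua,
                 residual = residual,
                 clamped = clamped),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf(
    "<inversion_result> StO2 %.2f%%, blood %.3f%%, melanosome %.4f%%%s\n",
    100 * x$StO2_hat, 100 * x$B_hat, 100 * x$M_hat,
    if (x$clamped) " (clamped)" else ""))
  invisible(x)
}

#' Signed percent error
#' @param expected Reference value, non-zero.
#' @param measured Observed value.
#' @return `(measured - expected) / expected * 100`.
#' @export
percent_error <- function(expected, measured) {
  if (any(expected == 0)) stop("percent_error: expected must be non-zero")
  (measured - expected) / expected * 100
}

#' Mean absolute percent error
#' @param errors Vector of signed percent errors.
#' @return Mean of their absolute values.
#' @export
mean_abs_percent_error <- function(errors) mean(abs(errors))
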