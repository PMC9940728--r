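#' Wavelength grid
#'
#' A regular, inclusive wavelength grid in nanometres. The package default is
#' 370-950 nm at 1 nm (581 samples), the range over which pigment bases are
#' characterized and over which all fits are carried out.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm), inclusive.
#' @param step_nm Grid spacing (nm), positive.
#' @return An object of class `wl_grid`.
#' @examples
#' g <- wl_grid(370, 950, 1)
#' length(wavelengths(g))  # 581
#' @export
wl_grid <- function(start_nm, stop_nm, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (!(start_nm < stop_nm)) stop("wl_grid: start_nm must be < stop_nm")
  if (!(step_nm > 0)) stop("wl_grid: step_nm must be > 0")
  structure(list(start_nm = as.numeric(start_nm),
                 stop_nm = as.numeric(stop_nm),
                 step_nm = as.numeric(step_nm)),
            class = "wl_grid")
}

#' Default wavelength grid (370-950 nm, 1 nm step)
#' @return A `wl_grid`.
#' @export
default_grid <- function() wl_grid(370, 950, 1)

#' Wavelengths of a grid
#' @param grid A `wl_grid`.
#' @return Numeric vector of wavelengths in nm.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  seq(grid$start_nm, grid$stop_nm, by = grid$step_nm)
}

#' @export
length.wl_grid <- function(x) length(wavelengths(x))

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, step %g nm (%d samples)\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x)))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Wavelength-indexed spectrum
#'
#' The universal currency of the package: a real-valued curve sampled on a
#' [wl_grid()]. Units are declared, never guessed: `"mm^-1"` for optical
#' coefficients, `"reflectance"` for dimensionless diffuse reflectance in
#' \[0, 1\].
#'
#' @param values Numeric vector, one value per grid wavelength. No NaN/NA.
#' @param grid A `wl_grid`.
#' @param unit Unit string; coefficient spectra (`"mm^-1"`) must be >= 0.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(values, grid, unit = "mm^-1") {
  stopifnot(inherits(grid, "wl_grid"))
  values <- as.numeric(values)
  if (length(values) != length(grid))
    stop(sprintf("spectrum: %d values for a grid of %d wavelengths",
                 length(values), length(grid)))
  if (anyNA(values) || any(!is.finite(values)))
    stop("spectrum: values must be finite (no NaN/NA/Inf)")
  if (identical(unit, "mm^-1") && any(values < 0))
    stop("spectrum: coefficient spectra must be non-negative")
  structure(list(grid = grid, values = values, unit = unit),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d samples, %g-%g nm [%s]; range %.4g-%.4g\n",
              length(x$values), x$grid$start_nm, x$grid$stop_nm, x$unit,
              min(x$values), max(x$values)))
  invisible(x)
}

check_same_grid <- function(a, b, what = "spectra") {
  if (!grids_equal(a$grid, b$grid))
    stop(sprintf("%s are on different wavelength grids", what))
  invisible(TRUE)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation onto `grid`. Extrapolation outside the source
#' wavelength range is refused: phantom design never guesses optical
#' properties outside the characterized range.
#'
#' @param spec A `spectrum`.
#' @param grid Target `wl_grid`; must lie inside the source range.
#' @return A `spectrum` on `grid` with the same unit.
#' @export
resample_spectrum <- function(spec, grid) {
  stopifnot(inherits(spec, "spectrum"), inherits(grid, "wl_grid"))
  src <- wavelengths(spec$grid)
  dst <- wavelengths(grid)
  if (min(dst) < min(src) - 1e-9 || max(dst) > max(src) + 1e-9)
    stop(sprintf(
      "resample_spectrum: target %g-%g nm extends outside source %g-%g nm",
      min(dst), max(dst), min(src), max(src)))
  vals <- approx(src, spec$values, xout = dst, method = "linear",
                 rule = 1)$y
  spectrum(vals, grid, unit = spec$unit)
}

#' Mie-Rayleigh power-law parameters
#'
#' Parameters of the reduced-scattering model
#' \deqn{\mu_s'(\lambda) = a\,[f\,(\lambda/\lambda_0)^{-4} +
#'   (1-f)\,(\lambda/\lambda_0)^{-b}]}
#' where `a` is the amplitude at the reference wavelength, `f_ray` the
#' Rayleigh fraction and `b_mie` the Mie scattering power. Reference
#' wavelength defaults to 500 nm.
#'
#' @param a Amplitude at `lambda0_nm`, mm^-1, >= 0.
#' @param f_ray Rayleigh fraction, in \[0, 1\].
#' @param b_mie Mie scattering power, in \[0, 4\].
#' @param lambda0_nm Reference wavelength (nm).
#' @return An object of class `power_law_params`.
#' @export
power_law_params <- function(a, f_ray, b_mie, lambda0_nm = 500) {
  if (a < 0) stop("power_law_params: a must be >= 0")
  if (f_ray < 0 || f_ray > 1) stop("power_law_params: f_ray must be in [0, 1]")
  if (b_mie < 0 || b_mie > 4) stop("power_law_params: b_mie must be in [0, 4]")
  structure(list(a = as.numeric(a), f_ray = as.numeric(f_ray),
                 b_mie = as.numeric(b_mie), lambda0_nm = as.numeric(lambda0_nm)),
            class = "power_law_params")
}

#' Evaluate the Mie-Rayleigh power law on a grid
#' @param p A [power_law_params()].
#' @param grid A `wl_grid`.
#' @return A `spectrum` of reduced scattering coefficients (mm^-1).
#' @export
power_law_eval <- function(p, grid) {
  stopifnot(inherits(p, "power_law_params"), inherits(grid, "wl_grid"))
  lam <- wavelengths(grid) / p$lambda0_nm
  vals <- p$a * (p$f_ray * lam^-4 + (1 - p$f_ray) * lam^-p$b_mie)
  spectrum(vals, grid, unit = "mm^-1")
}

#' Fit the Mie-Rayleigh power law to a reduced-scattering spectrum
#'
#' Bounded least squares over (a, f_ray, b_mie) with a >= 0, f_ray in
#' \[0, 1\], b_mie in \[0, 4\]. Used as the second stage of integrating-sphere
#' scattering post-processing (constraining the scattering slope to a
#' physically plausible Mie-Rayleigh shape) and to generate skin-like
#' scattering targets.
#'
#' @param spec A strictly positive `spectrum` of mu_s' values.
#' @param lambda0_nm Reference wavelength, default 500 nm.
#' @return A `power_law_params` with attributes `residual` (sum of squared
#'   residuals) and `fitted` (the fitted `spectrum`).
#' @export
power_law_fit <- function(spec, lambda0_nm = 500) {
  stopifnot(inherits(spec, "spectrum"))
  if (any(spec$values <= 0))
    stop("power_law_fit: spectrum must be strictly positive")
  lam <- wavelengths(spec$grid) / lambda0_nm
  y <- spec$values
  resid_fn <- function(par) {
    par["a"] * (par["f"] * lam^-4 + (1 - par["f"]) * lam^-par["b"]) - y
  }
  a0 <- approx(lam, y, xout = 1, rule = 2)$y
  # multistart over the (f, b) box; the surface has a ridge where f trades
  # off against b near b = 4
  starts <- expand.grid(f = c(0.05, 0.5, 0.95), b = c(0.5, 1.5, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- minpack.lm::nls.lm(
      par = c(a = a0, f = starts$f[i], b = starts$b[i]),
      lower = c(0, 0, 0), upper = c(Inf, 1, 4),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  par <- best$par
  p <- power_law_params(max(par[["a"]], 0), min(max(par[["f"]], 0), 1),
                        min(max(par[["b"]], 0), 4), lambda0_nm)
  attr(p, "residual") <- best$deviance
  attr(p, "fitted") <- power_law_eval(p, spec$grid)
  p
}

#' Sigmoid-weighted blend of two spectra
#'
#' Composite spectra measured on samples of two thicknesses are merged with a
#' logistic ramp: the `thin` spectrum is used below `lo_nm`, the `thick`
#' spectrum above `hi_nm`, and a sigmoid-weighted average in between. The
#' logistic is centred at `(lo + hi) / 2` with scale `(hi - lo) / 6` so the
#' off-spectrum weight is below 1% outside the transition region; outside
#' \[lo, hi\] the pure spectra are used exactly.
#'
#' @param thin,thick `spectrum` objects on a common grid.
#' @param lo_nm,hi_nm Transition region bounds (nm), defaults 560 and 620.
#' @return Blended `spectrum`.
#' @export
sigmoid_blend <- function(thin, thick, lo_nm = 560, hi_nm = 620) {
  stopifnot(inherits(thin, "spectrum"), inherits(thick, "spectrum"))
  check_same_grid(thin, thick)
  if (!(lo_nm < hi_nm)) stop("sigmoid_blend: lo_nm must be < hi_nm")
  lam <- wavelengths(thin$grid)
  centre <- (lo_nm + hi_nm) / 2
  scale <- (hi_nm - lo_nm) / 6
  w <- 1 / (1 + exp(-(lam - centre) / scale))
  w[lam <= lo_nm] <- 0
  w[lam >= hi_nm] <- 1
  spectrum(w * thick$values + (1 - w) * thin$values, thin$grid,
           unit = thin$unit)
}

#' Mean absolute error between two spectra
#'
#' MAE over wavelengths, optionally after a log10 transform. The log
#' transform is used for absorption-coefficient comparisons, which span
#' several orders of magnitude; reflectance and scattering comparisons are
#' made on the linear scale.
#'
#' @param a,b `spectrum` objects on the same grid.
#' @param log10_transform If TRUE both spectra must be strictly positive and
#'   are log10-transformed before differencing.
#' @return Scalar MAE.
#' @export
mean_abs_error <- function(a, b, log10_transform = FALSE) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  check_same_grid(a, b)
  x <- a$values; y <- b$values
  if (log10_transform) {
    if (any(x <= 0) || any(y <= 0))
      stop("mean_abs_error: log10 transform requires strictly positive spectra")
    x <- log10(x); y <- log10(y)
  }
  mean(abs(x - y))
}

#' Spectral angle mapper (SAM) between two spectra
#'
#' The angle, in degrees, between the two spectra viewed as vectors:
#' \deqn{\mathrm{SAM}(R, S) = \cos^{-1}\frac{R \cdot S}{\|R\|\,\|S\|}.}
#' Scale-invariant: it compares spectral shape, not magnitude. For
#' non-negative spectra the result lies in \[0, 90\] degrees.
#'
#' @param a,b `spectrum` objects on the same grid, neither all-zero.
#' @return Angle in degrees.
#' @export
spectral_angle <- function(a, b) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  check_same_grid(a, b)
  na <- sqrt(sum(a$values^2)); nb <- sqrt(sum(b$values^2))
  if (na == 0 || nb == 0)
    stop("spectral_angle: zero-norm spectrum")
  cosang <- sum(a$values * b$values) / (na * nb)
  cosang <- min(max(cosang, -1), 1)
  acos(cosang) * 180 / pi
}

#' Read a single-column spectrum CSV
#'
#' Dialect: header `wavelength_nm,value` (or `wavelength_nm,<name>`), one row
#' per wavelength, '.' decimal separator, UTF-8.
#'
#' @param path File path.
#' @param unit Unit to declare on the returned spectrum.
#' @return A `spectrum`. The grid is inferred from the wavelength column,
#'   which must be regularly spaced.
#' @export
read_spectrum <- function(path, unit = "mm^-1") {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "wavelength_nm")
    stop("read_spectrum: expected header 'wavelength_nm,<value>'")
  wl <- df[[1]]
  steps <- diff(wl)
  if (length(wl) < 2 || any(abs(steps - steps[1]) > 1e-9))
    stop("read_spectrum: wavelength column must be regularly spaced")
  grid <- wl_grid(wl[1], wl[length(wl)], steps[1])
  spectrum(df[[2]], grid, unit = unit)
}

#' Write a spectrum to CSV
#' @param spec A `spectrum`.
#' @param path File path.
#' @param name Column name for the value column.
#' @export
write_spectrum <- function(spec, path, name = "value") {
  df <- data.frame(wavelength_nm = wavelengths(spec$grid), v = spec$values)
  names(df)[2] <- name
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
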