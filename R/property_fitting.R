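#' Target tissue optical properties
#'
#' @param mua,musp `spectrum` objects (mm^-1) on a shared grid.
#' @param label Free-text label, e.g. "muscle".
#' @return An object of class `tissue_target`.
#' @export
tissue_target <- function(mua, musp, label = "tissue") {
  stopifnot(inherits(mua, "spectrum"), inherits(musp, "spectrum"))
  check_same_grid(mua, musp, "target spectra")
  structure(list(mua = mua, musp = musp, label = label),
            class = "tissue_target")
}

#' Wavelength band set
#'
#' Non-overlapping inclusive wavelength intervals with optional per-band
#' weights for the band-restricted joint fit. When weights are omitted each
#' band is auto-weighted by `K` divided by the in-band maximum of the target
#' property, so all bands contribute at comparable scale regardless of the
#' orders-of-magnitude span of tissue absorption.
#'
#' @param bands List of `c(lo_nm, hi_nm)` pairs, or a string like
#'   `"540-560,625-645,820-840"`.
#' @param abs_weights,scat_weights Optional per-band positive weights.
#' @param K Auto-weight magnitude used when weights are omitted.
#' @return An object of class `band_set`.
#' @export
band_set <- function(bands, abs_weights = NULL, scat_weights = NULL,
                     K = 1000) {
  if (is.character(bands)) {
    parts <- strsplit(strsplit(bands, ",", fixed = TRUE)[[1]], "-",
                      fixed = TRUE)
    bands <- lapply(parts, function(p) as.numeric(p))
  }
  stopifnot(is.list(bands))
  bands <- lapply(bands, function(b) {
    b <- as.numeric(b)
    if (length(b) != 2 || anyNA(b) || b[1] > b[2])
      stop("band_set: each band must be c(lo_nm, hi_nm) with lo <= hi")
    b
  })
  if (length(bands) > 1) {
    m <- do.call(rbind, bands)
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("band_set: bands must not overlap")
    bands <- bands[o]
  }
  chk_w <- function(w) {
    if (!is.null(w)) {
      if (length(w) != length(bands) || any(w <= 0))
        stop("band_set: weights must be positive, one per band")
    }
    w
  }
  structure(list(bands = bands, abs_weights = chk_w(abs_weights),
                 scat_weights = chk_w(scat_weights), K = K),
            class = "band_set")
}

#' Default muscle four-band set (blue, green, red, NIR)
#' @return A `band_set` covering 385-405, 530-570, 615-635 and 825-865 nm.
#' @export
muscle_bands <- function() band_set("385-405,530-570,615-635,825-865")

#' Default oximetry three-band set
#' @return A `band_set` covering 540-560, 625-645 and 820-840 nm.
#' @export
oximetry_bands <- function() band_set("540-560,625-645,820-840")

band_mask <- function(band, lam) lam >= band[1] - 1e-9 & lam <= band[2] + 1e-9

band_weight_vector <- function(bands, lam, target_values, given, K) {
  w <- rep(1, length(lam))
  for (j in seq_along(bands$bands)) {
    sel <- band_mask(bands$bands[[j]], lam)
    if (!any(sel)) stop("band_set: band outside the wavelength grid")
    w[sel] <- if (!is.null(given)) given[j] else
      K / max(max(abs(target_values[sel])), 1e-6)
  }
  w
}

# Lawson-Hanson NNLS behind one seam; exact KKT at termination
nnls_solve <- function(C, d) {
  sol <- pracma::lsqnonneg(C, d)
  x <- as.numeric(sol$x)
  names(x) <- colnames(C)
  list(x = x, resnorm = sum((C %*% x - d)^2))
}

#' Magnitude-equalizing absorption weights
#'
#' The weight at each wavelength is the maximum of the target absorption
#' coefficient divided by the absorption coefficient at that wavelength, so
#' that wavelengths with small absorption (red/NIR) count as much in the
#' least-squares fit as the large blue/green peaks. Values below `floor`
#' (mm^-1) are clamped before division to keep weights finite.
#'
#' @param mua_target Target absorption `spectrum`.
#' @param floor Clamp value, default 1e-6 mm^-1.
#' @return A dimensionless weight `spectrum` with minimum 1 at the argmax.
#' @export
absorption_weights <- function(mua_target, floor = 1e-6) {
  stopifnot(inherits(mua_target, "spectrum"))
  v <- mua_target$values
  if (all(v <= 0)) stop("absorption_weights: target is identically zero")
  v <- pmax(v, floor)
  spectrum(max(v) / v, mua_target$grid, unit = "dimensionless")
}

fit_diagnostics <- function(basis, target, rec) {
  fitted <- mix_properties(basis, rec)
  pos <- target$mua$values > 0 & fitted$mua$values > 0
  mae_abs_log <- if (all(pos)) {
    mean_abs_error(fitted$mua, target$mua, log10_transform = TRUE)
  } else NA_real_
  metrics <- list(
    mae_abs = mean_abs_error(fitted$mua, target$mua),
    mae_abs_log10 = mae_abs_log,
    sam_abs = if (any(fitted$mua$values > 0) && any(target$mua$values > 0))
      spectral_angle(fitted$mua, target$mua) else NA_real_,
    mae_scat = mean_abs_error(fitted$musp, target$musp),
    sam_scat = if (any(fitted$musp$values > 0) && any(target$musp$values > 0))
      spectral_angle(fitted$musp, target$musp) else NA_real_)
  list(fitted = fitted, metrics = metrics)
}

new_fit_result <- function(basis, target, rec, residual_abs, residual_scat,
                           extra = list()) {
  d <- fit_diagnostics(basis, target, rec)
  kappa <- tryCatch(kappa(basis_matrix(basis, "abs"), exact = FALSE),
                    error = function(e) NA_real_)
  structure(c(list(recipe = rec,
                   fitted_mua = d$fitted$mua, fitted_musp = d$fitted$musp,
                   residual_abs = residual_abs, residual_scat = residual_scat,
                   metrics = d$metrics,
                   ill_conditioned = is.finite(kappa) && kappa > 1e8),
              extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  print(x$recipe)
  cat(sprintf("  residuals: abs %.4g, scat %.4g\n",
              x$residual_abs, x$residual_scat))
  m <- x$metrics
  cat(sprintf("  absorption: MAE %.4g (log10 %.4g), SAM %.3g deg\n",
              m$mae_abs, m$mae_abs_log10, m$sam_abs))
  cat(sprintf("  scattering: MAE %.4g, SAM %.3g deg\n",
              m$mae_scat, m$sam_scat))
  if (isTRUE(x$ill_conditioned))
    cat("  note: basis condition number > 1e8; recipe may be non-unique\n")
  invisible(x)
}

#' Step 1: fit absorbing (non-white) pigment concentrations
#'
#' Weighted nonnegative least squares of the target absorption spectrum on
#' the non-white pigment absorption columns:
#' \deqn{\arg\min_{x \ge 0} \sum_\lambda [w(\lambda)\mu_a^{tissue}(\lambda)
#'   - w(\lambda) C_{abs}(\lambda) x]^2}
#' with w from [absorption_weights()].
#'
#' @param basis A `pigment_basis` containing at least one non-white pigment.
#' @param target A `tissue_target` on the basis grid.
#' @param weighted Use the magnitude-equalizing weights (default). With
#'   `FALSE` an unweighted fit is run, which also accepts an all-zero target.
#' @return A `recipe` over the non-white pigments, with attribute `resnorm`.
#' @export
fit_absorption <- function(basis, target, weighted = TRUE) {
  stopifnot(inherits(basis, "pigment_basis"), inherits(target, "tissue_target"))
  check_same_grid(target$mua, spectrum(numeric(length(basis$grid)),
                                       basis$grid), "target and basis")
  nw <- basis_names(basis, setdiff(pigment_categories(), "white"))
  if (!length(nw))
    stop("fit_absorption: basis has no non-white pigments")
  A <- basis_matrix(basis, "abs", nw)
  w <- if (weighted) absorption_weights(target$mua)$values
       else rep(1, length(basis$grid))
  sol <- nnls_solve(A * w, target$mua$values * w)
  r <- recipe(sol$x, basis$id)
  attr(r, "resnorm") <- sol$resnorm
  r
}

#' Step 2: fit white pigment concentrations to residual scattering
#'
#' The scattering already contributed by the absorbing pigments (from their
#' fitted concentrations and per-unit scattering spectra) is subtracted from
#' the target reduced scattering; the white pigments are then fit to the
#' residual by nonnegative least squares. Negative residuals (absorbers
#' already over-supplying scattering) are clamped to zero per wavelength.
#'
#' @param basis A `pigment_basis`.
#' @param target A `tissue_target`.
#' @param absorber_recipe `recipe` from [fit_absorption()]; an empty recipe
#'   reduces this to a plain NNLS on the raw target scattering.
#' @return A `recipe` over the white pigments, with attribute `resnorm`.
#' @export
fit_scattering <- function(basis, target,
                           absorber_recipe = recipe(numeric(0), basis$id)) {
  stopifnot(inherits(basis, "pigment_basis"), inherits(target, "tissue_target"))
  check_recipe(basis, absorber_recipe)
  whites <- basis_names(basis, "white")
  if (!length(whites))
    stop("fit_scattering: basis has no white pigments")
  absorber_scat <- mix_properties(basis, absorber_recipe)$musp$values
  residual <- pmax(target$musp$values - absorber_scat, 0)
  Z <- basis_matrix(basis, "scat", whites)
  sol <- nnls_solve(Z, residual)
  r <- recipe(sol$x, basis$id)
  attr(r, "resnorm") <- sol$resnorm
  r
}

merge_recipes <- function(a, b) {
  cc <- c(a$concentrations, b$concentrations)
  recipe(cc, a$basis_id)
}

#' Two-step broadband recipe fit
#'
#' [fit_absorption()] followed by [fit_scattering()], merged into one recipe
#' with residuals and MAE/SAM diagnostics for both properties.
#'
#' @inheritParams fit_absorption
#' @return A `fit_result`.
#' @export
fit_broadband <- function(basis, target, weighted = TRUE) {
  rx <- fit_absorption(basis, target, weighted = weighted)
  rz <- fit_scattering(basis, target, rx)
  rec <- merge_recipes(rx, rz)
  new_fit_result(basis, target, rec,
                 residual_abs = attr(rx, "resnorm"),
                 residual_scat = attr(rz, "resnorm"))
}

#' Band-restricted joint recipe fit
#'
#' Single joint nonnegative least squares over all pigments minimizing
#' \deqn{\sum_\lambda [w_a(\lambda)(\mu_a - C_{abs} q)^2 +
#'   w_s(\lambda)(\mu_s' - C_{scat} q)^2]}
#' with strong weights inside the requested bands and weight 1 outside.
#' With an empty band set this falls back to uniform weights, i.e. an
#' unweighted joint NNLS.
#'
#' @param basis A `pigment_basis`.
#' @param target A `tissue_target`.
#' @param bands A [band_set()], e.g. [muscle_bands()] or [oximetry_bands()].
#' @return A `fit_result`; its `band_metrics` element holds per-band MAE/SAM.
#' @export
fit_bands <- function(basis, target, bands = muscle_bands()) {
  stopifnot(inherits(basis, "pigment_basis"), inherits(target, "tissue_target"),
            inherits(bands, "band_set"))
  lam <- wavelengths(basis$grid)
  if (length(bands$bands)) {
    wa <- band_weight_vector(bands, lam, target$mua$values,
                             bands$abs_weights, bands$K)
    ws <- band_weight_vector(bands, lam, target$musp$values,
                             bands$scat_weights, bands$K)
  } else {
    wa <- ws <- rep(1, length(lam))
  }
  A <- basis_matrix(basis, "abs")
  S <- basis_matrix(basis, "scat")
  C <- rbind(A * sqrt(wa), S * sqrt(ws))
  d <- c(target$mua$values * sqrt(wa), target$musp$values * sqrt(ws))
  sol <- nnls_solve(C, d)
  rec <- recipe(sol$x, basis$id)
  fitted <- mix_properties(basis, rec)
  res_a <- sum(wa * (target$mua$values - fitted$mua$values)^2)
  res_s <- sum(ws * (target$musp$values - fitted$musp$values)^2)
  band_metrics <- lapply(bands$bands, function(b) {
    sel <- band_mask(b, lam)
    sub <- wl_grid(min(lam[sel]), max(lam[sel]),
                   if (sum(sel) > 1) diff(lam[sel])[1] else 1)
    list(band = b,
         mae_abs = mean(abs(fitted$mua$values[sel] - target$mua$values[sel])),
         mae_scat = mean(abs(fitted$musp$values[sel] -
                               target$musp$values[sel])))
  })
  new_fit_result(basis, target, rec, res_a, res_s,
                 extra = list(band_metrics = band_metrics, bands = bands))
}
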