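#' Target diffuse-reflectance spectrum
#'
#' @param reflectance A `spectrum` with values strictly inside (0, 1).
#' @param label Free-text label.
#' @return An object of class `reflectance_target`.
#' @export
reflectance_target <- function(reflectance, label = "reflectance") {
  stopifnot(inherits(reflectance, "spectrum"))
  if (any(reflectance$values <= 0) || any(reflectance$values >= 1))
    stop("reflectance_target: values must lie strictly in (0, 1)")
  structure(list(reflectance = reflectance, label = label),
            class = "reflectance_target")
}

subsample_grid <- function(grid, every_nm) {
  step <- max(every_nm, grid$step_nm)
  k <- max(1L, round(step / grid$step_nm))
  lam <- wavelengths(grid)
  idx <- seq(1L, length(lam), by = k)
  if (idx[length(idx)] != length(lam)) idx <- c(idx, length(lam))
  idx
}

#' Fit a pigment recipe to a measured diffuse-reflectance spectrum
#'
#' Nonlinear, nonnegative least squares: iterates pigment concentrations q,
#' maps them to optical-property spectra through the basis, predicts the
#' diffuse reflectance with the white Monte Carlo ensemble, and minimizes the
#' summed squared deviation from the target. The reference ensemble is held
#' fixed across iterations (common random numbers), making the objective
#' deterministic and smooth.
#'
#' The inner loop runs on a wavelength subsample (default every 5 nm) with a
#' bin-compressed path record; the returned prediction and metrics are on
#' the full grid. Initialization inverts the target through the diffusion
#' closed form against a generic skin-like scattering prior and runs the
#' broadband property fit on the result, falling back to uniform small
#' concentrations.
#'
#' A semi-infinite homogeneous medium has no intrinsic length scale, so its
#' diffuse reflectance depends on the optical properties only through the
#' per-wavelength ratio mu_a/mu_s': scaling every concentration by the same
#' factor leaves the predicted spectrum unchanged. Reflectance alone
#' therefore determines the recipe up to that one-parameter family. To pin
#' the scale, supply `musp_anchor`, the reduced scattering coefficient
#' (mm^-1) the phantom should have at `anchor_nm`; the anchor enters the
#' least squares as one extra weighted residual. Without an anchor the fit
#' returns whichever member of the family the start led to, and says so in
#' its diagnostics.
#'
#' @param basis A `pigment_basis` on the target's grid.
#' @param target A [reflectance_target()].
#' @param rec A `path_record` built with the phantom material's refractive
#'   index (epoxy: 1.56).
#' @param init Optional starting `recipe`.
#' @param musp_anchor Optional reduced scattering (mm^-1) at `anchor_nm`
#'   fixing the concentration scale.
#' @param anchor_nm Reference wavelength for the anchor, default 500 nm.
#' @param anchor_weight Weight of the (relative) anchor residual, default 10.
#' @param subsample_nm Inner-loop wavelength spacing (nm), default 5.
#' @param compress_bins Pathlength bins for the inner loop, default 4096.
#' @param max_iter Maximum optimizer iterations, default 200.
#' @param ftol Relative objective decrease tolerance, default 1e-10.
#' @return An object of class `reflectance_fit`: `recipe`, `predicted`
#'   (full-grid reflectance `spectrum`), `objective` (reflectance residuals
#'   only), `mae`, `sam`, `converged`, `diagnostics`.
#' @export
fit_reflectance <- function(basis, target, rec, init = NULL,
                            musp_anchor = NULL, anchor_nm = 500,
                            anchor_weight = 10,
                            subsample_nm = 5, compress_bins = 4096,
                            max_iter = 200, ftol = 1e-10) {
  stopifnot(inherits(basis, "pigment_basis"),
            inherits(target, "reflectance_target"),
            inherits(rec, "path_record"))
  check_same_grid(target$reflectance,
                  spectrum(numeric(length(basis$grid)), basis$grid),
                  "target and basis")
  diag_msgs <- character()
  cats <- vapply(basis$records, `[[`, "", "category")
  if (all(cats == "white") || all(cats %in% c("black")))
    diag_msgs <- c(diag_msgs,
                   "basis has a single optical role; fit may be unidentifiable")

  if (is.null(musp_anchor))
    diag_msgs <- c(diag_msgs,
                   "no scattering anchor: concentration scale set by the start")

  crec <- compress_paths(rec, compress_bins)
  g <- rec$config$g
  idx <- subsample_grid(basis$grid, subsample_nm)
  A <- basis_matrix(basis, "abs")[idx, , drop = FALSE]
  S <- basis_matrix(basis, "scat")[idx, , drop = FALSE]
  r_obs <- target$reflectance$values[idx]
  p <- ncol(A)
  s_anchor <- as.numeric(vapply(basis$records, function(r)
    resample_spectrum(r$scat_per_conc,
                      wl_grid(anchor_nm, anchor_nm + 1, 1))$values[1],
    numeric(1)))

  predict_sub <- function(q) {
    mua <- as.numeric(A %*% q)
    musp <- pmax(as.numeric(S %*% q), 1e-9)
    as.numeric(.wmc_reflectance(crec$escaped_paths, crec$escape_weights,
                                crec$n_launched, mua, musp / (1 - g)))
  }
  resid_fn <- function(q) {
    r <- predict_sub(q) - r_obs
    if (!is.null(musp_anchor))
      r <- c(r, anchor_weight * (sum(s_anchor * q) - musp_anchor) /
               musp_anchor)
    r
  }
  # analytic Jacobian: Rd depends on q through k(lambda) = mua(1-g)/musp
  jac_fn <- function(q) {
    mua <- as.numeric(A %*% q)
    musp <- pmax(as.numeric(S %*% q), 1e-9)
    gr <- .wmc_reflectance_grad(crec$escaped_paths, crec$escape_weights,
                                crec$n_launched, mua, musp / (1 - g))
    dk_dmua <- (1 - g) / musp
    dk_dmusp <- -(1 - g) * mua / musp^2
    J <- (gr$drd_dk * dk_dmua) * A + (gr$drd_dk * dk_dmusp) * S
    if (!is.null(musp_anchor))
      J <- rbind(J, anchor_weight * s_anchor / musp_anchor)
    J
  }

  q0 <- if (!is.null(init)) {
    check_recipe(basis, init)
    q <- numeric(p); names(q) <- colnames(A)
    q[names(init$concentrations)] <- init$concentrations
    q
  } else {
    init_albedo_nnls(A, S, s_anchor, crec, g, r_obs, musp_anchor,
                     fallback = init_reflectance_recipe(
                       basis, target, rec$config, musp_anchor, anchor_nm))
  }
  q0 <- pmax(q0, 0)

  # convergence is reported through the result, not as a condition
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = q0, lower = rep(0, p),
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = ftol, ptol = 1e-12, gtol = 0)))
  q <- pmax(fit$par, 0)
  converged <- fit$info %in% 1:4
  if (!converged)
    diag_msgs <- c(diag_msgs, paste0("optimizer not converged: ", fit$message))

  final <- recipe(q, basis$id)
  props <- mix_properties(basis, final)
  musp_safe <- spectrum(pmax(props$musp$values, 1e-9), basis$grid)
  predicted <- reflectance_spectrum(crec, props$mua, musp_safe)
  structure(list(recipe = final, predicted = predicted,
                 objective = sum((predict_sub(q) - r_obs)^2),
                 mae = mean_abs_error(predicted, target$reflectance),
                 sam = spectral_angle(predicted, target$reflectance),
                 converged = converged, n_iter = fit$niter,
                 diagnostics = diag_msgs),
            class = "reflectance_fit")
}

#' @export
print.reflectance_fit <- function(x, ...) {
  cat("<reflectance_fit>\n")
  print(x$recipe)
  cat(sprintf("  objective %.4g; MAE %.4g; SAM %.3g deg; %s (%d iter)\n",
              x$objective, x$mae, x$sam,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  for (m in x$diagnostics) cat("  warning:", m, "\n")
  invisible(x)
}

# primary initialization: invert each target reflectance value for the decay
# constant k = mua(1-g)/musp through the fixed path ensemble (Rd is strictly
# decreasing in k), which turns the fit into the linear homogeneous system
# (A - K S / (1-g)) q = 0; solved by NNLS together with the scale-anchor row.
# Exact for targets the basis can represent; a very good start otherwise.
init_albedo_nnls <- function(A, S, s_anchor, crec, g, r_obs, musp_anchor,
                             fallback) {
  out <- tryCatch({
    rd0 <- as.numeric(.wmc_reflectance(crec$escaped_paths,
                                       crec$escape_weights, crec$n_launched,
                                       0, 1))
    k <- vapply(r_obs, function(r) {
      if (r >= rd0) return(0)
      f <- function(kk) as.numeric(.wmc_reflectance(
        crec$escaped_paths, crec$escape_weights, crec$n_launched, kk, 1)) - r
      uniroot(f, c(0, 50), tol = 1e-14, extendInt = "downX")$root
    }, numeric(1))
    C <- A - (k / (1 - g)) * S
    anchor <- if (is.null(musp_anchor)) 1 else musp_anchor
    # row scale so the homogeneous block and the anchor row are comparable
    Cn <- rbind(C / max(abs(C)), s_anchor / anchor)
    d <- c(numeric(length(r_obs)), 1)
    q <- nnls_solve(Cn, d)$x
    names(q) <- colnames(A)
    if (all(q == 0)) fallback else q
  }, error = function(e) fallback)
  out
}

# starting recipe: diffusion-invert the target reflectance under a generic
# skin-like scattering prior (rescaled to the anchor when one is given),
# then run the broadband property fit
init_reflectance_recipe <- function(basis, target, config,
                                    musp_anchor = NULL, anchor_nm = 500) {
  p <- length(basis_names(basis))
  fallback <- rep(0.01, p)
  names(fallback) <- basis_names(basis)
  out <- tryCatch({
    a0 <- if (is.null(musp_anchor)) 1.5 else musp_anchor
    prior <- power_law_eval(power_law_params(a = a0, f_ray = 0.2,
                                             b_mie = 1.3,
                                             lambda0_nm = anchor_nm),
                            basis$grid)
    n_rel <- config$n_medium / config$n_outside
    mua_est <- diffusion_invert_mua(target$reflectance$values, prior$values,
                                    n_rel)
    tgt <- tissue_target(spectrum(pmax(mua_est, 1e-6), basis$grid), prior,
                         label = "diffusion-initialized")
    fr <- fit_broadband(basis, tgt)
    q <- numeric(p); names(q) <- basis_names(basis)
    q[names(fr$recipe$concentrations)] <- fr$recipe$concentrations
    if (all(q == 0)) fallback else q
  }, error = function(e) fallback)
  out
}
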