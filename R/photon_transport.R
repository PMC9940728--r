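#' Monte Carlo transport configuration
#'
#' @param n_medium Refractive index of the phantom material (epoxy: 1.56).
#' @param n_outside Refractive index outside (air: 1.0).
#' @param g Scattering anisotropy (Henyey-Greenstein), default 0.8.
#' @param n_photons Photons to launch; 1e5 is adequate for testing, 1e6 for
#'   production fits.
#' @param max_dimensionless_path Termination cap on cumulative pathlength in
#'   mean free paths. Residual weight at termination is tallied as escaping
#'   at the termination pathlength (tail capture), so energy is conserved
#'   exactly at zero absorption; the resulting upward bias at mu_a > 0 is
#'   bounded by exp(-mu_a * cap / mu_s) times the residual weight.
#' @param seed Integer RNG seed; recorded in the output.
#' @param weight_min Photon weight below which the walk is terminated after
#'   boundary splitting.
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(n_medium = 1.56, n_outside = 1.0, g = 0.8,
                             n_photons = 1e5, max_dimensionless_path = 1e5,
                             seed = 1, weight_min = 1e-6) {
  if (n_medium < 1) stop("transport_config: n_medium must be >= 1")
  if (g <= -1 || g >= 1) stop("transport_config: g must be in (-1, 1)")
  if (n_photons < 1e3) stop("transport_config: n_photons must be >= 1000")
  structure(list(n_medium = n_medium, n_outside = n_outside, g = g,
                 n_photons = as.integer(n_photons),
                 max_dimensionless_path = max_dimensionless_path,
                 seed = as.integer(seed), weight_min = weight_min),
            class = "transport_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  code
}

#' Run the white Monte Carlo reference ensemble
#'
#' Simulates a scattering-only pencil-beam random walk in a semi-infinite
#' homogeneous half-space at unit scattering coefficient, with
#' Henyey-Greenstein scattering and Fresnel weight splitting at the surface.
#' The recorded escape pathlengths and weights can be reweighted to the
#' diffuse reflectance of any (mu_a, mu_s') pair sharing the configuration's
#' refractive indices and anisotropy — one walk ensemble, many
#' optical-property queries. Specular reflection of the incident beam is
#' excluded from the diffuse tally (photons are launched inside the medium).
#'
#' @param config A [transport_config()].
#' @return An object of class `path_record` with elements `escaped_paths`
#'   (dimensionless, units of one scattering mean free path),
#'   `escape_weights`, `n_launched` and the generating `config`.
#' @export
run_reference <- function(config = transport_config()) {
  stopifnot(inherits(config, "transport_config"))
  out <- with_seed(config$seed, {
    .wmc_run(config$n_photons, config$n_medium, config$n_outside, config$g,
             config$max_dimensionless_path, config$weight_min)
  })
  structure(list(escaped_paths = out$escaped_paths,
                 escape_weights = out$escape_weights,
                 n_launched = out$n_launched,
                 config = config,
                 compressed = FALSE),
            class = "path_record")
}

#' @export
print.path_record <- function(x, ...) {
  cat(sprintf(
    "<path_record> %d photons (n=%.3g, g=%.2g, seed %d): %d escape events%s\n",
    x$n_launched, x$config$n_medium, x$config$g, x$config$seed,
    length(x$escaped_paths), if (x$compressed) " (compressed)" else ""))
  invisible(x)
}

#' Compress a path record into weighted pathlength bins
#'
#' Aggregates escape events into log-spaced pathlength bins (weight sum and
#' weighted mean path per bin). Total escaped weight is preserved exactly, so
#' the zero-absorption reflectance is unchanged; reflectance at mu_a > 0 is
#' approximated with relative error that shrinks with `n_bins`. Used to make
#' iterative reflectance fitting cheap.
#'
#' @param rec A `path_record`.
#' @param n_bins Number of bins, default 4096.
#' @return A compressed `path_record`.
#' @export
compress_paths <- function(rec, n_bins = 4096) {
  stopifnot(inherits(rec, "path_record"))
  if (rec$compressed || length(rec$escaped_paths) <= n_bins) return(rec)
  p <- rec$escaped_paths; w <- rec$escape_weights
  edges <- exp(seq(log(min(p)), log(max(p)), length.out = n_bins + 1))
  idx <- findInterval(p, edges, rightmost.closed = TRUE)
  wsum <- as.numeric(tapply(w, idx, sum))
  pbar <- as.numeric(tapply(w * p, idx, sum)) / wsum
  keep <- wsum > 0 & is.finite(pbar)
  structure(list(escaped_paths = pbar[keep], escape_weights = wsum[keep],
                 n_launched = rec$n_launched, config = rec$config,
                 compressed = TRUE),
            class = "path_record")
}

#' Diffuse reflectance from a reference ensemble
#'
#' \deqn{R_d = \frac{1}{N}\sum_i w_i\,e^{-\mu_a L_i}, \qquad
#'   L_i = \mathrm{path}_i/\mu_s,\ \ \mu_s = \mu_s'/(1-g).}
#'
#' @param rec A `path_record`.
#' @param mua Absorption coefficient, mm^-1, >= 0.
#' @param musp Reduced scattering coefficient, mm^-1, > 0.
#' @return Diffuse reflectance in \[0, 1\].
#' @export
diffuse_reflectance <- function(rec, mua, musp) {
  stopifnot(inherits(rec, "path_record"))
  if (any(musp <= 0)) stop("diffuse_reflectance: musp must be > 0")
  if (any(mua < 0)) stop("diffuse_reflectance: mua must be >= 0")
  mus <- musp / (1 - rec$config$g)
  as.numeric(.wmc_reflectance(rec$escaped_paths, rec$escape_weights,
                              rec$n_launched, mua, rep_len(mus, length(mua))))
}

#' Diffuse reflectance spectrum from optical-property spectra
#'
#' Vectorized [diffuse_reflectance()] over the wavelengths of `mua`/`musp`
#' from one shared reference ensemble.
#'
#' @param rec A `path_record`.
#' @param mua,musp `spectrum` objects (mm^-1) on a common grid; `musp` must
#'   be strictly positive.
#' @return A reflectance `spectrum`.
#' @export
reflectance_spectrum <- function(rec, mua, musp) {
  stopifnot(inherits(mua, "spectrum"), inherits(musp, "spectrum"))
  check_same_grid(mua, musp, "optical-property spectra")
  vals <- diffuse_reflectance(rec, mua$values, musp$values)
  spectrum(vals, mua$grid, unit = "reflectance")
}

#' Write / read a path-record cache
#'
#' Plain-text columnar cache keyed by the generating configuration, so
#' reflectance fits can re-use a reference ensemble across runs. The file is
#' a JSON header line followed by `path,weight` rows.
#'
#' @param rec A `path_record`.
#' @param path File path.
#' @return `read_path_record` returns a `path_record`.
#' @export
write_path_record <- function(rec, path) {
  stopifnot(inherits(rec, "path_record"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(unclass(rec$config), list(n_launched = rec$n_launched,
                                     compressed = rec$compressed))
  writeLines(paste0("#", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  writeLines("path,weight", con)
  writeLines(sprintf("%.17g,%.17g", rec$escaped_paths, rec$escape_weights),
             con)
  invisible(path)
}

#' @rdname write_path_record
#' @export
read_path_record <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  df <- read.csv(text = lines[-1])
  cfg <- transport_config(hdr$n_medium, hdr$n_outside, hdr$g, hdr$n_photons,
                          hdr$max_dimensionless_path, hdr$seed,
                          hdr$weight_min)
  structure(list(escaped_paths = df$path, escape_weights = df$weight,
                 n_launched = hdr$n_launched, config = cfg,
                 compressed = isTRUE(hdr$compressed)),
            class = "path_record")
}

#' Diffusion-approximation diffuse reflectance (closed form)
#'
#' Total diffuse reflectance of a semi-infinite homogeneous medium from
#' steady-state diffusion theory with an extrapolated boundary and an image
#' source:
#' \deqn{R_d = \tfrac12\left[e^{-\mu_{eff} z_0} +
#'   e^{-\mu_{eff}(z_0 + 2 z_e)}\right]}
#' with \eqn{z_0 = 1/(\mu_a + \mu_s')},
#' \eqn{D = 1/[3(\mu_a+\mu_s')]},
#' \eqn{\mu_{eff} = \sqrt{\mu_a/D}} and extrapolation length
#' \eqn{z_e = 2AD}, where A accounts for internal reflection at the
#' refractive-index mismatch (A = 1 when matched). Accurate at high
#' transport albedo; used to initialize reflectance inversions.
#'
#' @param mua,musp Optical coefficients, mm^-1 (vectorized).
#' @param n_rel Relative refractive index (medium / outside).
#' @return Diffuse reflectance.
#' @export
diffusion_reflectance <- function(mua, musp, n_rel = 1) {
  mut <- mua + musp
  z0 <- 1 / mut
  D <- 1 / (3 * mut)
  mueff <- sqrt(mua / D)
  A <- boundary_A(n_rel)
  ze <- 2 * A * D
  0.5 * (exp(-mueff * z0) + exp(-mueff * (z0 + 2 * ze)))
}

# Groenhuis/Egan empirical internal-reflection parameter
boundary_A <- function(n_rel) {
  if (abs(n_rel - 1) < 1e-12) return(1)
  rd <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + rd) / (1 - rd)
}

#' Invert the diffusion closed form for absorption
#'
#' Given a diffuse reflectance and a known reduced scattering coefficient,
#' solves [diffusion_reflectance()] for mu_a by monotone root bracketing.
#' Used to build a rough optical-property target for initializing the
#' reflectance recipe fit.
#'
#' @param rd Diffuse reflectance in (0, 1\].
#' @param musp Reduced scattering coefficient, mm^-1.
#' @param n_rel Relative refractive index.
#' @return Absorption coefficient, mm^-1 (vectorized over `rd`).
#' @export
diffusion_invert_mua <- function(rd, musp, n_rel = 1) {
  musp <- rep_len(musp, length(rd))
  vapply(seq_along(rd), function(i) {
    r <- min(rd[i], diffusion_reflectance(0, musp[i], n_rel))
    if (r <= 0) return(100)
    f <- function(m) diffusion_reflectance(m, musp[i], n_rel) - r
    if (f(0) <= 0) return(0)
    uniroot(f, c(0, 1000), tol = 1e-12)$root
  }, numeric(1))
}
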