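#' Pigment optical-property record
#'
#' Per-unit-concentration absorption and reduced-scattering spectra for one
#' pigment. Concentration unit is mass fraction, mg pigment per g total
#' phantom mass; spectra are mm^-1 per unit mass fraction.
#'
#' @param name Unique identifier, e.g. "PY74", "india_ink".
#' @param category One of "yellow", "magenta", "miscellaneous", "white",
#'   "black".
#' @param abs_per_conc,scat_per_conc Non-negative `spectrum` objects on a
#'   shared grid.
#' @return An object of class `pigment_record`.
#' @export
pigment_record <- function(name, category, abs_per_conc, scat_per_conc) {
  category <- match.arg(category, pigment_categories())
  stopifnot(inherits(abs_per_conc, "spectrum"),
            inherits(scat_per_conc, "spectrum"))
  check_same_grid(abs_per_conc, scat_per_conc, "pigment spectra")
  if (any(abs_per_conc$values < 0) || any(scat_per_conc$values < 0))
    stop("pigment_record: spectra must be non-negative")
  structure(list(name = as.character(name), category = category,
                 abs_per_conc = abs_per_conc, scat_per_conc = scat_per_conc),
            class = "pigment_record")
}

#' Pigment category levels
#' @return Character vector of the five categories.
#' @export
pigment_categories <- function() {
  c("yellow", "magenta", "miscellaneous", "white", "black")
}

#' Pigment basis
#'
#' An ordered collection of [pigment_record()]s on a common wavelength grid.
#' Columns of this basis are the per-unit-concentration spectra entering the
#' nonnegative least-squares recipe fits.
#'
#' @param records List of `pigment_record`s with unique names.
#' @param id Basis identifier string.
#' @return An object of class `pigment_basis`.
#' @export
pigment_basis <- function(records, id = "basis") {
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, TRUE, "pigment_record")))
  nms <- vapply(records, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("pigment_basis: duplicate pigment names")
  grid <- records[[1]]$abs_per_conc$grid
  for (r in records) {
    if (!grids_equal(r$abs_per_conc$grid, grid))
      stop("pigment_basis: all records must share one wavelength grid")
  }
  names(records) <- nms
  structure(list(records = records, grid = grid, id = id),
            class = "pigment_basis")
}

#' @export
print.pigment_basis <- function(x, ...) {
  cats <- vapply(x$records, `[[`, "", "category")
  cat(sprintf("<pigment_basis> '%s': %d pigments (%s), %g-%g nm\n",
              x$id, length(x$records),
              paste(sprintf("%d %s", table(factor(cats, pigment_categories())),
                            pigment_categories()), collapse = ", "),
              x$grid$start_nm, x$grid$stop_nm))
  invisible(x)
}

#' Names of pigments in a basis
#' @param basis A `pigment_basis`.
#' @param categories Optional subset of categories to keep.
#' @return Character vector of pigment names.
#' @export
basis_names <- function(basis, categories = NULL) {
  stopifnot(inherits(basis, "pigment_basis"))
  nms <- names(basis$records)
  if (!is.null(nms) && !is.null(categories)) {
    keep <- vapply(basis$records, `[[`, "", "category") %in% categories
    nms <- nms[keep]
  }
  nms
}

#' Restrict a basis to a subset of pigments
#' @param basis A `pigment_basis`.
#' @param names Pigment names to keep (order preserved).
#' @return A `pigment_basis`.
#' @export
basis_subset <- function(basis, names) {
  stopifnot(inherits(basis, "pigment_basis"))
  missing <- setdiff(names, basis_names(basis))
  if (length(missing))
    stop("basis_subset: unknown pigment(s): ", paste(missing, collapse = ", "))
  pigment_basis(basis$records[names], id = paste0(basis$id, "_subset"))
}

basis_matrix <- function(basis, which = c("abs", "scat"), names = NULL) {
  which <- match.arg(which)
  if (is.null(names)) names <- basis_names(basis)
  field <- if (which == "abs") "abs_per_conc" else "scat_per_conc"
  m <- vapply(basis$records[names], function(r) r[[field]]$values,
              numeric(length(basis$grid)))
  matrix(m, ncol = length(names), dimnames = list(NULL, names))
}

#' Pigment recipe
#'
#' A mapping from pigment name to concentration (mass fraction, mg/g), all
#' entries non-negative.
#'
#' @param concentrations Named numeric vector of concentrations >= 0.
#' @param basis_id Identifier of the basis the recipe refers to.
#' @return An object of class `recipe`.
#' @export
recipe <- function(concentrations, basis_id = "basis") {
  concentrations <- unlist(concentrations)
  if (length(concentrations) && is.null(names(concentrations)))
    stop("recipe: concentrations must be named by pigment")
  if (any(concentrations < 0)) stop("recipe: concentrations must be >= 0")
  if (anyDuplicated(names(concentrations)))
    stop("recipe: duplicate pigment names")
  structure(list(concentrations = concentrations,
                 basis_id = basis_id),
            class = "recipe")
}

#' @export
print.recipe <- function(x, ...) {
  cat(sprintf("<recipe> basis '%s'\n", x$basis_id))
  cc <- x$concentrations
  cc <- cc[cc > 0]
  if (!length(cc)) cat("  (all-zero recipe)\n")
  for (nm in names(cc)) cat(sprintf("  %-12s %.6g mg/g\n", nm, cc[[nm]]))
  invisible(x)
}

check_recipe <- function(basis, rec) {
  stopifnot(inherits(basis, "pigment_basis"), inherits(rec, "recipe"))
  unknown <- setdiff(names(rec$concentrations), basis_names(basis))
  if (length(unknown))
    stop("recipe names not in basis: ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Optical properties of a pigment mixture
#'
#' Concentration-linear superposition: mu_a and mu_s' of the mixture are the
#' concentration-weighted sums of the per-unit pigment spectra.
#'
#' @param basis A `pigment_basis`.
#' @param rec A `recipe` whose names are a subset of the basis.
#' @return List with `mua` and `musp` `spectrum` objects on the basis grid.
#' @export
mix_properties <- function(basis, rec) {
  check_recipe(basis, rec)
  n <- length(basis$grid)
  mua <- numeric(n); musp <- numeric(n)
  for (nm in names(rec$concentrations)) {
    c_i <- rec$concentrations[[nm]]
    mua <- mua + c_i * basis$records[[nm]]$abs_per_conc$values
    musp <- musp + c_i * basis$records[[nm]]$scat_per_conc$values
  }
  list(mua = spectrum(mua, basis$grid), musp = spectrum(musp, basis$grid))
}

gaussian_peak <- function(lam, centre, sigma, height) {
  height * exp(-0.5 * ((lam - centre) / sigma)^2)
}

# smooth short-wavelength absorption edge: ~height below edge_nm, ->0 above
absorption_edge <- function(lam, edge_nm, height, width = 8) {
  height / (1 + exp((lam - edge_nm) / width))
}

#' Generate a synthetic 20-pigment basis
#'
#' Deterministic-in-seed stand-in for a measured pigment characterization,
#' emulating the qualitative features of artist-pigment optical properties in
#' epoxy: 6 yellows (Gaussian absorption peaks at 400-460 nm, broad), 6
#' magentas (bimodal peaks in 500-600 nm, narrower; one variant with an extra
#' ~625 nm peak), 3 miscellaneous absorbers (one ~500 nm peak; two with
#' red/NIR absorption extending to 750 nm), 2 blacks (one spectrally flat,
#' one decreasing monotonically like India ink) and 3 whites (Mie-Rayleigh
#' power-law scattering with distinct amplitude/fraction/power, two with
#' short-wavelength absorption edges at 410 and 380 nm). All colored pigments
#' carry a small power-law scattering contribution, as measured colored
#' pigments do.
#'
#' @param seed Integer seed; the same seed always returns the same basis.
#' @param grid Wavelength grid, default 370-950 nm at 1 nm.
#' @return A `pigment_basis` of 20 records.
#' @export
generate_synthetic_basis <- function(seed = 1, grid = default_grid()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  lam <- wavelengths(grid)
  recs <- list()
  add <- function(name, category, mua, musp) {
    recs[[length(recs) + 1]] <<- pigment_record(
      name, category,
      spectrum(pmax(mua, 0), grid), spectrum(pmax(musp, 0), grid))
  }
  # small scattering carried by every colored pigment
  small_scat <- function() {
    p <- power_law_params(a = runif(1, 0.002, 0.01), f_ray = runif(1, 0, 0.3),
                          b_mie = runif(1, 0.5, 2))
    power_law_eval(p, grid)$values
  }

  # 6 yellows: single broad Gaussian peaks, centres 400-460 nm
  centres_y <- seq(400, 460, length.out = 6) + runif(6, -5, 5)
  for (i in 1:6) {
    sig <- runif(1, 25, 40)
    h <- runif(1, 0.6, 1.6)
    mua <- gaussian_peak(lam, centres_y[i], sig, h) +
      absorption_edge(lam, 390, 0.3 * h, width = 15)
    add(sprintf("yellow%02d", i), "yellow", mua, small_scat())
  }

  # 6 magentas: bimodal narrow peaks in 500-600 nm; #6 adds a ~625 nm peak
  for (i in 1:6) {
    c1 <- runif(1, 505, 545); gap <- runif(1, 25, 45)
    s1 <- runif(1, 12, 20); s2 <- runif(1, 12, 20)
    h <- runif(1, 0.5, 1.4)
    mua <- gaussian_peak(lam, c1, s1, h) +
      gaussian_peak(lam, min(c1 + gap, 600), s2, h * runif(1, 0.7, 1.1)) +
      gaussian_peak(lam, 420, 40, 0.15 * h)
    if (i == 6) mua <- mua + gaussian_peak(lam, 625, 15, 0.5 * h)
    add(sprintf("magenta%02d", i), "magenta", mua, small_scat())
  }

  # 3 miscellaneous: one ~500 nm peak; two red/NIR absorbers out to 750 nm
  add("misc_orange", "miscellaneous",
      gaussian_peak(lam, 500 + runif(1, -5, 5), runif(1, 25, 35),
                    runif(1, 0.5, 1.2)),
      small_scat())
  for (i in 1:2) {
    c_red <- runif(1, 640, 680)
    h <- runif(1, 0.4, 1)
    mua <- gaussian_peak(lam, c_red, runif(1, 30, 45), h) +
      gaussian_peak(lam, 720, 30, 0.4 * h) +
      absorption_edge(lam, 750, 0.1 * h, width = 20) *
        (1 - absorption_edge(lam, 560, 1, width = 20))
    add(sprintf("misc_rednir%d", i), "miscellaneous", mua, small_scat())
  }

  # 2 blacks: one flat, one monotone-decreasing (India-ink-like)
  flat <- runif(1, 0.25, 0.5)
  add("black_flat", "black", rep(flat, length(lam)) +
        0.01 * flat * (950 - lam) / 580, small_scat())
  h_ink <- runif(1, 0.5, 1)
  add("india_ink", "black", h_ink * (lam / 500)^-runif(1, 0.8, 1.3),
      small_scat())

  # 3 whites: distinct Mie-Rayleigh scattering; UV absorption edges
  white_par <- list(
    list(name = "white_tio2", a = runif(1, 1.5, 2.5), f = runif(1, 0.05, 0.15),
         b = runif(1, 0.6, 1.0), edge = 410),
    list(name = "white_zno", a = runif(1, 0.8, 1.4), f = runif(1, 0.2, 0.4),
         b = runif(1, 1.0, 1.6), edge = 380),
    list(name = "white_al2o3", a = runif(1, 0.3, 0.7), f = runif(1, 0.5, 0.8),
         b = runif(1, 1.6, 2.4), edge = NA))
  for (w in white_par) {
    musp <- power_law_eval(power_law_params(w$a, w$f, w$b), grid)$values
    mua <- if (is.na(w$edge)) rep(0, length(lam)) else
      absorption_edge(lam, w$edge, runif(1, 0.5, 1.5), width = 6)
    add(w$name, "white", mua, musp)
  }

  pigment_basis(recs, id = sprintf("synthetic_seed%d", seed))
}

#' Read / write a pigment basis
#'
#' CSV dialect: two files per basis, suffixed `_abs.csv` and `_scat.csv`.
#' Row 1 is the header `wavelength_nm,<name1>,<name2>,...`; row 2 is a
#' category sidecar `#category,<cat1>,<cat2>,...`; remaining rows are one
#' wavelength each.
#'
#' @param path Path stem; `read_basis("b")` reads `b_abs.csv` and
#'   `b_scat.csv`.
#' @param basis A `pigment_basis` (for writing).
#' @return `read_basis` returns a `pigment_basis`; `write_basis` returns the
#'   path stem invisibly.
#' @export
read_basis <- function(path) {
  read_one <- function(file) {
    lines <- readLines(file, encoding = "UTF-8")
    if (length(lines) < 3) stop("read_basis: truncated file ", file)
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    if (header[1] != "wavelength_nm")
      stop("read_basis: first column must be wavelength_nm in ", file)
    sidecar <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
    if (sidecar[1] != "#category")
      stop("read_basis: missing '#category' sidecar line in ", file)
    if (length(sidecar) != length(header))
      stop("read_basis: category sidecar length mismatch in ", file)
    df <- read.csv(text = lines[-2], check.names = FALSE)
    list(names = header[-1], categories = sidecar[-1], df = df)
  }
  a <- read_one(paste0(path, "_abs.csv"))
  s <- read_one(paste0(path, "_scat.csv"))
  if (!identical(a$names, s$names) || !identical(a$categories, s$categories))
    stop("read_basis: _abs and _scat files disagree on pigments")
  if (anyDuplicated(a$names)) stop("read_basis: duplicate pigment names")
  wl <- a$df[[1]]
  if (!identical(wl, s$df[[1]]))
    stop("read_basis: _abs and _scat files disagree on wavelengths")
  steps <- diff(wl)
  if (any(abs(steps - steps[1]) > 1e-9))
    stop("read_basis: wavelength column must be regularly spaced")
  grid <- wl_grid(wl[1], wl[length(wl)], steps[1])
  recs <- lapply(seq_along(a$names), function(i) {
    va <- a$df[[i + 1]]; vs <- s$df[[i + 1]]
    if (any(va < 0) || any(vs < 0))
      stop("read_basis: negative value for pigment ", a$names[i])
    if (!a$categories[i] %in% pigment_categories())
      stop("read_basis: invalid category '", a$categories[i], "' for ",
           a$names[i])
    pigment_record(a$names[i], a$categories[i],
                   spectrum(va, grid), spectrum(vs, grid))
  })
  pigment_basis(recs, id = basename(path))
}

#' @rdname read_basis
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "pigment_basis"))
  nms <- basis_names(basis)
  cats <- vapply(basis$records, `[[`, "", "category")
  wl <- wavelengths(basis$grid)
  write_one <- function(file, which) {
    m <- basis_matrix(basis, which)
    con <- file(file, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("wavelength_nm", nms), collapse = ","), con)
    writeLines(paste(c("#category", cats), collapse = ","), con)
    body <- cbind(wl, m)
    writeLines(apply(format(body, trim = TRUE, digits = 15, scientific = FALSE),
                     1, paste, collapse = ","), con)
  }
  write_one(paste0(path, "_abs.csv"), "abs")
  write_one(paste0(path, "_scat.csv"), "scat")
  invisible(path)
}
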