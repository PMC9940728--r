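# Shared fixtures, built once per test run. Coarse grids keep the suite fast
# without changing any of the mathematics being checked.

# coarse working grid for fitting tests: 370-950 nm at 5 nm (117 samples)
coarse_grid <- wl_grid(370, 950, 5)

# the standard synthetic 20-pigment basis on the coarse grid
fixture_basis <- generate_synthetic_basis(seed = 42, grid = coarse_grid)

# tiny 3-sample grid for hand-checkable arithmetic
tiny_grid <- wl_grid(400, 402, 1)
tiny_spec <- function(v) spectrum(v, tiny_grid)

# shared Monte Carlo reference ensembles (built lazily, reused across tests)
.mc_cache <- new.env(parent = emptyenv())

matched_record <- function() {
  if (is.null(.mc_cache$matched))
    .mc_cache$matched <- run_reference(transport_config(
      n_medium = 1, n_outside = 1, g = 0.8, n_photons = 2e4,
      max_dimensionless_path = 1e4, seed = 101))
  .mc_cache$matched
}

epoxy_record <- function() {
  if (is.null(.mc_cache$epoxy))
    .mc_cache$epoxy <- run_reference(transport_config(
      n_medium = 1.56, n_outside = 1, g = 0.8, n_photons = 5e3,
      max_dimensionless_path = 1e4, seed = 202))
  .mc_cache$epoxy
}

# hemoglobin-like absorption target on the coarse grid: visible double peak
# plus weak NIR baseline, resembling oxygenated blood in tissue
hemoglobin_like_target <- function(basis = fixture_basis) {
  lam <- wavelengths(basis$grid)
  mua <- 1.2 * exp(-0.5 * ((lam - 542) / 15)^2) +
    1.0 * exp(-0.5 * ((lam - 577) / 12)^2) +
    2.5 * exp(-0.5 * ((lam - 420) / 20)^2) +
    0.02 + 0.04 * pmax(lam - 700, 0) / 250
  musp <- power_law_eval(power_law_params(a = 1.2, f_ray = 0.2, b_mie = 1.2),
                         basis$grid)
  tissue_target(spectrum(mua, basis$grid), musp, label = "hemoglobin-like")
}
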