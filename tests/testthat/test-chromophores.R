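# random nonsingular chromophore sets for property-style round trips
random_chromophores <- function(seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  g <- skin_grid()
  lam <- wavelengths(g)
  peak <- function(c0, s0, h) h * exp(-0.5 * ((lam - c0) / s0)^2) + 0.01 * h
  chromophore_set(
    spectrum(peak(runif(1, 530, 560), runif(1, 10, 25), runif(1, 100, 400)), g),
    spectrum(peak(runif(1, 545, 580), runif(1, 10, 30), runif(1, 100, 400)) +
               peak(760, 20, runif(1, 20, 60)), g),
    spectrum(0.001 + 0.01 * (lam - 470) / 480, g),
    spectrum(0.0005 + peak(930, 20, 0.01), g),
    spectrum(runif(1, 20, 80) * (lam / 500)^-runif(1, 2, 4), g))
}

test_that("the skin absorption model is the stated linear combination", {
  ch <- synthetic_chromophores()
  zero <- skin_params(StO2 = 0.5, B = 0, W = 0, F = 0, M = 0)
  expect_true(all(skin_mua(zero, ch)$values == 0))

  # fully oxygenated blood is independent of the deoxy spectrum
  p1 <- skin_params(StO2 = 1, B = 0.05)
  ch2 <- ch
  ch2$mua_hb <- spectrum(10 * ch$mua_hb$values, ch$grid)
  expect_equal(skin_mua(p1, ch)$values, skin_mua(p1, ch2)$values)

  # direct evaluation against a hand-built combination
  p <- skin_params(StO2 = 0.7, B = 0.04, W = 0.5, F = 0.02, M = 3e-4)
  expected <- 0.7 * 0.04 * 2.3e-3 * ch$mua_hbo2$values +
    0.3 * 0.04 * 2.3e-3 * ch$mua_hb$values +
    0.5 * ch$mua_water$values + 0.02 * ch$mua_fat$values +
    3e-4 * ch$mua_mel$values
  expect_equal(skin_mua(p, ch)$values, expected, tolerance = 1e-12)
})

test_that("blood volume and hemoglobin concentration give 110 uM total hemoglobin", {
  p <- skin_params(StO2 = 0.3, B = 0.0478)
  expect_equal(total_hemoglobin(p), 1.0994e-4, tolerance = 1e-6)
  expect_equal(round(total_hemoglobin(p) * 1e6), 110)
  expect_equal(total_hemoglobin(skin_params(0.5, B = 0)), 0)
  expect_warning(p1 <- skin_params(0.5, B = 1), "sum")  # fractions over 1
  expect_equal(total_hemoglobin(p1), 2.3e-3)
})

test_that("band means are inclusive arithmetic means", {
  g <- wl_grid(500, 520, 1)
  expect_equal(band_mean(spectrum(rep(4, 21), g), c(505, 515)), 4)
  ramp <- spectrum(seq(0, 2, length.out = 21), g)
  expect_equal(band_mean(ramp, c(505, 515)), ramp$values[11])  # midpoint
  expect_error(band_mean(ramp, c(495, 515)), "outside")
})

test_that("three-band inversion round-trips the skin model exactly", {
  ch <- synthetic_chromophores()
  for (sto2 in c(0.30, 0.50, 0.80)) {
    p <- skin_params(StO2 = sto2, B = 0.0478, M = 2.55e-4)
    inv <- invert_sto2(skin_mua(p, ch), oximetry_bands(), ch)
    expect_equal(inv$StO2_hat, sto2, tolerance = 1e-10)
    expect_equal(inv$B_hat, 0.0478, tolerance = 1e-10)
    expect_equal(inv$M_hat, 2.55e-4, tolerance = 1e-10)
    expect_false(inv$clamped)
  }
})

test_that("inversion round trip holds for random parameters and chromophores", {
  for (seed in 1:4) {
    ch <- random_chromophores(seed)
    set.seed(seed + 100)
    for (k in 1:25) {
      p <- skin_params(StO2 = runif(1, 0.05, 0.95), B = runif(1, 0.01, 0.15),
                       M = runif(1, 1e-4, 5e-3))
      inv <- invert_sto2(skin_mua(p, ch), oximetry_bands(), ch)
      expect_equal(inv$StO2_hat, p$StO2, tolerance = 1e-8)
      expect_equal(inv$B_hat, p$B, tolerance = 1e-8)
      expect_equal(inv$M_hat, p$M, tolerance = 1e-8)
    }
  }
})

test_that("estimated StO2 is invariant to the assumed blood hemoglobin concentration", {
  ch <- synthetic_chromophores()
  p <- skin_params(StO2 = 0.63, B = 0.05)
  mua <- skin_mua(p, ch)
  i1 <- invert_sto2(mua, oximetry_bands(), ch, H = 2.3e-3)
  i2 <- invert_sto2(mua, oximetry_bands(), ch, H = 4.6e-3)
  expect_equal(i1$StO2_hat, i2$StO2_hat, tolerance = 1e-12)
  expect_equal(i1$M_hat, i2$M_hat, tolerance = 1e-12)
  expect_equal(i2$B_hat, i1$B_hat / 2, tolerance = 1e-10)  # B*H preserved
})

test_that("melanosome estimates are far more sensitive than StO2 to red-band errors", {
  ch <- synthetic_chromophores()
  p <- skin_params(StO2 = 0.5, B = 0.0478, M = 2.55e-4)
  bands <- oximetry_bands()
  bm <- vapply(bands$bands, function(b) band_mean(skin_mua(p, ch), b),
               numeric(1))
  # oracle: direct linear solve on perturbed band values, coded here
  solve_direct <- function(bvals) {
    col <- function(s) vapply(bands$bands, function(b) band_mean(s, b),
                              numeric(1))
    M3 <- cbind(col(ch$mua_hbo2), col(ch$mua_hb), col(ch$mua_mel))
    rhs <- bvals - 0.5 * col(ch$mua_water) - 0.02 * col(ch$mua_fat)
    u <- solve(M3, rhs)
    c(sto2 = u[1] / (u[1] + u[2]), M = u[3])
  }
  base <- solve_direct(bm)
  # red and NIR band absorption reading 0.01 / 0.005 mm^-1 too high: the
  # classic failure mode where a small absolute error produces a large
  # relative error in the (tiny) melanosome fraction but barely moves StO2
  pert <- solve_direct(bm + c(0, 0.01, 0.005))
  rel_M <- abs(pert["M"] - base["M"]) / base["M"]
  rel_sto2 <- abs(pert["sto2"] - base["sto2"]) / base["sto2"]
  expect_gt(rel_M, 1)                 # more than doubled
  expect_gt(rel_M, 10 * rel_sto2)

  # package inversion agrees with the direct-solve oracle
  inv <- invert_sto2(bm + c(0, 0.01, 0.005), bands, ch)
  expect_equal(inv$StO2_hat, as.numeric(pert["sto2"]), tolerance = 1e-10)
  expect_equal(inv$M_hat, as.numeric(pert["M"]), tolerance = 1e-10)
})

test_that("percent errors reproduce published oximetry-phantom bookkeeping", {
  expect_equal(percent_error(30.00, 32.94), 9.80, tolerance = 0.02)
  expect_equal(percent_error(0.0255, 0.0720), 182.35, tolerance = 0.005)
  expect_equal(percent_error(5, 5), 0)
  expect_error(percent_error(0, 1), "non-zero")
  # antisymmetry of the deviation
  expect_equal(percent_error(10, 12), -percent_error(10, 8))
  expect_equal(mean_abs_percent_error(c(9.81, -1.60, 1.51)), 4.31,
               tolerance = 0.005)
  expect_equal(mean_abs_percent_error(-7), 7)
  expect_equal(mean_abs_percent_error(c(0, 0, 0)), 0)
})

test_that("packaged synthetic chromophore table matches the generator", {
  path <- system.file("extdata", "chromophores_synthetic.csv",
                      package = "phantomkit")
  ch <- read_chromophores(path)
  ref <- synthetic_chromophores()
  expect_equal(ch$mua_hbo2$values, ref$mua_hbo2$values, tolerance = 1e-8)
  expect_equal(ch$mua_mel$values, ref$mua_mel$values, tolerance = 1e-8)
  expect_equal(wavelengths(ch$grid), wavelengths(skin_grid()))
})
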