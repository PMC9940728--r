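make_target <- function(basis, conc) {
  props <- mix_properties(basis, recipe(conc, basis$id))
  tissue_target(props$mua, props$musp)
}

test_that("absorption weights equalize magnitude across the spectrum", {
  w <- absorption_weights(tiny_spec(c(2, 1, 4)))
  expect_equal(w$values, c(2, 4, 1))
  expect_equal(absorption_weights(tiny_spec(c(3, 3, 3)))$values, c(1, 1, 1))
  wz <- absorption_weights(tiny_spec(c(1, 0, 2)))
  expect_true(all(is.finite(wz$values)))   # floor clamp keeps weights finite
  expect_equal(min(wz$values), 1)          # weight 1 at the argmax
  expect_error(absorption_weights(tiny_spec(c(0, 0, 0))), "zero")
})

test_that("absorption fit recovers a representable non-white mixture", {
  b <- fixture_basis
  truth <- stats::setNames(c(0.8, 1.5, 0.3),
                           c("yellow02", "magenta03", "india_ink"))
  tgt <- make_target(b, truth)
  rec <- fit_absorption(b, tgt)
  got <- rec$concentrations[names(truth)]
  expect_equal(as.numeric(got), as.numeric(truth), tolerance = 1e-8)
  others <- setdiff(names(rec$concentrations), names(truth))
  expect_lt(max(rec$concentrations[others]), 1e-8)
  # only non-white pigments receive concentrations
  expect_false(any(basis_names(b, "white") %in%
                     names(rec$concentrations[rec$concentrations > 0])))
})

test_that("absorption fit handles degenerate targets and bad inputs", {
  b <- fixture_basis
  zero <- tissue_target(spectrum(numeric(length(b$grid)), b$grid),
                        spectrum(numeric(length(b$grid)), b$grid))
  rec <- fit_absorption(b, zero, weighted = FALSE)
  expect_true(all(rec$concentrations == 0))
  expect_error(fit_absorption(b, zero, weighted = TRUE), "zero")
  whites_only <- basis_subset(b, basis_names(b, "white"))
  expect_error(fit_absorption(whites_only, zero, weighted = FALSE),
               "non-white")
})

test_that("scattering fit works on the absorber-subtracted residual", {
  b <- fixture_basis
  # residual equal to 2x one white column recovers concentration 2
  tgt_musp <- spectrum(2 * b$records$white_zno$scat_per_conc$values, b$grid)
  tgt <- tissue_target(spectrum(numeric(length(b$grid)), b$grid), tgt_musp)
  rz <- fit_scattering(b, tgt)
  expect_equal(rz$concentrations[["white_zno"]], 2, tolerance = 1e-8)
  expect_lt(max(rz$concentrations[setdiff(names(rz$concentrations),
                                          "white_zno")]), 1e-8)

  # absorbers already supplying all scattering leave nothing for whites
  absorbers <- stats::setNames(c(5, 5), c("yellow01", "magenta01"))
  supplied <- mix_properties(b, recipe(absorbers, b$id))$musp
  tgt2 <- tissue_target(spectrum(numeric(length(b$grid)), b$grid),
                        spectrum(0.5 * supplied$values, b$grid))
  rz2 <- fit_scattering(b, tgt2, recipe(absorbers, b$id))
  expect_true(all(rz2$concentrations == 0))
})

test_that("broadband two-step fit recovers a full known recipe", {
  b <- fixture_basis
  # the two-step method attributes all absorption to non-white pigments, so
  # an exactly recoverable recipe uses the non-absorbing white
  truth <- stats::setNames(c(0.6, 1.1, 0.25, 0.7),
                           c("yellow03", "magenta05", "black_flat",
                             "white_al2o3"))
  tgt <- make_target(b, truth)
  fr <- fit_broadband(b, tgt)
  got <- fr$recipe$concentrations[names(truth)]
  expect_equal(as.numeric(got), as.numeric(truth), tolerance = 1e-6)
  expect_lt(fr$metrics$mae_abs, 1e-6)
  expect_lt(fr$metrics$mae_scat, 1e-6)
  expect_lt(fr$metrics$sam_abs, 0.01)
  expect_lt(fr$metrics$sam_scat, 0.01)
})

test_that("joint band fit recovers recipes that include absorbing whites", {
  b <- fixture_basis
  truth <- stats::setNames(c(0.6, 1.1, 0.25, 2.0, 0.7),
                           c("yellow03", "magenta05", "black_flat",
                             "white_tio2", "white_al2o3"))
  tgt <- make_target(b, truth)
  fr <- fit_bands(b, tgt, band_set(list()))   # uniform-weight joint NNLS
  got <- fr$recipe$concentrations[names(truth)]
  expect_equal(as.numeric(got), as.numeric(truth), tolerance = 1e-6)
})

test_that("restricting the basis to a traditional white+black pair degrades the fit", {
  b <- fixture_basis
  tgt <- hemoglobin_like_target(b)
  full <- fit_broadband(b, tgt)
  trad <- fit_broadband(basis_subset(b, c("white_tio2", "india_ink")), tgt)
  expect_gte(trad$residual_abs, full$residual_abs)
  expect_gt(trad$metrics$mae_abs, full$metrics$mae_abs)
  expect_gt(trad$metrics$sam_abs, full$metrics$sam_abs)
})

test_that("band fit with uniform weights reduces to the unweighted joint fit", {
  b <- fixture_basis
  tgt <- hemoglobin_like_target(b)
  whole <- band_set(list(c(370, 950)), abs_weights = 1, scat_weights = 1)
  f1 <- fit_bands(b, tgt, whole)
  f2 <- fit_bands(b, tgt, band_set(list()))
  expect_equal(f1$recipe$concentrations, f2$recipe$concentrations,
               tolerance = 1e-10)
})

test_that("band fit drives in-band residuals to zero on representable targets", {
  b <- fixture_basis
  truth <- stats::setNames(c(0.9, 0.4, 1.5), c("magenta02", "india_ink",
                                               "white_tio2"))
  tgt <- make_target(b, truth)
  fr <- fit_bands(b, tgt, oximetry_bands())
  for (bm in fr$band_metrics) {
    expect_lt(bm$mae_abs, 1e-7)
    expect_lt(bm$mae_scat, 1e-7)
  }
})

test_that("raising a band weight cannot worsen that band's fit", {
  b <- fixture_basis
  tgt <- hemoglobin_like_target(b)
  lam <- wavelengths(b$grid)
  base_w <- c(1, 1, 1)
  boosted <- c(100, 1, 1)
  bands3 <- function(w) band_set("540-560,625-645,820-840",
                                 abs_weights = w, scat_weights = base_w)
  f_lo <- fit_bands(b, tgt, bands3(base_w))
  f_hi <- fit_bands(b, tgt, bands3(boosted))
  sel <- lam >= 540 & lam <= 560
  ssr <- function(fr) sum((fr$fitted_mua$values[sel] -
                             tgt$mua$values[sel])^2)
  expect_lte(ssr(f_hi), ssr(f_lo) + 1e-12)
})

test_that("fitted recipes satisfy the nonnegative optimality contracts", {
  b <- fixture_basis
  tgt <- hemoglobin_like_target(b)
  fr <- fit_bands(b, tgt, band_set(list()))
  q <- fr$recipe$concentrations
  expect_true(all(q >= 0))

  A <- phantomkit:::basis_matrix(b, "abs")
  S <- phantomkit:::basis_matrix(b, "scat")
  obj <- function(qq) sum((tgt$mua$values - A %*% qq)^2) +
    sum((tgt$musp$values - S %*% qq)^2)
  qv <- q[colnames(A)]
  best <- obj(qv)
  expect_lte(best, obj(numeric(ncol(A))))
  set.seed(31)
  for (k in 1:100) {
    probe <- runif(ncol(A), 0, 2) * qv + runif(ncol(A), 0, 0.1)
    expect_lte(best, obj(probe) + 1e-10)
  }
})

test_that("enlarging the basis never increases the optimal residual", {
  b <- fixture_basis
  tgt <- hemoglobin_like_target(b)
  nms <- basis_names(b)
  set.seed(13)
  nonwhite <- basis_names(b, setdiff(pigment_categories(), "white"))
  whites <- basis_names(b, "white")
  for (k in 1:5) {
    small_nms <- c(sample(nonwhite, 5), sample(whites, 2))
    big_nms <- unique(c(small_nms, sample(nms, 8)))
    small <- fit_broadband(basis_subset(b, small_nms), tgt)
    big <- fit_broadband(basis_subset(b, big_nms), tgt)
    expect_lte(big$residual_abs, small$residual_abs + 1e-9)
  }
})
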