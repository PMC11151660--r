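test_that("built-in variants encode their documented deltas from BASE", {
  v <- builtin_variants()
  expect_gte(length(v), 12L)
  expect_equal(v$BASE$bg_bvf, 0.01)
  expect_equal(v$BASE$bg_so2, c(0.70, 0.70))
  expect_equal(v$SMALL$vessel_radius, c(0.075, 0.5)) # BASE radii halved
  expect_equal(v$WATER_4cm$water_layer, 40)
  expect_equal(v$WATER_2cm$water_layer, 20)
  expect_equal(v$SKIN$skin_thickness, 0.3)
  expect_equal(v$SKIN$melanosome_fraction, c(0.001, 0.05))
  expect_equal(v$BG_H2O$bg_medium, "water")
  expect_true(v$`HET_0-100`$bg_het)
  expect_equal(v$RES_1.2$grid_spacing, 1.2)
  # every non-BASE variant differs from BASE in at least one field
  base <- unclass(v$BASE)[-1]
  for (nm in setdiff(names(v), "BASE")) {
    expect_false(identical(unclass(v[[nm]])[-1], base), label = nm)
  }
})

test_that("config validation rejects unphysical settings", {
  expect_error(variant_config("X", bg_so2 = c(0.5, 1.5)))
  expect_error(variant_config("X", skin_thickness = -1), "non-negative")
  expect_error(variant_config("X", skin_thickness = 1,
                              vessel_depth = c(0.5, 9)), "skin_thickness")
  expect_error(variant_config("X", grid_spacing = 0))
})

test_that("variant configs round-trip through structured text", {
  cfg <- builtin_variants()$SKIN
  path <- withr::local_tempfile(fileext = ".yaml")
  write_variant_config(cfg, path)
  expect_equal(read_variant_config(path), cfg)
})

test_that("fluence follows the layered closed form", {
  tab <- chromophore_table()
  bare <- variant_config("bare", bg_bvf = 0, illumination_spread = 0,
                         noise_sigma = 0)
  # no layers, zero depth, collimated beam: no attenuation at any wavelength
  expect_equal(fluence_at_depth(0, bare, tab), rep(1, 41))
  # monotone decrease with a thicker water layer, at every wavelength
  w2 <- variant_config("w2", water_layer = 20)
  w4 <- variant_config("w4", water_layer = 40)
  expect_true(all(fluence_at_depth(2, w4, tab) < fluence_at_depth(2, w2, tab)))
  # independent scalar evaluation of the closed form at 700 vs 900 nm for a
  # water background at 2 mm depth
  cfg <- variant_config("wbg", bg_medium = "water")
  phi <- fluence_at_depth(2, cfg, tab)
  mueff <- function(nm) {
    mua <- tab$mu_a_water[wavelength_index(nm)]
    sqrt(3 * mua * (mua + 1.0))
  }
  expect_equal(phi[wavelength_index(900)] / phi[wavelength_index(700)],
               exp(-2 * mueff(900)) / exp(-2 * mueff(700)),
               tolerance = 1e-12)
  # strictly decreasing in depth for fixed wavelength
  base <- builtin_variants()$BASE
  phis <- vapply(1:8, function(z) fluence_at_depth(z, base, tab)[21],
                 numeric(1))
  expect_true(all(diff(phis) < 0))
})

test_that("generation is deterministic and draw streams are per-spectrum", {
  cfg <- builtin_variants(n_spectra = 50, seed = 7)$BASE
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$amplitudes, b$amplitudes)
  expect_identical(a$so2, b$so2)
  # enlarging the dataset must not change earlier spectra
  big <- generate_dataset(cfg, n_spectra = 100)
  expect_identical(big$amplitudes[1:50, ], a$amplitudes)
  expect_identical(big$so2[1:50], a$so2)
})

test_that("with all attenuation off, linear unmixing recovers labels exactly", {
  an <- small_fixtures()$analytic
  est <- predict(build_lu(), an)
  expect_lt(max(abs(est - an$so2)), 1e-6)
})

test_that("melanin skin layer changes the mean spectral slope", {
  n <- 2000
  v <- builtin_variants(n_spectra = n, seed = 5)
  base <- generate_dataset(v$BASE)
  skin <- generate_dataset(v$SKIN)
  slope <- function(ds) ds$amplitudes[, 41] / ds$amplitudes[, 1]
  p <- stats::wilcox.test(slope(base), slope(skin))$p.value
  expect_lt(p, 0.01)
})

test_that("vessel labels are uniform on [0, 1]", {
  ds <- generate_dataset(builtin_variants()$BASE, n_spectra = 10000,
                         seed = 31)
  ks <- suppressWarnings(stats::ks.test(ds$so2, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ds$so2 >= 0 & ds$so2 <= 1))
})

test_that("spectral coloring deepens with depth in the expected direction", {
  tab <- chromophore_table()
  base <- builtin_variants()$BASE
  # at 1% bvf / 70% oxygenation the background attenuates 760 nm faster
  # than 800 nm, so the 760/800 fluence ratio must fall with depth
  r <- vapply(1:8, function(z) {
    phi <- fluence_at_depth(z, base, tab)
    phi[wavelength_index(760)] / phi[wavelength_index(800)]
  }, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("noise model perturbs amplitudes multiplicatively and keeps them non-negative", {
  cfg0 <- builtin_variants(n_spectra = 200, seed = 9)$BASE
  cfg0$noise_sigma <- 0
  clean <- generate_dataset(cfg0)
  noisy <- generate_dataset(builtin_variants(n_spectra = 200, seed = 9)$BASE)
  rel <- noisy$amplitudes / clean$amplitudes - 1
  expect_equal(stats::sd(as.numeric(rel)), 0.02, tolerance = 0.05)
  expect_true(all(noisy$amplitudes >= 0))
})
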