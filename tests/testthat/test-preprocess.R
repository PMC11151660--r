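make_selection_ds <- function(a800) {
  n <- length(a800)
  amps <- matrix(rep(a800, 41), n, 41)
  ds_from_matrix(amps, so2 = rep(0.5, n))
}

test_that("spectra selection applies the 10%-of-max threshold with fallback", {
  # threshold keeps 3 of 5, no fallback
  r <- select_spectra(make_selection_ds(c(1.0, 0.5, 0.2, 0.05, 0.01)))
  expect_equal(n_spectra(r$dataset), 3L)
  expect_false(r$report$fallback_used)
  expect_equal(r$report$n_kept_threshold, 3L)
  # threshold keeps 1 of 20 (5% < 10%): fallback takes the top 2
  r <- select_spectra(make_selection_ds(c(1.0, rep(0.01, 19))))
  expect_true(r$report$fallback_used)
  expect_equal(r$report$n_final, 2L)
  expect_equal(n_spectra(r$dataset), 2L)
  # degenerate ties: all amplitudes equal, everything kept
  r <- select_spectra(make_selection_ds(rep(0.7, 8)))
  expect_equal(r$report$n_final, 8L)
  expect_false(r$report$fallback_used)
  # selection is idempotent
  r2 <- select_spectra(r$dataset)
  expect_equal(n_spectra(r2$dataset), n_spectra(r$dataset))
  expect_error(select_spectra(make_selection_ds(numeric(0))))
})

test_that("selection never returns fewer than 10% of the input", {
  for (seed in 1:5) {
    u <- pa_runif_stream(seed, 0, 60)
    ds <- make_selection_ds(u^4) # heavy-tailed amplitudes
    r <- select_spectra(ds)
    expect_gte(r$report$n_final, ceiling(0.10 * 60))
  }
})

test_that("z-scoring gives population mean 0 / variance 1 over present slots", {
  x <- c(1, 2, 3)
  z <- zscore_spectrum(x, rep(TRUE, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-10)
  # affine invariance
  amps <- matrix(pa_runif_stream(1, 1, 41 * 6), 6, 41) + 0.5
  ds <- ds_from_matrix(amps)
  ds2 <- ds_from_matrix(3.7 * amps + 1.2)
  expect_equal(zscore_dataset(ds)$amplitudes, zscore_dataset(ds2)$amplitudes,
               tolerance = 1e-10)
  # masked statistics use the present entries only, masked slots stay 0
  mask <- matrix(FALSE, 1, 41)
  mask[1, 1:10] <- TRUE
  dsm <- ds_from_matrix(amps[1, , drop = FALSE], mask)
  zm <- zscore_dataset(dsm)
  expect_equal(mean(zm$amplitudes[1, 1:10]), 0, tolerance = 1e-10)
  expect_equal(mean(zm$amplitudes[1, 1:10]^2), 1, tolerance = 1e-10)
  expect_true(all(zm$amplitudes[1, 11:41] == 0))
  expect_equal(zm$amplitudes[1, 1:10], zscore_spectrum(amps[1, ], mask[1, ])[1:10])
  # z-scoring a z-scored dataset is the identity
  z1 <- zscore_dataset(ds)
  expect_equal(zscore_dataset(z1)$amplitudes, z1$amplitudes, tolerance = 1e-10)
  # constant spectra are rejected, not passed through
  cds <- ds_from_matrix(matrix(1, 2, 41))
  expect_error(zscore_dataset(cds), "constant")
  expect_error(zscore_spectrum(rep(2, 41)), "constant")
})

test_that("stratified resampling is uniform with replacement and seeded", {
  ds <- ds_from_matrix(matrix(pa_runif_stream(2, 0, 3 * 41), 3, 41) + 0.1,
                       so2 = c(0.1, 0.5, 0.9))
  r <- stratified_resample(ds, 10, seed = 4)
  expect_equal(n_spectra(r), 10L)
  expect_true(all(r$so2 %in% ds$so2))
  expect_identical(stratified_resample(ds, 10, seed = 4)$amplitudes,
                   r$amplitudes)
  # frequencies of 3 equally likely spectra at n = 1e5: 99.9% binomial band
  big <- stratified_resample(ds, 100000, seed = 8)
  freq <- table(big$so2) / 100000
  expect_true(all(freq > 0.32 & freq < 0.35))
})

test_that("wavelength subsetting masks slots and composes with z-scoring", {
  ds <- small_fixtures()$base
  full <- subset_wavelengths(ds, wavelength_grid()$wavelengths)
  expect_identical(full$mask, ds$mask)
  expect_identical(full$amplitudes, ds$amplitudes)
  sub <- subset_wavelengths(ds, c(700, 800, 900))
  expect_equal(which(sub$mask[1, ]), c(1L, 21L, 41L))
  expect_true(all(sub$amplitudes[, -c(1, 21, 41)] == 0))
  z <- zscore_dataset(sub)
  v <- z$amplitudes[5, c(1, 21, 41)]
  expect_equal(mean(v), 0, tolerance = 1e-10)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  expect_error(subset_wavelengths(ds, c(701, 800)), "not on the")
  expect_error(subset_wavelengths(ds, 800), "at least 2")
})
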