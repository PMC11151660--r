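test_that("trained LSTM weight shapes match the declared architecture", {
  m <- tiny_lstm()
  h <- m$hyper
  expect_equal(h$fc_input, 4100L) # 41 steps x 100 hidden
  expect_equal(dim(m$weights$W1), c(4100L, 1000L))
  expect_length(m$weights$b1, 1000L)
  # parameter count of the head's first layer
  expect_equal(prod(dim(m$weights$W1)) + length(m$weights$b1),
               h$fc_input * 1000 + 1000)
  expect_equal(dim(m$weights$wh), c(100L, 400L))
})

test_that("masked slots can never influence predictions", {
  m <- tiny_lstm()
  ds <- zscore_dataset(subset_wavelengths(small_fixtures()$base,
                                          evenly_spaced_wavelengths(10)))
  p0 <- predict(m, ds)
  junk <- ds
  junk$amplitudes[!junk$mask] <- 1e6 * pa_runif_stream(3, 3, sum(!junk$mask)) - 5e5
  p1 <- predict(m, junk)
  expect_identical(p0, p1)
  # fully masked spectra are rejected
  allmask <- ds
  allmask$mask[1, ] <- FALSE
  expect_error(predict(m, allmask), "no present wavelengths")
})

test_that("prediction is deterministic, bounded, and mask-flexible", {
  m <- tiny_lstm()
  for (nl in c(5, 20, 41)) {
    ds <- zscore_dataset(subset_wavelengths(small_fixtures()$base,
                                            evenly_spaced_wavelengths(nl)))
    p <- predict(m, ds)
    expect_true(all(p >= 0 & p <= 1))
    expect_identical(predict(m, ds), p)
  }
})

test_that("training contracts: normalization precondition, scheduler, loss", {
  raw <- small_fixtures()$base
  h <- lstm_hyperparams(epochs = 2, batch_size = 128, seed = 1)
  expect_error(train(build_lstm(h), raw), "not z-scored")
  faked <- raw
  faked$normalized <- TRUE # flag set but spectra not standardized
  expect_error(train(build_lstm(h), faked), "not z-scored")
  lg <- tiny_lstm()$log
  expect_equal(names(lg), c("epoch", "train_loss", "val_loss", "lr"))
  # learning rate only ever decays by the configured factor
  expect_true(all(lg$lr <= lg$lr[1]))
  expect_true(all(lg$lr %in% (lg$lr[1] * 0.5^(0:30))))
})

test_that("the LSTM separates two saturation levels from noiseless spectra", {
  s <- rep(c(0.2, 0.8), 100)
  scale <- 0.5 + pa_runif_stream(5, 1, 200)
  amps <- analytic_spectra(s, as.list(scale))
  ds <- zscore_dataset(ds_from_matrix(amps, so2 = s))
  # gentle learning rate: with only two target levels the default 1e-3
  # overshoots into sigmoid saturation under the absolute-error loss
  h <- lstm_hyperparams(epochs = 50, batch_size = 32, initial_lr = 1e-4,
                        seed = 2)
  m <- train(build_lstm(h), ds)
  expect_gt(m$log$train_loss[1], min(m$log$train_loss)) # optimization sanity
  held <- rep(c(0.2, 0.8), 20)
  hs <- 0.9 + pa_runif_stream(6, 1, 40)
  hds <- zscore_dataset(ds_from_matrix(analytic_spectra(held, as.list(hs)),
                                       so2 = held))
  eps <- mean(abs(predict(m, hds) - held))
  expect_lt(eps, 0.05)
})

test_that("linear unmixing recovers mixtures and is scale invariant", {
  tab <- chromophore_table()
  expect_equal(linear_unmixing(tab$mu_a_hbo2, table = tab), 1.0)
  expect_equal(linear_unmixing(tab$mu_a_hb, table = tab), 0.0)
  mix <- 0.3 * tab$mu_a_hbo2 + 0.7 * tab$mu_a_hb
  expect_equal(linear_unmixing(mix, table = tab), 0.3, tolerance = 1e-6)
  # independent oracle: exhaustive search over s minimizing the residual of
  # the unit-normalized model spectrum
  grid_lu <- function(x) {
    ss <- seq(0, 1, by = 1e-4)
    resid <- vapply(ss, function(s) {
      b <- s * tab$mu_a_hbo2 + (1 - s) * tab$mu_a_hb
      b <- b / sqrt(sum(b^2))
      sum((x - sum(x * b) * b)^2)
    }, numeric(1))
    ss[which.min(resid)]
  }
  for (s_true in c(0.15, 0.5, 0.82)) {
    x <- s_true * tab$mu_a_hbo2 + (1 - s_true) * tab$mu_a_hb
    expect_equal(linear_unmixing(x, table = tab), grid_lu(x),
                 tolerance = 2e-4)
    expect_equal(linear_unmixing(17.3 * x, table = tab),
                 linear_unmixing(x, table = tab), tolerance = 1e-12)
  }
  # masked fit uses the present wavelengths only
  mask <- rep(c(TRUE, FALSE), length.out = 41)
  expect_equal(linear_unmixing(mix * mask, mask, tab), 0.3, tolerance = 1e-6)
  expect_error(linear_unmixing(rep(1, 41), table = tab), "constant")
})

test_that("the feedforward baseline is wavelength-inflexible by design", {
  s <- pa_runif_stream(7, 0, 300)
  sc <- 0.5 + pa_runif_stream(7, 1, 300)
  ds <- zscore_dataset(ds_from_matrix(analytic_spectra(s, as.list(sc)),
                                      so2 = s))
  h <- lstm_hyperparams(epochs = 25, batch_size = 64, seed = 3)
  m <- train(build_lsd(hyper = h), ds)
  held_s <- pa_runif_stream(8, 0, 80)
  held <- zscore_dataset(ds_from_matrix(
    analytic_spectra(held_s, list(1)), so2 = held_s))
  eps <- stats::median(abs(predict(m, held) - held_s))
  expect_lt(eps, 0.05)
  masked <- zscore_dataset(subset_wavelengths(held, evenly_spaced_wavelengths(10)))
  expect_error(predict(m, masked), "full wavelength set")
  expect_error(train(build_lsd(hyper = h),
                     zscore_dataset(subset_wavelengths(ds_from_matrix(
                       analytic_spectra(s, as.list(sc)), so2 = s),
                       evenly_spaced_wavelengths(10)))),
               "full wavelength set")
})

test_that("LSTM matches the fixed-wavelength baseline on identical colored data", {
  cfg <- builtin_variants()$BASE
  tr <- paox:::prepare_training_data(cfg, 2500, 101)
  te <- paox:::prepare_training_data(cfg, 1000, 102)
  h <- lstm_hyperparams(epochs = 15, batch_size = 256, seed = 5)
  m_lstm <- train(build_lstm(h), tr)
  m_lsd <- train(build_lsd(hyper = h), tr)
  e_lstm <- stats::median(abs(predict(m_lstm, te) - te$so2))
  e_lsd <- stats::median(abs(predict(m_lsd, te) - te$so2))
  expect_lte(e_lstm, e_lsd + 0.02)
})

test_that("model checkpoints round-trip", {
  m <- tiny_lstm()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  ds <- zscore_dataset(small_fixtures()$base)
  expect_identical(predict(m2, ds), predict(m, ds))
  expect_error(suppressWarnings(load_model(withr::local_tempfile(fileext = ".rds"))))
})
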