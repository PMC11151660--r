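# independent brute-force Jensen-Shannon evaluation used as the oracle
js_oracle <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) sum(ifelse(a > 0, a * log(a / m), 0))
  0.5 * term(p) + 0.5 * term(q)
}

random_density <- function(seed, stream, k = 100) {
  u <- pa_runif_stream(seed, stream, k)
  u / sum(u)
}

test_that("per-wavelength histograms follow the binning conventions", {
  # point mass at zero lands in a single bin
  amps <- matrix(0, 50, 41)
  amps[, 1] <- pa_runif_stream(1, 0, 50) # one informative column
  ds <- ds_from_matrix(amps, normalized = TRUE)
  hs <- build_histograms(ds)
  expect_equal(dim(hs$density), c(100L, 41L))
  expect_equal(sum(hs$density[, 2] > 0), 1L)
  expect_equal(sum(hs$density[, 2]), 1)
  # a value exactly at the +3 edge is counted in the (right-closed) last bin
  amps2 <- matrix(0, 10, 41)
  amps2[1, 5] <- 3
  amps2[2, 5] <- -3
  hs2 <- build_histograms(ds_from_matrix(amps2, normalized = TRUE))
  expect_gt(hs2$density[100, 5], 0)
  expect_gt(hs2$density[1, 5], 0)
  # out-of-range values are excluded before normalization
  amps3 <- matrix(0, 100, 41)
  amps3[, 7] <- c(rep(10, 40), rep(0.5, 60))
  hs3 <- build_histograms(ds_from_matrix(amps3, normalized = TRUE))
  expect_equal(hs3$n_samples[7], 60L)
  expect_equal(sum(hs3$density[, 7]), 1)
  expect_error(build_histograms(ds_from_matrix(matrix(1, 0, 41))))
})

test_that("histogram in-range mass matches the normal-tail oracle", {
  z <- stats::qnorm(pa_runif_stream(9, 2, 100000))
  amps <- matrix(0, 100000, 41)
  amps[, 3] <- z
  hs <- build_histograms(ds_from_matrix(amps, normalized = TRUE))
  expect_equal(hs$n_samples[3] / 100000, stats::pnorm(3) - stats::pnorm(-3),
               tolerance = 2e-3)
})

test_that("KL divergence matches hand-evaluated cases", {
  p <- random_density(4, 1)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_identical(kl_divergence(c(1, 0), c(0, 1)), Inf)
  expect_error(kl_divergence(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("JS divergence equals the brute-force summation and its bounds", {
  for (k in 1:8) {
    p <- random_density(11, 2 * k)
    q <- random_density(11, 2 * k + 1)
    expect_equal(js_divergence(p, q), js_oracle(p, q), tolerance = 1e-12)
    expect_equal(js_divergence(p, q), js_divergence(q, p), tolerance = 1e-15)
    expect_gte(js_divergence(p, q), 0)
    expect_lte(js_divergence(p, q), log(2))
  }
  expect_equal(js_divergence(c(0.75, 0.25), c(0.25, 0.75)),
               js_oracle(c(0.75, 0.25), c(0.25, 0.75)), tolerance = 1e-15)
  # disjoint support attains the analytic maximum
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  expect_equal(js_distance(c(1, 0), c(0, 1)), sqrt(log(2)), tolerance = 1e-9)
  expect_equal(js_divergence(p <- random_density(3, 7), p), 0)
})

test_that("aggregate dataset distance: identity, symmetry, separation", {
  base <- zscore_dataset(small_fixtures()$base)
  water <- zscore_dataset(small_fixtures()$water4)
  # identity at full sampling is exactly zero
  d0 <- djs_bar(base, base, n_subsample = n_spectra(base), repeats = 2,
                seed = 5)
  expect_identical(d0$djs_bar, 0)
  # symmetry for full-size calls
  dab <- djs_bar(base, water, n_subsample = 1e6, repeats = 1, seed = 5)
  dba <- djs_bar(water, base, n_subsample = 1e6, repeats = 1, seed = 5)
  expect_equal(dab$djs_bar, dba$djs_bar, tolerance = 1e-12)
  expect_true(dab$djs_bar >= 0 && dab$djs_bar <= sqrt(log(2)))
  # a genuinely different dataset scores far above the split-half noise
  # floor (at sample sizes where the floor is histogram noise, not signal)
  v <- builtin_variants(n_spectra = 6000, seed = 55)
  big_base <- zscore_dataset(generate_dataset(v$BASE))
  big_water <- zscore_dataset(generate_dataset(v$WATER_4cm))
  half1 <- paox:::ds_take(big_base, 1:3000)
  half2 <- paox:::ds_take(big_base, 3001:6000)
  floor_score <- djs_bar(half1, half2, n_subsample = 1e6, repeats = 1,
                         seed = 5)$djs_bar
  sep <- djs_bar(big_base, big_water, n_subsample = 3000, repeats = 2,
                 seed = 5)$djs_bar
  expect_gt(sep, 3 * floor_score)
})

test_that("subsampling variability shrinks with subsample size", {
  cfg <- builtin_variants(n_spectra = 4000, seed = 21)
  a <- zscore_dataset(generate_dataset(cfg$BASE))
  b <- zscore_dataset(generate_dataset(cfg$SKIN))
  sd_small <- stats::sd(djs_bar(a, b, n_subsample = 300, repeats = 6,
                                seed = 3)$repeats)
  sd_big <- stats::sd(djs_bar(a, b, n_subsample = 3000, repeats = 6,
                              seed = 3)$repeats)
  expect_lt(sd_big, sd_small)
})

test_that("only the wavelength intersection enters the aggregate", {
  # wavelengths present in just one dataset must not affect the score:
  # mask them away after normalization and compare
  base <- zscore_dataset(small_fixtures()$base)
  keep <- evenly_spaced_wavelengths(15)
  t15 <- subset_wavelengths(zscore_dataset(small_fixtures()$skin), keep)
  r_full <- djs_bar(base, t15, n_subsample = 1e6, repeats = 1, seed = 2)
  r_restr <- djs_bar(subset_wavelengths(base, keep),
                     t15, n_subsample = 1e6, repeats = 1, seed = 2)
  expect_equal(r_full$djs_bar, r_restr$djs_bar, tolerance = 1e-12)
  expect_equal(r_full$n_lambda_used, 15L)
  # disjoint wavelength sets cannot be compared
  a1 <- zscore_dataset(subset_wavelengths(small_fixtures()$base,
                                          c(700, 705, 710)))
  a2 <- zscore_dataset(subset_wavelengths(small_fixtures()$skin,
                                          c(895, 900)))
  expect_error(djs_bar(a1, a2), "intersection")
})

test_that("candidate ranking puts the identity first and keeps stable ties", {
  base <- zscore_dataset(small_fixtures()$base)
  skin <- zscore_dataset(small_fixtures()$skin)
  water <- zscore_dataset(small_fixtures()$water4)
  rk <- rank_training_sets(base, list(WATER = water, BASE = base, SKIN = skin),
                           n_subsample = 400, repeats = 2, seed = 6)
  expect_equal(rk$candidate[1], "BASE")
  expect_lt(rk$djs_bar[1], 0.05)
  # identical candidates tie and keep input order
  rk2 <- rank_training_sets(base, list(first = skin, second = skin),
                            n_subsample = 1e6, repeats = 1, seed = 6)
  expect_equal(rk2$candidate, c("first", "second"))
  expect_equal(rk2$djs_bar[1], rk2$djs_bar[2])
  # a skin-like target selects the skin candidate
  skin2 <- zscore_dataset(generate_dataset(builtin_variants(n_spectra = 400,
                                                            seed = 77)$SKIN))
  rk3 <- rank_training_sets(skin2, list(BASE = base, SKIN = skin,
                                        WATER = water),
                            n_subsample = 400, repeats = 2, seed = 6)
  expect_equal(rk3$candidate[1], "SKIN")
})

test_that("Pearson correlation contract", {
  expect_equal(correlate_djs_error(1:5, 2 + 3 * (1:5)), 1.0)
  expect_equal(correlate_djs_error(1:5, rev(1:5)), -1.0)
  expect_equal(correlate_djs_error(c(0, 1, 2), c(1, 0, 1)), 0)
  expect_error(correlate_djs_error(rep(1, 4), 1:4), "constant")
  expect_error(correlate_djs_error(1:3, 1:4), "mismatch")
  expect_error(correlate_djs_error(1:2, 1:2), "at least 3")
})
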